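#' Per-nucleotide prediction profile
#'
#' Distributes the model margin over context positions: every feature
#' occurrence is rooted at a pair of vertices, and its weight-times-value
#' contribution is attributed in equal halves to the two roots (fully to
#' the root for self-pairs). Mass landing on reversed-copy vertices maps
#' back to the original context position; mass landing on abstract
#' structure-element vertices is divided equally among the element's
#' nucleotides, so the positionwise sum equals `margin - bias` exactly.
#'
#' @param model A `graphrbp_model` (or fitted [graphrbp()] object).
#' @param graph The site's `annotated_graph`, encoded with the model's
#'   parameters.
#' @return Numeric vector of length `context` with the per-position margin
#'   contributions.
#' @export
nucleotide_profile <- function(model, graph) {
  if (inherits(model, "graphrbp")) model <- model$model
  ex <- extract_features(graph, model$kernel, normalize = TRUE,
                         occurrences = TRUE)
  n_ctx <- graph$n_context
  if (!length(ex$key_val)) return(numeric(n_ctx))
  mw <- model$w[match(ex$key_id, model$ids)]
  mw[is.na(mw)] <- 0
  contrib <- mw * ex$key_val / ex$key_count
  cc <- contrib[ex$occ_key]
  self <- ex$occ_u == ex$occ_v
  nv <- nrow(graph$vertices)
  mass <- numeric(nv)
  mu <- rowsum(c(ifelse(self, cc, cc / 2), ifelse(self, 0, cc / 2)),
               c(ex$occ_u, ex$occ_v))
  mass[as.integer(rownames(mu))] <- mu[, 1L]
  v <- graph$vertices
  prof <- numeric(n_ctx)
  isn <- v$kind == "nucleotide" & mass != 0
  if (any(isn)) {
    pm <- rowsum(mass[isn], v$position[isn])
    prof[as.integer(rownames(pm))] <- pm[, 1L]
  }
  # abstract-element mass: spread over member nucleotides via relation links
  isa <- v$kind == "abstract_element" & mass != 0
  if (any(isa)) {
    e <- graph$edges
    rl <- e[e$label == "relation_link", , drop = FALSE]
    kind_of <- v$kind[order(v$id)]      # ids are 1..nv in order
    a_end <- ifelse(kind_of[rl$src] == "abstract_element", rl$src,
                    ifelse(kind_of[rl$dst] == "abstract_element", rl$dst, NA))
    r_end <- ifelse(kind_of[rl$src] == "relation", rl$src, rl$dst)
    n_end <- ifelse(kind_of[rl$src] == "nucleotide", rl$src,
                    ifelse(kind_of[rl$dst] == "nucleotide", rl$dst, NA))
    abs_of_rel <- setNames(a_end[!is.na(a_end)], r_end[!is.na(a_end)])
    nuc <- !is.na(n_end)
    owner_abs <- abs_of_rel[as.character(r_end[nuc])]
    nuc_pos <- v$position[n_end[nuc]]
    for (aid in which(isa)) {
      sel <- which(owner_abs == aid)
      if (!length(sel)) next
      pp <- nuc_pos[sel]
      prof[pp] <- prof[pp] + mass[aid] / length(pp)
    }
  }
  prof
}

#' Sliding-window binding scores from a profile
#'
#' Binding scores averaged over all `w`-nucleotide windows (step 1).
#'
#' @param profile Numeric per-nucleotide profile.
#' @param w Window size. Default 12.
#' @return Data frame with `start` (1-based) and `score` (window mean);
#'   empty when the profile is shorter than `w`.
#' @export
window_scores <- function(profile, w = 12L) {
  n <- length(profile)
  if (n < w) return(data.frame(start = integer(0), score = numeric(0)))
  cs <- c(0, cumsum(profile))
  starts <- seq_len(n - w + 1L)
  data.frame(start = starts, score = (cs[starts + w] - cs[starts]) / w)
}

#' Call high-affinity sites from windowed scores
#'
#' Selects the `top_fraction` highest-scoring windows over the whole
#' collection (ties broken by sequence id then position, stable), then
#' merges overlapping and directly abutting selected windows on the same
#' sequence into sites scored by their best member window.
#'
#' @param windows Data frame with columns `seqname`, `start`, `score`
#'   (e.g. stacked [window_scores()] results over many UTRs).
#' @param w Window size used to produce the scores. Default 12.
#' @param top_fraction Fraction of windows to keep. Default 0.01.
#' @return Data frame of merged sites: `seqname`, `start`, `end`, `score`;
#'   intervals are disjoint and non-abutting.
#' @export
call_sites <- function(windows, w = 12L, top_fraction = 0.01) {
  stopifnot(nrow(windows) >= 1L)
  n_top <- ceiling(top_fraction * nrow(windows))
  o <- order(-windows$score, windows$seqname, windows$start)
  sel <- windows[o[seq_len(n_top)], , drop = FALSE]
  sel$end <- sel$start + w - 1L
  sel <- sel[order(sel$seqname, sel$start), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(sel))) {
    row <- sel[i, ]
    if (!is.null(cur) && row$seqname == cur$seqname &&
        row$start <= cur$end + 1L) {
      cur$end <- max(cur$end, row$end)
      cur$score <- max(cur$score, row$score)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- row[, c("seqname", "start", "end", "score")]
    }
  }
  out[[length(out) + 1L]] <- cur
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract sequence and structure binding motifs
#'
#' For each folding hypothesis of each bound site, computes the
#' hypothesis-restricted per-nucleotide profile, takes the highest-scoring
#' `k`-mer inside the viewpoint (score = average margin per nucleotide),
#' and records its nucleotide sequence together with its structure-profile
#' string over `{S,E,H,I,M,B}`. The `top_n` highest-scoring `k`-mers are
#' pooled into column-normalized sequence (4 x k) and structure (6 x k)
#' frequency matrices, ready for logo rendering.
#'
#' @param model A fitted [graphrbp()] object (its mode decides whether
#'   hypotheses are folded), or a `graphrbp_model` plus explicit `mode`.
#' @param sites Bound `target_sites` (at most `max_sites` are used).
#' @param k Motif width. Default 12.
#' @param top_n Number of top k-mers pooled. Default 1000.
#' @param max_sites Soft cap on sites scored. Default 2000.
#' @param mode,folding,backend Overrides when `model` is a bare
#'   `graphrbp_model`.
#' @return An `rbp_motif`: `kmers` (data frame sorted by score descending),
#'   `sequence_matrix`, `structure_matrix`, `k`.
#' @export
extract_motif <- function(model, sites, k = 12L, top_n = 1000L,
                          max_sites = 2000L, mode = NULL,
                          folding = folding_params(),
                          backend = built_in_backend()) {
  if (inherits(model, "graphrbp")) {
    mode <- model$mode; folding <- model$folding; model_obj <- model$model
  } else {
    model_obj <- model
    if (is.null(mode)) mode <- "sequence"
  }
  sites <- head(sites, max_sites)
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(sites))) {
    st <- sites[i, ]
    if (st$vp_end - st$vp_start + 1L < k) { skipped <- skipped + 1L; next }
    ctx_len <- nchar(st$context)
    hyps <- if (mode == "structure") {
      fold_context(st$context, folding, backend)
    } else list(NULL)
    for (h in hyps) {
      if (is.null(h)) {
        g <- encode_sequence_only(st)
        els <- rep("E", ctx_len)
      } else {
        g <- encode_with_structure(st, list(h))
        els <- rep("E", ctx_len)
        wlen <- h$window[2L] - h$window[1L] + 1L
        pr <- h$pairs
        if (nrow(pr)) pr <- pr - (h$window[1L] - 1L)
        els[seq.int(h$window[1L], h$window[2L])] <-
          structure_elements(pr, wlen)
      }
      prof <- nucleotide_profile(model_obj, g)
      starts <- seq.int(st$vp_start, st$vp_end - k + 1L)
      cs <- c(0, cumsum(prof))
      sc <- (cs[starts + k] - cs[starts]) / k
      best <- starts[which.max(sc)]
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = st$site_id, start = best,
        seq = substr(st$context, best, best + k - 1L),
        struct = paste(els[seq.int(best, best + k - 1L)], collapse = ""),
        score = max(sc), stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) {
    warning(skipped, " site(s) skipped: viewpoint shorter than k")
  }
  if (!length(rows)) stop("no usable sites for motif extraction")
  km <- do.call(rbind, rows)
  km <- km[order(-km$score), , drop = FALSE]   # stable: input order on ties
  km <- head(km, top_n)
  rownames(km) <- NULL
  count_matrix <- function(strings, alphabet) {
    m <- matrix(0, nrow = length(alphabet), ncol = k,
                dimnames = list(alphabet, NULL))
    ch <- do.call(rbind, strsplit(strings, ""))
    for (j in seq_len(k)) {
      tb <- table(factor(ch[, j], levels = alphabet))
      m[, j] <- as.numeric(tb)
    }
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2L, cs, "/")
  }
  structure(list(kmers = km,
                 sequence_matrix = count_matrix(km$seq, c("A", "C", "G", "U")),
                 structure_matrix = count_matrix(km$struct,
                                                 c("S", "E", "H", "I", "M", "B")),
                 k = as.integer(k)),
            class = "rbp_motif")
}

#' @export
print.rbp_motif <- function(x, ...) {
  cat("RBP binding motif (", nrow(x$kmers), " ", x$k, "-mers)\n", sep = "")
  cat("  consensus (sequence): ",
      paste(rownames(x$sequence_matrix)[apply(x$sequence_matrix, 2L,
                                              which.max)], collapse = ""),
      "\n  consensus (structure): ",
      paste(rownames(x$structure_matrix)[apply(x$structure_matrix, 2L,
                                               which.max)], collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Plot motif frequency matrices
#' @param x An `rbp_motif`.
#' @param which `"sequence"` or `"structure"`.
#' @param ... Passed to `barplot`.
#' @export
plot.rbp_motif <- function(x, which = c("sequence", "structure"), ...) {
  which <- match.arg(which)
  m <- if (which == "sequence") x$sequence_matrix else x$structure_matrix
  graphics::barplot(m, names.arg = seq_len(ncol(m)), legend.text = TRUE,
                    xlab = "motif position", ylab = "frequency",
                    main = paste(which, "motif"), ...)
  invisible(x)
}

#' Write motif outputs: top k-mers and TRANSFAC-like matrices
#'
#' `<prefix>_kmers.txt` holds one k-mer per line (WebLogo-ready);
#' `<prefix>_seq_matrix.txt` and `<prefix>_struct_matrix.txt` hold the
#' column frequency matrices.
#'
#' @param motif An `rbp_motif`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_motif <- function(motif, prefix) {
  paths <- paste0(prefix, c("_kmers.txt", "_seq_matrix.txt",
                            "_struct_matrix.txt"))
  writeLines(motif$kmers$seq, paths[1L])
  write_mat <- function(m, path) {
    df <- data.frame(PO = seq_len(ncol(m)), t(m), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(motif$sequence_matrix, paths[2L])
  write_mat(motif$structure_matrix, paths[3L])
  invisible(paths)
}

#' Write per-nucleotide profiles as bedGraph-style TSV
#'
#' @param profiles Named list of numeric profiles (names = sequence ids).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(seqname = id, start = seq_along(p) - 1L,
               end = seq_along(p), value = p)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
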