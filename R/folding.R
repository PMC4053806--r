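#' Enumerate folding windows over a context
#'
#' Sliding windows of `window_len` nucleotides with step `step`, clipped to
#' the context; a final window ending exactly at the context end is appended
#' when the regular grid does not already reach it, so every position is
#' covered by at least one window.
#'
#' @param context_len Context length in nucleotides.
#' @param params A [folding_params()] object.
#' @return Integer matrix with columns `start`, `end` (1-based, closed).
#' @export
enumerate_windows <- function(context_len, params = folding_params()) {
  context_len <- as.integer(context_len)
  stopifnot(context_len >= 1L)
  w <- params$window_len; s <- params$step
  if (context_len <= w) {
    return(cbind(start = 1L, end = context_len))
  }
  starts <- seq.int(1L, context_len - w + 1L, by = s)
  ends <- starts + w - 1L
  if (ends[length(ends)] < context_len) {
    starts <- c(starts, context_len - w + 1L)
    ends <- c(ends, context_len)
  }
  cbind(start = as.integer(starts), end = as.integer(ends))
}

#' Built-in folding backend
#'
#' A deterministic secondary-structure folder: Nussinov-style dynamic
#' program with a stacking-aware score, plus exact best-first enumeration of
#' suboptimal structures within an energy threshold. Every pair pays an
#' opening penalty `p_open`; each directly stacked pair earns a bonus equal
#' to minus the mean strength of the two pairs (GC/AU/GU strengths). With
#' the defaults an isolated pair is never favorable — the "no lonely pairs"
#' behavior of thermodynamic folders — while helices gain roughly
#' `-(strength - p_open)` per stacked pair. Energies are in arbitrary
#' units. With `pair_count = TRUE` every allowed pair scores -1 with no
#' stacking term, so `-MFE` equals the maximum number of pairs (the plain
#' Nussinov objective, used for oracle comparisons).
#'
#' @param p_open Helix-opening penalty per pair. Default 1.5.
#' @param s_gc,s_au,s_gu Pair strengths. Defaults 4.5, 3.5, 2.5.
#' @param min_loop Minimum hairpin loop size. Default 3.
#' @param pair_count Use the pure pair-counting score. Default `FALSE`.
#' @return A `fold_backend` object.
#' @export
built_in_backend <- function(p_open = 1.5, s_gc = 4.5, s_au = 3.5,
                             s_gu = 2.5, min_loop = 3L, pair_count = FALSE) {
  if (pair_count) { p_open <- -1; s_gc <- s_au <- s_gu <- 0 }
  fold <- function(seq, energy_band, max_enum) {
    probe <- .fold_enumerate(seq, 1e18, 1L, p_open, s_gc, s_au, s_gu,
                             as.integer(min_loop))
    mfe <- probe$mfe
    thr <- if (mfe < 0) (1 - energy_band) * mfe else mfe
    res <- .fold_enumerate(seq, thr, as.integer(max_enum),
                           p_open, s_gc, s_au, s_gu, as.integer(min_loop))
    list(mfe = mfe, pairs = res$pairs, energy = res$energy)
  }
  structure(list(fold = fold, name = "built_in"), class = "fold_backend")
}

#' External folding backend via ViennaRNA RNAsubopt
#'
#' Shells out to `RNAsubopt` to enumerate suboptimal structures within the
#' energy band (kcal/mol). Shapes are computed in-package from the returned
#' dot-bracket strings.
#'
#' @param rnasubopt Name or path of the `RNAsubopt` executable.
#' @return A `fold_backend` object.
#' @export
viennarna_backend <- function(rnasubopt = "RNAsubopt") {
  fold <- function(seq, energy_band, max_enum) {
    if (Sys.which(rnasubopt) == "") stop("RNAsubopt executable not found")
    out <- suppressWarnings(
      system2(rnasubopt, args = c("-e", "1", "--noconv"),
              input = seq, stdout = TRUE, stderr = FALSE))
    parse1 <- parse_subopt(out)
    if (!length(parse1$energy)) stop("RNAsubopt returned no structures")
    mfe <- min(parse1$energy)
    band_kcal <- max(0.01, abs(mfe) * energy_band)
    out <- suppressWarnings(
      system2(rnasubopt, args = c("-e", format(band_kcal), "--noconv"),
              input = seq, stdout = TRUE, stderr = FALSE))
    ps <- parse_subopt(out)
    thr <- if (mfe < 0) (1 - energy_band) * mfe else mfe
    keep <- ps$energy <= thr + 1e-6
    o <- order(ps$energy[keep])
    o <- o[seq_len(min(length(o), max_enum))]
    list(mfe = mfe,
         pairs = lapply(ps$db[keep][o], db_to_pairs),
         energy = ps$energy[keep][o])
  }
  structure(list(fold = fold, name = "viennarna"), class = "fold_backend")
}

parse_subopt <- function(lines) {
  hit <- grepl("^[.()]+\\s+-?[0-9.]+", lines)
  parts <- strsplit(trimws(lines[hit]), "\\s+")
  list(db = vapply(parts, `[`, character(1), 1L),
       energy = as.numeric(vapply(parts, `[`, character(1), 2L)))
}

#' Convert dot-bracket notation to a base-pair matrix
#' @param db Dot-bracket string.
#' @return Integer matrix with columns `i`, `j` (1-based, `i < j`).
#' @export
db_to_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0); out <- NULL
  for (p in seq_along(ch)) {
    if (ch[p] == "(") stack <- c(stack, p)
    else if (ch[p] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket string")
      out <- rbind(out, c(stack[length(stack)], p))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  if (is.null(out)) out <- matrix(integer(0), ncol = 2)
  colnames(out) <- c("i", "j")
  out[order(out[, 1L]), , drop = FALSE]
}

#' Convert a base-pair matrix to dot-bracket notation
#' @param pairs Integer matrix with columns `i`, `j`.
#' @param len Sequence length.
#' @return Dot-bracket string.
#' @export
pairs_to_db <- function(pairs, len) {
  ch <- rep(".", len)
  if (nrow(pairs)) { ch[pairs[, 1L]] <- "("; ch[pairs[, 2L]] <- ")" }
  paste(ch, collapse = "")
}

# helices: maximal runs of directly stacked pairs
# returns data.frame(outer_i, outer_j, inner_i, inner_j, id) sorted by outer_i
find_helices <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(outer_i = integer(0), outer_j = integer(0),
                      inner_i = integer(0), inner_j = integer(0)))
  }
  p <- pairs[order(pairs[, 1L]), , drop = FALSE]
  key <- paste(p[, 1L], p[, 2L])
  has_outer <- paste(p[, 1L] - 1L, p[, 2L] + 1L) %in% key
  starts <- which(!has_outer)
  out <- lapply(starts, function(s) {
    i <- p[s, 1L]; j <- p[s, 2L]
    ii <- i; jj <- j
    while (paste(ii + 1L, jj - 1L) %in% key) { ii <- ii + 1L; jj <- jj - 1L }
    data.frame(outer_i = i, outer_j = j, inner_i = ii, inner_j = jj)
  })
  h <- do.call(rbind, out)
  h[order(h$outer_i), , drop = FALSE]
}

# parent helix of each helix (NA = external); helices sorted by outer_i
helix_parents <- function(h) {
  n <- nrow(h)
  parent <- rep(NA_integer_, n)
  stack <- integer(0)
  for (q in seq_len(n)) {
    while (length(stack) &&
           !(h$outer_i[q] > h$inner_i[stack[length(stack)]] &&
             h$outer_j[q] < h$inner_j[stack[length(stack)]])) {
      stack <- stack[-length(stack)]
    }
    if (length(stack)) parent[q] <- stack[length(stack)]
    stack <- c(stack, q)
  }
  parent
}

#' Abstract shape of a secondary structure
#'
#' Computes the shape string of a structure at a given abstraction level.
#' Stem lengths are always ignored (a helix is one `[]` regardless of
#' length). Level 5 keeps the helix arrangement only, merging helices
#' separated by internal loops or bulges; level 3 keeps those helix breaks;
#' level 1 additionally records unpaired stretches as `_`. A structure
#' without pairs has shape `"_"` at every level.
#'
#' @param pairs Integer matrix with columns `i`, `j` (1-based).
#' @param len Sequence length.
#' @param level Abstraction level: 1, 3 or 5.
#' @return Shape string.
#' @export
shape_string <- function(pairs, len, level = 3L) {
  stopifnot(level %in% c(1L, 3L, 5L))
  if (!nrow(pairs)) return("_")
  h <- find_helices(pairs)
  parent <- helix_parents(h)
  children_of <- function(q) which(!is.na(parent) & parent == q)
  render <- function(idx, a, b) {
    # idx: helices directly inside interval [a, b], in order
    parts <- character(0)
    pos <- a
    for (q in idx) {
      if (level == 1L && h$outer_i[q] > pos) parts <- c(parts, "_")
      if (level == 5L) {
        qq <- q
        repeat {
          ch <- children_of(qq)
          if (length(ch) != 1L) break
          qq <- ch
        }
        inner <- render(children_of(qq), h$inner_i[qq] + 1L, h$inner_j[qq] - 1L)
      } else {
        inner <- render(children_of(q), h$inner_i[q] + 1L, h$inner_j[q] - 1L)
      }
      parts <- c(parts, paste0("[", inner, "]"))
      pos <- h$outer_j[q] + 1L
    }
    if (level == 1L && pos <= b) parts <- c(parts, "_")
    paste(parts, collapse = "")
  }
  top <- which(is.na(parent))
  render(top, 1L, len)
}

#' Assign structure elements to positions
#'
#' Standard loop decomposition: paired positions are stems (S); unpaired
#' positions are classified by their innermost enclosing pair as hairpin
#' (H), internal loop (I), bulge (B), multiloop (M), or external (E) when no
#' pair encloses them.
#'
#' @param pairs Integer matrix with columns `i`, `j` (1-based).
#' @param len Sequence length.
#' @return Character vector of length `len` over `{S,E,H,I,M,B}`.
#' @export
structure_elements <- function(pairs, len) {
  el <- rep("E", len)
  if (!nrow(pairs)) return(el)
  partner <- integer(len)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  el[partner > 0L] <- "S"
  # direct children of each pair, and the enclosing pair of each position
  p <- pairs[order(pairs[, 1L]), , drop = FALSE]
  enclosing <- rep(0L, len)             # index into p, 0 = external
  nchild <- rep(0L, nrow(p))
  child1 <- rep(0L, nrow(p))            # a direct child (if exactly one)
  stack <- integer(0)
  pos_open <- integer(len); pos_open[p[, 1L]] <- seq_len(nrow(p))
  pos_close <- integer(len); pos_close[p[, 2L]] <- seq_len(nrow(p))
  for (x in seq_len(len)) {
    if (pos_open[x] > 0L) {
      q <- pos_open[x]
      if (length(stack)) {
        par <- stack[length(stack)]
        nchild[par] <- nchild[par] + 1L
        child1[par] <- q
      }
      stack <- c(stack, q)
    } else if (pos_close[x] > 0L) {
      stack <- stack[-length(stack)]
    } else {
      enclosing[x] <- if (length(stack)) stack[length(stack)] else 0L
    }
  }
  unp <- which(partner == 0L)
  for (x in unp) {
    q <- enclosing[x]
    if (q == 0L) next
    if (nchild[q] == 0L) el[x] <- "H"
    else if (nchild[q] >= 2L) el[x] <- "M"
    else {
      cc <- child1[q]
      left <- p[cc, 1L] - p[q, 1L] - 1L
      right <- p[q, 2L] - p[cc, 2L] - 1L
      el[x] <- if (left > 0L && right > 0L) "I" else "B"
    }
  }
  el
}

#' Select shape representatives (shreps) among candidate structures
#'
#' Applies the shrep rule: candidates outside the energy band relative to
#' the window MFE are dropped (for negative MFE, retain `E <= (1 - band) *
#' MFE`; for non-negative MFE only the MFE structure); among candidates of
#' identical shape only the lowest-energy one is kept; at most `max_shreps`
#' survive, sorted by energy so the MFE structure is always first.
#'
#' @param energies Numeric candidate energies.
#' @param shapes Character candidate shapes (at the working abstraction).
#' @param mfe Window minimum free energy.
#' @param energy_band Band fraction (see [folding_params()]).
#' @param max_shreps Maximum representatives kept.
#' @return Integer indices of the selected candidates, energy ascending.
#' @export
select_shreps <- function(energies, shapes, mfe, energy_band = 0.10,
                          max_shreps = 3L) {
  thr <- if (mfe < 0) (1 - energy_band) * mfe else mfe
  ok <- which(energies <= thr + 1e-9)
  ok <- ok[order(energies[ok])]
  ok <- ok[!duplicated(shapes[ok])]
  head(ok, max_shreps)
}

#' Fold one window into structure hypotheses
#'
#' Runs the folding backend on a window sequence and reduces the candidate
#' structures to at most `max_shreps` shape representatives within the
#' energy band (see [select_shreps()]).
#'
#' @param seq_window RNA string of the window.
#' @param params A [folding_params()] object.
#' @param backend A `fold_backend`; default [built_in_backend()].
#' @return List of `structure_hypothesis` objects, each with fields
#'   `window` (set to the window span by [fold_context()]), `pairs`
#'   (window-relative, 1-based), `shape`, `energy`.
#' @export
fold_window <- function(seq_window, params = folding_params(),
                        backend = built_in_backend()) {
  stopifnot(nzchar(seq_window))
  res <- backend$fold(seq_window, params$energy_band, params$max_enum)
  len <- nchar(seq_window)
  shapes <- vapply(res$pairs, shape_string, character(1), len = len,
                   level = params$abstraction)
  sel <- select_shreps(res$energy, shapes, res$mfe, params$energy_band,
                       params$max_shreps)
  lapply(sel, function(q) {
    structure(list(window = c(1L, len), pairs = res$pairs[[q]],
                   shape = shapes[q], energy = res$energy[q]),
              class = "structure_hypothesis")
  })
}

#' Fold a full context with sliding windows
#'
#' Enumerates windows over the context ([enumerate_windows()]), folds each
#' one ([fold_window()]) and returns all structure hypotheses with pairs and
#' window spans lifted to context coordinates.
#'
#' @param context RNA string of the extended site.
#' @param params A [folding_params()] object.
#' @param backend A `fold_backend`.
#' @return List of `structure_hypothesis` objects in context coordinates.
#' @export
fold_context <- function(context, params = folding_params(),
                         backend = built_in_backend()) {
  win <- enumerate_windows(nchar(context), params)
  out <- list()
  for (q in seq_len(nrow(win))) {
    ws <- win[q, 1L]; we <- win[q, 2L]
    hyps <- tryCatch(
      fold_window(substr(context, ws, we), params, backend),
      error = function(e) stop("folding failed in window [", ws, ",", we,
                               "]: ", conditionMessage(e)))
    for (h in hyps) {
      h$window <- c(ws, we)
      if (nrow(h$pairs)) h$pairs <- h$pairs + (ws - 1L)
      out[[length(out) + 1L]] <- h
    }
  }
  out
}
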