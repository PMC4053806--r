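# Annotated directed (hyper)graph encoding of a target site.
#
# Vertices: nucleotides (kind "nucleotide", label = base), abstract structure
# elements (kind "abstract_element", label in S/E/H/I/M/B), and relation
# vertices (kind "relation") linking each abstract element to its nucleotides
# through non-traversable "relation_link" edges. Edge directions: backbone
# 5'->3', base pairs from the 5'-side nucleotide to the 3'-side one, abstract
# adjacency from the element nearer the external region toward more deeply
# nested elements (multiloops -> hairpins). The whole graph is then
# duplicated with inverted edges and labels prefixed "r", so that features
# remain direction-discriminative in both readings.

new_graph_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$v <- list(); env$e <- list(); env$nv <- 0L
  env
}

gb_add_vertices <- function(gb, label, kind, position, viewpoint) {
  n <- length(label)
  ids <- gb$nv + seq_len(n)
  gb$v[[length(gb$v) + 1L]] <- data.frame(
    id = ids, label = label, kind = kind,
    position = as.integer(position), viewpoint = viewpoint,
    stringsAsFactors = FALSE)
  gb$nv <- gb$nv + n
  ids
}

gb_add_edges <- function(gb, src, dst, label, traversable = TRUE) {
  if (!length(src)) return(invisible(NULL))
  gb$e[[length(gb$e) + 1L]] <- data.frame(
    src = src, dst = dst, label = label, traversable = traversable,
    stringsAsFactors = FALSE)
  invisible(NULL)
}

# one structure component: nucleotide path + base pairs + abstract layer
add_structure_component <- function(gb, chars, positions, vp, pairs_rel) {
  len <- length(chars)
  nid <- gb_add_vertices(gb, chars, "nucleotide", positions, vp)
  if (len > 1L) {
    gb_add_edges(gb, nid[-len], nid[-1L], "backbone")
  }
  if (nrow(pairs_rel)) {
    gb_add_edges(gb, nid[pairs_rel[, 1L]], nid[pairs_rel[, 2L]], "basepair")
  }
  el <- structure_elements(pairs_rel, len)
  # abstract elements: one S per helix (both strands), one vertex per
  # contiguous run of equal loop/external letters
  members <- list(); lab <- character(0)
  h <- find_helices(pairs_rel)
  helix_of_abs <- integer(0)   # abstract index per helix row
  for (q in seq_len(nrow(h))) {
    m <- c(seq.int(h$outer_i[q], h$inner_i[q]),
           seq.int(h$inner_j[q], h$outer_j[q]))
    members[[length(members) + 1L]] <- m
    lab <- c(lab, "S")
    helix_of_abs[q] <- length(members)
  }
  unp_letter <- el
  unp_letter[el == "S"] <- NA
  run_of_pos <- rep(NA_integer_, len)
  r <- rle(unp_letter)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  for (q in seq_along(r$values)) {
    if (is.na(r$values[q])) next
    m <- seq.int(starts[q], stops[q])
    members[[length(members) + 1L]] <- m
    lab <- c(lab, r$values[q])
    run_of_pos[m] <- length(members)
  }
  n_abs <- length(members)
  if (n_abs) {
    vp_abs <- vapply(members, function(m) any(vp[m]), logical(1))
    aid <- gb_add_vertices(gb, lab, "abstract_element", NA_integer_, vp_abs)
    # abstract adjacency from the helix perspective
    es <- integer(0); ed <- integer(0)
    helix_at <- rep(NA_integer_, len)
    for (q in seq_len(nrow(h))) helix_at[members[[helix_of_abs[q]]]] <- q
    for (q in seq_len(nrow(h))) {
      me <- helix_of_abs[q]
      for (p in c(h$outer_i[q] - 1L, h$outer_j[q] + 1L)) {   # outer side
        if (p < 1L || p > len) next
        if (!is.na(run_of_pos[p])) {
          es <- c(es, run_of_pos[p]); ed <- c(ed, me)
        } else if (!is.na(helix_at[p])) {
          hp <- helix_at[p]
          if (h$outer_i[hp] < h$outer_i[q] && h$outer_j[hp] > h$outer_j[q]) {
            es <- c(es, helix_of_abs[hp]); ed <- c(ed, me)
          }
        }
      }
      for (p in c(h$inner_i[q] + 1L, h$inner_j[q] - 1L)) {   # inner side
        if (p < 1L || p > len) next
        if (!is.na(run_of_pos[p])) {
          es <- c(es, me); ed <- c(ed, run_of_pos[p])
        } else if (!is.na(helix_at[p])) {
          hc <- helix_at[p]
          if (h$outer_i[hc] > h$outer_i[q] && h$outer_j[hc] < h$outer_j[q]) {
            es <- c(es, me); ed <- c(ed, helix_of_abs[hc])
          }
        }
      }
    }
    if (length(es)) {
      keep <- !duplicated(paste(es, ed))
      gb_add_edges(gb, aid[es[keep]], aid[ed[keep]], "abstract_adjacency")
    }
    # relation vertices, non-traversable links
    rid <- gb_add_vertices(gb, rep("REL", n_abs), "relation", NA_integer_,
                           FALSE)
    gb_add_edges(gb, aid, rid, "relation_link", traversable = FALSE)
    for (q in seq_len(n_abs)) {
      gb_add_edges(gb, rep(rid[q], length(members[[q]])),
                   nid[members[[q]]], "relation_link", traversable = FALSE)
    }
  }
  invisible(NULL)
}

finish_graph <- function(gb, n_context, mirror = TRUE) {
  v <- do.call(rbind, gb$v)
  e <- if (length(gb$e)) do.call(rbind, gb$e)
       else data.frame(src = integer(0), dst = integer(0),
                       label = character(0), traversable = logical(0),
                       stringsAsFactors = FALSE)
  v$copy <- "main"
  if (mirror) {
    n <- nrow(v)
    v2 <- v
    v2$id <- v$id + n
    v2$label <- paste0("r", v$label)
    v2$copy <- "rev"
    e2 <- e
    e2$src <- e$dst + n
    e2$dst <- e$src + n
    v <- rbind(v, v2)
    e <- rbind(e, e2)
  }
  rownames(v) <- rownames(e) <- NULL
  structure(list(vertices = v, edges = e, n_context = n_context),
            class = "annotated_graph")
}

#' Encode a target site as a sequence-only graph
#'
#' Path graph over the context nucleotides with backbone edges in 5'->3'
#' direction, plus the reversed relabeled copy; secondary structure is
#' ignored entirely.
#'
#' @param site One row of a `target_sites` data frame (or a list with
#'   `context`, `vp_start`, `vp_end`).
#' @param mirror Add the reversed relabeled copy. Default `TRUE` (the
#'   `FALSE` setting exists for direction-sensitivity controls).
#' @return An `annotated_graph`.
#' @export
encode_sequence_only <- function(site, mirror = TRUE) {
  ctx <- site$context
  len <- nchar(ctx)
  stopifnot(len >= 1L, site$vp_start >= 1L, site$vp_end >= site$vp_start,
            site$vp_end <= len)
  chars <- strsplit(ctx, "")[[1]]
  vp <- seq_len(len) >= site$vp_start & seq_len(len) <= site$vp_end
  gb <- new_graph_builder()
  nid <- gb_add_vertices(gb, chars, "nucleotide", seq_len(len), vp)
  if (len > 1L) gb_add_edges(gb, nid[-len], nid[-1L], "backbone")
  finish_graph(gb, len, mirror)
}

#' Encode a target site with structure hypotheses
#'
#' Each structure hypothesis (shrep) becomes one connected component holding
#' the nucleotides of its folding window, backbone and base-pair edges, the
#' abstract structure-element layer (S/E/H/I/M/B vertices joined by
#' outer-to-inner abstract adjacency edges), and non-traversable relation
#' vertices linking each element to its nucleotides. The multi-component
#' graph is then duplicated, reversed and prefixed as in
#' [encode_sequence_only()], so one site yields a single feature vector
#' accumulated over all plausible structures.
#'
#' @param site One row of a `target_sites` data frame.
#' @param hypotheses List of `structure_hypothesis` (context coordinates),
#'   e.g. from [fold_context()].
#' @param mirror Add the reversed relabeled copy. Default `TRUE`.
#' @return An `annotated_graph`.
#' @export
encode_with_structure <- function(site, hypotheses, mirror = TRUE) {
  ctx <- site$context
  len <- nchar(ctx)
  stopifnot(len >= 1L, site$vp_start >= 1L, site$vp_end >= site$vp_start,
            site$vp_end <= len, length(hypotheses) >= 1L)
  chars <- strsplit(ctx, "")[[1]]
  vp_all <- seq_len(len) >= site$vp_start & seq_len(len) <= site$vp_end
  gb <- new_graph_builder()
  for (h in hypotheses) {
    ws <- h$window[1L]; we <- h$window[2L]
    if (ws < 1L || we > len) stop("hypothesis window outside context")
    if (nrow(h$pairs) && (min(h$pairs) < ws || max(h$pairs) > we)) {
      stop("hypothesis has base pairs outside its window")
    }
    idx <- seq.int(ws, we)
    pr <- h$pairs
    if (nrow(pr)) pr <- pr - (ws - 1L)
    add_structure_component(gb, chars[idx], idx, vp_all[idx], pr)
  }
  finish_graph(gb, len, mirror)
}

#' Encode a target site
#'
#' Dispatches to [encode_sequence_only()] or [encode_with_structure()].
#'
#' @param site One row of a `target_sites` data frame.
#' @param mode `"sequence"` or `"structure"`.
#' @param folding [folding_params()] (structure mode).
#' @param backend Folding backend (structure mode).
#' @param hypotheses Optional precomputed hypotheses (structure mode).
#' @return An `annotated_graph`.
#' @export
encode_site <- function(site, mode = c("sequence", "structure"),
                        folding = folding_params(),
                        backend = built_in_backend(), hypotheses = NULL) {
  mode <- match.arg(mode)
  if (mode == "sequence") return(encode_sequence_only(site))
  if (is.null(hypotheses)) {
    hypotheses <- fold_context(site$context, folding, backend)
  }
  encode_with_structure(site, hypotheses)
}

#' Write a line-based text dump of an annotated graph
#'
#' One `V` line per vertex (`id label kind position viewpoint copy`) and one
#' `E` line per edge (`src dst label traversable`), for debugging and for
#' external oracles.
#'
#' @param graph An `annotated_graph`.
#' @param con Connection or file path.
#' @return Invisibly, the lines written.
#' @export
write_graph_dump <- function(graph, con = stdout()) {
  v <- graph$vertices; e <- graph$edges
  lines <- c(
    sprintf("V\t%d\t%s\t%s\t%s\t%d\t%s", v$id, v$label, v$kind,
            ifelse(is.na(v$position), ".", v$position),
            as.integer(v$viewpoint), v$copy),
    sprintf("E\t%d\t%d\t%s\t%d", e$src, e$dst, e$label,
            as.integer(e$traversable)))
  writeLines(lines, con)
  invisible(lines)
}
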