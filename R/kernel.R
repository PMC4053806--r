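#' Extract NSPD-kernel features from an annotated graph
#'
#' Explicit feature map of the neighborhood-subgraph-pairwise-distance
#' kernel with the hypergraph, direction and viewpoint extensions: for every
#' ordered pair of roots of the same feature set (ground or abstract) at
#' directed shortest-path distance `d <= D` over traversable edges and every
#' radius r <= R, a feature pairs the canonical labels of the two
#' neighborhood subgraphs; additionally, hybrid features pair the abstract
#' and nucleotide endpoints of every relation (hyperedge) vertex. Pairs are
#' only counted when at least one root (for hybrid: the nucleotide endpoint)
#' lies in the viewpoint. Counts are normalized to unit Euclidean norm
#' within each `(r, d, feature-set)` block and the concatenation is scaled
#' to unit norm, so no block dominates.
#'
#' @param graph An `annotated_graph`.
#' @param params A [kernel_params()] object.
#' @param normalize Apply block + global normalization. Default `TRUE`.
#' @param occurrences Also return the individual feature occurrences (root
#'   vertex pairs), needed for per-nucleotide profiles. Default `FALSE`.
#' @return A `sparse_fv` object: `ids` (hashed integer indices, or canonical
#'   key strings in exact mode), `val`, and the parameter fingerprint. With
#'   `occurrences = TRUE` also per-key tables and occurrence triples.
#' @export
extract_features <- function(graph, params = kernel_params(),
                             normalize = TRUE, occurrences = FALSE) {
  v <- graph$vertices; e <- graph$edges
  kind_i <- match(v$kind, c("nucleotide", "abstract_element", "relation")) - 1L
  raw <- .nspdk_extract(v$label, kind_i, v$viewpoint,
                        e$src, e$dst, e$label, e$traversable,
                        params$R, params$D, params$bits,
                        params$exact_mode, params$undirected,
                        isTRUE(occurrences))
  val <- raw$count
  if (normalize && length(val)) {
    bn <- rowsum(val^2, raw$block)
    val <- val / sqrt(bn[raw$block, 1L])
    val <- val / sqrt(sum(val^2))
  }
  if (params$exact_mode) {
    ids <- raw$keys; vv <- val
  } else {
    # hashing trick: colliding keys fold into one index
    agg <- rowsum(val, raw$index)
    ids <- as.integer(rownames(agg)); vv <- as.numeric(agg)
  }
  out <- list(ids = ids, val = vv,
              fingerprint = params_fingerprint(params, "fv"),
              params = params)
  if (occurrences) {
    out$key_val <- val
    out$key_count <- raw$count
    out$key_id <- if (params$exact_mode) raw$keys else raw$index
    out$occ_key <- raw$occ_key
    out$occ_u <- raw$occ_u
    out$occ_v <- raw$occ_v
  }
  structure(out, class = "sparse_fv")
}

#' Canonical label of a neighborhood subgraph
#'
#' Deterministic graph-invariant label of the subgraph induced by the
#' vertices reachable from `root` via at most `r` traversable directed
#' edges (following edge orientation): the sorted multiset of per-vertex
#' signatures (distance from root, vertex label, sorted multiset of
#' incident edge descriptors within the subgraph), with the root identified
#' by its zero distance. Isomorphic rooted subgraphs always receive
#' identical labels.
#'
#' @param graph An `annotated_graph`.
#' @param root Vertex id (must not be a relation vertex).
#' @param r Neighborhood radius.
#' @param undirected Ignore edge orientation. Default `FALSE`.
#' @return Canonical label string.
#' @export
neighborhood <- function(graph, root, r, undirected = FALSE) {
  v <- graph$vertices; e <- graph$edges
  kind_i <- match(v$kind, c("nucleotide", "abstract_element", "relation")) - 1L
  .nspdk_neighborhood(v$label, kind_i, e$src, e$dst, e$label, e$traversable,
                      as.integer(root), as.integer(r), isTRUE(undirected))
}

#' Sparse inner product of two feature vectors
#'
#' @param a,b `sparse_fv` objects extracted with identical parameters.
#' @return The inner product; 1 for a nonempty normalized vector with
#'   itself.
#' @export
fv_dot <- function(a, b) {
  stopifnot(inherits(a, "sparse_fv"), inherits(b, "sparse_fv"))
  if (!identical(a$fingerprint, b$fingerprint)) {
    stop("feature vectors extracted with different kernel parameters")
  }
  m <- match(a$ids, b$ids)
  ok <- !is.na(m)
  sum(a$val[ok] * b$val[m[ok]])
}

#' Serialize a sparse feature vector as SVM-light style text lines
#' @param fv A `sparse_fv`.
#' @return Character scalar `"id:value ..."` with ids sorted.
#' @export
format_sparse_fv <- function(fv) {
  o <- order(fv$ids)
  paste(sprintf("%s:%.10g", as.character(fv$ids[o]), fv$val[o]),
        collapse = " ")
}

#' Compute feature vectors for a set of target sites
#'
#' Pipeline step shared by fitting and prediction: per site, fold (structure
#' mode), encode as an annotated graph and extract NSPD-kernel features.
#'
#' @param sites A `target_sites` data frame.
#' @param mode `"sequence"` or `"structure"`.
#' @param folding A [folding_params()] object.
#' @param kernel A [kernel_params()] object.
#' @param backend Folding backend; default [built_in_backend()].
#' @param verbose Print progress every 100 sites.
#' @return List of `sparse_fv`, one per site.
#' @export
site_features <- function(sites, mode = c("sequence", "structure"),
                          folding = folding_params(),
                          kernel = kernel_params(),
                          backend = built_in_backend(), verbose = FALSE) {
  mode <- match.arg(mode)
  n <- nrow(sites)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    g <- encode_site(sites[i, ], mode, folding, backend)
    out[[i]] <- extract_features(g, kernel)
    if (verbose && i %% 100L == 0L) {
      message("  encoded ", i, "/", n, " sites")
    }
  }
  out
}

# features x examples sparse matrix (hashed mode only)
fv_matrix <- function(vectors, bits) {
  stopifnot(length(vectors) >= 1L)
  ii <- unlist(lapply(vectors, `[[`, "ids"), use.names = FALSE)
  stopifnot(is.numeric(ii))
  jj <- rep(seq_along(vectors),
            vapply(vectors, function(v) length(v$ids), integer(1)))
  xx <- unlist(lapply(vectors, `[[`, "val"), use.names = FALSE)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(2^bits, length(vectors)))
}
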