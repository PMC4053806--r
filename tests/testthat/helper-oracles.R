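# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: reverse complement by hand, rooted-subgraph
# isomorphism via igraph VF2, kernel dot products via isomorphism-class
# counting, and maximum base pairing via a memoized recursion.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGUT", "UGCAA", s), "")[[1]]), collapse = "")
}

# ---- random labeled directed graphs (as annotated_graph objects) ----------

rand_graph <- function(n, p_edge = 0.25, labels = c("A", "C", "G", "U"),
                       elabels = c("backbone", "basepair")) {
  v <- data.frame(id = seq_len(n),
                  label = sample(labels, n, replace = TRUE),
                  kind = "nucleotide", position = seq_len(n),
                  viewpoint = TRUE, copy = "main",
                  stringsAsFactors = FALSE)
  pairs <- expand.grid(src = seq_len(n), dst = seq_len(n))
  pairs <- pairs[pairs$src != pairs$dst, ]
  keep <- runif(nrow(pairs)) < p_edge
  e <- data.frame(src = pairs$src[keep], dst = pairs$dst[keep],
                  label = sample(elabels, sum(keep), replace = TRUE),
                  traversable = rep(TRUE, sum(keep)),
                  stringsAsFactors = FALSE)
  structure(list(vertices = v, edges = e, n_context = n),
            class = "annotated_graph")
}

# ---- rooted neighborhood subgraph extraction + VF2 isomorphism ------------

# directed BFS distances over traversable edges
oracle_dists <- function(g, root, maxd) {
  n <- nrow(g$vertices)
  e <- g$edges[g$edges$traversable, , drop = FALSE]
  dist <- rep(NA_integer_, n)
  dist[root] <- 0L
  frontier <- root
  d <- 0L
  while (length(frontier) && d < maxd) {
    d <- d + 1L
    nxt <- unique(e$dst[e$src %in% frontier])
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# neighborhood subgraph as an igraph with combined vertex colors
# (label + root flag) and edge colors
oracle_nbh_subgraph <- function(g, root, r) {
  dist <- oracle_dists(g, root, r)
  keep <- which(!is.na(dist) & dist <= r)
  v <- g$vertices[keep, , drop = FALSE]
  e <- g$edges[g$edges$traversable &
                 g$edges$src %in% keep & g$edges$dst %in% keep, , drop = FALSE]
  idx <- match(seq_len(nrow(g$vertices)), keep)
  list(labels = paste0(v$label, ifelse(v$id == root, "*", "")),
       src = idx[e$src], dst = idx[e$dst], elab = e$label)
}

oracle_iso <- function(a, b) {
  if (length(a$labels) != length(b$labels)) return(FALSE)
  if (!identical(sort(a$labels), sort(b$labels))) return(FALSE)
  if (length(a$src) != length(b$src)) return(FALSE)
  all_lab <- unique(c(a$labels, b$labels))
  all_el <- unique(c(a$elab, b$elab))
  mk <- function(x) {
    gi <- igraph::make_empty_graph(n = length(x$labels), directed = TRUE)
    if (length(x$src)) {
      gi <- igraph::add_edges(gi, rbind(x$src, x$dst))
    }
    gi
  }
  igraph::isomorphic(mk(a), mk(b), method = "vf2",
                     vertex.color1 = match(a$labels, all_lab),
                     vertex.color2 = match(b$labels, all_lab),
                     edge.color1 = match(a$elab, all_el),
                     edge.color2 = match(b$elab, all_el))
}

# ---- paired-neighborhood isomorphism-counting kernel oracle ---------------

# Computes the normalized dot product between two graphs by brute force:
# neighborhoods are grouped into isomorphism classes with VF2, occurrences
# counted per (r, d, class_u, class_v), block-normalized per (r, d) and
# globally normalized, exactly as the kernel defines.
oracle_nspdk_dot <- function(ga, gb, R, D) {
  reps <- list()          # isomorphism class representatives
  class_of <- function(nb) {
    for (ci in seq_along(reps)) {
      if (oracle_iso(reps[[ci]], nb)) return(ci)
    }
    reps[[length(reps) + 1L]] <<- nb
    length(reps)
  }
  feats <- function(g) {
    n <- nrow(g$vertices)
    cls <- matrix(NA_integer_, n, R + 1L)
    for (u in seq_len(n)) for (r in 0:R) {
      cls[u, r + 1L] <- class_of(oracle_nbh_subgraph(g, u, r))
    }
    keys <- character(0); blks <- character(0)
    for (u in seq_len(n)) {
      dist <- oracle_dists(g, u, D)
      for (v in which(!is.na(dist))) {
        d <- dist[v]
        for (r in 0:R) {
          keys <- c(keys, paste(r, d, cls[u, r + 1L], cls[v, r + 1L],
                                sep = "|"))
          blks <- c(blks, paste(r, d, sep = "|"))
        }
      }
    }
    tab <- tapply(rep(1, length(keys)), keys, sum)
    blk_of <- tapply(blks, keys, `[`, 1L)
    val <- as.numeric(tab)
    bn <- tapply(val^2, as.character(blk_of), sum)
    val <- val / sqrt(bn[as.character(blk_of)])
    val <- val / sqrt(sum(val^2))
    setNames(as.numeric(val), names(tab))
  }
  fa <- feats(ga); fb <- feats(gb)
  common <- intersect(names(fa), names(fb))
  sum(fa[common] * fb[common])
}

# ---- maximum base pairing (plain Nussinov objective) ----------------------

oracle_max_pairs <- function(seq, min_loop = 3L) {
  ch <- strsplit(seq, "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (ok(ch[i], ch[k])) {
        best <- max(best, 1L + rec(i + 1L, k - 1L) + rec(k + 1L, j))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(1L, nchar(seq))
}
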