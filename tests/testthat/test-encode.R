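# Directed annotated hypergraph encoding

test_that("sequence-only encoding builds the 5'->3' path plus the reversed relabeled copy", {
  st <- target_sites_from_seqs(c(x = "ACG"))
  g <- encode_sequence_only(st[1, ])
  v <- g$vertices; e <- g$edges
  expect_equal(nrow(v), 6L)
  expect_equal(nrow(e), 4L)
  main <- v[v$copy == "main", ]
  expect_identical(main$label, c("A", "C", "G"))
  rev <- v[v$copy == "rev", ]
  expect_identical(rev$label, c("rA", "rC", "rG"))
  expect_identical(rev$position, main$position)
  expect_identical(rev$viewpoint, main$viewpoint)
  # main edges A->C, C->G; reversed copy rC->rA, rG->rC
  em <- e[e$src %in% main$id, ]
  expect_equal(v$label[em$src], c("A", "C"))
  expect_equal(v$label[em$dst], c("C", "G"))
  er <- e[e$src %in% rev$id, ]
  expect_setequal(paste(v$label[er$src], v$label[er$dst]),
                  c("rC rA", "rG rC"))
})

test_that("single-nucleotide context gives two vertices and no edges", {
  st <- target_sites_from_seqs(c(x = "A"))
  g <- encode_sequence_only(st[1, ])
  expect_equal(nrow(g$vertices), 2L)
  expect_equal(nrow(g$edges), 0L)
})

test_that("an invalid viewpoint is rejected at construction", {
  expect_error(target_sites_from_seqs(c(x = "ACG"), vp_start = 3, vp_end = 2))
  expect_error(target_sites_from_seqs(c(x = "ACG"), vp_start = 1, vp_end = 4))
})

test_that("a hairpin hypothesis yields the S/H abstract layer with outer-to-inner adjacency", {
  st <- target_sites_from_seqs(c(h = "GGGAAACCC"))
  hyp <- list(structure(list(window = c(1L, 9L),
                             pairs = cbind(c(1L, 2L, 3L), c(9L, 8L, 7L)),
                             shape = "[]", energy = -1),
                        class = "structure_hypothesis"))
  g <- encode_with_structure(st[1, ], hyp)
  v <- g$vertices; e <- g$edges
  ab <- v[v$kind == "abstract_element" & v$copy == "main", ]
  expect_setequal(ab$label, c("S", "H"))
  sid <- ab$id[ab$label == "S"]; hid <- ab$id[ab$label == "H"]
  aa <- e[e$label == "abstract_adjacency" & e$src %in% ab$id, ]
  expect_equal(nrow(aa), 1L)
  expect_equal(aa$src, sid)
  expect_equal(aa$dst, hid)
  # relation vertex of S links nucleotides 1,2,3,7,8,9; H links 4,5,6
  rl <- e[e$label == "relation_link", ]
  rel_of <- function(aid) rl$dst[rl$src == aid]
  mem_of <- function(aid) sort(v$position[rl$dst[rl$src == rel_of(aid)]])
  expect_equal(mem_of(sid), c(1L, 2L, 3L, 7L, 8L, 9L))
  expect_equal(mem_of(hid), c(4L, 5L, 6L))
  # base-pair edges run 5' -> 3'
  bp <- e[e$label == "basepair" & e$src %in% v$id[v$copy == "main"], ]
  expect_true(all(v$position[bp$src] < v$position[bp$dst]))
})

test_that("relation vertices carry no traversable edges", {
  st <- target_sites_from_seqs(c(h = "GGGAAACCCAAAGGGUUUCCC"))
  g <- encode_site(st[1, ], "structure")
  v <- g$vertices; e <- g$edges
  rel <- v$id[v$kind == "relation"]
  trav <- e[e$traversable, ]
  expect_false(any(trav$src %in% rel | trav$dst %in% rel))
})

test_that("a zero-pair hypothesis reduces to the sequence path plus one external element", {
  st <- target_sites_from_seqs(c(x = "ACGUA"))
  hyp <- list(structure(list(window = c(1L, 5L),
                             pairs = matrix(integer(0), ncol = 2),
                             shape = "_", energy = 0),
                        class = "structure_hypothesis"))
  g <- encode_with_structure(st[1, ], hyp)
  v <- g$vertices
  ab <- v[v$kind == "abstract_element" & v$copy == "main", ]
  expect_equal(ab$label, "E")
  g0 <- encode_sequence_only(st[1, ])
  nuc <- v[v$kind == "nucleotide", ]
  expect_identical(nuc$label, g0$vertices$label)
  bb <- g$edges[g$edges$label == "backbone", ]
  bb0 <- g0$edges[g0$edges$label == "backbone", ]
  expect_equal(nrow(bb), nrow(bb0))
})

test_that("each hypothesis becomes one component, duplicated in the reversed copy", {
  st <- target_sites_from_seqs(c(x = "GGGAAACCCGGAAACC"))
  h1 <- structure(list(window = c(1L, 16L),
                       pairs = cbind(c(1L, 2L, 3L), c(9L, 8L, 7L)),
                       shape = "[]", energy = -2), class = "structure_hypothesis")
  h2 <- structure(list(window = c(1L, 16L),
                       pairs = matrix(integer(0), ncol = 2),
                       shape = "_", energy = -1), class = "structure_hypothesis")
  g <- encode_with_structure(st[1, ], list(h1, h2))
  ig <- igraph::graph_from_data_frame(g$edges[, c("src", "dst")],
                                      vertices = g$vertices$id,
                                      directed = FALSE)
  expect_equal(igraph::components(ig)$no, 4L)
})

test_that("the graph dump lists every vertex and edge", {
  st <- target_sites_from_seqs(c(x = "ACG"))
  g <- encode_sequence_only(st[1, ])
  lines <- write_graph_dump(g, tempfile())
  expect_equal(sum(startsWith(lines, "V")), nrow(g$vertices))
  expect_equal(sum(startsWith(lines, "E")), nrow(g$edges))
})

test_that("multiloop structures get M elements linked between enclosing and enclosed stems", {
  # two hairpins inside an enclosing stem
  db <- "((((...))((...))..))"
  st <- target_sites_from_seqs(c(x = strrep("A", 20)))
  hyp <- list(structure(list(window = c(1L, 20L), pairs = db_to_pairs(db),
                             shape = "[[][]]", energy = -3),
                        class = "structure_hypothesis"))
  g <- encode_with_structure(st[1, ], hyp)
  v <- g$vertices; e <- g$edges
  ab <- v[v$kind == "abstract_element" & v$copy == "main", ]
  expect_equal(sum(ab$label == "M"), 1L)   # one contiguous M run (17-18)
  expect_equal(sum(ab$label == "S"), 3L)
  expect_equal(sum(ab$label == "H"), 2L)
  aa <- e[e$label == "abstract_adjacency", ]
  lab <- function(id) v$label[match(id, v$id)]
  arcs <- paste(lab(aa$src), lab(aa$dst))
  # outer stem feeds the inner stems; hairpins are termini
  expect_true(all(c("S S", "S H") %in% arcs))
  expect_false(any(startsWith(arcs, "H ")))
})
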