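# NSPD-kernel explicit features: worked enumerations, canonical labels,
# direction and viewpoint semantics, normalization, hashing

seq_graph <- function(s, vp_start = 1L, vp_end = nchar(s), mirror = TRUE) {
  st <- target_sites_from_seqs(setNames(s, "x"), vp_start = vp_start,
                               vp_end = vp_end)
  encode_sequence_only(st[1, ], mirror = mirror)
}

test_that("worked enumeration: 'AC' gives 4 features at R=0,D=0 and 12 at R=1,D=1", {
  g <- seq_graph("AC")
  f0 <- extract_features(g, kernel_params(R = 0, D = 0, exact_mode = TRUE),
                         normalize = FALSE)
  expect_length(f0$ids, 4L)
  expect_true(all(f0$val == 1))
  f1 <- extract_features(g, kernel_params(R = 1, D = 1, exact_mode = TRUE),
                         normalize = FALSE)
  expect_length(f1$ids, 12L)
  expect_true(all(f1$val == 1))
})

test_that("neighborhoods follow edge orientation: a sink vertex sees only itself", {
  g <- seq_graph("AC")
  cid <- g$vertices$id[g$vertices$label == "C"]
  expect_identical(neighborhood(g, cid, 1), neighborhood(g, cid, 0))
  aid <- g$vertices$id[g$vertices$label == "A"]
  expect_false(identical(neighborhood(g, aid, 1), neighborhood(g, aid, 0)))
})

test_that("relation vertices are rejected as neighborhood roots", {
  st <- target_sites_from_seqs(c(h = "GGGAAACCC"))
  g <- encode_site(st[1, ], "structure")
  rel <- g$vertices$id[g$vertices$kind == "relation"][1]
  expect_error(neighborhood(g, rel, 1), "relation")
})

test_that("isomorphic rooted subgraphs receive identical canonical labels", {
  set.seed(21)
  for (t in 1:20) {
    g <- rand_graph(sample(4:8, 1))
    n <- nrow(g$vertices)
    perm <- sample(n)
    g2 <- g
    g2$vertices <- g$vertices[order(perm), ]
    g2$vertices$id <- seq_len(n)
    g2$edges$src <- perm[g$edges$src]
    g2$edges$dst <- perm[g$edges$dst]
    root <- sample(n, 1)
    for (r in 0:2) {
      expect_identical(neighborhood(g, root, r),
                       neighborhood(g2, perm[root], r))
    }
  }
})

test_that("exact-mode dot products match the brute-force paired-neighborhood oracle", {
  set.seed(33)
  kp <- kernel_params(R = 2, D = 2, exact_mode = TRUE)
  for (t in 1:8) {
    ga <- rand_graph(sample(4:8, 1))
    gb <- rand_graph(sample(4:8, 1))
    fa <- extract_features(ga, kp)
    fb <- extract_features(gb, kp)
    expect_equal(fv_dot(fa, fb), oracle_nspdk_dot(ga, gb, 2, 2),
                 tolerance = 1e-10)
  }
})

test_that("normalized vectors have unit self-dot; disjoint alphabets give zero", {
  g1 <- seq_graph("ACGU")
  f1 <- extract_features(g1, kernel_params(R = 1, D = 2, exact_mode = TRUE))
  expect_equal(fv_dot(f1, f1), 1.0)
  g2 <- rand_graph(4, labels = "X")
  f2 <- extract_features(g2, kernel_params(R = 1, D = 2, exact_mode = TRUE))
  expect_equal(fv_dot(f1, f2), 0.0)
})

test_that("dot product errors on mismatched kernel parameters", {
  g <- seq_graph("ACG")
  f1 <- extract_features(g, kernel_params(R = 1, D = 1, exact_mode = TRUE))
  f2 <- extract_features(g, kernel_params(R = 2, D = 1, exact_mode = TRUE))
  expect_error(fv_dot(f1, f2), "different")
})

test_that("hashed and exact modes agree when no collision occurs", {
  set.seed(9)
  for (t in 1:5) {
    s1 <- paste(sample(c("A", "C", "G", "U"), 15, replace = TRUE), collapse = "")
    s2 <- paste(sample(c("A", "C", "G", "U"), 15, replace = TRUE), collapse = "")
    ge <- kernel_params(R = 1, D = 3, exact_mode = TRUE)
    gh <- kernel_params(R = 1, D = 3, bits = 24)
    f1e <- extract_features(seq_graph(s1), ge)
    f2e <- extract_features(seq_graph(s2), ge)
    f1h <- extract_features(seq_graph(s1), gh)
    f2h <- extract_features(seq_graph(s2), gh)
    collided <- length(f1h$ids) < length(f1e$ids) ||
      length(f2h$ids) < length(f2e$ids)
    if (!collided) {
      expect_equal(fv_dot(f1h, f2h), fv_dot(f1e, f2e), tolerance = 1e-12)
    } else {
      succeed("hash collision detected and reported")
    }
  }
})

test_that("direction is discriminative: 'AAC' and 'CAA' differ; the undirected no-mirror control collides", {
  kp <- kernel_params(R = 1, D = 2, exact_mode = TRUE)
  fa <- extract_features(seq_graph("AAC"), kp)
  fb <- extract_features(seq_graph("CAA"), kp)
  expect_false(identical(sort(fa$ids), sort(fb$ids)))
  ku <- kernel_params(R = 1, D = 2, exact_mode = TRUE, undirected = TRUE)
  fa2 <- extract_features(seq_graph("AAC", mirror = FALSE), ku)
  fb2 <- extract_features(seq_graph("CAA", mirror = FALSE), ku)
  expect_identical(sort(fa2$ids), sort(fb2$ids))
  expect_equal(fv_dot(fa2, fb2), 1.0)
})

test_that("mirror copy contributes the same total feature mass as the main copy", {
  set.seed(14)
  for (t in 1:5) {
    s <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE), collapse = "")
    kp <- kernel_params(R = 1, D = 2, exact_mode = TRUE)
    fm <- extract_features(seq_graph(s, mirror = TRUE), kp, normalize = FALSE)
    f1 <- extract_features(seq_graph(s, mirror = FALSE), kp, normalize = FALSE)
    expect_equal(sum(fm$val), 2 * sum(f1$val))
  }
})

test_that("without viewpoint vertices the feature vector is empty", {
  g <- seq_graph("ACGUACGU")
  g$vertices$viewpoint <- FALSE
  f <- extract_features(g, kernel_params(R = 1, D = 2, exact_mode = TRUE))
  expect_length(f$ids, 0L)
  # with a single viewpoint position, only features rooted there survive
  g2 <- seq_graph("ACGUACGU", vp_start = 1, vp_end = 1)
  f2 <- extract_features(g2, kernel_params(R = 0, D = 0, exact_mode = TRUE),
                         normalize = FALSE)
  expect_length(f2$ids, 2L)   # the A vertex and its rA mirror
})

test_that("sequence-only locality: mutations beyond R + D backbone steps from the viewpoint do not change features", {
  set.seed(77)
  kp <- kernel_params(R = 2, D = 3, exact_mode = TRUE)
  reach <- kp$R + kp$D
  for (t in 1:25) {
    len <- 30L
    s <- sample(c("A", "C", "G", "U"), len, replace = TRUE)
    vs <- sample(5:20, 1); ve <- vs + sample(2:5, 1)
    far <- which(seq_len(len) < vs - reach | seq_len(len) > ve + reach)
    if (!length(far)) next
    p <- sample(far, 1)
    s2 <- s
    s2[p] <- sample(setdiff(c("A", "C", "G", "U"), s[p]), 1)
    f1 <- extract_features(seq_graph(paste(s, collapse = ""), vs, ve), kp)
    f2 <- extract_features(seq_graph(paste(s2, collapse = ""), vs, ve), kp)
    o1 <- order(f1$ids); o2 <- order(f2$ids)
    expect_identical(f1$ids[o1], f2$ids[o2])
    expect_equal(f1$val[o1], f2$val[o2])
  }
})

test_that("feature support is non-decreasing in R and D", {
  g <- seq_graph("ACGUACGUAC")
  n_feat <- function(R, D) {
    length(extract_features(g, kernel_params(R = R, D = D,
                                             exact_mode = TRUE))$ids)
  }
  for (R in 0:2) expect_lte(n_feat(R, 2), n_feat(R + 1, 2))
  for (D in 0:3) expect_lte(n_feat(1, D), n_feat(1, D + 1))
})

test_that("sparse serialization lists sorted id:value pairs", {
  g <- seq_graph("AC")
  f <- extract_features(g, kernel_params(R = 0, D = 0, bits = 16))
  txt <- format_sparse_fv(f)
  parts <- strsplit(txt, " ")[[1]]
  ids <- as.integer(sub(":.*", "", parts))
  expect_false(is.unsorted(ids))
  expect_length(parts, length(f$ids))
})
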