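# Per-nucleotide profiles, window scores, site calling, motif extraction

test_that("profile mass is conserved: positions sum to margin minus bias", {
  spec <- synthetic_spec(n_pos = 15, n_neg = 15, seq_len = 40,
                         motif = "ACGUAC", seed = 6)
  sites <- generate_classification_set(spec)
  kp <- kernel_params(R = 1, D = 3, bits = 16)
  fit <- graphrbp(sites, mode = "sequence", kernel = kp)
  for (i in c(1, 10, 20)) {
    g <- encode_site(sites[i, ], "sequence")
    prof <- nucleotide_profile(fit, g)
    expect_length(prof, nchar(sites$context[i]))
    fv <- extract_features(g, kp)
    expect_equal(sum(prof), margin(fit, fv) - fit$model$bias,
                 tolerance = 1e-9)
  }
  # structure mode, including abstract and hybrid feature mass
  fit2 <- graphrbp(sites[c(1:8, 16:23), ], mode = "structure", kernel = kp)
  g2 <- encode_site(sites[2, ], "structure")
  prof2 <- nucleotide_profile(fit2, g2)
  fv2 <- extract_features(g2, kp)
  expect_equal(sum(prof2), margin(fit2, fv2) - fit2$model$bias,
               tolerance = 1e-9)
})

test_that("a zero-weight model yields an all-zero profile", {
  st <- target_sites_from_seqs(c(x = "ACGUACGUACGU"))
  g <- encode_sequence_only(st[1, ])
  m <- graphrbp:::new_model("classification", ids = integer(0),
                            w = numeric(0), bias = 1,
                            kernel = kernel_params(bits = 16))
  expect_equal(nucleotide_profile(m, g), rep(0, 12))
})

test_that("window scores average the profile over sliding 12-mers", {
  prof <- rep(2.5, 30)
  ws <- window_scores(prof)
  expect_equal(nrow(ws), 30 - 12 + 1)
  expect_true(all(ws$score == 2.5))
  spike <- rep(0, 30); spike[15] <- 12
  ws2 <- window_scores(spike)
  expect_equal(sum(ws2$score == 1), 12L)
  expect_equal(sum(ws2$score == 0), nrow(ws2) - 12L)
  expect_equal(nrow(window_scores(rep(1, 11))), 0L)
})

test_that("site calling keeps the top fraction and merges overlapping and abutting windows", {
  w <- data.frame(seqname = "u1", start = 1:100,
                  score = c(rep(0, 100)))
  w$score[50] <- 5
  cs <- call_sites(w, w = 12, top_fraction = 0.01)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$start, 50)
  expect_equal(cs$end, 61)
  # overlapping windows merge
  w2 <- data.frame(seqname = "u1", start = c(5, 6, 40), score = c(3, 2, 1))
  cs2 <- call_sites(w2, w = 12, top_fraction = 2/3)
  expect_equal(nrow(cs2), 1L)
  expect_equal(c(cs2$start, cs2$end, cs2$score), c(5, 17, 3))
  # abutting windows ([5,16] then [17,28]) merge too
  w3 <- data.frame(seqname = "u1", start = c(5, 17), score = c(3, 2))
  cs3 <- call_sites(w3, w = 12, top_fraction = 1)
  expect_equal(nrow(cs3), 1L)
  expect_equal(c(cs3$start, cs3$end), c(5, 28))
  # merged output is disjoint and non-abutting
  set.seed(3)
  w4 <- data.frame(seqname = sample(c("a", "b"), 200, TRUE),
                   start = sample(1:150, 200, TRUE), score = rnorm(200))
  cs4 <- call_sites(w4, w = 12, top_fraction = 0.2)
  for (sq in unique(cs4$seqname)) {
    x <- cs4[cs4$seqname == sq, ]
    x <- x[order(x$start), ]
    if (nrow(x) > 1) expect_true(all(x$start[-1] > x$end[-nrow(x)] + 1))
  }
})

test_that("profiles of predicted sites are near zero outside the viewpoint reach", {
  spec <- synthetic_spec(n_pos = 15, n_neg = 15, seq_len = 40,
                         motif = "ACGUAC", seed = 6)
  sites <- generate_classification_set(spec)
  kp <- kernel_params(R = 1, D = 2, bits = 16)
  fit <- graphrbp(sites, mode = "sequence", kernel = kp)
  st <- target_sites_from_seqs(c(x = strrep("ACGU", 15)),
                               vp_start = 25, vp_end = 34)
  prof <- predict(fit, st, type = "profile")[[1]]
  reach <- kp$R + kp$D
  outside <- c(seq_len(25 - reach - 1), seq.int(34 + reach + 1, 60))
  expect_true(all(prof[outside] == 0))
})

test_that("motif extraction recovers an implanted motif and reports normalized matrices", {
  spec <- synthetic_spec(n_pos = 60, n_neg = 60, seq_len = 40,
                         motif = "UCAUGUAC", mutation_rate = 0, seed = 12)
  sites <- generate_classification_set(spec)
  fit <- graphrbp(sites, mode = "sequence",
                  kernel = kernel_params(R = 2, D = 4, bits = 18))
  mot <- extract_motif(fit, sites[sites$label == "bound", ], k = 12,
                       top_n = 50)
  expect_s3_class(mot, "rbp_motif")
  expect_true(all(abs(colSums(mot$sequence_matrix) - 1) < 1e-12))
  expect_true(all(abs(colSums(mot$structure_matrix) - 1) < 1e-12))
  expect_false(is.unsorted(rev(mot$kmers$score)))
  hits <- grepl(spec$motif, mot$kmers$seq, fixed = TRUE)
  expect_gte(mean(hits), 0.5)
})

test_that("motif extraction skips sites with viewpoints shorter than k and breaks ties by input order", {
  sites <- target_sites_from_seqs(
    c(a = "ACGUACGUACGUACG", b = "ACGUACGUACGUACG"), vp_start = 1,
    vp_end = c(15, 5))
  m <- graphrbp:::new_model("classification", ids = integer(0),
                            w = numeric(0), bias = 0,
                            kernel = kernel_params(bits = 16))
  expect_warning(mot <- extract_motif(m, sites, k = 12, mode = "sequence"),
                 "skipped")
  expect_equal(nrow(mot$kmers), 1L)
  expect_equal(mot$kmers$site_id, "a")
  expect_equal(mot$kmers$start, 1L)   # all-equal scores: first window wins
})

test_that("hairpin-constrained motifs show H-majority columns at motif positions with stems at the borders", {
  # positives: motif in a hairpin loop; negatives: the same hairpin
  # scaffold with a scrambled loop, so the loop content is what the model
  # must learn
  sp <- synthetic_spec(n_pos = 40, n_neg = 0, seq_len = 60,
                       motif_context = "hairpin_loop", mutation_rate = 0,
                       seed = 21)
  sn <- synthetic_spec(n_pos = 40, n_neg = 0, seq_len = 60,
                       motif_context = "hairpin_loop", mutation_rate = 1,
                       seed = 22)
  pos <- generate_classification_set(sp)
  neg <- generate_classification_set(sn)
  neg$label <- "unbound"
  neg$site_id <- paste0("n", neg$site_id)
  neg$seqname <- neg$site_id
  sites <- rbind(pos, neg)
  fit <- graphrbp(sites, mode = "structure",
                  kernel = kernel_params(R = 1, D = 3, bits = 18))
  mot <- extract_motif(fit, sites[sites$label == "bound", ], k = 12,
                       top_n = 100)
  hfreq <- mot$structure_matrix["H", ]
  expect_gte(sum(hfreq >= 0.5), 6L)                   # loop core
  expect_gte(max(mot$structure_matrix["S", ]), 0.5)   # stem at a border
  expect_gte(mean(grepl(sp$motif, mot$kmers$seq, fixed = TRUE)), 0.5)
})

test_that("motif and profile outputs serialize to plain text", {
  spec <- synthetic_spec(n_pos = 20, n_neg = 20, seq_len = 30,
                         motif = "ACGUA", seed = 3)
  sites <- generate_classification_set(spec)
  fit <- graphrbp(sites, mode = "sequence",
                  kernel = kernel_params(R = 1, D = 2, bits = 16))
  mot <- extract_motif(fit, sites[sites$label == "bound", ], k = 8,
                       top_n = 10)
  pre <- tempfile()
  paths <- write_motif(mot, pre)
  expect_true(all(file.exists(paths)))
  expect_equal(length(readLines(paths[1])), nrow(mot$kmers))
  prof <- predict(fit, sites[1, ], type = "profile")
  names(prof) <- sites$site_id[1]
  pf <- tempfile()
  write_profiles(prof, pf)
  expect_equal(nrow(read.table(pf)), nchar(sites$context[1]))
})
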