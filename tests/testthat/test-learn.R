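# Training, metrics, cross-validation, line search, model persistence

fv_stub <- function(ids, val = rep(1, length(ids)), bits = 16L) {
  v <- sqrt(sum(val^2))
  structure(list(ids = as.integer(ids), val = val / v,
                 fingerprint = graphrbp:::params_fingerprint(
                   kernel_params(bits = bits), "fv"),
                 params = kernel_params(bits = bits)),
            class = "sparse_fv")
}

test_that("the SGD classifier separates separable singleton-feature classes and is deterministic", {
  vecs <- c(lapply(1:10, function(i) fv_stub(1L)),
            lapply(1:10, function(i) fv_stub(2L)))
  y <- rep(c(1L, -1L), each = 10)
  m1 <- train_classifier(vecs, y, classifier_params(seed = 4))
  m2 <- train_classifier(vecs, y, classifier_params(seed = 4))
  expect_identical(m1$w, m2$w)
  expect_identical(m1$bias, m2$bias)
  marg <- vapply(vecs, function(v) margin(m1, v), numeric(1))
  expect_equal(auroc(marg, y), 1.0)
  expect_true(all(sign(marg) == y))
})

test_that("single-class input is rejected", {
  vecs <- lapply(1:5, function(i) fv_stub(i))
  expect_error(train_classifier(vecs, rep(1L, 5), classifier_params()),
               "class")
})

test_that("the regularized hinge objective decreases with training", {
  set.seed(2)
  vecs <- lapply(1:40, function(i) fv_stub(sample(1:50, 5)))
  y <- rep(c(1L, -1L), 20)
  for (i in 1:40) if (y[i] == 1) vecs[[i]]$ids[1] <- 99L
  cp1 <- classifier_params(epochs = 1, seed = 3)
  cp20 <- classifier_params(epochs = 20, seed = 3)
  o1 <- graphrbp:::hinge_objective(vecs, y, train_classifier(vecs, y, cp1),
                                   cp1$lambda)
  o20 <- graphrbp:::hinge_objective(vecs, y, train_classifier(vecs, y, cp20),
                                    cp20$lambda)
  expect_lt(o20, o1)
})

test_that("margins are linear and reduce to the bias on non-matching features", {
  m <- graphrbp:::new_model("classification", ids = c(3L, 7L), w = c(2, -1),
                            bias = 0.5, kernel = kernel_params(bits = 16))
  f <- fv_stub(c(3L, 8L), c(1, 1))
  expect_equal(margin(m, fv_stub(99L)), 0.5)
  a <- 3.7
  fa <- f; fa$val <- a * f$val
  expect_equal(margin(m, fa) - m$bias, a * (margin(m, f) - m$bias))
})

test_that("eps-SVR reproduces an exact linear relationship and flattens when the tube swallows the range", {
  vecs <- lapply(1:8, function(i) fv_stub(i))
  y <- c(0.1, 0.5, -0.3, 0.8, -0.7, 0.2, 0.9, -0.1)
  m <- train_regressor(vecs, y, regression_params(c = 100, epsilon = 0))
  pred <- vapply(vecs, function(v) margin(m, v), numeric(1))
  expect_equal(pred, y, tolerance = 1e-2)
  mflat <- train_regressor(vecs, y, regression_params(c = 1, epsilon = 10))
  pflat <- vapply(vecs, function(v) margin(mflat, v), numeric(1))
  expect_lt(diff(range(pflat)), 1e-6)
  expect_error(train_regressor(vecs, rep(1, 8), regression_params()),
               "constant")
})

test_that("AUROC follows the Mann-Whitney formulation with ties at one half", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, -1, -1)), 1.0)
  expect_equal(auroc(rep(0.3, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_equal(auroc(c(0.8, 0.7, 0.9, 0.1), c(1, 1, -1, -1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "single class")
  # invariance under strictly increasing transforms; label-flip symmetry
  set.seed(6)
  m <- rnorm(40); y <- rep(c(1L, -1L), 20)
  expect_equal(auroc(exp(m), y), auroc(m, y))
  expect_equal(auroc(m, y), 1 - auroc(m, -y))
})

test_that("AUROC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (t in 1:5) {
    m <- rnorm(50); y <- rep(c(1L, -1L), 25)
    ref <- as.numeric(pROC::auc(pROC::roc(y, m, quiet = TRUE,
                                          direction = "<", levels = c(-1, 1))))
    expect_equal(auroc(m, y), ref, tolerance = 1e-12)
  }
})

test_that("average precision matches hand-computed rankings", {
  expect_equal(average_precision(c(3, 2, 1), c(1, -1, 1)), (1 + 2/3) / 2)
  expect_equal(average_precision(c(3, 2, 1), c(1, 1, -1)), 1.0)
  # single positive at rank k of n -> 1/k
  expect_equal(average_precision(c(5, 4, 3, 2), c(-1, -1, 1, -1)), 1/3)
  expect_error(average_precision(1:3, rep(-1, 3)), "positives")
})

test_that("relative error reduction follows (x' - x)/(1 - x)", {
  expect_equal(relative_error_reduction(0.5, 0.75), 0.5)
  expect_equal(relative_error_reduction(0.8, 0.8), 0)
  expect_equal(relative_error_reduction(0.65, 0.86), 0.6)
  expect_error(relative_error_reduction(1, 1), "< 1")
})

test_that("cross-validation is stratified, covers each example once, and is seed-reproducible", {
  spec <- synthetic_spec(n_pos = 30, n_neg = 30, seq_len = 30,
                         motif = "ACGUA", seed = 2)
  sites <- generate_classification_set(spec)
  kp <- kernel_params(R = 1, D = 2, bits = 16)
  vec <- site_features(sites, "sequence", kernel = kp)
  y <- ifelse(sites$label == "bound", 1L, -1L)
  cv1 <- crossvalidate(vectors = vec, labels = y, k = 5, seed = 3)
  cv2 <- crossvalidate(vectors = vec, labels = y, k = 5, seed = 3)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$margins, cv2$margins)
  expect_equal(sort(unique(cv1$fold)), 1:5)
  expect_true(all(table(cv1$fold, y) == 6))
  # permuted labels give chance-level performance
  set.seed(99)
  yp <- sample(y)
  cvp <- crossvalidate(vectors = vec, labels = yp, k = 5, seed = 3)
  expect_lt(abs(cvp$mean_auroc - 0.5), 0.2)
})

test_that("the tuning subset is 1000 sequences or 10 percent, whichever is smaller", {
  expect_equal(tuning_subset_size(50000), 1000L)
  expect_equal(tuning_subset_size(800), 80L)
  expect_equal(tuning_subset_size(10000), 1000L)
})

test_that("line search picks the best grid value and reserves the tuning subset", {
  spec <- synthetic_spec(n_pos = 60, n_neg = 60, seq_len = 30,
                         motif = "ACGUA", seed = 5)
  sites <- generate_classification_set(spec)
  ls <- line_search(sites, grids = list(D = c(0L, 3L)),
                    kernel = kernel_params(R = 1, D = 0, bits = 16),
                    k = 3, seed = 5, max_rounds = 1)
  expect_true(ls$best$D %in% c(0L, 3L))
  expect_length(ls$tuning_idx, tuning_subset_size(120))
  expect_true(all(ls$history$score >= 0 & ls$history$score <= 1))
  # the chosen value scored at least as well as the baseline
  expect_gte(ls$score, max(ls$history$score) - 1e-12)
})

test_that("models write and reload with bit-identical margins", {
  vecs <- c(lapply(1:6, function(i) fv_stub(sample(1:30, 4))),
            lapply(1:6, function(i) fv_stub(sample(31:60, 4))))
  y <- rep(c(1L, -1L), each = 6)
  m <- train_classifier(vecs, y, classifier_params(seed = 8))
  p <- tempfile(fileext = ".model")
  write_model(m, p)
  m2 <- read_model(p)
  expect_identical(m$bias, m2$bias)
  expect_identical(m$w, m2$w)
  expect_identical(m$ids, m2$ids)
  for (v in vecs[1:3]) expect_identical(margin(m, v), margin(m2, v))
})
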