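# Learning on explicit kernel features: Pegasos-style SGD for the
# margin-based classifier, kernlab eps-SVR (precomputed Gram) for affinity
# regression, plus the evaluation metrics and hyperparameter line search.

as_pm1 <- function(labels) {
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(-1, 1)))
    return(as.integer(labels))
  }
  l <- as.character(labels)
  stopifnot(all(l %in% c("bound", "unbound")))
  ifelse(l == "bound", 1L, -1L)
}

#' Train the margin-based classifier by stochastic gradient descent
#'
#' Minimizes the lambda-regularized hinge loss over the explicit feature
#' vectors with a Pegasos-style schedule (`eta_t = 1 / (lambda * (t + t0))`,
#' per-epoch seeded shuffling, unregularized bias). Deterministic under a
#' fixed seed.
#'
#' @param vectors List of `sparse_fv` (hashed mode).
#' @param labels `+1`/`-1` integers or `"bound"`/`"unbound"`.
#' @param params A [classifier_params()] object.
#' @return A `graphrbp_model` of kind `"classification"` with sparse
#'   weights and bias.
#' @export
train_classifier <- function(vectors, labels, params = classifier_params()) {
  y <- as_pm1(labels)
  n <- length(vectors)
  stopifnot(n == length(y))
  if (length(unique(y)) < 2L) stop("need at least one example per class")
  stopifnot(is.numeric(vectors[[1L]]$ids))
  bits <- vectors[[1L]]$params$bits
  w <- numeric(2^bits)
  s <- 1.0; b <- 0.0
  lambda <- params$lambda
  t0 <- 1 / lambda
  t <- 0L
  set.seed(params$seed)
  for (ep in seq_len(params$epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1L
      eta <- 1 / (lambda * (t + t0))
      fv <- vectors[[i]]
      m <- s * sum(w[fv$ids] * fv$val) + b
      s <- s * (1 - eta * lambda)
      if (y[i] * m < 1) {
        w[fv$ids] <- w[fv$ids] + (eta * y[i] / s) * fv$val
        b <- b + eta * y[i]
      }
      if (s < 1e-9) { w <- w * s; s <- 1.0 }
    }
  }
  w <- w * s
  nz <- which(w != 0)
  new_model(kind = "classification", ids = nz, w = w[nz], bias = b,
            kernel = vectors[[1L]]$params, classifier = params)
}

#' Train the epsilon-insensitive support vector regression
#'
#' Solves the eps-SVR dual on the Gram matrix of the explicit feature
#' vectors (via kernlab) and reconstructs the sparse primal weights, so the
#' model predicts by a plain inner product like the classifier.
#'
#' @param vectors List of `sparse_fv` (hashed mode).
#' @param affinities Numeric response (at least two distinct values).
#' @param params A [regression_params()] object.
#' @return A `graphrbp_model` of kind `"regression"`.
#' @export
train_regressor <- function(vectors, affinities, params = regression_params()) {
  n <- length(vectors)
  stopifnot(n == length(affinities))
  if (length(unique(affinities)) < 2L) stop("constant regression targets")
  bits <- vectors[[1L]]$params$bits
  X <- fv_matrix(vectors, bits)
  G <- as.matrix(Matrix::crossprod(X))
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(G), y = affinities,
                  type = "eps-svr", C = params$c,
                  epsilon = params$epsilon, scaled = FALSE),
    error = function(e) {
      if (grepl("No Support Vectors", conditionMessage(e))) NULL
      else stop(e)
    })
  if (is.null(fit)) {
    # the epsilon tube swallows the whole target range: any flat model
    # centered in the range is optimal
    return(new_model(kind = "regression", ids = integer(0), w = numeric(0),
                     bias = (max(affinities) + min(affinities)) / 2,
                     kernel = vectors[[1L]]$params, regression = params))
  }
  sv <- kernlab::SVindex(fit)
  a <- kernlab::coef(fit)
  if (is.list(a)) a <- a[[1L]]
  wvec <- as.numeric(X[, sv, drop = FALSE] %*% a)
  bias <- -kernlab::b(fit)
  nz <- which(wvec != 0)
  new_model(kind = "regression", ids = nz, w = wvec[nz], bias = bias,
            kernel = vectors[[1L]]$params, regression = params)
}

new_model <- function(kind, ids, w, bias, kernel, classifier = NULL,
                      regression = NULL) {
  structure(list(kind = kind, ids = ids, w = w, bias = bias,
                 kernel = kernel, classifier = classifier,
                 regression = regression),
            class = "graphrbp_model")
}

#' Prediction margin of a model on a feature vector
#'
#' The signed linear score `w . x + bias`. For classification, positive
#' values predict binding and the magnitude tracks affinity.
#'
#' @param model A `graphrbp_model` (or fitted [graphrbp()] object).
#' @param fv A `sparse_fv` extracted with the model's kernel parameters.
#' @return Numeric margin.
#' @export
margin <- function(model, fv) {
  if (inherits(model, "graphrbp")) model <- model$model
  stopifnot(inherits(model, "graphrbp_model"), inherits(fv, "sparse_fv"))
  if (!identical(params_fingerprint(fv$params, "fv"),
                 params_fingerprint(model$kernel, "fv"))) {
    stop("feature vector and model use different kernel parameters")
  }
  m <- match(fv$ids, model$ids)
  ok <- !is.na(m)
  sum(fv$val[ok] * model$w[m[ok]]) + model$bias
}

#' Area under the ROC curve from prediction margins
#'
#' Mann-Whitney formulation; tied margins contribute 1/2.
#'
#' @param margins Numeric scores.
#' @param labels `+1`/`-1` or `"bound"`/`"unbound"`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(margins, labels) {
  y <- as_pm1(labels)
  np <- sum(y == 1L); nn <- sum(y == -1L)
  if (np == 0L || nn == 0L) stop("AUROC undefined with a single class")
  r <- rank(margins)
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision (area under the precision-recall curve)
#'
#' Mean over the positives of the precision at each positive's rank, with
#' margins sorted descending and ties broken by stable input order. Better
#' suited than AUROC for unbalanced classes.
#'
#' @inheritParams auroc
#' @return Average precision in `(0, 1]`.
#' @export
average_precision <- function(margins, labels) {
  y <- as_pm1(labels)
  if (!any(y == 1L)) stop("average precision undefined without positives")
  o <- order(-margins)
  ys <- y[o] == 1L
  prec <- cumsum(ys) / seq_along(ys)
  mean(prec[ys])
}

#' Relative error reduction
#'
#' `(x' - x) / (1 - x)`: the improvement of a performance `x'` over a
#' baseline `x`, measured against the remaining error `1 - x`.
#'
#' @param x Baseline performance in `[0, 1)`.
#' @param x_prime Improved performance.
#' @return Relative error reduction.
#' @export
relative_error_reduction <- function(x, x_prime) {
  if (any(x >= 1)) stop("baseline performance must be < 1")
  (x_prime - x) / (1 - x)
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k) stop("fewer than k examples in one class")
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Tenfold cross-validation of a classification model
#'
#' The data is subdivided into k stratified segments (seeded); a model is
#' trained on k-1 segments and the remaining segment is predicted, so each
#' site is predicted exactly once. Feature vectors are computed once and
#' reused across folds.
#'
#' @param sites `target_sites` with a `label` column, or `NULL` if
#'   `vectors` is given.
#' @param k Number of folds. Default 10.
#' @param seed Fold-assignment and training seed.
#' @param mode,folding,kernel,classifier,backend Passed to the pipeline
#'   (see [graphrbp()]).
#' @param vectors Optional precomputed list of `sparse_fv`.
#' @param labels Labels when `vectors` is given.
#' @return A `graphrbp_cv` object: per-fold and mean AUROC and average
#'   precision, out-of-fold margins, fold assignment.
#' @export
crossvalidate <- function(sites = NULL, k = 10L, seed = 1L,
                          mode = c("sequence", "structure"),
                          folding = folding_params(),
                          kernel = kernel_params(),
                          classifier = classifier_params(),
                          backend = built_in_backend(),
                          vectors = NULL, labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(vectors)) {
    stopifnot(!is.null(sites$label))
    labels <- sites$label
    vectors <- site_features(sites, mode, folding, kernel, backend)
  }
  y <- as_pm1(labels)
  fold <- stratified_folds(y, k, seed)
  marg <- numeric(length(y))
  fold_auc <- fold_apr <- numeric(k)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    cp <- classifier; cp$seed <- classifier$seed + f
    mdl <- train_classifier(vectors[tr], y[tr], cp)
    marg[te] <- vapply(vectors[te], function(v) margin(mdl, v), numeric(1))
    fold_auc[f] <- auroc(marg[te], y[te])
    fold_apr[f] <- average_precision(marg[te], y[te])
  }
  structure(list(fold_auroc = fold_auc, mean_auroc = mean(fold_auc),
                 fold_apr = fold_apr, mean_apr = mean(fold_apr),
                 margins = marg, fold = fold, k = k, seed = seed),
            class = "graphrbp_cv")
}

#' @export
print.graphrbp_cv <- function(x, ...) {
  cat("Cross-validation (", x$k, " folds)\n", sep = "")
  cat("  mean AUROC:", formatC(x$mean_auroc, digits = 4, format = "f"), "\n")
  cat("  mean APR:  ", formatC(x$mean_apr, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Size of the hyperparameter-tuning subset
#'
#' 1,000 sequences or 10% of the available data, whichever is smaller.
#'
#' @param n Number of available examples.
#' @return Integer subset size.
#' @export
tuning_subset_size <- function(n) {
  min(1000L, as.integer(floor(0.1 * n)))
}

#' Round-robin line search over hyperparameters
#'
#' Optimizes one parameter at a time over its grid, all others fixed, in a
#' round-robin fashion, scoring each candidate by cross-validated AUROC on
#' a held-aside stratified tuning subset of [tuning_subset_size()] examples.
#' Cycles until a full round changes nothing or `max_rounds` is reached.
#' The tuning subset must be discarded from subsequent performance
#' assessment; its indices are returned for that purpose.
#'
#' @param sites `target_sites` with labels.
#' @param grids Named list of candidate vectors; names among `R`, `D`,
#'   `abstraction`, `lambda`, `epochs`.
#' @param mode,folding,kernel,classifier,backend Baseline pipeline settings.
#' @param k Folds of the tuning cross-validation. Default 5.
#' @param seed Seed for subset selection and folds.
#' @param max_rounds Maximum full round-robin cycles. Default 3.
#' @return List with `best` (named parameter values), `folding`, `kernel`,
#'   `classifier` (updated objects), `tuning_idx` (row indices used for
#'   tuning, to be excluded downstream) and `history`.
#' @export
line_search <- function(sites, grids, mode = c("sequence", "structure"),
                        folding = folding_params(), kernel = kernel_params(),
                        classifier = classifier_params(),
                        backend = built_in_backend(),
                        k = 5L, seed = 1L, max_rounds = 3L) {
  mode <- match.arg(mode)
  stopifnot(length(grids) >= 1L, !is.null(names(grids)))
  y <- as_pm1(sites$label)
  n <- length(y)
  set.seed(seed)
  m <- tuning_subset_size(n)
  # stratified subset
  idx <- unlist(lapply(unique(y), function(cl) {
    cand <- which(y == cl)
    sample(cand, max(1L, round(m * length(cand) / n)))
  }))
  idx <- sort(idx)
  if (length(unique(y[idx])) < 2L) stop("tuning subset lacks both classes")
  sub <- sites[idx, ]
  cur <- list(R = kernel$R, D = kernel$D, abstraction = folding$abstraction,
              lambda = classifier$lambda, epochs = classifier$epochs)
  score_of <- function(cur) {
    kp <- kernel; kp$R <- as.integer(cur$R); kp$D <- as.integer(cur$D)
    fp <- folding; fp$abstraction <- as.integer(cur$abstraction)
    cp <- classifier; cp$lambda <- cur$lambda
    cp$epochs <- as.integer(cur$epochs)
    cv <- crossvalidate(sub, k = k, seed = seed, mode = mode, folding = fp,
                        kernel = kp, classifier = cp, backend = backend)
    cv$mean_auroc
  }
  history <- list()
  best_score <- score_of(cur)
  for (round in seq_len(max_rounds)) {
    changed <- FALSE
    for (pn in names(grids)) {
      for (val in grids[[pn]]) {
        if (identical(val, cur[[pn]])) next
        cand <- cur; cand[[pn]] <- val
        sc <- score_of(cand)
        history[[length(history) + 1L]] <-
          data.frame(round = round, param = pn, value = val, score = sc)
        if (sc > best_score + 1e-12) {
          best_score <- sc; cur <- cand; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  kernel$R <- as.integer(cur$R); kernel$D <- as.integer(cur$D)
  folding$abstraction <- as.integer(cur$abstraction)
  classifier$lambda <- cur$lambda
  classifier$epochs <- as.integer(cur$epochs)
  list(best = cur, score = best_score, folding = folding, kernel = kernel,
       classifier = classifier, tuning_idx = idx,
       history = do.call(rbind, history))
}

# regularized hinge objective, for monotonicity checks
hinge_objective <- function(vectors, labels, model, lambda) {
  y <- as_pm1(labels)
  ms <- vapply(vectors, function(v) margin(model, v), numeric(1))
  mean(pmax(0, 1 - y * ms)) + lambda / 2 * sum(model$w^2)
}
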