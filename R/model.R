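#' Fit a graph-kernel model of RBP binding preferences
#'
#' The central fitting function: target sites are (optionally) folded into
#' structure hypotheses, encoded as directed annotated hypergraphs, turned
#' into explicit NSPD-kernel feature vectors restricted to the binding-site
#' viewpoint, and a linear model is trained on them — a margin-based
#' classifier (SGD on the regularized hinge loss) for bound/unbound labels,
#' or an epsilon-insensitive support vector regression for continuous
#' affinities.
#'
#' @param sites A `target_sites` data frame (see [build_target_sites()] or
#'   [target_sites_from_seqs()]). Classification uses the `label` column
#'   (`"bound"`/`"unbound"`), regression the `affinity` column; `task` is
#'   inferred from whichever is present.
#' @param task `"classification"` or `"regression"`; inferred if `NULL`.
#' @param mode `"sequence"` (sequence-only graphs) or `"structure"` (full
#'   hypergraph encoding with folded shreps).
#' @param folding A [folding_params()] object.
#' @param kernel A [kernel_params()] object.
#' @param classifier A [classifier_params()] object (classification).
#' @param regression A [regression_params()] object (regression).
#' @param backend Folding backend; default [built_in_backend()].
#' @param verbose Report progress.
#' @return An object of class `graphrbp` with `print`, `summary`, `coef`,
#'   `predict`, `residuals` and `plot` methods.
#' @seealso [crossvalidate()], [line_search()], [nucleotide_profile()],
#'   [extract_motif()]
#' @examples
#' spec <- synthetic_spec(n_pos = 30, n_neg = 30, seq_len = 40,
#'                        motif = "ACGUAC", seed = 7)
#' sites <- generate_classification_set(spec)
#' fit <- graphrbp(sites, mode = "sequence",
#'                 kernel = kernel_params(R = 1, D = 2, bits = 16))
#' fit
#' @export
graphrbp <- function(sites, task = NULL, mode = c("sequence", "structure"),
                     folding = folding_params(), kernel = kernel_params(),
                     classifier = classifier_params(),
                     regression = regression_params(),
                     backend = built_in_backend(), verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(task)) {
    task <- if (any(!is.na(sites$affinity))) "regression" else "classification"
  }
  task <- match.arg(task, c("classification", "regression"))
  if (task == "classification") {
    stopifnot(all(!is.na(sites$label)))
  } else {
    stopifnot(all(!is.na(sites$affinity)))
  }
  if (verbose) message("encoding ", nrow(sites), " sites (", mode, " mode)")
  vectors <- site_features(sites, mode, folding, kernel, backend, verbose)
  model <- if (task == "classification") {
    train_classifier(vectors, sites$label, classifier)
  } else {
    train_regressor(vectors, sites$affinity, regression)
  }
  fitted <- vapply(vectors, function(v) margin(model, v), numeric(1))
  obj <- structure(list(model = model, task = task, mode = mode,
                        folding = folding, kernel = kernel,
                        classifier = classifier, regression = regression,
                        backend_name = backend$name,
                        fitted = fitted,
                        labels = sites$label, affinities = sites$affinity,
                        n_sites = nrow(sites), call = match.call()),
                   class = "graphrbp")
  obj
}

#' @export
print.graphrbp <- function(x, ...) {
  cat("Graph-kernel RBP binding model (", x$task, ", ", x$mode,
      " mode)\n", sep = "")
  cat("  sites: ", x$n_sites, "; kernel R=", x$kernel$R, " D=", x$kernel$D,
      " bits=", x$kernel$bits, sep = "")
  if (x$mode == "structure") {
    cat("; abstraction level ", x$folding$abstraction, sep = "")
  }
  cat("\n  nonzero weights: ", length(x$model$w),
      "; bias: ", formatC(x$model$bias, digits = 4, format = "g"),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.graphrbp <- function(object, ...) {
  out <- list(task = object$task, mode = object$mode,
              n_sites = object$n_sites,
              n_weights = length(object$model$w))
  if (object$task == "classification") {
    out$train_auroc <- auroc(object$fitted, object$labels)
    out$train_apr <- average_precision(object$fitted, object$labels)
  } else {
    out$train_rmse <- sqrt(mean((object$fitted - object$affinities)^2))
    out$train_spearman <- cor(object$fitted, object$affinities,
                              method = "spearman")
  }
  structure(out, class = "summary.graphrbp")
}

#' @export
print.summary.graphrbp <- function(x, ...) {
  cat("Graph-kernel RBP binding model (", x$task, ", ", x$mode, " mode)\n",
      sep = "")
  cat("  sites:", x$n_sites, " nonzero weights:", x$n_weights, "\n")
  if (!is.null(x$train_auroc)) {
    cat("  training AUROC:", formatC(x$train_auroc, digits = 4, format = "f"),
        " APR:", formatC(x$train_apr, digits = 4, format = "f"), "\n")
  } else {
    cat("  training RMSE:", formatC(x$train_rmse, digits = 4, format = "f"),
        " Spearman:", formatC(x$train_spearman, digits = 4, format = "f"),
        "\n")
  }
  invisible(x)
}

#' @export
coef.graphrbp <- function(object, ...) {
  setNames(object$model$w, as.character(object$model$ids))
}

#' Predict from a fitted graph-kernel RBP model
#'
#' @param object A fitted [graphrbp()] object.
#' @param newdata A `target_sites` data frame.
#' @param type `"margin"` for one signed score per site, `"profile"` for
#'   per-nucleotide profiles (list of [nucleotide_profile()] results).
#' @param ... Unused.
#' @return Numeric margins, or a list of profiles.
#' @export
predict.graphrbp <- function(object, newdata,
                             type = c("margin", "profile"), ...) {
  type <- match.arg(type)
  backend <- if (identical(object$backend_name, "viennarna"))
    viennarna_backend() else built_in_backend()
  if (type == "margin") {
    vectors <- site_features(newdata, object$mode, object$folding,
                             object$kernel, backend)
    return(vapply(vectors, function(v) margin(object$model, v), numeric(1)))
  }
  lapply(seq_len(nrow(newdata)), function(i) {
    g <- encode_site(newdata[i, ], object$mode, object$folding, backend)
    prof <- nucleotide_profile(object$model, g)
    attr(prof, "site_id") <- newdata$site_id[i]
    prof
  })
}

#' @export
residuals.graphrbp <- function(object, ...) {
  if (object$task != "regression") {
    stop("residuals are defined for regression fits")
  }
  object$fitted - object$affinities
}

#' Plot a fitted graph-kernel RBP model
#'
#' For classification, overlaid histograms of the training margins per
#' class; for regression, fitted against observed affinities.
#'
#' @param x A fitted [graphrbp()] object.
#' @param ... Passed to the underlying graphics call.
#' @export
plot.graphrbp <- function(x, ...) {
  if (x$task == "classification") {
    y <- as_pm1(x$labels)
    rng <- range(x$fitted)
    br <- seq(rng[1L], rng[2L], length.out = 30L)
    hp <- hist(x$fitted[y == 1L], breaks = br, plot = FALSE)
    hn <- hist(x$fitted[y == -1L], breaks = br, plot = FALSE)
    ymax <- max(hp$counts, hn$counts)
    plot(hp, col = grDevices::adjustcolor("firebrick", 0.5),
         ylim = c(0, ymax), main = "Training margins",
         xlab = "prediction margin", ...)
    plot(hn, col = grDevices::adjustcolor("steelblue", 0.5), add = TRUE)
    graphics::legend("topleft", fill = c("firebrick", "steelblue"),
                     legend = c("bound", "unbound"), bty = "n")
  } else {
    plot(x$affinities, x$fitted, xlab = "observed affinity",
         ylab = "fitted margin", main = "Regression fit", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Write a model to a self-describing text archive
#'
#' Header lines record all hyperparameters; the weight table lists
#' `feature_id value` pairs at full precision, so a written model reloads
#' bit-identically.
#'
#' @param model A `graphrbp_model` or fitted `graphrbp` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  mode <- "sequence"; folding <- NULL
  if (inherits(model, "graphrbp")) {
    mode <- model$mode; folding <- model$folding; model <- model$model
  }
  k <- model$kernel
  hdr <- c("graphrbp-model\t1",
           paste0("kind\t", model$kind),
           paste0("mode\t", mode),
           paste0("R\t", k$R), paste0("D\t", k$D), paste0("bits\t", k$bits),
           paste0("exact_mode\t", as.integer(k$exact_mode)),
           paste0("undirected\t", as.integer(k$undirected)))
  if (!is.null(folding)) {
    hdr <- c(hdr,
             paste0("window_len\t", folding$window_len),
             paste0("step\t", folding$step),
             paste0("max_shreps\t", folding$max_shreps),
             paste0("energy_band\t", sprintf("%.17g", folding$energy_band)),
             paste0("abstraction\t", folding$abstraction))
  }
  hdr <- c(hdr, paste0("bias\t", sprintf("%.17g", model$bias)), "weights")
  wl <- sprintf("%s\t%.17g", as.character(model$ids), model$w)
  writeLines(c(hdr, wl), path)
  invisible(path)
}

#' Read a model written by [write_model()]
#' @param path Path to the model archive.
#' @return A `graphrbp_model`.
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  stopifnot(grepl("^graphrbp-model\t", lines[1L]))
  wi <- match("weights", lines)
  kv <- strsplit(lines[2:(wi - 1L)], "\t", fixed = TRUE)
  h <- setNames(vapply(kv, `[`, character(1), 2L),
                vapply(kv, `[`, character(1), 1L))
  k <- kernel_params(R = as.integer(h["R"]), D = as.integer(h["D"]),
                     bits = as.integer(h["bits"]),
                     exact_mode = h["exact_mode"] == "1",
                     undirected = h["undirected"] == "1")
  wt <- strsplit(lines[seq.int(wi + 1L, length(lines))], "\t", fixed = TRUE)
  ids <- vapply(wt, `[`, character(1), 1L)
  if (!k$exact_mode) ids <- as.integer(ids)
  new_model(kind = unname(h["kind"]), ids = ids,
            w = as.numeric(vapply(wt, `[`, character(1), 2L)),
            bias = as.numeric(h["bias"]), kernel = k)
}
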