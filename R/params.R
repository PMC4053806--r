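#' Folding parameters
#'
#' Controls how representative secondary structures (shreps) are computed for
#' a target-site context: the context is folded in sliding windows and, per
#' window, up to `max_shreps` shape-representative structures within
#' `energy_band` of the window minimum free energy are kept.
#'
#' @param window_len Window length in nucleotides. Default 150.
#' @param step Window step in nucleotides. Default 37.
#' @param max_shreps Maximum shape representatives kept per window. Default 3.
#' @param energy_band Fraction of the window MFE defining the suboptimal
#'   energy band: for a negative MFE, structures with energy
#'   `E <= (1 - energy_band) * MFE` are eligible. Default 0.10.
#' @param abstraction Shape abstraction level, one of 1, 3 or 5. Level 5
#'   records the helix arrangement only (e.g. `"[]"`), level 3 additionally
#'   keeps helix breaks caused by internal loops and bulges, level 1 keeps
#'   all loop detail including unpaired stretches (`"_"`). Stem lengths are
#'   always ignored. Default 3.
#' @param max_enum Cap on structures enumerated per window by the built-in
#'   folder before shape grouping. Default 40.
#' @return An object of class `folding_params`.
#' @export
folding_params <- function(window_len = 150L, step = 37L, max_shreps = 3L,
                           energy_band = 0.10, abstraction = 3L,
                           max_enum = 40L) {
  window_len <- as.integer(window_len); step <- as.integer(step)
  max_shreps <- as.integer(max_shreps)
  stopifnot(window_len >= step, step >= 1L, max_shreps >= 1L,
            energy_band > 0, energy_band < 1,
            abstraction %in% c(1L, 3L, 5L))
  structure(list(window_len = window_len, step = step,
                 max_shreps = max_shreps, energy_band = energy_band,
                 abstraction = as.integer(abstraction),
                 max_enum = as.integer(max_enum)),
            class = "folding_params")
}

#' Kernel parameters
#'
#' Parameters of the NSPD graph-kernel explicit feature map: pairs of
#' same-radius neighborhood subgraphs at bounded distance, restricted to the
#' binding-site viewpoint.
#'
#' @param R Maximum neighborhood radius (features use all radii r <= R).
#' @param D Maximum root distance (all distances `d <= D`).
#' @param bits Hashed feature-space size is `2^bits`. Default 20.
#' @param exact_mode If `TRUE`, features are keyed by their canonical string
#'   instead of a hashed index (collision-free; used for testing/oracles).
#' @param undirected If `TRUE`, edges are traversed ignoring orientation.
#'   Provided as a negative control: undirected traversal cannot
#'   discriminate a sequence from its reverse. Default `FALSE`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(R = 2L, D = 5L, bits = 20L, exact_mode = FALSE,
                          undirected = FALSE) {
  R <- as.integer(R); D <- as.integer(D); bits <- as.integer(bits)
  stopifnot(R >= 0L, D >= 0L, bits >= 8L, bits <= 30L)
  structure(list(R = R, D = D, bits = bits,
                 exact_mode = isTRUE(exact_mode),
                 undirected = isTRUE(undirected)),
            class = "kernel_params")
}

#' Classifier parameters
#'
#' Parameters of the stochastic-gradient-descent (Pegasos-style) linear
#' classifier on the explicit kernel features: the regularization strength
#' `lambda` and the number of training `epochs` trade off fit against
#' regularization.
#'
#' @param lambda Regularization strength (> 0). Default 1e-3.
#' @param epochs Number of passes over the training set. Default 20.
#' @param seed Seed for the per-epoch example shuffling. Default 1.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(lambda = 1e-3, epochs = 20L, seed = 1L) {
  stopifnot(lambda > 0, epochs >= 1)
  structure(list(lambda = lambda, epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "classifier_params")
}

#' Regression parameters
#'
#' Parameters of the epsilon-insensitive support vector regression used for
#' affinity data: `c` and `epsilon` trade off fit against regularization.
#'
#' @param c Cost parameter (> 0). Default 1.
#' @param epsilon Width of the insensitive tube (>= 0). Default 0.1.
#' @return An object of class `regression_params`.
#' @export
regression_params <- function(c = 1, epsilon = 0.1) {
  stopifnot(c > 0, epsilon >= 0)
  structure(list(c = c, epsilon = epsilon), class = "regression_params")
}

params_fingerprint <- function(kernel, mode) {
  paste(kernel$R, kernel$D, kernel$bits, kernel$exact_mode,
        kernel$undirected, mode, sep = "/")
}
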