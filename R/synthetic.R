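# Synthetic data with known ground truth: random-background transcripts with
# implanted sequence motifs, optionally constrained to structural contexts
# (hairpin loop, stem), bound/unbound labels, and continuous affinities
# driven by motif match quality plus noise. Emulates the shape of CLIP-seq
# (classification) and in-vitro affinity (regression) training data; it does
# not simulate read-level artifacts.

#' Specification of a synthetic data set
#'
#' @param n_pos,n_neg Numbers of bound/unbound sequences.
#' @param seq_len Sequence length in nucleotides. Default 60.
#' @param motif Implanted RNA motif. Default an 8-mer.
#' @param motif_context `"anywhere"` (unconstrained placement),
#'   `"hairpin_loop"` (motif framed by a complementary stem so it folds
#'   into a hairpin loop) or `"stem_flanked"` (motif paired with its
#'   reverse complement downstream, so it sits in a stem).
#' @param mutation_rate Per-position probability of mutating an implanted
#'   motif position. Default 0.1.
#' @param affinity_noise_sd Gaussian noise on affinities, as a standard
#'   deviation on the match-score scale (signal amplitude 2). Default 0.25.
#' @param stem_len Stem length for structured contexts. Default 8.
#' @param decoy_motif Implant the motif (unconstrained) into negatives too,
#'   so only the structural context separates the classes. Default `FALSE`.
#' @param markov1 Use a first-order Markov background instead of i.i.d.
#'   uniform. Default `FALSE`.
#' @param seed Integer seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_pos = 500L, n_neg = 500L, seq_len = 60L,
                           motif = "UCAUGUAC",
                           motif_context = c("anywhere", "hairpin_loop",
                                             "stem_flanked"),
                           mutation_rate = 0.1, affinity_noise_sd = 0.25,
                           stem_len = 8L, decoy_motif = FALSE,
                           markov1 = FALSE, seed = 1L) {
  motif_context <- match.arg(motif_context)
  motif <- chartr("T", "U", toupper(motif))
  stopifnot(nchar(motif) < seq_len, mutation_rate >= 0, mutation_rate <= 1,
            affinity_noise_sd >= 0)
  if (motif_context != "anywhere" &&
      nchar(motif) + 2L * stem_len + 2L > seq_len) {
    stop("sequence too short for the structured motif context")
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 seq_len = as.integer(seq_len), motif = motif,
                 motif_context = motif_context,
                 mutation_rate = mutation_rate,
                 affinity_noise_sd = affinity_noise_sd,
                 stem_len = as.integer(stem_len),
                 decoy_motif = isTRUE(decoy_motif),
                 markov1 = isTRUE(markov1), seed = as.integer(seed)),
            class = "synthetic_spec")
}

.BASES <- c("A", "C", "G", "U")

random_background <- function(n, len, markov1 = FALSE) {
  if (!markov1) {
    m <- matrix(sample(.BASES, n * len, replace = TRUE), nrow = n)
    return(apply(m, 1L, paste, collapse = ""))
  }
  # mildly sticky first-order chain
  P <- matrix(0.15, 4, 4, dimnames = list(.BASES, .BASES))
  diag(P) <- 0.55
  vapply(seq_len(n), function(i) {
    s <- character(len)
    s[1L] <- sample(.BASES, 1L)
    for (p in seq_len(len - 1L)) {
      s[p + 1L] <- sample(.BASES, 1L, prob = P[s[p], ])
    }
    paste(s, collapse = "")
  }, character(1))
}

mutate_motif <- function(motif, rate) {
  ch <- strsplit(motif, "")[[1]]
  hit <- runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(.BASES, b), 1L),
                      character(1))
  }
  paste(ch, collapse = "")
}

implant <- function(seq, insert, at) {
  paste0(substr(seq, 1L, at - 1L), insert,
         substr(seq, at + nchar(insert), nchar(seq)))
}

#' Generate a labeled classification set
#'
#' Positives are background sequences with the (per-position mutated) motif
#' implanted at a random position; for structured contexts the flanks are
#' designed complementary so the motif folds into the requested context
#' under the built-in folder. Negatives are background only (or carry an
#' unconstrained motif copy when `decoy_motif` is set). The viewpoint spans
#' the whole sequence. Reproducible byte-for-byte under a fixed seed.
#'
#' @param spec A [synthetic_spec()] object.
#' @return A `target_sites` data frame with a `label` column.
#' @export
generate_classification_set <- function(spec) {
  set.seed(spec$seed)
  len <- spec$seq_len; mlen <- nchar(spec$motif)
  pos <- random_background(spec$n_pos, len, spec$markov1)
  neg <- random_background(spec$n_neg, len, spec$markov1)
  if (spec$n_pos > 0L) {
    for (i in seq_len(spec$n_pos)) {
      m <- mutate_motif(spec$motif, spec$mutation_rate)
      if (spec$motif_context == "anywhere") {
        at <- sample.int(len - mlen + 1L, 1L)
        pos[i] <- implant(pos[i], m, at)
      } else if (spec$motif_context == "hairpin_loop") {
        # GC stem; homopolymer runs capped at 2 to avoid slipped foldings
        # that swallow loop edges
        repeat {
          s5 <- sample(c("G", "C"), spec$stem_len, replace = TRUE)
          if (max(rle(s5)$lengths) <= 2L) break
        }
        stem5 <- paste(s5, collapse = "")
        ins <- paste0(stem5, m, rna_revcomp(stem5))
        at <- sample.int(len - nchar(ins) + 1L, 1L)
        pos[i] <- implant(pos[i], ins, at)
      } else {   # stem_flanked: motif paired with its reverse complement
        spacer <- paste(rep("A", 4L), collapse = "")
        ins <- paste0(m, spacer, rna_revcomp(m))
        at <- sample.int(len - nchar(ins) + 1L, 1L)
        pos[i] <- implant(pos[i], ins, at)
      }
    }
  }
  if (spec$decoy_motif && spec$n_neg > 0L) {
    gc_arm <- function() {
      repeat {
        s <- sample(c("G", "C"), spec$stem_len, replace = TRUE)
        if (max(rle(s)$lengths) <= 2L) return(paste(s, collapse = ""))
      }
    }
    for (i in seq_len(spec$n_neg)) {
      m <- mutate_motif(spec$motif, spec$mutation_rate)
      if (spec$motif_context == "hairpin_loop") {
        # composition-matched decoy: same GC arms flanking the motif, but
        # the arms are independent, so no hairpin forms around the motif;
        # only the base-pairing relation separates the classes
        ins <- paste0(gc_arm(), m, gc_arm())
        at <- sample.int(len - nchar(ins) + 1L, 1L)
        neg[i] <- implant(neg[i], ins, at)
      } else {
        at <- sample.int(len - mlen + 1L, 1L)
        neg[i] <- implant(neg[i], m, at)
      }
    }
  }
  seqs <- c(pos, neg)
  names(seqs) <- sprintf("s%04d", seq_along(seqs))
  ts <- target_sites_from_seqs(seqs)
  ts$label <- rep(c("bound", "unbound"), c(spec$n_pos, spec$n_neg))
  ts
}

#' Best motif match score of a sequence
#'
#' Maximum fraction of matching positions over all alignments of the motif.
#'
#' @param seqs Character vector of sequences.
#' @param motif Motif string.
#' @return Numeric scores in `[0, 1]`.
#' @export
motif_match_score <- function(seqs, motif) {
  mlen <- nchar(motif)
  mch <- strsplit(motif, "")[[1]]
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < mlen) return(0)
    ch <- strsplit(s, "")[[1]]
    best <- 0L
    for (at in seq_len(n - mlen + 1L)) {
      hits <- sum(ch[at:(at + mlen - 1L)] == mch)
      if (hits > best) best <- hits
    }
    best / mlen
  }, numeric(1), USE.NAMES = FALSE)
}

#' Occupancy-style motif match score of a sequence
#'
#' Log of the sum over all motif-length windows of Boltzmann-weighted match
#' qualities, `log(sum_w exp(beta * (match_w - 1)))`: the equilibrium
#' log-occupancy of a protein whose binding energy degrades by `beta /
#' motif length` per mismatch. Unlike the best-match score this responds to
#' every partial site, which is what a bulk binding assay measures.
#'
#' @param seqs Character vector of sequences.
#' @param motif Motif string.
#' @param beta Mismatch sharpness. Default 8 (about one unit per mismatch
#'   for an 8-mer).
#' @return Numeric scores (log scale).
#' @export
motif_occupancy_score <- function(seqs, motif, beta = 8) {
  mch <- strsplit(motif, "")[[1]]
  mlen <- length(mch)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < mlen) return(-Inf)
    q <- vapply(seq_len(n - mlen + 1L), function(at)
      sum(ch[at:(at + mlen - 1L)] == mch) / mlen, numeric(1))
    log(sum(exp(beta * (q - 1))))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a continuous-affinity set
#'
#' Each of the first `n_pos` sequences receives a motif copy degraded by a
#' random number of substitutions (the rest stay background), giving a
#' graded range of site qualities. The true signal is the occupancy-style
#' match score ([motif_occupancy_score()]) of the final sequence, and the
#' measured affinity adds Gaussian noise:
#' `affinity = signal + N(0, affinity_noise_sd)`, emulating graded
#' in-vitro binding measurements.
#'
#' @param spec A [synthetic_spec()] object (`n_pos + n_neg` sequences are
#'   generated; positives get implants, negatives stay background).
#' @return A `target_sites` data frame with the measured `affinity` and the
#'   noise-free ground truth in `signal`.
#' @export
generate_affinity_set <- function(spec) {
  set.seed(spec$seed)
  len <- spec$seq_len; mlen <- nchar(spec$motif)
  n <- spec$n_pos + spec$n_neg
  seqs <- random_background(n, len, spec$markov1)
  for (i in seq_len(spec$n_pos)) {
    k <- sample.int(floor(mlen / 2) + 1L, 1L) - 1L   # 0..mlen/2 mutations
    ch <- strsplit(spec$motif, "")[[1]]
    if (k > 0L) {
      at_mut <- sample.int(mlen, k)
      ch[at_mut] <- vapply(ch[at_mut],
                           function(b) sample(setdiff(.BASES, b), 1L),
                           character(1))
    }
    at <- sample.int(len - mlen + 1L, 1L)
    seqs[i] <- implant(seqs[i], paste(ch, collapse = ""), at)
  }
  signal <- motif_occupancy_score(seqs, spec$motif)
  aff <- signal + rnorm(n, 0, spec$affinity_noise_sd)
  names(seqs) <- sprintf("s%04d", seq_len(n))
  ts <- target_sites_from_seqs(seqs)
  ts$affinity <- aff
  ts$signal <- signal
  ts
}
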