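# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Stratified fold assignment
#'
#' Assigns each trial to one of `k` folds so that every fold holds a
#' near-equal share of each class. Used for both the outer three-fold
#' assessment and the classifier's inner fitness folds, so that spatial
#' filters and feature standardization can be fitted leakage-free on
#' training folds only.
#'
#' @param labels class label per trial (coerced to factor).
#' @param k number of folds.
#' @param seed integer seed for the within-class shuffle (`NULL` leaves the
#'   RNG state alone).
#' @return integer vector of fold indices in `1:k`, one per trial.
#' @export
stratified_folds <- function(labels, k, seed = NULL) {
  labels <- as.factor(labels)
  if (k < 2) stop("k must be at least 2")
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Welch power spectral density (one-sided, density scaling), Hann windows.
# x: numeric vector or channels-in-columns matrix; returns list(freq, psd)
# where psd has one column per input column. Segment length in samples.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (seg_len > n) stop("segment longer than signal")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / seg_len)  # periodic Hann
  u <- sum(w^2)
  nf <- seg_len %/% 2 + 1L
  acc <- matrix(0, nf, ncol(x))
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L), , drop = FALSE] * w
    sp <- mvfft(seg)[seq_len(nf), , drop = FALSE]
    acc <- acc + Mod(sp)^2
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double all interior bins (DC and Nyquist appear once)
  interior <- seq(2L, nf - if (seg_len %% 2L == 0L) 1L else 0L)
  psd[interior, ] <- 2 * psd[interior, ]
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = psd)
}

# Integrated band power [lo, hi) from a welch_psd result, per column.
band_power <- function(wp, lo, hi) {
  df <- wp$freq[2] - wp$freq[1]
  sel <- wp$freq >= lo & wp$freq < hi
  colSums(wp$psd[sel, , drop = FALSE]) * df
}

# Power of a sinusoidal component at frequency f0 (amplitude^2 / 2 estimate)
# via quadrature correlation; used by cleaning reports and tests.
tone_power <- function(x, fs, f0) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  s <- sum(x * sin(2 * pi * f0 * t))
  c <- sum(x * cos(2 * pi * f0 * t))
  2 * (s^2 + c^2) / n^2
}

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
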