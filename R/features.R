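# Trial features: per-channel mean square (time domain), Welch band powers
# (frequency domain), CSP log-variance (spatial domain), fused into one
# standardized feature matrix.

#' Mean-square amplitude per channel
#'
#' `value[t, c] = mean(x[t, c, ]^2)` over the MI window — the time-domain
#' feature block.
#'
#' @param epochs an `epoch_set`.
#' @return trials x channels matrix, columns named `ms:<channel>`.
#' @export
mean_square_feature <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop("empty epoch set")
  out <- apply(epochs$data^2, c(1, 2), mean)
  colnames(out) <- paste0("ms:", channel_names(epochs))
  out
}

channel_names <- function(epochs) {
  dimnames(epochs$data)[[2]] %||% paste0("ch", seq_len(dim(epochs$data)[2]))
}

# One trial as a channels x samples matrix (dimension-drop safe).
epoch_matrix <- function(arr, t) {
  matrix(arr[t, , ], nrow = dim(arr)[2])
}

#' Welch band-power features
#'
#' Welch periodogram (Hann windows, 50% overlap by default) per trial and
#' channel, integrated over the mu and beta bands — the frequency-domain
#' feature block.
#'
#' @param epochs an `epoch_set`.
#' @param segment_s Welch segment length in seconds.
#' @param overlap fractional segment overlap.
#' @param bands named list of `c(lo, hi)` band edges in Hz.
#' @return trials x (channels * bands) matrix, columns named
#'   `psd:<band>:<channel>`.
#' @export
psd_band_features <- function(epochs, segment_s = 1.0, overlap = 0.5,
                              bands = list(mu = c(8, 13), beta = c(13, 32))) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  if (d[1] == 0) stop("empty epoch set")
  fs <- epochs$sample_rate_hz
  for (b in bands)
    if (b[2] > fs / 2) stop("band extends beyond the Nyquist frequency")
  seg <- as.integer(round(segment_s * fs))
  if (seg > d[3]) stop("segment longer than the epoch")
  nb <- length(bands)
  out <- matrix(0, d[1], d[2] * nb)
  for (t in seq_len(d[1])) {
    wp <- welch_psd(t(epoch_matrix(epochs$data, t)), fs, seg, overlap)
    for (j in seq_len(nb))
      out[t, ((j - 1) * d[2] + 1):(j * d[2])] <-
        band_power(wp, bands[[j]][1], bands[[j]][2])
  }
  colnames(out) <- as.vector(vapply(names(bands), function(bn)
    paste0("psd:", bn, ":", channel_names(epochs)), character(d[2])))
  out
}

# Trace-normalized covariance of one epoch (channels x samples matrix).
trial_covariance <- function(x) {
  cv <- tcrossprod(x) / ncol(x)
  cv / sum(diag(cv))
}

#' Fit common spatial patterns
#'
#' Estimates per-class mean covariances from trace-normalized per-trial
#' covariances, whitens their composite, and eigendecomposes the whitened
#' class-1 covariance. Each filter's eigenvalue is the class-1 share of
#' variance in that direction; the class-2 share is its complement, so the
#' first and last filters are the most discriminative. A small ridge
#' (1e-9 x trace) keeps the composite invertible on short epochs.
#'
#' @param epochs an `epoch_set`, or a trials x channels x samples array.
#' @param labels class labels (taken from `epochs` when omitted); class 1 is
#'   the first factor level.
#' @param n_pairs filter pairs retained at feature time (default 3).
#' @return a `csp_model` with `filters` (rows are filters, sorted by
#'   descending eigenvalue), `eigenvalues`, `n_pairs`, `class_covariances`.
#' @export
fit_csp <- function(epochs, labels = NULL, n_pairs = 3) {
  if (inherits(epochs, "epoch_set")) {
    labels <- labels %||% epochs$labels
    arr <- epochs$data
  } else arr <- epochs
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2) stop("CSP needs exactly two classes")
  d <- dim(arr)
  covs <- lapply(seq_len(d[1]), function(t)
    trial_covariance(epoch_matrix(arr, t)))
  cls <- levels(labels)
  c1 <- Reduce(`+`, covs[labels == cls[1]]) / sum(labels == cls[1])
  c2 <- Reduce(`+`, covs[labels == cls[2]]) / sum(labels == cls[2])
  csp_from_covariances(c1, c2, n_pairs, classes = cls)
}

#' CSP from class covariance matrices
#'
#' The core simultaneous-diagonalization step, exposed directly for worked
#' examples and cross-checks: whiten `c1 + c2`, eigendecompose the whitened
#' `c1`, sort descending. For class covariances `diag(2, 1)` and
#' `diag(1, 2)` the eigenvalues are 2/3 and 1/3 with axis-aligned filters.
#'
#' @param c1,c2 symmetric class covariance matrices.
#' @param n_pairs filter pairs retained at feature time.
#' @param classes class names carried in the model.
#' @return a `csp_model`.
#' @export
csp_from_covariances <- function(c1, c2, n_pairs = 3,
                                 classes = c("left", "right")) {
  comp <- c1 + c2
  comp <- comp + diag(1e-9 * sum(diag(comp)), nrow(comp))
  ec <- eigen(comp, symmetric = TRUE)
  if (min(ec$values) <= 0)
    stop("composite covariance is singular; add regularization")
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)   # whitening
  S1 <- P %*% c1 %*% t(P)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)    # descending eigenvalues
  W <- t(e1$vectors) %*% P                           # rows are filters
  structure(list(filters = W, eigenvalues = e1$values,
                 n_pairs = as.integer(n_pairs),
                 class_covariances = list(c1, c2), classes = classes),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model: %d filters, %d pairs retained, top eig %.3f>\n",
              nrow(x$filters), x$n_pairs, x$eigenvalues[1]))
  invisible(x)
}

#' Normalized CSP log-variance features
#'
#' Projects each epoch on the first and last `n_pairs` filters and returns
#' `log(var_j / sum_j var_j)` — the spatial-domain feature block.
#'
#' @param model a fitted `csp_model`.
#' @param epochs an `epoch_set` with the same channel count.
#' @return trials x (2 * n_pairs) matrix, columns named `csp:f<k>`.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  nch <- nrow(model$filters)
  if (d[2] != nch) stop("channel count does not match the CSP model")
  sel <- c(seq_len(model$n_pairs), (nch - model$n_pairs + 1L):nch)
  W <- model$filters[sel, , drop = FALSE]
  out <- matrix(0, d[1], length(sel))
  for (t in seq_len(d[1])) {
    z <- W %*% epoch_matrix(epochs$data, t)
    v <- apply(z, 1, var)
    out[t, ] <- log(v / sum(v))
  }
  colnames(out) <- paste0("csp:f", sel)
  out
}

#' Fuse feature blocks into a standardized matrix
#'
#' Binds the blocks column-wise and z-scores every column using means and
#' standard deviations computed on the training rows only, so no test-fold
#' statistics leak into the features.
#'
#' @param ... feature blocks (matrices with equal row counts).
#' @param train_idx row indices treated as training data (default all rows).
#' @return a `feature_matrix`: list with standardized `values`, the
#'   `center`/`scale` vectors and `train_idx`.
#' @export
assemble_features <- function(..., train_idx = NULL) {
  blocks <- list(...)
  n <- unique(vapply(blocks, nrow, 0L))
  if (length(n) != 1) stop("feature blocks have mismatched trial counts")
  values <- do.call(cbind, blocks)
  train_idx <- train_idx %||% seq_len(n)
  center <- colMeans(values[train_idx, , drop = FALSE])
  scale <- apply(values[train_idx, , drop = FALSE], 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  values <- sweep(sweep(values, 2, center), 2, scale, `/`)
  structure(list(values = values, center = center, scale = scale,
                 train_idx = train_idx),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix: %d trials x %d features>\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
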