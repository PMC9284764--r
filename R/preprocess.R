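# Four-stage cleaning chain: moving-average baseline removal -> adaptive
# 50 Hz LMS cancellation -> ICA blink removal -> zero-phase 8-32 Hz
# Butterworth band-pass, followed by MI-window epoching. The stage order is
# fixed; preprocess_chain() is the driver.

new_cleaning_report <- function(stage, metrics) {
  structure(list(stage = stage, metrics = metrics),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("<cleaning_report: %s>\n", x$stage))
  str(x$metrics, give.attr = FALSE)
  invisible(x)
}

#' Serialize a cleaning report as a JSON log line
#'
#' @param report a `cleaning_report`.
#' @return a single-line JSON string.
#' @export
cleaning_report_json <- function(report) {
  stopifnot(inherits(report, "cleaning_report"))
  as.character(jsonlite::toJSON(list(stage = report$stage,
                                     metrics = report$metrics),
                                auto_unbox = TRUE, digits = NA))
}

#' Remove baseline drift with a centered moving average
#'
#' Subtracts from every channel its centered running mean over `window_s`
#' seconds (reflect-padded at the edges), killing DC offsets and sub-1/window
#' drift while leaving the 8-32 Hz rhythms essentially untouched.
#'
#' @param raw a `raw_recording`.
#' @param window_s averaging window in seconds (default 1.0).
#' @return a `raw_recording`.
#' @export
remove_baseline <- function(raw, window_s = 1.0) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sample_rate_hz
  w <- as.integer(round(window_s * fs))
  if (w %% 2L == 0L) w <- w + 1L  # centered window
  if (w < 3L) stop("window too short: need at least 3 samples")
  n <- ncol(raw$data)
  if (w > n) stop("window longer than recording")
  half <- (w - 1L) %/% 2L
  kern <- rep(1 / w, w)
  data <- raw$data
  for (c in seq_len(nrow(data))) {
    x <- data[c, ]
    xp <- c(rev(x[2:(half + 1L)]), x, rev(x[(n - half):(n - 1L)]))
    m <- stats::filter(xp, kern, sides = 2)
    data[c, ] <- x - as.numeric(m[(half + 1L):(half + n)])
  }
  new_raw_recording(data, fs, raw$channel_labels, schedule = raw$schedule,
                    aux_blink_ref = raw$aux_blink_ref)
}

#' Adaptive cancellation of power-line interference
#'
#' A two-weight LMS adaptive noise canceller with a quadrature (sin/cos)
#' reference at `f0` tracks the interference amplitude and phase per channel
#' and subtracts it, leaving narrowband brain rhythms away from `f0`
#' untouched. The report logs the power of the `f0` component before and
#' after per channel.
#'
#' @param raw a `raw_recording`.
#' @param f0 interference frequency in Hz (default 50).
#' @param lms_step LMS adaptation step; the quadrature reference has unit
#'   amplitude, so convergence speed is independent of signal scale.
#' @return list with elements `raw` (cleaned recording) and `report`
#'   (a `cleaning_report` with before/after `f0` power).
#' @export
remove_line_noise <- function(raw, f0 = 50, lms_step = 0.002) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sample_rate_hz
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency")
  if (lms_step <= 0) stop("lms_step must be positive")
  n <- ncol(raw$data)
  t <- (seq_len(n) - 1) / fs
  sref <- sin(2 * pi * f0 * t)
  cref <- cos(2 * pi * f0 * t)
  data <- raw$data
  before <- after <- numeric(nrow(data))
  for (c in seq_len(nrow(data))) {
    before[c] <- tone_power(data[c, ], fs, f0)
    data[c, ] <- lms_cancel_cpp(data[c, ], sref, cref, lms_step)
    after[c] <- tone_power(data[c, ], fs, f0)
  }
  out <- new_raw_recording(data, fs, raw$channel_labels,
                           schedule = raw$schedule,
                           aux_blink_ref = raw$aux_blink_ref)
  list(raw = out,
       report = new_cleaning_report("line_noise",
                                    list(f0 = f0,
                                         power_before = before,
                                         power_after = after)))
}

component_kurtosis <- function(x) {
  x <- x - mean(x)
  mean(x^4) / mean(x^2)^2
}

power_fraction_below <- function(x, fs, cutoff = 4) {
  sp <- Mod(fft(x - mean(x)))^2
  nf <- length(x) %/% 2 + 1L
  f <- (seq_len(nf) - 1) * fs / length(x)
  sum(sp[seq_len(nf)][f < cutoff]) / sum(sp[seq_len(nf)])
}

#' ICA-based removal of blink (EOG) artifacts
#'
#' Decomposes the recording with FastICA and zeroes components identified as
#' ocular. When the recording carries a blink reference trace
#' (`aux_blink_ref`, as produced by [inject_artifacts()]), a component is
#' flagged if its absolute correlation with the reference exceeds
#' `corr_threshold`; otherwise a component is flagged if it is both
#' heavy-tailed (kurtosis above `kurtosis_threshold`) and dominated by
#' sub-4 Hz power (fraction above `lowfreq_fraction`), the signature of
#' sparse slow blink pulses.
#'
#' @param raw a `raw_recording`.
#' @param n_components number of ICA components (default: channel count).
#' @param corr_threshold reference-correlation criterion.
#' @param kurtosis_threshold kurtosis criterion (reference-free mode).
#' @param lowfreq_fraction sub-4 Hz power-fraction criterion
#'   (reference-free mode).
#' @param seed integer seed for the ICA initialization.
#' @return list with `raw` (cleaned) and `report` (flagged components and
#'   their criterion scores).
#' @export
remove_eog <- function(raw, n_components = NULL, corr_threshold = 0.7,
                       kurtosis_threshold = 5.0, lowfreq_fraction = 0.6,
                       seed = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  nch <- nrow(raw$data)
  n <- ncol(raw$data)
  if (n <= nch) stop("need more samples than channels for ICA")
  nc <- as.integer(n_components %||% nch)
  if (nc > nch) stop("n_components cannot exceed the channel count")
  X <- t(raw$data)                       # samples x channels
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  dec <- with_seed(seed, ica::icafast(Xc, nc = nc, center = FALSE,
                                      maxit = 200, tol = 1e-6))
  S <- dec$S                              # samples x nc sources
  M <- dec$M                              # channels x nc mixing
  use_ref <- !is.null(raw$aux_blink_ref)
  scores <- numeric(nc)
  if (use_ref) {
    ref <- raw$aux_blink_ref
    scores <- abs(apply(S, 2, function(s) cor(s, ref)))
    flagged <- which(scores > corr_threshold)
  } else {
    kur <- apply(S, 2, component_kurtosis)
    lf <- apply(S, 2, power_fraction_below, fs = raw$sample_rate_hz)
    scores <- kur
    flagged <- which(kur > kurtosis_threshold & lf > lowfreq_fraction)
  }
  keep <- setdiff(seq_len(nc), flagged)
  Xhat <- S[, keep, drop = FALSE] %*% t(M[, keep, drop = FALSE])
  data <- t(sweep(Xhat, 2, mu, `+`))
  out <- new_raw_recording(data, raw$sample_rate_hz, raw$channel_labels,
                           schedule = raw$schedule,
                           aux_blink_ref = raw$aux_blink_ref)
  list(raw = out,
       report = new_cleaning_report("eog_ica",
                                    list(criterion = if (use_ref) "reference"
                                                     else "kurtosis+lowfreq",
                                         flagged = flagged,
                                         scores = scores)))
}

# Sixth-order Butterworth band-pass coefficients (order-3 low-pass
# prototype -> order-6 band-pass transfer function, -3 dB at the edges).
butter_bp <- function(low, high, fs) {
  signal::butter(3, c(low, high) / (fs / 2), type = "pass")
}

#' Zero-phase Butterworth band-pass
#'
#' Applies a sixth-order Butterworth band-pass forward and backward
#' (zero phase). The effective magnitude response is the squared single-pass
#' response, so the gain at the nominal 8 and 32 Hz edges is 0.5.
#'
#' @param raw a `raw_recording`.
#' @param low,high band edges in Hz (defaults 8 and 32).
#' @param order single-pass filter order (6 = order-3 prototype).
#' @return a `raw_recording` containing the 8-32 Hz signals.
#' @export
bandpass <- function(raw, low = 8, high = 32, order = 6) {
  stopifnot(inherits(raw, "raw_recording"))
  fs <- raw$sample_rate_hz
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  if (order %% 2L != 0L) stop("band-pass order must be even")
  bf <- signal::butter(order %/% 2L, c(low, high) / (fs / 2), type = "pass")
  data <- raw$data
  for (c in seq_len(nrow(data)))
    data[c, ] <- signal::filtfilt(bf, data[c, ])
  new_raw_recording(data, fs, raw$channel_labels, schedule = raw$schedule,
                    aux_blink_ref = raw$aux_blink_ref)
}

new_epoch_set <- function(data, labels, sample_rate_hz) {
  stopifnot(length(labels) == dim(data)[1])
  structure(list(data = data, labels = factor(labels,
                                              levels = c("left", "right")),
                 sample_rate_hz = sample_rate_hz),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set: %d trials x %d ch x %d samples @ %g Hz>\n",
              d[1], d[2], d[3], x$sample_rate_hz))
  invisible(x)
}

#' Extract per-trial motor-imagery epochs
#'
#' Cuts the named phase window (default the MI window: 2-7 s of an
#' assessment trial, 1-5 s of a training trial) out of every trial.
#'
#' @param raw a `raw_recording`.
#' @param schedule a `trial_schedule`; defaults to the one attached to `raw`.
#' @param phase phase name to cut (default `"mi"`).
#' @return an `epoch_set` (trials x channels x samples array plus labels).
#' @export
extract_epochs <- function(raw, schedule = NULL, phase = "mi") {
  stopifnot(inherits(raw, "raw_recording"))
  schedule <- schedule %||% raw$schedule
  if (is.null(schedule)) stop("no schedule attached or supplied")
  fs <- raw$sample_rate_hz
  win <- phase_window(schedule, phase)
  len <- as.integer(round((win[2] - win[1]) * fs))
  ntr <- nrow(schedule$events)
  data <- array(0, dim = c(ntr, nrow(raw$data), len))
  for (i in seq_len(ntr)) {
    on <- schedule$events$onset_s[i]
    i0 <- as.integer(round((on + win[1]) * fs)) + 1L
    i1 <- i0 + len - 1L
    if (i1 > ncol(raw$data))
      stop(sprintf("trial %d window extends past the recording end",
                   schedule$events$trial_index[i]))
    data[i, , ] <- raw$data[, i0:i1]
  }
  new_epoch_set(data, if (ntr > 0) schedule$events$label else character(0),
                fs)
}

#' Run the full cleaning chain in its fixed order
#'
#' baseline -> adaptive line-noise cancellation -> ICA blink removal ->
#' band-pass -> epoching. Stage parameters come from the `preprocessing`
#' group of the run configuration.
#'
#' @param raw a `raw_recording`.
#' @param config run configuration (see [default_run_config()]).
#' @param seed seed for the ICA stage.
#' @return list with `epochs` (an `epoch_set`), `raw` (the cleaned
#'   continuous recording) and `reports` (per-stage cleaning reports).
#' @export
preprocess_chain <- function(raw, config = default_run_config(),
                             seed = NULL) {
  p <- config$preprocessing
  r1 <- remove_baseline(raw, p$baseline_window_s)
  r2 <- remove_line_noise(r1, p$line_f0, p$lms_step)
  r3 <- remove_eog(r2$raw, corr_threshold = p$ica_corr_threshold,
                   kurtosis_threshold = p$ica_kurtosis_threshold,
                   lowfreq_fraction = p$ica_lowfreq_fraction, seed = seed)
  r4 <- bandpass(r3$raw, p$band_low, p$band_high)
  list(epochs = extract_epochs(r4),
       raw = r4,
       reports = list(line = r2$report, eog = r3$report))
}
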