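# Synthetic two-class motor-imagery EEG generator.
#
# Generative model: two hemispheric sources fixed at the C3 / C4 positions
# each emit band-limited mu (8-13 Hz) and beta (13-30 Hz) oscillations
# (narrowband-filtered Gaussian noise, unit RMS per band, scaled by the
# subject amplitudes). During a motor-imagery window the CONTRAlateral
# source amplitude is multiplied by (1 - erd_depth * gain): a right-hand
# trial desynchronizes the left source and vice versa. Source-to-channel
# mixing weights are Gaussian in scalp distance, and independent pink noise
# is added per channel. All amplitudes are on an arbitrary microvolt-like
# scale.

#' Subject-level generator parameters
#'
#' @param mu_amp RMS amplitude of each hemispheric mu (8-13 Hz) source.
#' @param beta_amp RMS amplitude of each beta (13-30 Hz) source.
#' @param erd_depth maximal fractional amplitude suppression of the
#'   contralateral source during motor imagery, in `[0, 1]`. The effective
#'   suppression is `erd_depth * gain` of the scene condition.
#' @param pink_noise_sd standard deviation of the per-channel 1/f noise.
#' @param spatial_spread Gaussian width of the source-to-channel mixing
#'   kernel, in scalp-projection units.
#' @param engagement_range per-trial engagement is drawn uniformly from this
#'   interval of `[0, 1]` and multiplies the ERD depth for that trial,
#'   emulating fluctuating imagery vividness/attention across trials (the
#'   dominant source of single-trial recognition errors in practice). Use
#'   `c(1, 1)` for a fully deterministic per-window ERD.
#' @return a `subject_params` list.
#' @export
subject_params <- function(mu_amp = 2, beta_amp = 1, erd_depth = 1,
                           pink_noise_sd = 1, spatial_spread = 0.4,
                           engagement_range = c(0, 1)) {
  if (erd_depth < 0 || erd_depth > 1) stop("erd_depth must be in [0, 1]")
  if (mu_amp < 0 || beta_amp < 0 || pink_noise_sd < 0)
    stop("amplitudes must be non-negative")
  if (length(engagement_range) != 2 || any(engagement_range < 0) ||
      any(engagement_range > 1) || engagement_range[1] > engagement_range[2])
    stop("engagement_range must be an ordered interval within [0, 1]")
  structure(list(mu_amp = mu_amp, beta_amp = beta_amp, erd_depth = erd_depth,
                 pink_noise_sd = pink_noise_sd,
                 spatial_spread = spatial_spread,
                 engagement_range = engagement_range),
            class = "subject_params")
}

#' Scene stimulation condition
#'
#' The scene gain multiplies the subject's ERD depth, emulating how more
#' immersive stimulation (static < dynamic < VR) deepens the contralateral
#' desynchronization.
#'
#' @param name one of `"static"`, `"dynamic"`, `"vr"`.
#' @param gain multiplier in `[0, 1]`; `NULL` picks the packaged default
#'   (static 0.2, dynamic 0.5, vr 0.8).
#' @export
scene_condition <- function(name = c("static", "dynamic", "vr"), gain = NULL) {
  name <- match.arg(name)
  defaults <- c(static = 0.2, dynamic = 0.5, vr = 0.8)
  gain <- gain %||% defaults[[name]]
  if (gain < 0 || gain > 1) stop("gain must be in [0, 1]")
  structure(list(name = name, gain = gain), class = "scene_condition")
}

#' Construct a raw recording
#'
#' Wraps a channels x samples matrix with its sampling rate and channel
#' labels; used for bringing externally generated or probe signals into the
#' pipeline (simulated sessions come from [simulate_session()]).
#'
#' @param data channels x samples numeric matrix.
#' @param sample_rate_hz sampling rate in Hz.
#' @param channel_labels one label per row (default `ch1`, `ch2`, ...).
#' @param schedule optional `trial_schedule` the recording covers.
#' @param aux_blink_ref optional blink reference trace.
#' @return a `raw_recording`.
#' @export
raw_recording <- function(data, sample_rate_hz,
                          channel_labels = paste0("ch", seq_len(nrow(data))),
                          schedule = NULL, aux_blink_ref = NULL) {
  new_raw_recording(as.matrix(data), sample_rate_hz, channel_labels,
                    schedule = schedule, aux_blink_ref = aux_blink_ref)
}

new_raw_recording <- function(data, sample_rate_hz, channel_labels,
                              schedule = NULL, aux_blink_ref = NULL) {
  stopifnot(nrow(data) == length(channel_labels))
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_labels = channel_labels, schedule = schedule,
                 aux_blink_ref = aux_blink_ref),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording: %d ch x %d samples @ %g Hz (%.1f s)%s>\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              ncol(x$data) / x$sample_rate_hz,
              if (!is.null(x$aux_blink_ref)) ", blink ref" else ""))
  invisible(x)
}

# Band-limited Gaussian noise, unit RMS: white noise -> 4th-order
# Butterworth band-pass (zero phase), renormalized.
narrowband_noise <- function(n, fs, lo, hi) {
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / rms(x)
}

# 1/f-amplitude ("pink") noise, unit RMS, via frequency-domain shaping.
pink_noise <- function(n) {
  nf <- n %/% 2 + 1L
  mag <- c(0, 1 / sqrt(seq_len(nf - 1L)))
  phase <- runif(nf, 0, 2 * pi)
  half <- mag * exp(1i * phase)
  if (n %% 2L == 0L) half[nf] <- Re(half[nf])
  spec <- c(half, Conj(rev(half[2:(nf - if (n %% 2L == 0L) 1L else 0L)])))
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / rms(x)
}

# Gaussian mixing weights from each source position to every channel.
mixing_weights <- function(montage, src_pos, spread) {
  d2 <- (montage$positions[, 1] - src_pos[1])^2 +
        (montage$positions[, 2] - src_pos[2])^2
  exp(-d2 / (2 * spread^2))
}

#' Simulate one motor-imagery session
#'
#' Generates a 19-channel recording covering `schedule`. During every
#' motor-imagery window the contralateral hemispheric source amplitude is
#' multiplied by `(1 - erd_depth * gain * engagement)`, where the trial's
#' engagement is drawn uniformly from the subject's `engagement_range`; with
#' full engagement the class-conditional contralateral mu power during MI is
#' reduced by `(1 - erd_depth * gain)^2` in expectation.
#'
#' @param schedule a `trial_schedule` (its MI phase defines the ERD windows).
#' @param subject a [subject_params()] list.
#' @param scene a [scene_condition()].
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @param sample_rate_hz sampling rate (study setting 1000 Hz).
#' @return a `raw_recording` with the schedule attached.
#' @export
simulate_session <- function(schedule, subject = subject_params(),
                             scene = scene_condition("vr"), seed = NULL,
                             sample_rate_hz = 1000) {
  stopifnot(inherits(schedule, "trial_schedule"))
  fs <- sample_rate_hz
  dur <- max(schedule_duration_s(schedule), 1)
  n <- as.integer(round(dur * fs))
  montage <- make_montage()
  with_seed(seed, {
    src_left <- subject$mu_amp * narrowband_noise(n, fs, 8, 13) +
      subject$beta_amp * narrowband_noise(n, fs, 13, 30)
    src_right <- subject$mu_amp * narrowband_noise(n, fs, 8, 13) +
      subject$beta_amp * narrowband_noise(n, fs, 13, 30)

    env_left <- rep(1, n)
    env_right <- rep(1, n)
    if (nrow(schedule$events) > 0) {
      mi <- phase_window(schedule, "mi")
      engagement <- runif(nrow(schedule$events),
                          subject$engagement_range[1],
                          subject$engagement_range[2])
      for (i in seq_len(nrow(schedule$events))) {
        on <- schedule$events$onset_s[i]
        idx <- (as.integer(round((on + mi[1]) * fs)) + 1L):
               as.integer(round((on + mi[2]) * fs))
        factor_i <- 1 - subject$erd_depth * scene$gain * engagement[i]
        if (schedule$events$label[i] == "right") {
          env_left[idx] <- factor_i  # right-hand MI -> left-hemisphere ERD
        } else {
          env_right[idx] <- factor_i
        }
      }
    }

    w_left <- mixing_weights(montage, montage$positions["C3", ],
                             subject$spatial_spread)
    w_right <- mixing_weights(montage, montage$positions["C4", ],
                              subject$spatial_spread)
    data <- outer(w_left, src_left * env_left) +
            outer(w_right, src_right * env_right)
    if (subject$pink_noise_sd > 0) {
      for (c in seq_len(nrow(data)))
        data[c, ] <- data[c, ] + subject$pink_noise_sd * pink_noise(n)
    }
    new_raw_recording(data, fs, montage$labels, schedule = schedule)
  })
}

# Smooth biphasic blink template of about `dur_s` seconds, peak amplitude 1.
blink_template <- function(fs, dur_s = 0.3) {
  t <- seq(0, dur_s, by = 1 / fs)
  w <- sin(2 * pi * t / dur_s) * sin(pi * t / dur_s)^2
  w / max(abs(w))
}

#' Inject baseline drift, 50 Hz line noise and blink artifacts
#'
#' Adds the three noise classes the cleaning chain targets: (i) per-channel
#' random-walk baseline drift, (ii) a common-mode 50 Hz sinusoid with slowly
#' wandering phase, and (iii) biphasic blink pulses (~0.3 s, amplitude
#' `blink_amp`) at Poisson times, weighted strongest on the anterior (FC)
#' row and decaying with distance from the front midline. The clean blink
#' pulse train is stored in `aux_blink_ref` so ICA-based removal can be
#' validated against it.
#'
#' @param raw a `raw_recording`.
#' @param drift_sd drift standard deviation accumulated over 1 s (0 = none).
#' @param line_amp amplitude of the 50 Hz component (0 = none).
#' @param blink_rate_hz mean blink rate (0 = none).
#' @param blink_amp peak amplitude of a blink at the most anterior channels.
#' @param seed integer seed.
#' @return a `raw_recording` with artifacts added.
#' @export
inject_artifacts <- function(raw, drift_sd = 0, line_amp = 0,
                             blink_rate_hz = 0, blink_amp = 40, seed = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  if (drift_sd < 0 || line_amp < 0 || blink_rate_hz < 0 || blink_amp < 0)
    stop("artifact parameters must be non-negative")
  fs <- raw$sample_rate_hz
  n <- ncol(raw$data)
  nch <- nrow(raw$data)
  data <- raw$data
  aux <- raw$aux_blink_ref
  with_seed(seed, {
    if (drift_sd > 0) {
      for (c in seq_len(nch))
        data[c, ] <- data[c, ] + cumsum(rnorm(n, 0, drift_sd / sqrt(fs)))
    }
    if (line_amp > 0) {
      t <- (seq_len(n) - 1) / fs
      phase <- cumsum(rnorm(n, 0, 0.1 / sqrt(fs)))  # slow phase wander
      line <- line_amp * sin(2 * pi * 50 * t + phase)
      data <- data + matrix(line, nch, n, byrow = TRUE)
    }
    if (blink_rate_hz > 0) {
      montage <- make_montage()
      # topographic weight: strongest toward the anterior midline
      front <- c(0, 1)
      d2 <- (montage$positions[, 1] - front[1])^2 +
            (montage$positions[, 2] - front[2])^2
      wch <- exp(-d2 / (2 * 0.5^2))
      tpl <- blink_template(fs)
      train <- numeric(n)
      tt <- rexp(1, blink_rate_hz)
      while (tt < n / fs - length(tpl) / fs) {
        i0 <- as.integer(round(tt * fs)) + 1L
        idx <- i0:(i0 + length(tpl) - 1L)
        train[idx] <- train[idx] + tpl
        tt <- tt + rexp(1, blink_rate_hz)
      }
      data <- data + blink_amp * outer(wch, train)
      aux <- train
    }
  })
  new_raw_recording(data, fs, raw$channel_labels, schedule = raw$schedule,
                    aux_blink_ref = aux)
}
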