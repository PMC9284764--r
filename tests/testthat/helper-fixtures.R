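# Shared fixture builders. All synthetic data is generated in code at test
# time; nothing is read from disk.

# Wrap a plain channels x samples matrix as a recording.
raw_from_matrix <- function(m, fs = 1000, labels = NULL) {
  m <- as.matrix(m)
  raw_recording(m, fs, labels %||% paste0("ch", seq_len(nrow(m))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A sinusoid recording of `dur` seconds on one channel.
sine_raw <- function(freq, dur = 20, fs = 1000, amp = 1) {
  t <- (seq_len(dur * fs) - 1) / fs
  raw_from_matrix(matrix(amp * sin(2 * pi * freq * t), 1), fs)
}

# Epochs of white noise: trials x channels x samples, labels alternating.
noise_epochs <- function(n_trials = 20, n_ch = 4, n_samp = 500, sd = 1,
                         seed = 1, fs = 1000) {
  set.seed(seed)
  arr <- array(rnorm(n_trials * n_ch * n_samp, sd = sd),
               dim = c(n_trials, n_ch, n_samp))
  mibci:::new_epoch_set(arr, rep(c("left", "right"),
                                 length.out = n_trials), fs)
}

# Strongly separable two-class epochs: the first channel's variance differs
# by `ratio` between classes.
separable_epochs <- function(n_trials = 30, n_ch = 4, n_samp = 500,
                             ratio = 10, seed = 2, fs = 1000) {
  ep <- noise_epochs(n_trials, n_ch, n_samp, seed = seed, fs = fs)
  right <- ep$labels == "right"
  ep$data[right, 1, ] <- ep$data[right, 1, ] * sqrt(ratio)
  ep
}

# Two well-separated Gaussian blobs for classifier tests.
gaussian_blobs <- function(n_per_class = 100, d = 5, sep = 6, seed = 3) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * d), ncol = d),
             matrix(rnorm(n_per_class * d, mean = sep), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = factor(rep(c("left", "right"), each = n_per_class)))
}
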