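test_that("mean-square features obey the closed-form identities", {
  ep <- noise_epochs(4, 2, 1000)
  ep$data[1, , ] <- 0
  ep$data[2, , ] <- 2
  ep$data[3, 1, ] <- sqrt(2) * sin(2 * pi * 10 * (0:999) / 1000)
  ms <- mean_square_feature(ep)
  expect_equal(ms[1, ], c(0, 0), ignore_attr = TRUE)
  expect_equal(ms[2, ], c(4, 4), ignore_attr = TRUE)
  expect_lt(abs(ms[3, 1] - 1), 1e-6)   # amplitude sqrt(2) -> A^2/2 = 1
  expect_error(mean_square_feature(noise_epochs(0, 2, 100)), "empty")
})

test_that("Welch band powers satisfy the sinusoid and Parseval checks", {
  fs <- 1000
  ep <- noise_epochs(2, 1, 5000, fs = fs)
  amp <- 3
  ep$data[1, 1, ] <- amp * sin(2 * pi * 10 * (0:4999) / fs)
  ep$data[2, 1, ] <- 0
  pb <- psd_band_features(ep)
  mu <- pb[1, 1]; beta <- pb[1, 2]
  expect_lt(abs(mu - amp^2 / 2) / (amp^2 / 2), 0.05)
  expect_lt(beta, 0.01 * mu)
  expect_equal(pb[2, ], c(0, 0), ignore_attr = TRUE)

  wn <- noise_epochs(5, 1, 5000, sd = 2, seed = 9)
  tot <- psd_band_features(wn, bands = list(all = c(0, 500)))
  expect_lt(max(abs(tot - 4) / 4), 0.05)
  expect_error(psd_band_features(wn, bands = list(bad = c(400, 600))),
               "Nyquist")
})

test_that("CSP reproduces the worked covariance example exactly", {
  m <- csp_from_covariances(diag(c(2, 1)), diag(c(1, 2)))
  expect_equal(m$eigenvalues, c(2 / 3, 1 / 3), tolerance = 1e-8)
  # filters aligned with the coordinate axes
  w <- abs(m$filters / sqrt(rowSums(m$filters^2)))
  expect_equal(sort(apply(w, 1, max)), c(1, 1), tolerance = 1e-8)
})

test_that("CSP matches a brute-force generalized-eigendecomposition oracle", {
  principal_cos <- function(a, b) {
    qa <- qr.Q(qr(a)); qb <- qr.Q(qr(b))
    min(svd(t(qa) %*% qb)$d)
  }
  for (seed in 1:3) {
    set.seed(seed)
    c1 <- crossprod(matrix(rnorm(40 * 19), 40))
    c2 <- crossprod(matrix(rnorm(40 * 19), 40))
    model <- csp_from_covariances(c1, c2)
    # oracle: eigenvectors of solve(C1 + C2) %*% C1
    ge <- eigen(solve(c1 + c2) %*% c1)
    ord <- order(Re(ge$values), decreasing = TRUE)
    expect_equal(sort(model$eigenvalues), sort(Re(ge$values)),
                 tolerance = 1e-6)
    # transposed filters are generalized eigenvectors of (C1, C1 + C2):
    # the top/bottom triples span the oracle's extreme eigenspaces
    top <- t(model$filters[1:3, , drop = FALSE])
    bot <- t(model$filters[17:19, , drop = FALSE])
    expect_gt(principal_cos(top, Re(ge$vectors[, ord[1:3]])), 1 - 1e-6)
    expect_gt(principal_cos(bot, Re(ge$vectors[, ord[17:19]])), 1 - 1e-6)
    # simultaneous diagonalization: per-filter class variances sum to one
    w <- model$filters
    expect_equal(diag(w %*% c1 %*% t(w)), model$eigenvalues,
                 tolerance = 1e-6)
    expect_equal(diag(w %*% c1 %*% t(w)) + diag(w %*% c2 %*% t(w)),
                 rep(1, 19), tolerance = 1e-6)
  }
})

test_that("white-noise classes give undiscriminative eigenvalues near 1/2", {
  ep <- noise_epochs(40, 6, 800, seed = 5)
  m <- fit_csp(ep)
  expect_lt(max(abs(m$eigenvalues - 0.5)), 0.05)
})

test_that("CSP is invariant to scaling and symmetric under label swap", {
  ep <- separable_epochs(30, 5, 600, seed = 6)
  m1 <- fit_csp(ep)
  scaled <- ep
  scaled$data <- ep$data * 7
  m2 <- fit_csp(scaled)
  expect_equal(m1$eigenvalues, m2$eigenvalues, tolerance = 1e-9)
  swapped <- ep
  swapped$labels <- factor(ifelse(ep$labels == "left", "right", "left"),
                           levels = c("left", "right"))
  m3 <- fit_csp(swapped)
  expect_equal(sort(m1$eigenvalues), sort(1 - m3$eigenvalues),
               tolerance = 1e-7)
})

test_that("CSP log-variance features are normalized and deterministic", {
  ep <- separable_epochs(20, 5, 600, seed = 7)
  m <- fit_csp(ep, n_pairs = 2)
  f <- csp_features(m, ep)
  expect_equal(dim(f), c(20, 4))
  expect_equal(rowSums(exp(f)), rep(1, 20), tolerance = 1e-9)
  dup <- ep
  dup$data[2, , ] <- dup$data[1, , ]
  fd <- csp_features(m, dup)
  expect_identical(fd[1, ], fd[2, ])
  bad <- noise_epochs(4, 3, 600)
  expect_error(csp_features(m, bad), "channel count")
})

test_that("lateralized classes are separated by the first CSP feature", {
  sched <- build_assessment_schedule(1, 30, seed = 8)
  sub <- subject_params(erd_depth = 0.9, engagement_range = c(1, 1))
  raw <- simulate_session(sched, sub, scene_condition("vr", gain = 1),
                          seed = 9)
  ep <- extract_epochs(bandpass(raw))
  m <- fit_csp(ep)
  f <- csp_features(m, ep)[, 1]
  g1 <- f[ep$labels == "left"]; g2 <- f[ep$labels == "right"]
  d <- abs(mean(g1) - mean(g2)) /
    sqrt((var(g1) + var(g2)) / 2)
  expect_gt(d, 1)
})

test_that("feature fusion yields 63 leak-free standardized columns", {
  sched <- build_assessment_schedule(1, 10, seed = 10)
  raw <- simulate_session(sched, seed = 11)
  ep <- extract_epochs(bandpass(raw))
  m <- fit_csp(ep)
  train <- 1:6
  fm <- assemble_features(mean_square_feature(ep), psd_band_features(ep),
                          csp_features(m, ep), train_idx = train)
  expect_equal(ncol(fm$values), 19 + 38 + 6)
  expect_lt(max(abs(colMeans(fm$values[train, ]))), 1e-9)
  expect_equal(unname(apply(fm$values[train, ], 2, sd)), rep(1, 63),
               tolerance = 1e-9)
  expect_error(assemble_features(matrix(0, 3, 2), matrix(0, 4, 2)),
               "mismatched")
})
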