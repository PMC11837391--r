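test_that("ridge solutions match direct linear-algebra oracles", {
  # hand example: X = [1, 0]', y = [2, 0]', lambda = 1 -> w = 2/(1+1) = 1
  m <- fit_ridge(matrix(c(1, 0), 2), c(2, 0), 1, intercept = FALSE)
  expect_equal(as.numeric(m$weights), 1)
  set.seed(1)
  X <- matrix(stats::rnorm(15 * 6), 15)
  y <- stats::rnorm(15)
  for (lam in c(0.5, 3)) {
    w <- fit_ridge(X, y, lam, intercept = FALSE)$weights
    oracle <- solve(crossprod(X) + diag(lam, 6), crossprod(X, y))
    expect_lt(max(abs(w - oracle)) / max(abs(oracle)), 1e-10)
  }
  # lambda -> 0 recovers ordinary least squares (pseudoinverse oracle)
  w0 <- fit_ridge(X, y, 1e-10, intercept = FALSE)$weights
  expect_equal(as.numeric(w0), as.numeric(qr.solve(X, y)), tolerance = 1e-6)
  # shrinkage limit
  whuge <- fit_ridge(X, y, 1e12, intercept = FALSE)$weights
  expect_lt(max(abs(whuge)), 1e-8)
})

test_that("ridge rejects near-singular unregularized systems", {
  X <- cbind(1:10, 2 * (1:10))
  expect_error(fit_ridge(X, stats::rnorm(10), 1e-14, intercept = FALSE),
               "singular")
})

test_that("lagged design places a delta feature at the exact row offset", {
  n <- 500
  f <- matrix(0, n, 1); f[250, 1] <- 1
  d <- build_lagged_design(f, lags_ms = c(0, 100), rate_hz = 100,
                           in_rate = 100, feature_set = "a")
  # zero-lag column keeps the impulse at its row; +100 ms displaces by 10
  expect_equal(which.max(abs(d$matrix[, 1])), 250)
  expect_equal(which.max(abs(d$matrix[, 2])), 260)
  expect_equal(length(default_lags_ms()), 61)
})

test_that("lagged design at lag zero reproduces the downsampled feature", {
  sp <- gen_stimulus_pair(20, 1000, seed = 1)
  feats <- structure(list(envelope = sp$envelope, motion = sp$motion,
                          rate_hz = 1000,
                          usable_mask = rep(TRUE, length(sp$envelope))),
                     class = "stimulus_features")
  d <- build_lagged_design(feats, lags_ms = 0, rate_hz = 100, feature_set = "a")
  ref <- decimate_zero_phase(sp$envelope, 10, 1000)
  expect_equal(d$matrix[, 1], ref, tolerance = 1e-12)
})

test_that("generic forward model recovers kernels and shrinks to null on noise EEG", {
  sc <- small_cohort()
  prep <- sc$prep[1:3]                   # homogeneous group A
  m <- fit_generic_forward(prep, "av")
  expect_gt(kernel_recovery_correlation(m, sc$raw[[1]]$truth), 0.8)
  expect_gt(m$mean_r, 0.2)
  expect_true(m$lambda %in% 10^seq(-2, 6))
  expect_error(fit_generic_forward(prep, "av", lambda_grid = numeric(0)),
               "empty")
})

test_that("surrogate z-scores are standard-normal-ish under independence and large under coupling", {
  prep <- small_cohort()$prep[1:3]
  st <- forward_stats(prep, default_lags_ms(), 100, "a")
  W <- ridge_from_stats(st[[1]], 100)
  d <- build_lagged_design(prep[[2]]$features, default_lags_ms(), 100,
                           feature_set = "a")
  ds <- downsample_eeg(prep[[2]]$eeg, 100)
  n <- min(nrow(d$matrix), nrow(ds$data))
  d$matrix <- d$matrix[seq_len(n), , drop = FALSE]
  d$valid <- d$valid[seq_len(n)] & ds$mask[seq_len(n)]
  # independent target: z centred near 0
  set.seed(5)
  Ynull <- matrix(stats::rnorm(n * ncol(ds$data)), n)
  r0 <- rep(0, ncol(Ynull))
  amn <- surrogate_zscore(r0, W, Ynull, d, n_surrogates = 60, seed = 2)
  expect_lt(abs(mean(amn$z)), 0.6)
  # true EEG: strongly driven channels z >> 2
  X <- d$matrix[d$valid, , drop = FALSE]
  robs <- as.numeric(stats::cor(X %*% W, ds$data[seq_len(n), ][d$valid, ]))
  am <- surrogate_zscore(robs, W, ds$data[seq_len(n), , drop = FALSE], d,
                         n_surrogates = 60, seed = 3)
  expect_gt(max(am$z), 5)
})

test_that("circular shifting preserves the autocorrelation structure", {
  x <- gen_stimulus_pair(20, 1000, seed = 3)$envelope
  sh <- c(x[5001:length(x)], x[1:5000])
  a1 <- stats::acf(x, lag.max = 50, plot = FALSE)$acf
  a2 <- stats::acf(sh, lag.max = 50, plot = FALSE)$acf
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("decoders reconstruct the stimulus and fail on shuffled EEG", {
  prep <- small_cohort()$prep[1:3]
  d <- fit_decoder(prep, "envelope", "single")
  expect_gt(mean(d$r), 0.3)
  shuf <- lapply(prep, function(s) {
    set.seed(9)
    s$eeg$data <- s$eeg$data[, sample(ncol(s$eeg$data))]
    s
  })
  d0 <- fit_decoder(shuf, "envelope", "single")
  expect_lt(max(abs(d0$r)), 2 / sqrt(2000))
})

test_that("forward and backward single-channel models are reciprocal at zero noise", {
  # one feature, one channel, identity kernel at lag 0
  sp <- gen_stimulus_pair(30, 1000, seed = 6)
  x <- decimate_zero_phase(sp$envelope, 10, 1000)
  x <- (x - mean(x)) / stats::sd(x)
  y <- 2.5 * x                                   # "EEG" = scaled feature
  fwd <- fit_ridge(matrix(x), y, 1e-6)
  bwd <- fit_ridge(matrix(y), x, 1e-6)
  expect_equal(as.numeric(fwd$weights) * as.numeric(bwd$weights), 1,
               tolerance = 1e-4)
})

test_that("per-lag decoding finds the kernel peak and flags flat profiles", {
  co <- gen_cohort(3, preset_A = preset_td(a_peak_ms = 100, v_peak_ms = 100),
                   preset_B = preset_td(a_peak_ms = 100, v_peak_ms = 100),
                   seed = 21, duration_s = 40, n_channels = 12)
  prep <- prepare_subjects(co)
  pr <- per_lag_decoding(prep, "envelope", lags_ms = seq(-100, 250, by = 10))
  expect_lt(abs(pr$optimal_lag_ms - 100), 11)
  expect_false(pr$flat_flag)
  expect_s3_class(pr$test, "group_test")
})
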