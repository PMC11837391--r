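test_that("filter chain attenuates mains and passes theta with zero phase", {
  rate <- 1000
  t <- (0:19999) / rate
  mont <- make_montage(8)
  mk <- function(f) toy_eeg(matrix(rep(sin(2 * pi * f * t), 8), nrow = 8,
                                   byrow = TRUE), montage = mont)
  sel <- 3000:17000                              # away from filter edges
  y50 <- filter_chain(mk(50))$data[1, sel]
  expect_lt(20 * log10(max(sqrt(mean(y50^2)), 1e-12) / sqrt(0.5)), -40)
  y5 <- filter_chain(mk(5))$data[1, ]
  x5 <- sin(2 * pi * 5 * t)
  expect_lt(abs(sqrt(mean(y5[sel]^2)) / sqrt(0.5) - 1), 0.02)
  cc <- stats::ccf(x5[sel], y5[sel], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)     # zero-phase contract
})

test_that("the composite zero-phase filters have symmetric impulse responses", {
  x <- numeric(8001); x[4001] <- 1
  for (y in list(butter_filtfilt(x, 1000, low = 1, high = 70),
                 notch_filtfilt(x, 1000, 50))) {
    asym <- max(abs(y - rev(y))) / max(abs(y))
    expect_lt(asym, 1e-8)
  }
})

test_that("filter chain rejects too-short records", {
  mont <- make_montage(8)
  expect_error(filter_chain(toy_eeg(matrix(0, 8, 500), montage = mont)),
               "short")
})

test_that("bad-channel detection flags a gross-amplitude channel and only that one", {
  set.seed(1)
  mont <- make_montage(12)
  X <- matrix(stats::rnorm(12 * 5000), 12)
  eeg <- toy_eeg(X, montage = mont)
  expect_identical(detect_bad_channels(eeg), integer(0))
  eeg$data[7, ] <- eeg$data[7, ] * 50
  expect_identical(detect_bad_channels(eeg), 7L)
  eeg$data[1:4, ] <- eeg$data[1:4, ] * 100
  expect_error(detect_bad_channels(eeg), "flagged")
})

test_that("spherical-spline interpolation reconstructs a smooth field", {
  mont <- make_montage(24)
  field <- topography(mont$positions, c(0.3, 0.2, 0.9), 0.8) +
    0.5 * topography(mont$positions, c(-0.5, 0.1, 0.8), 0.9)
  eeg <- toy_eeg(matrix(rep(field, 50), ncol = 50), montage = mont)
  held <- c(5, 12, 20)
  rec <- interpolate_channels(eeg, held)
  expect_equal(rec$data[held, 1], field[held], tolerance = 0.05)
  expect_gt(stats::cor(rec$data[held, 1], field[held]), 0.99)
  expect_identical(interpolate_channels(eeg, integer(0))$data, eeg$data)
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(2)
  eeg <- toy_eeg(matrix(stats::rnorm(8 * 100) + 3, 8))
  r1 <- rereference_average(eeg)
  expect_lt(max(abs(colMeans(r1$data))), 1e-10)
  r2 <- rereference_average(r1)
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("artifact masking covers an injected spike with padding, leaves clean data alone", {
  set.seed(3)
  eeg <- toy_eeg(matrix(stats::rnorm(8 * 5000, sd = 10), 8))
  clean <- mask_artifact_segments(eeg, abs_amp_uv = 150, pad_ms = 200)
  expect_true(all(clean$artifact_mask))
  eeg$data[4, 2500] <- 500
  m <- mask_artifact_segments(eeg, abs_amp_uv = 150, pad_ms = 200)
  expect_true(all(!m$artifact_mask[2300:2700]))
  expect_true(m$artifact_mask[2090])
  eeg$data[4, ] <- 500
  expect_error(mask_artifact_segments(eeg, 150, 200), "masked")
})

test_that("the ICA hook is identity without inputs and removes supplied components", {
  set.seed(4)
  S <- matrix(stats::rnorm(2 * 1000), 2)       # sources
  A <- matrix(c(1, 0.5, 0.3, 1), 2)            # mixing
  eeg <- structure(list(data = A %*% S, rate_hz = 1000,
                        artifact_mask = rep(TRUE, 1000)),
                   class = "eeg_recording")
  expect_identical(ica_hook(eeg)$data, eeg$data)
  out <- ica_hook(eeg, unmixing = solve(A), reject = 2)
  expect_equal(out$data, A %*% rbind(S[1, ], 0), tolerance = 1e-10)
})

test_that("preprocess_eeg runs the full ordered sequence deterministically", {
  s <- small_cohort()$raw[[1]]
  p1 <- preprocess_eeg(s$eeg)
  p2 <- preprocess_eeg(s$eeg)
  expect_identical(p1$data, p2$data)
  expect_length(p1$log, 7)
  expect_match(p1$log[1], "bandpass")
  expect_match(p1$log[6], "low-pass")
})
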