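test_that("stimulus pair: identity case cross-correlates at lag zero and is deterministic", {
  a <- gen_stimulus_pair(20, 1000, av_lag_ms = 0, phase_shift_rad = 0,
                         seed = 1, mix_shared = 1, broadband_sd = 0)
  b <- gen_stimulus_pair(20, 1000, av_lag_ms = 0, phase_shift_rad = 0,
                         seed = 1, mix_shared = 1, broadband_sd = 0)
  expect_identical(a, b)
  cc <- stats::ccf(a$envelope, a$motion, lag.max = 200, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("stimulus pair: a pure +50 ms lag shows as +pi/2 CPSD phase at 5 Hz", {
  sp <- gen_stimulus_pair(60, 1000, theta_hz = 5, av_lag_ms = 50,
                          phase_shift_rad = 0, seed = 3, mix_shared = 1,
                          broadband_sd = 0)
  ph <- cpsd_phase(sp$envelope, sp$motion, 1000, 5)
  expect_lt(abs(ph - pi / 2), pi / 32)
})

test_that("stimulus pair: imposed theta rotation is recovered by a direct DFT oracle", {
  for (phi in c(-2, pi / 2, 3)) {
    sp <- gen_stimulus_pair(60, 1000, theta_hz = 5, av_lag_ms = 0,
                            phase_shift_rad = phi, seed = 11, mix_shared = 1,
                            broadband_sd = 0)
    # oracle: phase of the raw cross-spectrum, averaged over 4.5-5.5 Hz
    n <- length(sp$envelope)
    f <- (seq_len(n) - 1) * 1000 / n
    E <- stats::fft(sp$envelope - mean(sp$envelope))
    M <- stats::fft(sp$motion - mean(sp$motion))
    sel <- f >= 4.5 & f <= 5.5
    phase <- Arg(sum(Conj(E[sel]) * M[sel]))
    expect_lt(abs(wrap_angle(phase - phi)), pi / 32)
  }
})

test_that("stimulus pair: theta-band power dominates the band-limited spectrum", {
  frac <- function(x) {
    x <- x - mean(x)
    s <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) * 1000 / length(x)
    sum(s[f >= 2 & f <= 8]) / sum(s[f >= 0.5 & f <= 30])
  }
  for (seed in 1:3) {
    sp <- gen_stimulus_pair(60, 1000, seed = seed)
    expect_gte(frac(sp$envelope), 0.70)
    expect_gte(frac(sp$motion), 0.70)
  }
})

test_that("stimulus pair rejects invalid parameters", {
  expect_error(gen_stimulus_pair(10, 1000, phase_shift_rad = 4))
  expect_error(gen_stimulus_pair(10, 10, theta_hz = 5))
  expect_error(gen_stimulus_pair(10, 1000, av_lag_ms = NaN))
})

test_that("moving-square video matches the pixel-count oracle and wraps", {
  fr <- gen_video_frames(2, 10, square_speed_px = 5, seed = 2, side = 10,
                         luminance = 100, background = 0)
  for (k in 1:19) {
    d <- abs(fr[k + 1, , ] - fr[k, , ])
    expect_equal(sum(d > 0), 2 * 10 * 5)       # side * speed pixels in and out
    expect_true(all(d[d > 0] == 100))
  }
  fr0 <- gen_video_frames(1, 10, square_speed_px = 0, seed = 2)
  expect_true(all(fr0[2, , ] == fr0[1, , ]))
  expect_identical(gen_video_frames(1, 5, 3, seed = 7),
                   gen_video_frames(1, 5, 3, seed = 7))
})

test_that("gaze stream is piecewise stationary with one saccade between two centres", {
  gz <- gen_gaze_stream(2, 300, rbind(c(100, 100), c(400, 300)), noise_px = 0,
                        seed = 1, frame_w = 500, frame_h = 400)
  v <- sqrt(diff(gz$x)^2 + diff(gz$y)^2)
  expect_equal(sum(v > 50), 1)                  # exactly one jump
  expect_true(all(gz$x >= 1 & gz$x <= 500))
  gz1 <- gen_gaze_stream(1, 300, matrix(c(50, 50), 1), noise_px = 0, seed = 1)
  expect_true(all(gz1$x == 50) && all(gz1$y == 50))
  expect_error(gen_gaze_stream(1, 300, matrix(numeric(0), 0, 2)))
})

test_that("gen_eeg realizes the forward model: lag and linearity", {
  mont <- make_montage(8)
  tr <- make_ground_truth(8, a_peak_ms = 100, v_peak_ms = -50, snr_db = Inf,
                          montage = mont)
  sp <- gen_stimulus_pair(30, 1000, seed = 2, mix_shared = 0)
  feats <- list(envelope = sp$envelope, motion = sp$motion)
  eeg <- gen_eeg(feats, tr, seed = 1)
  ch <- which.max(topography(mont$positions, c(0, 0.35, 0.94), 0.45))
  cc <- stats::ccf(sp$envelope, eeg$data[ch, ], lag.max = 300, plot = FALSE)
  # response peaks ~100 ms after the stimulus
  expect_lt(abs(-cc$lag[which.max(cc$acf)] - 100), 15)

  # linearity in the kernels at zero noise
  trA <- tr; trA$kernels[2, , ] <- 0
  trV <- tr; trV$kernels[1, , ] <- 0
  eA <- gen_eeg(feats, trA, seed = 1)
  eV <- gen_eeg(feats, trV, seed = 1)
  expect_equal(eA$data + eV$data, eeg$data, tolerance = 1e-10)
})

test_that("gen_eeg rejects kernels longer than the signal", {
  tr <- make_ground_truth(8, montage = make_montage(8))
  sp <- gen_stimulus_pair(0.2, 1000, seed = 1)
  expect_error(gen_eeg(list(envelope = sp$envelope, motion = sp$motion), tr),
               "lag span")
})

test_that("cohort generation is deterministic and labels groups", {
  co1 <- gen_cohort(2, seed = 9, duration_s = 10, n_channels = 8)
  co2 <- gen_cohort(2, seed = 9, duration_s = 10, n_channels = 8)
  expect_identical(co1[[1]]$eeg$data, co2[[1]]$eeg$data)
  expect_identical(vapply(co1, `[[`, "", "group_label"), c("A", "A", "B", "B"))
  # group B draws from the atypical preset: auditory kernel early
  expect_lt(co1[[3]]$truth$a_peak_ms, co1[[3]]$truth$v_peak_ms)
  expect_gt(co1[[1]]$truth$a_peak_ms, co1[[1]]$truth$v_peak_ms)
})

test_that("von Mises sampler concentrates around mu and respects kappa", {
  set.seed(1)
  a <- rvonmises(2000, pi / 2, 8)
  m <- circ_mean_r(a)
  expect_lt(abs(wrap_angle(m$mean_rad - pi / 2)), 0.1)
  expect_gt(m$r_bar, 0.9)
  u <- rvonmises(2000, 0, 0)
  expect_lt(circ_mean_r(u)$r_bar, 0.1)
})
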