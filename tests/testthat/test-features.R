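test_that("envelope of a pure tone is its amplitude", {
  t <- (0:79999) / 8000
  env <- extract_envelope(2 * sin(2 * pi * 440 * t), 8000)
  sel <- 1000:(length(env) - 1000)               # exclude filter edges
  expect_lt(max(abs(env[sel] - 2)) / 2, 0.01)
})

test_that("envelope demodulates an AM tone with the right depth and is amplitude-equivariant", {
  t <- (0:79999) / 8000
  x <- (1 + 0.5 * cos(2 * pi * 5 * t)) * sin(2 * pi * 440 * t)
  env <- extract_envelope(x, 8000)
  sel <- 1000:(length(env) - 1000)
  e <- env[sel] - mean(env[sel])
  F <- Mod(stats::fft(e))
  f <- (seq_along(e) - 1) * 1000 / length(e)
  depth <- 2 * F[which.min(abs(f - 5))] / length(e) / mean(env[sel])
  expect_lt(abs(depth - 0.5) / 0.5, 0.05)
  expect_equal(extract_envelope(3 * x, 8000), 3 * env, tolerance = 1e-9)
})

test_that("envelope handles degenerate inputs", {
  expect_equal(extract_envelope(numeric(8000), 8000), numeric(1000))
  expect_error(extract_envelope(c(1, NA, 3), 8000))
})

test_that("I-VT: static gaze is one fixation; two centres give two with exact centroids", {
  gz0 <- gen_gaze_stream(2, 300, matrix(c(50, 50), 1), noise_px = 0, seed = 1)
  fx0 <- ivt_fixations(gz0, px_per_deg = 35)
  expect_equal(nrow(fx0), 1)
  expect_equal(fx0$offset_s - fx0$onset_s, max(gz0$t), tolerance = 0.01)

  gz <- gen_gaze_stream(2, 300, rbind(c(100, 100), c(420, 100)), noise_px = 0,
                        seed = 1, frame_w = 500, frame_h = 200)
  fx <- ivt_fixations(gz, px_per_deg = 35)
  expect_equal(nrow(fx), 2)
  expect_lt(abs(fx$cx[1] - 100), 1)
  expect_lt(abs(fx$cx[2] - 420), 1)
  expect_identical(nrow(ivt_fixations(gz[1, , drop = FALSE])), 0L)
})

test_that("visual motion equals a brute-force per-pixel oracle on small fixtures", {
  fr <- gen_video_frames(1, 10, square_speed_px = 3, seed = 4, height = 64,
                         width = 64, side = 8, luminance = 120)
  fx <- data.frame(onset_s = 0, offset_s = 2, cx = 32, cy = 32)
  vm <- extract_visual_motion(fr, 10, fx, window_px = 21, diff_threshold = 10)
  oracle <- vapply(seq_len(dim(fr)[1] - 1), function(k) {
    acc <- c()
    for (r in 22:42) for (cc in 22:42) {       # 21x21 window around (32,32)
      d <- abs(fr[k + 1, r, cc] - fr[k, r, cc])
      if (d > 10) acc <- c(acc, d)
    }
    if (length(acc) == 0) 0 else mean(acc)
  }, 0)
  expect_identical(vm$per_frame, oracle)
})

test_that("visual motion: static scene is zero, moving square hits its luminance", {
  fr0 <- gen_video_frames(1, 10, square_speed_px = 0, seed = 1)
  fx <- data.frame(onset_s = 0, offset_s = 2, cx = 48, cy = 48)
  vm0 <- extract_visual_motion(fr0, 10, fx)
  expect_true(all(vm0$motion == 0))
  fr <- gen_video_frames(1, 10, square_speed_px = 5, seed = 2, side = 10,
                         luminance = 100)
  vm <- extract_visual_motion(fr, 10, fx, window_px = 318)
  expect_true(all(vm$per_frame == 100))        # mean over supra-threshold pixels
})

test_that("visual motion marks fixation gaps unusable and ZOH matches linear upsampling closely", {
  fr <- gen_video_frames(1, 10, square_speed_px = 2, seed = 3)
  fx <- data.frame(onset_s = 0, offset_s = 0.45, cx = 48, cy = 48)
  vm <- extract_visual_motion(fr, 10, fx)
  expect_true(any(!vm$usable_mask))
  expect_true(all(vm$motion[!vm$usable_mask] == 0))
  # sensitivity: linear interpolation of per-frame values stays close to ZOH
  pf <- vm$per_frame[!is.na(vm$per_frame)]
  if (stats::sd(pf) > 0) {
    t_f <- seq_along(pf) / 10
    lin <- stats::approx(t_f, pf, xout = seq(0.1, max(t_f), by = 1e-3),
                         rule = 2)$y
    zoh <- rep(pf, each = 100)[seq_along(lin)]
    expect_gt(stats::cor(lin, zoh), 0.8)
  }
})

test_that("align_and_normalize gives unit masked RMS and respects the mask", {
  s <- small_cohort()$raw[[1]]
  mask <- rep(TRUE, length(s$features_true$envelope))
  mask[1:10000] <- FALSE
  an <- align_and_normalize(s$features_true$envelope, s$features_true$motion,
                            s$eeg, usable_mask = mask)
  m <- an$features$usable_mask
  expect_equal(sqrt(mean(an$features$envelope[m]^2)), 1, tolerance = 1e-10)
  expect_equal(sqrt(mean(an$eeg$data[3, m]^2)), 1, tolerance = 1e-10)
  # oracle: normalization constant equals the hand-computed masked RMS
  rms <- sqrt(mean(s$features_true$envelope[m]^2))
  expect_equal(an$features$envelope[m][1],
               s$features_true$envelope[m][1] / rms, tolerance = 1e-12)
})

test_that("align_and_normalize flags zero-RMS columns instead of dividing", {
  s <- small_cohort()$raw[[1]]
  zero <- numeric(length(s$features_true$envelope))
  an <- align_and_normalize(s$features_true$envelope, zero, s$eeg)
  expect_true(any(grepl("motion", an$features$flags)))
  expect_true(all(an$features$motion == 0))
})

test_that("MI: perfect dependence saturates at log2(n_bins), symmetry and bounds hold", {
  x <- c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6, 7.7, 8.8)
  expect_equal(mutual_information(x, x, 4, 100, 1)$mi_bits, 2)
  set.seed(3)
  a <- stats::rnorm(300); b <- stats::rnorm(300)
  m1 <- mutual_information(a, b, 4, 50, 1)$mi_bits
  m2 <- mutual_information(b, a, 4, 50, 1)$mi_bits
  expect_identical(m1, m2)
  expect_gte(m1, 0)
  expect_lte(m1, 2)
})

test_that("MI: independent signals are not significant at alpha = 0.001; constant input flagged", {
  set.seed(7)
  mi <- mutual_information(stats::runif(10000), stats::runif(10000),
                           n_bins = 4, n_perm = 1500, seed = 2)
  expect_gt(mi$p_value, 0.001)
  expect_warning(res <- mutual_information(rep(1, 200), stats::rnorm(200)),
                 "constant")
  expect_equal(res$mi_bits, 0)
  expect_identical(res$flag, "constant-input")
})
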