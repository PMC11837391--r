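test_that("coherence is 1 for self, bounded, and symmetric in its arguments", {
  set.seed(1)
  x <- stats::rnorm(30000); y <- stats::rnorm(30000)
  expect_equal(welch_coherence(x, x, 1000)$coh, rep(1, length(coherence_grid())),
               tolerance = 1e-9)
  c1 <- welch_coherence(x, y, 1000)
  c2 <- welch_coherence(y, x, 1000)
  expect_equal(c1$coh, c2$coh, tolerance = 1e-12)
  expect_true(all(c1$coh >= 0 & c1$coh <= 1))
})

test_that("independent-noise coherence sits at the small-sample bias level", {
  set.seed(2)
  x <- stats::rnorm(31500); y <- stats::rnorm(31500)   # ~20 segments
  cc <- welch_coherence(x, y, 1000)
  expect_lt(abs(mean(cc$coh) - 1 / cc$n_seg) , 0.03)
  expect_lt(max(cc$coh), 0.3)
})

test_that("welch cross-spectra match a direct DFT-segment oracle", {
  set.seed(3)
  rate <- 100
  x <- stats::rnorm(2000); y <- stats::rnorm(2000)
  # oracle: explicit segmentation, Hamming window, periodogram averaging
  N <- 300; hop <- 150
  w <- signal::hamming(N)
  starts <- seq(1, 2000 - N + 1, by = hop)
  Sxx <- Syy <- numeric(N); Sxy <- complex(N)
  for (s0 in starts) {
    seg <- function(v) { sv <- v[s0:(s0 + N - 1)]; stats::fft((sv - mean(sv)) * w) }
    X <- seg(x); Y <- seg(y)
    Sxx <- Sxx + Mod(X)^2; Syy <- Syy + Mod(Y)^2; Sxy <- Sxy + Conj(X) * Y
  }
  coh_or <- Mod(Sxy)^2 / (Sxx * Syy)
  freqs <- (seq_len(N) - 1) * rate / N
  keep <- freqs <= 35
  grid <- coherence_grid()
  oracle <- stats::approx(freqs[keep], coh_or[keep], grid, rule = 2)$y
  got <- welch_coherence(x, y, rate, window_s = 3, overlap = 0.5)
  expect_equal(got$coh, oracle, tolerance = 1e-10)
})

test_that("coherence rejects records with too few segments", {
  expect_error(welch_coherence(stats::rnorm(4000), stats::rnorm(4000), 1000),
               "segments")
})

test_that("CPSD phase follows the pure-delay law with the documented sign", {
  x <- gen_stimulus_pair(40, 1000, seed = 4, mix_shared = 1,
                         broadband_sd = 0)$envelope
  expect_equal(cpsd_phase(x, x, 1000, 5), 0)
  for (delay_ms in c(30, 50, 80)) {
    d <- round(delay_ms)
    y <- c(rep(0, d), x[1:(length(x) - d)])     # y lags x
    ph <- cpsd_phase(x, y, 1000, 5)
    expect_lt(abs(wrap_angle(ph + 2 * pi * 5 * delay_ms / 1000)), pi / 32)
    # antisymmetry
    expect_lt(abs(wrap_angle(cpsd_phase(y, x, 1000, 5) + ph)), 1e-8)
  }
})

test_that("band peaks find an injected coupling frequency; flat bands fall back to midpoint", {
  grid <- coherence_grid()
  spec <- exp(-((grid - 5)^2))
  pk <- band_peak(grid, spec, "theta")
  expect_lt(abs(pk$f_peak_hz - 5), 0.34)
  mono <- seq_along(grid) / length(grid)
  expect_equal(band_peak(grid, mono, "delta")$f_peak_hz, 4, tolerance = 0.34)
  flat <- band_peak(grid, rep(1, length(grid)), "theta")
  expect_true(flat$flat_flag)
  expect_equal(flat$f_peak_hz, 6)
})

test_that("surrogate coherence z is calibrated under the null and large under coupling", {
  set.seed(6)
  zr <- replicate(20, {
    x <- stats::rnorm(30000); y <- stats::rnorm(30000)
    mean(surrogate_coherence_z(x, y, 1000, seed = sample.int(1e6, 1))$z)
  })
  expect_lt(abs(mean(zr)), 0.2)
  sp <- gen_stimulus_pair(60, 1000, seed = 8, mix_shared = 1)
  z <- surrogate_coherence_z(sp$envelope, sp$motion, 1000, seed = 9)
  expect_gt(z$z[which.min(abs(z$freqs_hz - 5))], 5)
})

test_that("audio-visual phase shift wraps, averages circularly, and rejects empty sets", {
  expect_equal(av_phase_shift(c(0, 0), c(0, 0))$subject, 0)
  expect_equal(av_phase_shift(c(0, 0), c(pi / 2, pi / 2))$subject, pi / 2)
  ps <- av_phase_shift(c(0, 0), c(3, -3))       # wrap-around mean near pi
  expect_gt(abs(ps$subject), 3)
  expect_error(av_phase_shift(1, 2, electrodes = integer(0)), "empty")
})

test_that("subject-level analysis recovers the imposed theta offset but not in delta", {
  cs <- clean_subject()
  sp <- subject_coherence_phase(cs$prep, seed = 1)
  el <- which(sp$A$theta$reliable)
  d_theta <- av_phase_shift(sp$A$theta$phi, sp$V$theta$phi, electrodes = el)
  expect_lt(abs(wrap_angle(d_theta$subject - pi / 2)), pi / 8)
  el_d <- which(sp$A$delta$reliable)
  d_delta <- av_phase_shift(sp$A$delta$phi, sp$V$delta$phi, electrodes = el_d)
  expect_lt(abs(wrap_angle(d_delta$subject)), pi / 8)
  expect_true(sp$A$theta$f_peak_hz >= 4 && sp$A$theta$f_peak_hz <= 8)
  expect_true(all(sp$A$coh >= 0 & sp$A$coh <= 1, na.rm = TRUE))
})
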