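test_that("circular mean and resultant length match vector-sum arithmetic", {
  m <- circ_mean_r(c(0, pi / 2))
  expect_equal(m$mean_rad, pi / 4)
  expect_equal(m$r_bar, cos(pi / 4))
  same <- circ_mean_r(rep(1.2, 7))
  expect_equal(same$mean_rad, 1.2)
  expect_equal(same$r_bar, 1)
  anti <- circ_mean_r(c(0, pi))
  expect_lt(anti$r_bar, 1e-12)
  expect_identical(anti$flag, "undefined-mean")
  # brute-force oracle on arbitrary angles
  set.seed(1)
  a <- stats::runif(50, -pi, pi)
  expect_equal(circ_mean_r(a)$r_bar,
               Mod(sum(exp(1i * a))) / 50, tolerance = 1e-12)
})

test_that("weighted circular mean uses the weights", {
  m <- circ_mean_r(c(0, pi / 2), weights = c(3, 1))
  expect_lt(m$mean_rad, pi / 4)
  expect_error(circ_mean_r(c(0, 1), weights = c(0, 0)))
})

test_that("rayleigh test: concentration rejects, uniform grids do not", {
  conc <- rayleigh_test(rep(0.7, 30))
  expect_equal(conc$r_bar, 1)
  expect_lt(conc$p_value, 1e-6)
  unif <- rayleigh_test(seq(-pi, pi, length.out = 37)[-37])
  expect_lt(unif$r_bar, 1e-10)
  expect_gt(unif$p_value, 0.99)
  set.seed(2)
  pow <- mean(replicate(200, rayleigh_test(rvonmises(30, 1, 2))$p_value < 0.05))
  expect_gt(pow, 0.9)
})

test_that("all circular statistics are invariant to a global rotation", {
  set.seed(3)
  a <- rvonmises(25, 0.3, 4)
  b <- rvonmises(25, -0.5, 4)
  for (rot in c(1, -2.5)) {
    expect_equal(rayleigh_test(a)$statistic,
                 rayleigh_test(wrap_angle(a + rot))$statistic, tolerance = 1e-10)
    expect_equal(watson_williams(list(a, b))$statistic,
                 watson_williams(list(wrap_angle(a + rot),
                                      wrap_angle(b + rot)))$statistic,
                 tolerance = 1e-10)
    expect_equal(circ_mean_r(a)$r_bar, circ_mean_r(wrap_angle(a + rot))$r_bar,
                 tolerance = 1e-12)
  }
})

test_that("watson-williams: identical groups accept, separated groups reject, low r flagged", {
  a <- rvonmises(30, 0, 8)
  ww0 <- watson_williams(list(a, a))
  expect_lt(ww0$statistic, 1e-6)
  expect_gt(ww0$p_value, 0.9)
  set.seed(4)
  pow <- mean(replicate(100, {
    g1 <- rvonmises(30, 0, 8); g2 <- rvonmises(30, pi / 2, 8)
    watson_williams(list(g1, g2))$p_value < 0.05
  }))
  expect_gt(pow, 0.95)
  set.seed(5)
  flat <- watson_williams(list(rvonmises(30, 0, 0.1), rvonmises(30, 0, 0.1)))
  expect_identical(flat$flag, "low-concentration")
})

test_that("two-way circular ANOVA is calibrated under the null and detects a main effect", {
  set.seed(6)
  fa <- rep(1:2, each = 30); fb <- rep(rep(1:2, each = 15), 2)
  rej <- replicate(200, circ_anova2(rvonmises(60, 0, 5), fa, fb)$p_value < 0.05)
  expect_true(all(rowMeans(rej) <= 0.09))
  pow <- mean(replicate(100, {
    ang <- wrap_angle(rvonmises(60, 0, 8) + rep(c(0, pi / 2), each = 30))
    circ_anova2(ang, fa, fb)$p_value[1] < 0.05
  }))
  expect_gt(pow, 0.9)
  expect_error(circ_anova2(rvonmises(10, 0, 2), rep(1:2, each = 5),
                           c(rep(1, 5), rep(1:2, length.out = 5))),
               "empty cell")
})

test_that("phase-accuracy correlation: exact anticorrelation, null bound, interaction term", {
  set.seed(7)
  phi <- rvonmises(30, 0, 1.5)
  acc <- -abs(wrap_angle(phi))
  res <- phase_accuracy_correlation(phi, acc)
  expect_equal(res$r, -1, tolerance = 1e-12)
  nullr <- replicate(200, phase_accuracy_correlation(
    rvonmises(30, 0, 1), stats::rnorm(30))$r)
  expect_gt(mean(abs(nullr) < 0.36), 0.9)
  grp <- rep(c("A", "B"), each = 15)
  res2 <- phase_accuracy_correlation(phi, acc + stats::rnorm(30, sd = 0.01),
                                     group = grp)
  expect_true(is.finite(res2$interaction_t))
  expect_error(phase_accuracy_correlation(rep(0.5, 10), stats::rnorm(10)),
               "zero variance")
})
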