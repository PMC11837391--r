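#' @title Circular statistics
#' @description
#' Descriptive and inferential statistics on phase angles: circular mean
#' and resultant length, Rayleigh uniformity test, Watson-Williams
#' multi-sample test, Harrison-Kanji two-way circular ANOVA, and the
#' phase-shift / reconstruction-accuracy correlation analysis.  All tests
#' return a uniform record (statistic, df, p, r_bar, flags).
#' @name circstats
NULL

#' Circular mean and resultant length
#'
#' @param angles_rad angles in radians (any wrapping).
#' @param weights optional nonnegative weights.
#' @return list: `mean_rad` in (-pi, pi], `r_bar` in [0, 1], `flag`
#'   ("undefined-mean" when the resultant is numerically zero).
#' @export
circ_mean_r <- function(angles_rad, weights = NULL) {
  stopifnot(length(angles_rad) >= 1)
  if (is.null(weights)) weights <- rep(1, length(angles_rad))
  stopifnot(all(weights >= 0), sum(weights) > 0)
  C <- sum(weights * cos(angles_rad)) / sum(weights)
  S <- sum(weights * sin(angles_rad)) / sum(weights)
  r <- sqrt(C^2 + S^2)
  flag <- if (r < 1e-12) "undefined-mean" else NULL
  list(mean_rad = if (r < 1e-12) NA_real_ else wrap_angle(atan2(S, C)),
       r_bar = r, flag = flag)
}

# maximum-likelihood concentration estimate from a mean resultant length
# (standard A1-inverse approximation)
kappa_from_rbar <- function(r) {
  if (r < 0.53) 2 * r + r^3 + 5 * r^5 / 6
  else if (r < 0.85) -0.4 + 1.39 * r + 0.43 / (1 - r)
  else 1 / (r^3 - 4 * r^2 + 3 * r)
}

#' Rayleigh test of circular uniformity
#'
#' z = n r_bar^2 with the standard small-sample-corrected exponential
#' approximation for the p-value.
#'
#' @param angles_rad angles in radians (n >= 4).
#' @return list (`circ_test`): `statistic` (z), `r_bar`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles_rad) {
  n <- length(angles_rad)
  stopifnot(n >= 4)
  r <- circ_mean_r(angles_rad)$r_bar
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * r)^2)) - (1 + 2 * n))
  structure(list(statistic = z, r_bar = r, p_value = min(1, max(0, p)),
                 n = n, df = NULL, test = "rayleigh"), class = "circ_test")
}

#' Watson-Williams multi-sample test for equal mean directions
#'
#' F statistic with (k - 1, N - k) degrees of freedom, corrected by the
#' standard concentration factor 1 + 3/(8 kappa).  The result is flagged
#' unreliable when the pooled resultant length is below 0.45 (the
#' concentration assumption is then violated).
#'
#' @param samples list of angle vectors (>= 2 groups, each n >= 5).
#' @return list (`circ_test`): `statistic` (F), `df`, `p_value`,
#'   `r_bar` (pooled), `flag`.
#' @export
watson_williams <- function(samples) {
  stopifnot(length(samples) >= 2, all(vapply(samples, length, 0L) >= 5))
  k <- length(samples)
  ns <- vapply(samples, length, 0L)
  N <- sum(ns)
  Rs <- vapply(samples, function(a) length(a) * circ_mean_r(a)$r_bar, 0)
  all_angles <- unlist(samples)
  R <- N * circ_mean_r(all_angles)$r_bar
  rw <- sum(Rs) / N
  flag <- if (rw < 0.45) "low-concentration" else NULL
  kk <- kappa_from_rbar(rw)
  corr <- 1 + 3 / (8 * kk)
  Fstat <- corr * ((N - k) * (sum(Rs) - R)) / ((k - 1) * (N - sum(Rs)))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  structure(list(statistic = Fstat, df = c(k - 1, N - k), p_value = p,
                 r_bar = rw, flag = flag, test = "watson-williams"),
            class = "circ_test")
}

#' Harrison-Kanji two-way ANOVA for circular data
#'
#' Decomposes the resultant-length "sums of squares" of a two-factor
#' design (main effects and interaction).  Under high concentration
#' (pooled kappa > 2) F ratios against the residual term are used, with
#' the 1 + 3/(8 kappa) correction; under moderate concentration
#' chi-squared approximations (2 kappa SS) are used and the interaction
#' is not separable.
#'
#' @param angles angles in radians.
#' @param factor_a,factor_b factors (coercible; near-balanced design,
#'   each cell n >= 5).
#' @return data.frame with one row per effect: `effect`, `statistic`,
#'   `df1`, `df2`, `p_value`, plus attributes `kappa`, `regime`.
#' @export
circ_anova2 <- function(angles, factor_a, factor_b) {
  fa <- as.factor(factor_a); fb <- as.factor(factor_b)
  stopifnot(length(angles) == length(fa), length(angles) == length(fb))
  tab <- table(fa, fb)
  if (any(tab == 0)) stop("empty cell in the two-way design")
  if (any(tab < 5)) warning("cells with n < 5; approximations unreliable")
  p <- nlevels(fa); q <- nlevels(fb); N <- length(angles)
  res_len <- function(a) {
    if (length(a) == 0) return(0)
    length(a) * circ_mean_r(a)$r_bar
  }
  R <- res_len(angles)
  Ra <- vapply(levels(fa), function(l) res_len(angles[fa == l]), 0)
  Rb <- vapply(levels(fb), function(l) res_len(angles[fb == l]), 0)
  Rab <- outer(levels(fa), levels(fb),
               Vectorize(function(i, j) res_len(angles[fa == i & fb == j])))
  na <- as.numeric(table(fa)); nb <- as.numeric(table(fb))
  nab <- as.matrix(tab)
  rbar <- R / N
  kk <- kappa_from_rbar(rbar)
  ss_a <- sum(Ra^2 / na) - R^2 / N
  ss_b <- sum(Rb^2 / nb) - R^2 / N
  ss_cells <- sum(Rab^2 / nab)
  ss_ab <- ss_cells - sum(Ra^2 / na) - sum(Rb^2 / nb) + R^2 / N
  ss_res <- N - ss_cells
  df <- c(a = p - 1, b = q - 1, ab = (p - 1) * (q - 1))
  df_res <- N - p * q
  if (kk > 2) {
    corr <- 1 + 3 / (8 * kk)
    stat <- corr * c(ss_a / df["a"], ss_b / df["b"], ss_ab / df["ab"]) /
      (ss_res / df_res)
    pv <- stats::pf(stat, df, df_res, lower.tail = FALSE)
    out <- data.frame(effect = c("A", "B", "A:B"), statistic = stat,
                      df1 = as.numeric(df), df2 = df_res, p_value = pv)
    attr(out, "regime") <- "F"
  } else {
    stat <- 2 * kk * c(ss_a, ss_b, ss_ab)
    pv <- stats::pchisq(stat, df, lower.tail = FALSE)
    out <- data.frame(effect = c("A", "B", "A:B"), statistic = stat,
                      df1 = as.numeric(df), df2 = NA, p_value = pv)
    attr(out, "regime") <- "chisq"
  }
  attr(out, "kappa") <- kk
  rownames(out) <- NULL
  out
}

#' Phase-shift extent versus reconstruction accuracy
#'
#' The phase-shift extent is the absolute wrapped difference from zero,
#' |wrap(delta_phi)| in [0, pi] (an alternative, distance from the group
#' circular mean, is available via `reference = "group-mean"`).  Returns
#' the Pearson correlation between extent and accuracy, and, when groups
#' are given, the t statistic of the group x extent interaction from a
#' linear model.
#'
#' @param delta_phi per-subject phase shifts (radians).
#' @param accuracy per-subject reconstruction accuracies.
#' @param group optional factor for the interaction model.
#' @param reference "zero" (default) or "group-mean".
#' @return list: `r`, `p_value`, `extent`, and when grouped,
#'   `interaction_t`, `interaction_p`.
#' @export
phase_accuracy_correlation <- function(delta_phi, accuracy, group = NULL,
                                       reference = c("zero", "group-mean")) {
  reference <- match.arg(reference)
  stopifnot(length(delta_phi) == length(accuracy), length(delta_phi) >= 8)
  if (reference == "zero") {
    extent <- abs(wrap_angle(delta_phi))
  } else {
    stopifnot(!is.null(group))
    extent <- rep(NA_real_, length(delta_phi))
    for (g in unique(group)) {
      i <- group == g
      mu <- circ_mean_r(delta_phi[i])$mean_rad
      extent[i] <- abs(wrap_angle(delta_phi[i] - mu))
    }
  }
  if (stats::sd(extent) == 0) stop("zero variance in phase-shift extent")
  ct <- stats::cor.test(extent, accuracy)
  out <- list(r = unname(ct$estimate), p_value = ct$p.value, extent = extent)
  if (!is.null(group)) {
    fit <- stats::lm(accuracy ~ group * extent)
    co <- summary(fit)$coefficients
    irow <- grep(":extent", rownames(co))
    out$interaction_t <- co[irow, "t value"]
    out$interaction_p <- co[irow, "Pr(>|t|)"]
  }
  out
}
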