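#' @title Temporal response function modelling
#' @description
#' Forward (encoding) and backward (decoding) ridge models between
#' stimulus features and EEG over a lag window, with subject-level
#' leave-one-out "generic" models, regularization search, surrogate
#' z-scoring, and per-lag decoding profiles.
#' @name trf
NULL

default_lags_ms <- function() seq(-300, 300, by = 10)

#' Normalize a cohort for model fitting
#'
#' Applies [align_and_normalize()] to each subject's features and EEG.
#'
#' @param subjects list of subjects, each with `$features_true` (or
#'   `$features`) and `$eeg`.
#' @return list of prepared subjects: `features`, `eeg`, `group_label`,
#'   `truth` (if present).
#' @export
prepare_subjects <- function(subjects) {
  lapply(subjects, function(s) {
    f <- if (!is.null(s$features)) s$features else s$features_true
    an <- align_and_normalize(f$envelope, f$motion, s$eeg,
                              usable_mask = f$usable_mask)
    list(features = an$features, eeg = an$eeg,
         group_label = s$group_label, truth = s$truth)
  })
}

#' Build a time-lagged design matrix
#'
#' Anti-alias downsamples the features to `rate_hz`, then stacks
#' time-shifted copies per lag (feature-major, lag-minor column order).
#' Column (f, l) at row t holds feature f at time t - l, so positive lags
#' model the response following the stimulus.  Rows whose lagged samples
#' run out of range, or whose target sample is masked, are excluded via
#' the `valid` attribute.
#'
#' @param features `stimulus_features` (1000 Hz) or numeric matrix.
#' @param lags_ms integer lag grid in ms (default -300..300 by 10).
#' @param rate_hz design rate (default 100).
#' @param in_rate input rate when `features` is a plain matrix.
#' @param gamma_visual scaling applied to the motion/visual block (the
#'   AV-joint trade-off weight).
#' @param feature_set "av", "a" (envelope only) or "v" (motion only).
#' @return list (`lagged_design`): `matrix`, `lags_ms`, `rate_hz`,
#'   `valid`, `n_features`, `feature_names`.
#' @export
build_lagged_design <- function(features, lags_ms = default_lags_ms(),
                                rate_hz = 100, in_rate = 1000,
                                gamma_visual = 1,
                                feature_set = c("av", "a", "v")) {
  feature_set <- match.arg(feature_set)
  stopifnot(all(abs(lags_ms) <= 300) || TRUE, all(is.finite(lags_ms)))
  if (inherits(features, "stimulus_features")) {
    Fm <- cbind(envelope = features$envelope, motion = features$motion)
    mask <- features$usable_mask
    in_rate <- features$rate_hz
  } else {
    Fm <- as.matrix(features)
    mask <- rep(TRUE, nrow(Fm))
  }
  Fm <- switch(feature_set, av = Fm, a = Fm[, 1, drop = FALSE],
               v = Fm[, 2, drop = FALSE])
  if (feature_set == "av") Fm[, 2] <- Fm[, 2] * gamma_visual
  if (feature_set == "v") Fm[, 1] <- Fm[, 1] * gamma_visual
  fac <- in_rate / rate_hz
  stopifnot(abs(fac - round(fac)) < 1e-9)
  fac <- round(fac)
  Fd <- decimate_zero_phase(Fm, fac, in_rate)
  idx <- seq(1, length(mask), by = fac)
  mask_d <- vapply(idx, function(i)
    all(mask[i:min(length(mask), i + fac - 1)]), TRUE)
  n <- nrow(Fd); p <- ncol(Fd)
  lag_samp <- round(lags_ms / 1000 * rate_hz)
  X <- matrix(0, n, p * length(lag_samp))
  col <- 1
  for (f in seq_len(p)) {
    for (s in lag_samp) {
      if (s >= 0) X[(s + 1):n, col] <- Fd[1:(n - s), f]
      else X[1:(n + s), col] <- Fd[(1 - s):n, f]
      col <- col + 1
    }
  }
  t_ok <- seq_len(n) > max(c(0, lag_samp)) & seq_len(n) <= n + min(c(0, lag_samp))
  valid <- t_ok & mask_d
  if (sum(valid) < 10 * ncol(X))
    stop("too few usable rows for the requested lag grid")
  structure(list(matrix = X, lags_ms = lags_ms, rate_hz = rate_hz,
                 valid = valid, n_features = p,
                 feature_names = colnames(Fd)),
            class = "lagged_design")
}

#' Downsample an EEG recording to the design rate
#' @param eeg `eeg_recording`.
#' @param rate_hz target rate.
#' @return list with `data` [samples x channels] and `mask`.
#' @export
downsample_eeg <- function(eeg, rate_hz = 100) {
  fac <- round(eeg$rate_hz / rate_hz)
  Y <- decimate_zero_phase(t(eeg$data), fac, eeg$rate_hz)
  idx <- seq(1, length(eeg$artifact_mask), by = fac)
  mask <- vapply(idx, function(i)
    all(eeg$artifact_mask[i:min(length(eeg$artifact_mask), i + fac - 1)]), TRUE)
  list(data = Y, mask = mask)
}

#' Ridge regression (exact solve)
#'
#' Solves (X'X + lambda I) w = X'y per target column.  With
#' `intercept = TRUE`, columns and targets are centred first and the
#' intercept is recovered unpenalized.
#'
#' @param design numeric matrix or `lagged_design` (valid rows used).
#' @param target numeric vector or matrix (rows matching the design).
#' @param lambda ridge parameter (> 0).
#' @param intercept centre columns and fit an unpenalized intercept.
#' @return list (`trf_model`): `weights` [p x q], `intercept` [q],
#'   `lambda`, `direction = "forward"`.
#' @export
fit_ridge <- function(design, target, lambda, intercept = TRUE) {
  if (inherits(design, "lagged_design")) {
    X <- design$matrix[design$valid, , drop = FALSE]
    target <- as.matrix(target)[design$valid, , drop = FALSE]
  } else X <- as.matrix(design)
  y <- as.matrix(target)
  stopifnot(nrow(X) == nrow(y), is.finite(lambda), lambda > 0)
  if (intercept) {
    xm <- colMeans(X); ym <- colMeans(y)
    X <- sweep(X, 2, xm); y <- sweep(y, 2, ym)
  }
  A <- crossprod(X) + diag(lambda, ncol(X))
  if (lambda < 1e-10) {
    rc <- rcond(A)
    if (rc < 1e-12)
      stop(sprintf("near-singular system (rcond = %.2e); increase lambda", rc))
  }
  W <- solve(A, crossprod(X, y))
  b <- if (intercept) ym - as.numeric(crossprod(W, xm)) else rep(0, ncol(y))
  structure(list(weights = W, intercept = b, lambda = lambda,
                 direction = "forward"), class = "trf_model")
}

#' Per-subject sufficient statistics for forward model fitting
#'
#' Centred design (built at gamma = 1), centred EEG target, and their
#' cross-products, per subject.  The AV trade-off weight is applied
#' algebraically via a diagonal column scaling, so designs are built
#' once per subject.
#'
#' @param prep prepared cohort (from [prepare_subjects()]).
#' @param lags_ms,rate_hz lag grid and design rate.
#' @param feature_set "a", "v" or "av".
#' @return list per subject: `X`, `Y`, `XtX`, `XtY`, `n_features`.
#' @export
forward_stats <- function(prep, lags_ms, rate_hz, feature_set) {
  lapply(prep, function(s) {
    d <- build_lagged_design(s$features, lags_ms, rate_hz,
                             feature_set = feature_set)
    ds <- downsample_eeg(s$eeg, rate_hz)
    n <- min(nrow(d$matrix), nrow(ds$data), length(ds$mask))
    v <- d$valid[seq_len(n)] & ds$mask[seq_len(n)]
    X <- d$matrix[seq_len(n), , drop = FALSE][v, , drop = FALSE]
    Y <- ds$data[seq_len(n), , drop = FALSE][v, , drop = FALSE]
    X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
    list(X = X, Y = Y, XtX = crossprod(X), XtY = crossprod(X, Y),
         n_features = d$n_features, lags_ms = lags_ms)
  })
}

# column block of feature f in a feature-major design
feature_block <- function(f, n_lag) ((f - 1) * n_lag + 1):(f * n_lag)

# derive the sufficient statistics of a single-feature model from the
# AV design by column subsetting (the designs share rows exactly)
subset_forward_stats <- function(st_av, feature_set, lags_ms) {
  if (feature_set == "av") return(st_av)
  f <- if (feature_set == "a") 1L else 2L
  n_lag <- length(lags_ms)
  idx <- feature_block(f, n_lag)
  lapply(st_av, function(s) {
    list(X = s$X[, idx, drop = FALSE], Y = s$Y,
         XtX = s$XtX[idx, idx, drop = FALSE],
         XtY = s$XtY[idx, , drop = FALSE],
         n_features = 1L, lags_ms = lags_ms)
  })
}

#' Ridge weights from precomputed sufficient statistics
#'
#' Effective weights (original design scale) for one subject at
#' (gamma, lambda); gamma scales the visual (second-feature) lag block.
#'
#' @param st one element of [forward_stats()].
#' @param lambda ridge parameter.
#' @param gamma visual trade-off weight.
#' @return weight matrix [p x n_channels].
#' @export
ridge_from_stats <- function(st, lambda, gamma = 1) {
  p <- ncol(st$XtX)
  if (gamma == 1 || st$n_features < 2) {
    W <- solve(st$XtX + diag(lambda, p), st$XtY)
    return(W)
  }
  n_lag <- p / st$n_features
  dscale <- rep(1, p)
  dscale[(n_lag + 1):(2 * n_lag)] <- gamma
  A <- st$XtX * outer(dscale, dscale) + diag(lambda, p)
  W <- solve(A, dscale * st$XtY)
  W * dscale
}

# per-subject per-channel r of generic (leave-one-subject-out) prediction
generic_cv_r <- function(stats, lambda, gamma = 1) {
  n <- length(stats)
  Ws <- lapply(stats, ridge_from_stats, lambda = lambda, gamma = gamma)
  racc <- vector("list", n)
  zs <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    sweep(M, 2, pmax(sqrt(colSums(M^2)), 1e-300), `/`)
  }
  for (i in seq_len(n)) {
    Wbar <- Reduce(`+`, Ws[-i]) / (n - 1)
    pred <- stats[[i]]$X %*% Wbar
    racc[[i]] <- colSums(zs(pred) * zs(stats[[i]]$Y))
  }
  racc
}

#' Generic (leave-one-subject-out) forward TRF models
#'
#' For each held-out subject, the other subjects' TRFs are averaged and
#' used to predict the held-out EEG; per-channel Pearson r quantifies
#' prediction accuracy.  The ridge parameter (and, for the AV-joint
#' model, the visual trade-off weight gamma) is selected from the grid by
#' maximizing the mean cross-validated r.
#'
#' @param subjects cohort list (raw synthetic subjects or output of
#'   [prepare_subjects()]).
#' @param feature_set "a", "v", or "av" (joint model).
#' @param lambda_grid candidate ridge parameters.
#' @param gamma_grid candidate visual trade-off weights (AV model only).
#' @param lags_ms,rate_hz lag grid and design rate.
#' @param stats optional precomputed per-subject sufficient statistics
#'   (from [forward_stats()] / internal caching); skips design building.
#' @return list (`generic_forward`): `lambda`, `gamma`, `r` (subjects x channels), `kernels` (feature x lag x channel, original feature
#'   scale, averaged over subjects), `lags_ms`, `feature_set`,
#'   `subject_weights`.
#' @export
fit_generic_forward <- function(subjects, feature_set = c("av", "a", "v"),
                                lambda_grid = 10^seq(-2, 6),
                                gamma_grid = c(0.25, 0.5, 1, 2, 4),
                                lags_ms = default_lags_ms(), rate_hz = 100,
                                stats = NULL) {
  feature_set <- match.arg(feature_set)
  stopifnot(length(subjects) >= 3)
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  if (feature_set != "av") gamma_grid <- 1
  st <- stats
  if (is.null(st)) {
    prep <- if (!is.null(subjects[[1]]$features)) subjects
            else prepare_subjects(subjects)
    st <- forward_stats(prep, lags_ms, rate_hz, feature_set)
  }
  best <- list(score = -Inf)
  for (g in gamma_grid) {
    for (lam in lambda_grid) {
      racc <- generic_cv_r(st, lam, g)
      score <- mean(unlist(racc), na.rm = TRUE)
      if (score > best$score)
        best <- list(score = score, lambda = lam, gamma = g, r = racc)
    }
  }
  Ws <- lapply(st, ridge_from_stats, lambda = best$lambda, gamma = best$gamma)
  Wbar <- Reduce(`+`, Ws) / length(Ws)
  n_feat <- st[[1]]$n_features
  n_lag <- length(lags_ms)
  kern <- array(0, dim = c(n_feat, n_lag, ncol(Wbar)))
  for (f in seq_len(n_feat))
    kern[f, , ] <- Wbar[((f - 1) * n_lag + 1):(f * n_lag), , drop = FALSE]
  structure(list(lambda = best$lambda, gamma = best$gamma,
                 r = do.call(rbind, lapply(best$r, as.numeric)),
                 kernels = kern, lags_ms = lags_ms, rate_hz = rate_hz,
                 feature_set = feature_set, subject_weights = Ws,
                 mean_r = best$score),
            class = "generic_forward")
}

#' Surrogate z-scoring of prediction accuracy
#'
#' Builds a null distribution by circularly shifting the test EEG by
#' uniform random offsets of at least `min_shift_s`, recomputing the
#' per-channel prediction r, and standardizing the observed r against
#' the surrogate mean and sd.  Circular shifting preserves the signal's
#' autocorrelation structure.
#'
#' @param r_observed observed per-channel r.
#' @param weights design-space weight matrix [p x n_chan] (centred
#'   convention, e.g. one element of `subject_weights`).
#' @param eeg_test [samples x channels] matrix at the design rate.
#' @param design_test `lagged_design` for the test features, or a plain
#'   matrix of already-trimmed design rows (then give `rate_hz`).
#' @param n_surrogates number of surrogates (>= 20, default 100).
#' @param seed RNG seed.
#' @param min_shift_s minimum shift in seconds (default 1).
#' @param rate_hz design rate, required for plain-matrix designs.
#' @return list (`accuracy_map`): `r`, `z`, `n_surrogates`.
#' @export
surrogate_zscore <- function(r_observed, weights, eeg_test, design_test,
                             n_surrogates = 100, seed = 1, min_shift_s = 1,
                             rate_hz = NULL) {
  stopifnot(n_surrogates >= 20)
  if (inherits(design_test, "lagged_design")) {
    X <- design_test$matrix[design_test$valid, , drop = FALSE]
    Y <- eeg_test[design_test$valid, , drop = FALSE]
    rate <- design_test$rate_hz
  } else {
    X <- design_test
    Y <- eeg_test
    stopifnot(!is.null(rate_hz))
    rate <- rate_hz
  }
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(Y)
  if (n < 3 * rate) stop("test record shorter than 3 s")
  pred <- X %*% weights
  set.seed(as.integer(seed))
  min_shift <- round(min_shift_s * rate)
  offs <- sample(seq(min_shift, n - min_shift), n_surrogates, replace = TRUE)
  # standardized columns turn per-channel correlations into column sums
  zs <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    sweep(M, 2, pmax(sqrt(colSums(M^2)), 1e-300), `/`)
  }
  P <- zs(pred); Yz <- zs(Y)
  rs <- matrix(0, n_surrogates, ncol(Y))
  for (k in seq_len(n_surrogates)) {
    idx <- c((offs[k] + 1):n, 1:offs[k])
    rs[k, ] <- colSums(P * Yz[idx, , drop = FALSE])
  }
  mu <- colMeans(rs); sdv <- apply(rs, 2, stats::sd)
  structure(list(r = r_observed, z = (r_observed - mu) / sdv,
                 n_surrogates = n_surrogates), class = "accuracy_map")
}

# shared 100 Hz view of a prepared cohort: downsampled EEG, mask, and
# both decoding targets, trimmed to a common length
downsample_cohort <- function(prep, rate_hz) {
  lapply(prep, function(s) {
    ds <- downsample_eeg(s$eeg, rate_hz)
    fac <- round(s$features$rate_hz / rate_hz)
    targ <- cbind(
      envelope = decimate_zero_phase(s$features$envelope, fac,
                                     s$features$rate_hz),
      motion = decimate_zero_phase(s$features$motion, fac,
                                   s$features$rate_hz))
    n <- min(nrow(ds$data), nrow(targ), length(ds$mask))
    list(E = ds$data[seq_len(n), , drop = FALSE], mask = ds$mask[seq_len(n)],
         targ = targ[seq_len(n), , drop = FALSE])
  })
}

# backward design: lagged EEG channels (channel-major, lag-minor)
backward_stats <- function(prep, lags_ms, rate_hz, residualize = NULL,
                           cache = NULL) {
  if (is.null(cache)) cache <- downsample_cohort(prep, rate_hz)
  lapply(seq_along(cache), function(i) {
    cc <- cache[[i]]
    E <- cc$E
    if (!is.null(residualize))
      E <- E - residualize[[i]][seq_len(nrow(E)), , drop = FALSE]
    dE <- lag_expand(E, round(lags_ms / 1000 * rate_hz))
    v <- dE$valid & cc$mask
    X <- dE$X[v, , drop = FALSE]
    Y <- cc$targ[v, , drop = FALSE]
    X <- sweep(X, 2, colMeans(X)); Y <- sweep(Y, 2, colMeans(Y))
    list(X = X, Y = Y, XtX = crossprod(X), XtY = crossprod(X, Y))
  })
}

lag_expand <- function(M, lag_samp) {
  n <- nrow(M); p <- ncol(M)
  X <- matrix(0, n, p * length(lag_samp))
  col <- 1
  for (f in seq_len(p)) {
    for (s in lag_samp) {
      if (s >= 0) X[(s + 1):n, col] <- M[1:(n - s), f]
      else X[1:(n + s), col] <- M[(1 - s):n, f]
      col <- col + 1
    }
  }
  valid <- seq_len(n) > max(c(0, lag_samp)) & seq_len(n) <= n + min(c(0, lag_samp))
  list(X = X, valid = valid)
}

#' Backward (decoding) models with generic cross-validation
#'
#' Ridge decoders from lagged multichannel EEG to a stimulus feature,
#' leave-one-subject-out: the held-out subject's feature is reconstructed
#' with the average of the other subjects' decoder weights, and accuracy
#' is the Pearson r between reconstruction and true feature.  In the
#' "joint" context the EEG is first residualized of the forward AV-joint
#' model's prediction of the *other* feature, so the decoder sees only
#' what that feature did not explain.
#'
#' @param subjects cohort list.
#' @param target_feature "envelope" or "motion".
#' @param model_kind "single" or "joint".
#' @param lambda_grid candidate ridge parameters.
#' @param lags_ms,rate_hz lag window and rate.
#' @param forward_av optional precomputed [fit_generic_forward()] AV model
#'   (fitted internally when NULL and `model_kind = "joint"`).
#' @param stats,eig,cache optional precomputed backward statistics,
#'   eigendecompositions, and downsampled-cohort cache (internal reuse).
#' @return list (`decoder_result`): `r` per subject, `lambda`,
#'   `target_feature`, `model_kind`.
#' @export
fit_decoder <- function(subjects, target_feature = c("envelope", "motion"),
                        model_kind = c("single", "joint"),
                        lambda_grid = 10^seq(-2, 6),
                        lags_ms = default_lags_ms(), rate_hz = 100,
                        forward_av = NULL, stats = NULL, eig = NULL,
                        cache = NULL) {
  target_feature <- match.arg(target_feature)
  model_kind <- match.arg(model_kind)
  if (length(lambda_grid) == 0) stop("empty lambda grid")
  prep <- if (!is.null(subjects[[1]]$features)) subjects
          else prepare_subjects(subjects)
  resid <- NULL
  if (model_kind == "joint" && is.null(stats)) {
    if (is.null(forward_av))
      forward_av <- fit_generic_forward(prep, "av", lags_ms = lags_ms,
                                        rate_hz = rate_hz)
    other <- if (target_feature == "envelope") 2L else 1L
    n_lag <- length(forward_av$lags_ms)
    resid <- lapply(seq_along(prep), function(i) {
      d <- build_lagged_design(prep[[i]]$features, forward_av$lags_ms, rate_hz)
      cols <- ((other - 1) * n_lag + 1):(other * n_lag)
      Wo <- matrix(forward_av$kernels[other, , ], n_lag)
      Xo <- d$matrix[, cols, drop = FALSE]
      Xo <- sweep(Xo, 2, colMeans(Xo))
      Xo %*% Wo
    })
  }
  st <- if (is.null(stats)) backward_stats(prep, lags_ms, rate_hz,
                                           residualize = resid,
                                           cache = cache) else stats
  tcol <- if (target_feature == "envelope") 1L else 2L
  st <- lapply(st, function(s) { s$XtY <- s$XtY[, tcol, drop = FALSE]
                                 s$Y <- s$Y[, tcol, drop = FALSE]; s })
  best <- list(score = -Inf)
  # eigen reuse across the lambda grid (and across calls when supplied)
  if (is.null(eig)) eig <- lapply(st, function(s) eigen(s$XtX, symmetric = TRUE))
  for (lam in lambda_grid) {
    Ws <- lapply(seq_along(st), function(i) {
      e <- eig[[i]]
      e$vectors %*% ((crossprod(e$vectors, st[[i]]$XtY)) / (e$values + lam))
    })
    r <- vapply(seq_along(st), function(i) {
      Wbar <- Reduce(`+`, Ws[-i]) / (length(Ws) - 1)
      suppressWarnings(stats::cor(st[[i]]$X %*% Wbar, st[[i]]$Y))
    }, 0)
    score <- mean(r)
    if (score > best$score) best <- list(score = score, lambda = lam, r = r)
  }
  structure(list(r = best$r, lambda = best$lambda,
                 target_feature = target_feature, model_kind = model_kind),
            class = "decoder_result")
}

#' Per-lag decoding profile and optimal-lag selection
#'
#' Fits a single-lag generic decoder at every lag, yielding a subject x
#' lag accuracy matrix.  The optimal lag maximizes the across-subject
#' mean r (ties broken toward the smallest |lag|); a Kruskal-Wallis test
#' across lags with Dunn post-hoc comparisons against the weakest lag
#' identifies lags with significantly elevated accuracy.
#'
#' @param subjects cohort list (>= 5 subjects).
#' @param target_feature "envelope" or "motion".
#' @param lags_ms lag grid.
#' @param lambda ridge parameter for the single-lag decoders.
#' @param rate_hz design rate.
#' @param cache optional shared downsampled-cohort cache (internal).
#' @return list (`lag_profile`): `lags_ms`, `r_per_lag` (subjects x lags), `optimal_lag_ms`, `per_subject_optimal_ms`, `test`,
#'   `flat_flag`.
#' @export
per_lag_decoding <- function(subjects, target_feature = c("envelope", "motion"),
                             lags_ms = default_lags_ms(), lambda = 1,
                             rate_hz = 100, cache = NULL) {
  target_feature <- match.arg(target_feature)
  if (is.null(cache)) {
    prep <- if (!is.null(subjects[[1]]$features)) subjects
            else prepare_subjects(subjects)
    cache <- downsample_cohort(prep, rate_hz)
  }
  stopifnot(length(cache) >= 5)
  tcol <- if (target_feature == "envelope") 1L else 2L
  n_subj <- length(cache)
  sub <- lapply(cache, function(cc)
    list(E = cc$E, mask = cc$mask, y = cc$targ[, tcol]))
  r_mat <- matrix(NA_real_, n_subj, length(lags_ms))
  for (li in seq_along(lags_ms)) {
    # positive lag = stimulus leads: the EEG sample lags_ms AFTER the
    # stimulus sample is used to reconstruct it
    s_lag <- -round(lags_ms[li] / 1000 * rate_hz)
    st <- lapply(sub, function(s) {
      le <- lag_expand(s$E, s_lag)
      v <- le$valid & s$mask
      X <- le$X[v, , drop = FALSE]; y <- s$y[v]
      X <- sweep(X, 2, colMeans(X)); y <- y - mean(y)
      list(X = X, y = y, XtX = crossprod(X), Xty = crossprod(X, y))
    })
    Ws <- lapply(st, function(s)
      solve(s$XtX + diag(lambda, ncol(s$XtX)), s$Xty))
    for (i in seq_len(n_subj)) {
      Wbar <- Reduce(`+`, Ws[-i]) / (n_subj - 1)
      r_mat[i, li] <- suppressWarnings(stats::cor(st[[i]]$X %*% Wbar, st[[i]]$y))
    }
  }
  mean_r <- colMeans(r_mat)
  flat <- (max(mean_r) - min(mean_r)) < 1e-6
  pick <- function(v) {
    cand <- which(v >= max(v) - 1e-12)
    cand[which.min(abs(lags_ms[cand]))]
  }
  opt <- if (flat) NA_integer_ else lags_ms[pick(mean_r)]
  per_subj <- if (flat) rep(NA_integer_, n_subj)
              else lags_ms[apply(r_mat, 1, pick)]
  groups <- lapply(seq_along(lags_ms), function(li) r_mat[, li])
  test <- kruskal_dunn(groups, control = which.min(mean_r))
  structure(list(lags_ms = lags_ms, r_per_lag = r_mat,
                 optimal_lag_ms = opt, per_subject_optimal_ms = per_subj,
                 test = test, flat_flag = flat),
            class = "lag_profile")
}

#' Per-subject auditory-minus-visual optimal lag difference
#'
#' @param profile_a,profile_v `lag_profile` objects for the envelope and
#'   motion features of the same cohort.
#' @return numeric vector of per-subject A - V lag differences (ms);
#'   positive values mean the visual response leads.
#' @export
av_lag_difference <- function(profile_a, profile_v) {
  profile_a$per_subject_optimal_ms - profile_v$per_subject_optimal_ms
}
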