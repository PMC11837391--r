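#' Default run configuration
#'
#' All analysis parameters with their defaults: 1000 Hz EEG and feature
#' rate, 100 Hz model rate, -300..300 ms lag window, 4 MI bins, the
#' 0.1-30 Hz / 0.33 Hz coherence grid, 50 coherence surrogates, and 1000
#' cluster permutations.  Cohort-scale parameters (8 + 8 subjects, 60 s,
#' 16 channels) are the desk-scale demo defaults.
#'
#' @param ... overrides (unknown keys are rejected).
#' @return named list (`run_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    n_per_group = 8,
    duration_s = 60,
    n_channels = 16,
    streams = "full",
    preset_A = preset_td(),
    preset_B = preset_asd(),
    lags_ms = default_lags_ms(),
    rate_hz = 100,
    lambda_grid = 10^seq(-2, 6),
    gamma_grid = c(0.25, 0.5, 1, 2, 4),
    n_surrogates_trf = 100,
    n_surrogates_coh = 50,
    n_perm_cluster = 1000,
    mi_bins = 4,
    mi_perm = 200,
    trial_min_s = 9,
    phase_electrodes = NULL,   # NULL = all channels
    out_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, ov)
}

#' Load a run configuration from YAML
#' @param path YAML file with config overrides.
#' @return `run_config` list.
#' @export
read_config <- function(path) {
  ov <- yaml::read_yaml(path)
  do.call(default_config, ov)
}

# features stage: extract envelope/motion from the rendered streams, or
# fall back to the generating series for eeg_only subjects
extract_subject_features <- function(subj) {
  if (is.null(subj$audio)) {
    return(list(envelope = subj$features_true$envelope,
                motion = subj$features_true$motion,
                rate_hz = subj$features_true$rate_hz,
                usable_mask = rep(TRUE, length(subj$features_true$envelope))))
  }
  env <- extract_envelope(subj$audio$wave, subj$audio$rate_hz)
  fix <- ivt_fixations(subj$gaze)
  vm <- extract_visual_motion(subj$frames, subj$fps, fix)
  n <- min(length(env), length(vm$motion), ncol(subj$eeg$data))
  list(envelope = env[seq_len(n)], motion = vm$motion[seq_len(n)],
       rate_hz = 1000, usable_mask = vm$usable_mask[seq_len(n)])
}

group_of <- function(prep) vapply(prep, `[[`, "", "group_label")

#' Run the full analysis graph
#'
#' simulate -> feature extraction -> EEG preprocessing -> forward TRF
#' (A, V, AV-joint) with surrogate z-scoring and cluster-based group
#' comparison -> decoding (single and joint context) with rank-based
#' contrasts -> per-lag decoding and optimal-lag comparison -> coherence
#' and CPSD phase in delta/theta -> circular statistics -> phase-shift /
#' accuracy correlation.  Deterministic given `config$seed`.
#'
#' @param config from [default_config()].
#' @return list (`run_report`) of tables and fitted objects; see the
#'   methods vignette for the report schema.
#' @export
run_full <- function(config = default_config()) {
  seed <- config$seed
  # ---- simulate + features + preprocessing ----
  # per-subject postprocessing drops the heavy audio/video streams as
  # soon as the features are extracted, so memory stays flat
  stage2 <- function(s) {
    f <- extract_subject_features(s)
    n <- min(length(f$envelope), ncol(s$eeg$data))
    s$eeg$data <- s$eeg$data[, seq_len(n), drop = FALSE]
    s$eeg$artifact_mask <- s$eeg$artifact_mask[seq_len(n)]
    eeg <- preprocess_eeg(s$eeg)
    an <- align_and_normalize(f$envelope[seq_len(n)], f$motion[seq_len(n)],
                              eeg, usable_mask = f$usable_mask[seq_len(n)])
    list(features = an$features, eeg = an$eeg,
         group_label = s$group_label, truth = s$truth)
  }
  prep <- gen_cohort(config$n_per_group, config$preset_A, config$preset_B,
                     seed = seed, duration_s = config$duration_s,
                     n_channels = config$n_channels,
                     streams = config$streams, postprocess = stage2)
  montage <- attr(prep, "montage")
  groups <- group_of(prep)
  idxA <- which(groups == "A"); idxB <- which(groups == "B")

  # ---- stimulus features analysis (MI) ----
  mi <- lapply(prep, function(s) {
    m <- s$features$usable_mask
    mutual_information(s$features$envelope[m], s$features$motion[m],
                       n_bins = config$mi_bins, n_perm = config$mi_perm,
                       seed = child_seed(seed, 77))
  })
  mi_bits <- vapply(mi, `[[`, 0, "mi_bits")
  mi_test <- stats::t.test(mi_bits[idxA], mi_bits[idxB])
  mi_table <- data.frame(subject = seq_along(prep), group = groups,
                         mi_bits = mi_bits,
                         p_value = vapply(mi, `[[`, 0, "p_value"))

  # ---- forward TRF models ----
  # the AV design statistics are built once; A-only and V-only models
  # reuse them by column subsetting
  st_av_all <- forward_stats(prep, config$lags_ms, config$rate_hz, "av")
  fwd <- list()
  acc_tables <- list()
  cluster_res <- list()
  for (fs in c("a", "v", "av")) {
    st <- subset_forward_stats(st_av_all, fs, config$lags_ms)
    m <- fit_generic_forward(prep, fs, lambda_grid = config$lambda_grid,
                             gamma_grid = config$gamma_grid,
                             lags_ms = config$lags_ms,
                             rate_hz = config$rate_hz, stats = st)
    # surrogate z per subject against the generic model of the others
    Ws <- lapply(st, ridge_from_stats, lambda = m$lambda, gamma = m$gamma)
    zmat <- matrix(NA_real_, length(prep), ncol(st[[1]]$Y))
    for (i in seq_along(prep)) {
      Wbar <- Reduce(`+`, Ws[-i]) / (length(Ws) - 1)
      am <- surrogate_zscore(m$r[i, ], Wbar, st[[i]]$Y, st[[i]]$X,
                             n_surrogates = config$n_surrogates_trf,
                             seed = child_seed(seed, 100 + i),
                             rate_hz = config$rate_hz)
      zmat[i, ] <- am$z
    }
    fwd[[fs]] <- m
    acc_tables[[fs]] <- data.frame(
      subject = rep(seq_along(prep), each = ncol(zmat)),
      group = rep(groups, each = ncol(zmat)),
      channel = rep(seq_len(ncol(zmat)), length(prep)),
      model = fs, r = as.numeric(t(m$r)), z = as.numeric(t(zmat)))
    cluster_res[[fs]] <- cluster_permutation(
      zmat[idxA, , drop = FALSE], zmat[idxB, , drop = FALSE],
      montage$adjacency, n_perm = config$n_perm_cluster,
      seed = child_seed(seed, 200))
    fwd[[fs]]$z <- zmat
  }

  # ---- decoding ----
  dec <- list()
  ds_cache <- list()
  for (grp in c("A", "B")) {
    sel <- prep[groups == grp]
    fav <- fit_generic_forward(sel, "av", lambda_grid = config$lambda_grid,
                               gamma_grid = config$gamma_grid,
                               lags_ms = config$lags_ms,
                               rate_hz = config$rate_hz,
                               stats = st_av_all[groups == grp])
    ds_cache[[grp]] <- downsample_cohort(sel, config$rate_hz)
    # the single-model backward design (and its eigendecomposition) is
    # shared by both target features
    st_single <- backward_stats(sel, config$lags_ms, config$rate_hz,
                                cache = ds_cache[[grp]])
    eig_single <- lapply(st_single, function(s) eigen(s$XtX, symmetric = TRUE))
    for (tf in c("envelope", "motion")) {
      dec[[paste(grp, tf, "single", sep = ".")]] <-
        fit_decoder(sel, tf, "single", lambda_grid = config$lambda_grid,
                    lags_ms = config$lags_ms, rate_hz = config$rate_hz,
                    stats = st_single, eig = eig_single)
      dec[[paste(grp, tf, "joint", sep = ".")]] <-
        fit_decoder(sel, tf, "joint", lambda_grid = config$lambda_grid,
                    lags_ms = config$lags_ms, rate_hz = config$rate_hz,
                    forward_av = fav, cache = ds_cache[[grp]])
    }
  }
  decoding_table <- do.call(rbind, lapply(names(dec), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(group = parts[1], feature = parts[2], model = parts[3],
               subject = seq_along(dec[[k]]$r), r = dec[[k]]$r)
  }))
  # within-group joint-vs-single contrasts (Dunn), per feature
  contrast_rows <- list()
  for (grp in c("A", "B")) for (tf in c("envelope", "motion")) {
    kd <- kruskal_dunn(list(dec[[paste(grp, tf, "joint", sep = ".")]]$r,
                            dec[[paste(grp, tf, "single", sep = ".")]]$r))
    contrast_rows[[paste(grp, tf)]] <- data.frame(
      group = grp, feature = tf, contrast = "joint-vs-single",
      mean_rank_diff = kd$dunn_table$mean_rank_diff[1],
      p_adj = kd$dunn_table$p_adj[1])
  }
  # across-group single-model contrasts per feature
  for (tf in c("envelope", "motion")) {
    kd <- kruskal_dunn(list(dec[[paste("A", tf, "single", sep = ".")]]$r,
                            dec[[paste("B", tf, "single", sep = ".")]]$r))
    contrast_rows[[paste("AB", tf)]] <- data.frame(
      group = "A-vs-B", feature = tf, contrast = "group",
      mean_rank_diff = kd$dunn_table$mean_rank_diff[1],
      p_adj = kd$dunn_table$p_adj[1])
  }
  decoding_contrasts <- do.call(rbind, contrast_rows)

  # ---- per-lag decoding / optimal lags ----
  lag_profiles <- list()
  lag_rows <- list()
  for (grp in c("A", "B")) {
    sel <- prep[groups == grp]
    pa <- per_lag_decoding(sel, "envelope", lags_ms = config$lags_ms,
                           rate_hz = config$rate_hz, cache = ds_cache[[grp]])
    pv <- per_lag_decoding(sel, "motion", lags_ms = config$lags_ms,
                           rate_hz = config$rate_hz, cache = ds_cache[[grp]])
    lag_profiles[[grp]] <- list(envelope = pa, motion = pv,
                                av_diff = av_lag_difference(pa, pv))
    lag_rows[[grp]] <- data.frame(
      group = grp, optimal_lag_a_ms = pa$optimal_lag_ms,
      optimal_lag_v_ms = pv$optimal_lag_ms,
      mean_av_diff_ms = mean(lag_profiles[[grp]]$av_diff))
  }
  optimal_lag_table <- do.call(rbind, lag_rows)

  # ---- coherence and phase ----
  spect <- lapply(seq_along(prep), function(i)
    subject_coherence_phase(prep[[i]], n_surrogates = config$n_surrogates_coh,
                            seed = child_seed(seed, 300 + i),
                            trial_min_s = config$trial_min_s,
                            electrodes = config$phase_electrodes))
  coh_rows <- list()
  for (i in seq_along(spect)) for (cond in c("A", "V"))
    for (b in c("delta", "theta")) {
      sp <- spect[[i]][[cond]]
      fsel <- which.min(abs(sp$freqs_hz - sp[[b]]$f_peak_hz))
      coh_rows[[length(coh_rows) + 1]] <- data.frame(
        subject = i, group = groups[i], condition = cond, band = b,
        f_peak_hz = sp[[b]]$f_peak_hz,
        coherence = mean(sp$coh[, fsel]),
        z = mean(sp$z[, fsel]))
    }
  coherence_table <- do.call(rbind, coh_rows)

  phase_rows <- list()
  for (i in seq_along(spect)) for (b in c("delta", "theta")) {
    el <- config$phase_electrodes
    if (is.null(el)) {
      el <- which(spect[[i]]$A[[b]]$reliable)
      if (length(el) < 2) el <- NULL
    }
    ps <- av_phase_shift(spect[[i]]$A[[b]]$phi, spect[[i]]$V[[b]]$phi,
                         electrodes = el)
    phase_rows[[length(phase_rows) + 1]] <- data.frame(
      subject = i, group = groups[i], band = b,
      delta_phi = ps$subject, r_bar = ps$r_bar)
  }
  phase_table <- do.call(rbind, phase_rows)

  # ---- circular statistics ----
  circ <- list()
  for (b in c("delta", "theta")) {
    phis <- phase_table[phase_table$band == b, ]
    circ[[b]] <- list(
      rayleigh_A = rayleigh_test(phis$delta_phi[phis$group == "A"]),
      rayleigh_B = rayleigh_test(phis$delta_phi[phis$group == "B"]),
      watson_williams = watson_williams(
        list(phis$delta_phi[phis$group == "A"],
             phis$delta_phi[phis$group == "B"])),
      mean_A = circ_mean_r(phis$delta_phi[phis$group == "A"]),
      mean_B = circ_mean_r(phis$delta_phi[phis$group == "B"]))
  }
  circ$anova2 <- circ_anova2(phase_table$delta_phi,
                             phase_table$group, phase_table$band)

  # ---- phase shift vs reconstruction accuracy ----
  theta_phi <- phase_table[phase_table$band == "theta", ]
  acc_env <- c(dec[["A.envelope.single"]]$r, dec[["B.envelope.single"]]$r)
  acc_mot <- c(dec[["A.motion.single"]]$r, dec[["B.motion.single"]]$r)
  # subjects are ordered group A first, matching the decoder outputs
  pac <- list(
    envelope = phase_accuracy_correlation(theta_phi$delta_phi, acc_env,
                                          group = groups),
    motion = phase_accuracy_correlation(theta_phi$delta_phi, acc_mot,
                                        group = groups))

  report <- list(config = config, groups = groups,
                 mi = list(table = mi_table, t_test = mi_test),
                 forward = fwd, accuracy_tables = acc_tables,
                 clusters = cluster_res,
                 decoding = list(table = decoding_table,
                                 contrasts = decoding_contrasts,
                                 fits = dec),
                 lags = list(profiles = lag_profiles,
                             table = optimal_lag_table),
                 coherence_table = coherence_table,
                 phase_table = phase_table,
                 circ = circ,
                 phase_accuracy = pac)
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write the numeric report tables of a run
#'
#' CSV tables plus a JSON summary carrying the resolved configuration
#' hash, under `dir`.
#'
#' @param report `run_report` from [run_full()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$mi$table, "mi")
  for (fs in names(report$accuracy_tables))
    wr(report$accuracy_tables[[fs]], paste0("accuracy_", fs))
  wr(report$decoding$table, "decoding")
  wr(report$decoding$contrasts, "decoding_contrasts")
  wr(report$lags$table, "optimal_lags")
  wr(report$coherence_table, "coherence")
  wr(report$phase_table, "phase")
  cfg <- report$config
  cfg$preset_A <- unlist(cfg$preset_A); cfg$preset_B <- unlist(cfg$preset_B)
  summary <- list(
    config_hash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
    theta_watson_williams_F = report$circ$theta$watson_williams$statistic,
    theta_watson_williams_p = report$circ$theta$watson_williams$p_value,
    theta_phase_mean_A = report$circ$theta$mean_A$mean_rad,
    theta_phase_mean_B = report$circ$theta$mean_B$mean_rad,
    cluster_p = lapply(report$clusters, function(cl) cl$p_perm))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    p <- file.path(dir, "summary.json")
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Ground-truth recovery validation on synthetic data
#'
#' Regenerates a synthetic cohort and checks kernel recovery, optimal-lag
#' recovery, phase recovery, and (optionally) cluster-test calibration
#' against fixed thresholds; returns a machine-readable pass/fail
#' summary.
#'
#' @param config `run_config`; must describe a synthetic run.
#' @param check_calibration run the (slower) cluster null-calibration
#'   check.
#' @param n_calib null simulations for the calibration check.
#' @return list of named checks, each with `value`, `threshold`, `pass`.
#' @export
validate_recovery <- function(config = default_config(streams = "eeg_only"),
                              check_calibration = FALSE, n_calib = 100) {
  if (!identical(config$streams, "eeg_only") && !identical(config$streams, "full"))
    stop("validation requires a synthetic cohort configuration")
  cohort <- gen_cohort(config$n_per_group, config$preset_A, config$preset_B,
                       seed = config$seed, duration_s = config$duration_s,
                       n_channels = config$n_channels, streams = "eeg_only")
  prep <- prepare_subjects(cohort)
  groups <- group_of(prep)
  checks <- list()
  add <- function(name, value, threshold, pass)
    checks[[name]] <<- list(value = value, threshold = threshold, pass = pass)

  selA <- prep[groups == "A"]
  m <- fit_generic_forward(selA, "av", lags_ms = config$lags_ms,
                           rate_hz = config$rate_hz,
                           lambda_grid = config$lambda_grid,
                           gamma_grid = config$gamma_grid)
  truthA <- cohort[[which(groups == "A")[1]]]$truth
  kc <- kernel_recovery_correlation(m, truthA)
  add("kernel_recovery_r", kc, 0.9, kc >= 0.9)

  pa <- per_lag_decoding(selA, "envelope", lags_ms = config$lags_ms,
                         rate_hz = config$rate_hz)
  pv <- per_lag_decoding(selA, "motion", lags_ms = config$lags_ms,
                         rate_hz = config$rate_hz)
  lag_err_a <- abs(pa$optimal_lag_ms - config$preset_A$a_peak_ms)
  lag_err_v <- abs(pv$optimal_lag_ms - config$preset_A$v_peak_ms)
  add("lag_recovery_a_err_ms", lag_err_a, 20, lag_err_a <= 20)
  add("lag_recovery_v_err_ms", lag_err_v, 20, lag_err_v <= 20)

  ph <- cohort_phase_shift(prep[groups == "A"], band = "theta",
                           seed = config$seed)
  err <- abs(wrap_angle(ph$group_mean - config$preset_A$theta_phase_shift_rad))
  add("phase_recovery_err_rad", err, pi / 8, err <= pi / 8)

  if (check_calibration) {
    fpr <- cluster_null_fpr(n_sims = n_calib, seed = config$seed)
    add("cluster_fwer", fpr, 0.075, fpr <= 0.075)
  }
  checks$all_pass <- all(vapply(checks, function(c_) isTRUE(c_$pass), TRUE))
  checks
}

#' Correlation between recovered and true kernels
#'
#' Correlates the concatenated (feature x lag x channel) recovered
#' kernel tensor with the ground-truth tensor sampled on the same lag
#' grid.
#'
#' @param model `generic_forward`.
#' @param truth `ground_truth`.
#' @return Pearson correlation.
#' @export
kernel_recovery_correlation <- function(model, truth) {
  true_k <- truth_kernels_on(truth, model$lags_ms)
  if (model$feature_set == "a") true_k <- true_k[1, , , drop = FALSE]
  if (model$feature_set == "v") true_k <- true_k[2, , , drop = FALSE]
  stats::cor(as.numeric(model$kernels), as.numeric(true_k))
}

# sample the ground-truth kernels on an arbitrary lag grid
truth_kernels_on <- function(truth, lags_ms) {
  n_chan <- dim(truth$kernels)[3]
  out <- array(0, dim = c(2, length(lags_ms), n_chan))
  for (f in 1:2) for (ch in seq_len(n_chan))
    out[f, , ch] <- stats::approx(truth$lags_ms, truth$kernels[f, , ch],
                                  lags_ms, rule = 2)$y
  out
}

#' Cohort-level audio-visual phase shift
#'
#' Subject-level theta (or delta) phase shifts from the coherence/CPSD
#' analysis, and their circular mean across subjects.
#'
#' @param prep prepared cohort subset.
#' @param band "theta" or "delta".
#' @param seed RNG seed for the coherence surrogates.
#' @param electrodes analysis electrode set (default all).
#' @return list: `per_subject` (radians), `group_mean`, `r_bar`.
#' @export
cohort_phase_shift <- function(prep, band = "theta", seed = 1,
                               electrodes = NULL) {
  phis <- vapply(seq_along(prep), function(i) {
    sp <- subject_coherence_phase(prep[[i]], seed = child_seed(seed, 300 + i),
                                  electrodes = electrodes)
    el <- electrodes
    if (is.null(el)) {
      el <- which(sp$A[[band]]$reliable)
      if (length(el) < 2) el <- NULL
    }
    av_phase_shift(sp$A[[band]]$phi, sp$V[[band]]$phi,
                   electrodes = el)$subject
  }, 0)
  cm <- circ_mean_r(phis)
  list(per_subject = phis, group_mean = cm$mean_rad, r_bar = cm$r_bar)
}

#' Family-wise error of the cluster permutation test under the null
#'
#' Simulates label-exchangeable per-channel maps (spatially correlated
#' Gaussian subject maps, no group effect) and reports the fraction of
#' simulations with any cluster p below `alpha`.
#'
#' @param n_sims number of simulated datasets.
#' @param n_per_group subjects per group.
#' @param n_channels channels.
#' @param n_perm permutations per test.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return empirical family-wise error rate.
#' @export
cluster_null_fpr <- function(n_sims = 400, n_per_group = 12, n_channels = 16,
                             n_perm = 250, alpha = 0.05, seed = 1) {
  mont <- make_montage(n_channels)
  d <- mont$positions %*% t(mont$positions)
  d[] <- acos(pmin(1, pmax(-1, d)))
  S <- exp(-d^2 / (2 * 0.4^2)); S <- S / sqrt(rowSums(S^2))
  set.seed(as.integer(seed))
  hits <- 0
  for (i in seq_len(n_sims)) {
    M <- matrix(stats::rnorm(2 * n_per_group * n_channels),
                2 * n_per_group) %*% S
    res <- cluster_permutation(M[seq_len(n_per_group), ],
                               M[(n_per_group + 1):(2 * n_per_group), ],
                               mont$adjacency, n_perm = max(500, n_perm),
                               seed = child_seed(seed, i))
    if (length(res$p_perm) > 0 && any(res$p_perm < alpha)) hits <- hits + 1
  }
  hits / n_sims
}
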