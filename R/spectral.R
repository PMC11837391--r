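#' @title Stimulus-brain coherence and cross-spectral phase
#' @description
#' Magnitude-squared coherence by Welch's averaged modified periodogram
#' (3 s Hamming windows, 50% overlap by default), surrogate-standardized
#' coherence, band peak identification in delta/theta, and cross-power
#' spectral density (CPSD) phase at the coherence peak.
#' @name spectral
NULL

#' Welch frequency grid
#' @keywords internal
coherence_grid <- function() seq(0.1, 30, by = 0.33)

# Segment FFTs with a Hamming window.  `runs` restricts segments to
# contiguous usable spans (trials); segments never straddle a boundary.
welch_segments <- function(x, rate_hz, window_s = 3, overlap = 0.5,
                           runs = NULL, max_freq = 35) {
  N <- round(window_s * rate_hz)
  hop <- round(N * (1 - overlap))
  if (is.null(runs)) runs <- data.frame(start = 1, end = length(x))
  w <- hamming_window(N)
  starts <- integer(0)
  for (r in seq_len(nrow(runs))) {
    s0 <- runs$start[r]
    while (s0 + N - 1 <= runs$end[r]) { starts <- c(starts, s0); s0 <- s0 + hop }
  }
  if (length(starts) < 3) stop("fewer than 3 Welch segments; record too short")
  freqs <- (seq_len(N) - 1) * rate_hz / N
  keep <- freqs <= max_freq
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + N - 1)]
    stats::fft((seg - mean(seg)) * w)[keep]
  }, complex(sum(keep)))
  list(F = segs, freqs = freqs[keep], hop_s = hop / rate_hz, n_seg = length(starts))
}

coh_from_ffts <- function(Fx, Fy, pairing = NULL) {
  K <- ncol(Fx)
  if (is.null(pairing)) pairing <- seq_len(K)
  Sxy <- rowMeans(Conj(Fx) * Fy[, pairing, drop = FALSE])
  Sxx <- rowMeans(Mod(Fx)^2)
  Syy <- rowMeans(Mod(Fy)^2)
  list(coh = Mod(Sxy)^2 / (Sxx * Syy), Sxy = Sxy)
}

#' Magnitude-squared coherence (Welch)
#'
#' C(f) = |Sxy|^2 / (Sxx Syy) with Welch averaging over Hamming-windowed
#' segments, interpolated onto the analysis grid 0.1-30 Hz in 0.33 Hz
#' steps.
#'
#' @param x,y numeric vectors of equal length.
#' @param rate_hz sampling rate.
#' @param window_s segment length in seconds (default 3).
#' @param overlap fractional overlap (default 0.5).
#' @param runs optional data.frame(start, end) of usable spans (trials).
#' @return list (`coherence_spectrum`): `freqs_hz`, `coh`, `n_seg`.
#' @export
welch_coherence <- function(x, y, rate_hz, window_s = 3, overlap = 0.5,
                            runs = NULL) {
  stopifnot(length(x) == length(y))
  Fx <- welch_segments(x, rate_hz, window_s, overlap, runs)
  Fy <- welch_segments(y, rate_hz, window_s, overlap, runs)
  if (Fx$n_seg < 2) stop("coherence degenerate with fewer than 2 segments")
  cc <- coh_from_ffts(Fx$F, Fy$F)
  grid <- coherence_grid()
  coh <- stats::approx(Fx$freqs, cc$coh, grid, rule = 2)$y
  structure(list(freqs_hz = grid, coh = coh, n_seg = Fx$n_seg),
            class = "coherence_spectrum")
}

#' Surrogate-standardized coherence spectrum
#'
#' The null preserves each signal's autocorrelation by circularly
#' shifting the neural time course relative to the stimulus: shifts are
#' realized as segment re-pairings at multiples of the Welch hop (>= 1 s),
#' so cached segment FFTs are reused.  z = (coh - mean_surr) / sd_surr
#' per frequency.
#'
#' @param x,y numeric vectors (x = stimulus, y = neural).
#' @param rate_hz sampling rate.
#' @param n_surrogates number of surrogates (>= 20, default 50).
#' @param seed RNG seed.
#' @param window_s,overlap,runs Welch parameters as in
#'   [welch_coherence()].
#' @return list (`coherence_z`): `freqs_hz`, `coh`, `z`, `n_surrogates`.
#' @export
surrogate_coherence_z <- function(x, y, rate_hz, n_surrogates = 50, seed = 1,
                                  window_s = 3, overlap = 0.5, runs = NULL) {
  stopifnot(n_surrogates >= 20)
  Fx <- welch_segments(x, rate_hz, window_s, overlap, runs)
  Fy <- welch_segments(y, rate_hz, window_s, overlap, runs)
  K <- Fx$n_seg
  obs <- coh_from_ffts(Fx$F, Fy$F)$coh
  set.seed(as.integer(seed))
  min_m <- max(1, ceiling(1 / Fx$hop_s))
  ms <- sample(seq(min_m, K - 1), n_surrogates, replace = TRUE)
  surr <- vapply(ms, function(m) {
    pairing <- ((seq_len(K) + m - 1) %% K) + 1
    coh_from_ffts(Fx$F, Fy$F, pairing)$coh
  }, numeric(length(obs)))
  mu <- rowMeans(surr); sdv <- apply(surr, 1, stats::sd)
  z <- (obs - mu) / sdv
  z[sdv == 0] <- NA_real_
  grid <- coherence_grid()
  structure(list(freqs_hz = grid,
                 coh = stats::approx(Fx$freqs, obs, grid, rule = 2)$y,
                 z = stats::approx(Fx$freqs, z, grid, rule = 2)$y,
                 n_surrogates = n_surrogates),
            class = "coherence_z")
}

#' Peak frequency of a band
#'
#' Frequency of maximum (surrogate-corrected) coherence within the band;
#' for multi-channel input the spectra are averaged across the supplied
#' electrode set first.  Delta is operationalized as 1-4 Hz and theta as
#' 4-8 Hz.
#'
#' @param freqs_hz frequency grid.
#' @param values coherence (or z) vector, or matrix [n_chan x n_freq].
#' @param band "delta" or "theta", or a numeric c(lo, hi).
#' @param electrodes channel subset for matrix input (default all).
#' @return list: `f_peak_hz`, `flat_flag`.
#' @export
band_peak <- function(freqs_hz, values, band = c("theta", "delta"),
                      electrodes = NULL) {
  if (is.character(band)) {
    band <- match.arg(band)
    band <- if (band == "delta") c(1, 4) else c(4, 8)
  }
  if (is.matrix(values)) {
    if (is.null(electrodes)) electrodes <- seq_len(nrow(values))
    values <- colMeans(values[electrodes, , drop = FALSE])
  }
  sel <- freqs_hz >= band[1] & freqs_hz <= band[2]
  stopifnot(any(sel))
  v <- values[sel]; f <- freqs_hz[sel]
  if (max(v) - min(v) < 1e-12)
    return(list(f_peak_hz = mean(band), flat_flag = TRUE))
  list(f_peak_hz = f[which.max(v)], flat_flag = FALSE)
}

#' Cross-power spectral density phase at a frequency
#'
#' Phase angle of the Welch-averaged cross-spectrum at the native bin
#' nearest `f_eval_hz`, wrapped to (-pi, pi].  Sign convention: positive
#' phase means `y` leads `x` (a pure delay of y by tau gives
#' -2 pi f tau).
#'
#' @param x,y numeric vectors.
#' @param rate_hz sampling rate.
#' @param f_eval_hz evaluation frequency.
#' @param window_s,overlap,runs Welch parameters.
#' @return phase in radians.
#' @export
cpsd_phase <- function(x, y, rate_hz, f_eval_hz, window_s = 3, overlap = 0.5,
                       runs = NULL) {
  Fx <- welch_segments(x, rate_hz, window_s, overlap, runs)
  Fy <- welch_segments(y, rate_hz, window_s, overlap, runs)
  Sxy <- rowMeans(Conj(Fx$F) * Fy$F)
  i <- which.min(abs(Fx$freqs - f_eval_hz))
  wrap_angle(Arg(Sxy[i]))
}

#' Audio-visual phase shift
#'
#' Wrapped circular difference phi_V - phi_A per channel; positive values
#' mean the visual stream leads the auditory stream.  The subject-level
#' value is the circular mean over the analysis electrode set.
#'
#' @param phi_a,phi_v per-channel phases (radians).
#' @param electrodes electrode subset (default all).
#' @return list: `per_channel` (wrapped differences), `subject`
#'   (circular mean over the set), `r_bar`.
#' @export
av_phase_shift <- function(phi_a, phi_v, electrodes = NULL) {
  stopifnot(length(phi_a) == length(phi_v))
  if (is.null(electrodes)) electrodes <- seq_along(phi_a)
  if (length(electrodes) == 0) stop("empty electrode set")
  d <- wrap_angle(phi_v - phi_a)
  cm <- circ_mean_r(d[electrodes])
  list(per_channel = d, subject = cm$mean_rad, r_bar = cm$r_bar)
}

#' Subject-level coherence and phase analysis
#'
#' For one subject: per-channel surrogate-standardized coherence against
#' each stimulus feature, band peak frequencies (delta, theta) from the
#' cluster-averaged z spectrum, and per-channel CPSD phase at each peak.
#' Trials are contiguous usable spans of at least `trial_min_s` seconds.
#'
#' @param prep prepared subject (from [prepare_subjects()]).
#' @param n_surrogates surrogates for the coherence null (default 50).
#' @param seed RNG seed.
#' @param window_s,overlap Welch parameters.
#' @param trial_min_s minimum trial length (default 9).
#' @param electrodes electrode set for peak identification (default all).
#' @return nested list by condition (A = envelope, V = motion) with
#'   `coh`, `z` [n_chan x n_freq], `freqs_hz`, and per band `f_peak_hz`
#'   and `phi` (per-channel phase).
#' @export
subject_coherence_phase <- function(prep, n_surrogates = 50, seed = 1,
                                    window_s = 3, overlap = 0.5,
                                    trial_min_s = 9, electrodes = NULL) {
  eeg <- prep$eeg
  rate <- eeg$rate_hz
  runs <- true_runs(eeg$artifact_mask)
  runs <- runs[(runs$end - runs$start + 1) >= trial_min_s * rate, , drop = FALSE]
  if (nrow(runs) == 0) stop("no usable trial of sufficient length")
  n_chan <- nrow(eeg$data)
  grid <- coherence_grid()
  # EEG channel segment FFTs are shared by both stimulus conditions
  Fy_all <- lapply(seq_len(n_chan), function(ch)
    welch_segments(eeg$data[ch, ], rate, window_s, overlap, runs))
  out <- list()
  for (cond in c("A", "V")) {
    feat <- if (cond == "A") prep$features$envelope else prep$features$motion
    Fx <- welch_segments(feat, rate, window_s, overlap, runs)
    coh <- z <- matrix(NA_real_, n_chan, length(grid))
    Sxy_native <- matrix(NA_complex_, n_chan, length(Fx$freqs))
    for (ch in seq_len(n_chan)) {
      Fy <- Fy_all[[ch]]
      obs <- coh_from_ffts(Fx$F, Fy$F)
      Sxy_native[ch, ] <- obs$Sxy
      K <- Fx$n_seg
      set.seed(child_seed(seed, ch + ifelse(cond == "A", 0, 5000)))
      min_m <- max(1, ceiling(1 / Fx$hop_s))
      ms <- sample(seq(min_m, K - 1), n_surrogates, replace = TRUE)
      surr <- vapply(ms, function(m) {
        pairing <- ((seq_len(K) + m - 1) %% K) + 1
        coh_from_ffts(Fx$F, Fy$F, pairing)$coh
      }, numeric(length(Fx$freqs)))
      mu <- rowMeans(surr); sdv <- apply(surr, 1, stats::sd)
      zi <- (obs$coh - mu) / sdv
      coh[ch, ] <- stats::approx(Fx$freqs, obs$coh, grid, rule = 2)$y
      z[ch, ] <- stats::approx(Fx$freqs, zi, grid, rule = 2)$y
    }
    out[[cond]] <- list(coh = coh, z = z, freqs_hz = grid,
                        Sxy_native = Sxy_native, native_freqs = Fx$freqs)
  }
  # Band peaks from the elementwise minimum of the two conditions' z
  # spectra: the frequency where coherence is prominent for BOTH stimulus
  # conditions.  Both phases are then evaluated at that one common
  # frequency, so the response-kernel phase cancels in the V - A
  # difference, which is only defined where the two streams share
  # coupling.
  for (b in c("delta", "theta")) {
    z_min <- pmin(out$A$z, out$V$z)
    pk <- band_peak(grid, z_min, b, electrodes)
    i_grid <- which.min(abs(grid - pk$f_peak_hz))
    reliable <- out$A$z[, i_grid] > 2 & out$V$z[, i_grid] > 2
    for (cond in c("A", "V")) {
      i_native <- which.min(abs(out[[cond]]$native_freqs - pk$f_peak_hz))
      # EEG->stimulus phase (positive = stimulus leads response), so
      # phi_V - phi_A recovers the imposed theta offset with positive
      # values meaning the visual stream leads
      out[[cond]][[b]] <- list(
        f_peak_hz = pk$f_peak_hz, flat_flag = pk$flat_flag,
        phi = wrap_angle(-Arg(out[[cond]]$Sxy_native[, i_native])),
        reliable = reliable)
    }
  }
  out$A$Sxy_native <- out$V$Sxy_native <- NULL
  out
}
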