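#' Extract the speech envelope
#'
#' Magnitude of the analytic signal, anti-alias low-passed, resampled to
#' `out_rate`, and zero-phase low-pass filtered at `lowpass_hz`.  The
#' anti-alias step is the same 40 Hz zero-phase Butterworth applied at the
#' source rate, so no additional design is needed before the rate change.
#'
#' @param audio mono numeric waveform.
#' @param audio_rate sampling rate in Hz (>= 2000).
#' @param out_rate output rate (default 1000).
#' @param lowpass_hz low-pass cutoff (default 40).
#' @return numeric envelope at `out_rate` Hz (near-nonnegative; zero-phase
#'   filtering can introduce tiny ringing undershoots).
#' @export
extract_envelope <- function(audio, audio_rate, out_rate = 1000,
                             lowpass_hz = 40) {
  if (any(!is.finite(audio))) stop("audio contains non-finite samples")
  stopifnot(audio_rate >= 2000)
  if (all(audio == 0)) return(numeric(round(length(audio) / audio_rate * out_rate)))
  env <- Mod(analytic_signal(audio))
  env <- butter_filtfilt(env, audio_rate, high = lowpass_hz, order = 4)
  t_in <- (seq_along(env) - 1) / audio_rate
  n_out <- round(length(audio) / audio_rate * out_rate)
  t_out <- (seq_len(n_out) - 1) / out_rate
  env_rs <- stats::approx(t_in, env, t_out, rule = 2)$y
  butter_filtfilt(env_rs, out_rate, high = lowpass_hz, order = 4)
}

#' I-VT velocity-threshold fixation classification
#'
#' Gaze samples whose point-to-point angular velocity stays below the
#' threshold form fixations; adjacent fixations separated by less than
#' `merge_gap_ms` (and less than `merge_deg` apart) are merged, and
#' fixations shorter than `min_fix_ms` are discarded.  Defaults are the
#' vendor-published I-VT values (30 deg/s, 75 ms merge window, 0.5 deg
#' merge angle, 60 ms minimum).  Samples with missing coordinates break
#' fixations; gaps are never interpolated beyond `max_gap_ms`.
#'
#' @param gaze data.frame with columns `t` (s, monotone), `x`, `y` (px).
#' @param velocity_threshold_deg_s classification threshold.
#' @param px_per_deg pixel-to-degree conversion of the screen geometry.
#' @param merge_gap_ms,merge_deg,min_fix_ms,max_gap_ms filter parameters.
#' @return data.frame with columns `onset_s`, `offset_s`, `cx`, `cy`.
#' @export
ivt_fixations <- function(gaze, velocity_threshold_deg_s = 30, px_per_deg = 35,
                          merge_gap_ms = 75, merge_deg = 0.5,
                          min_fix_ms = 60, max_gap_ms = 75) {
  if (nrow(gaze) < 2) return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                        cx = numeric(0), cy = numeric(0)))
  stopifnot(!is.unsorted(gaze$t))
  dt <- diff(gaze$t)
  dpx <- sqrt(diff(gaze$x)^2 + diff(gaze$y)^2)
  vel <- dpx / px_per_deg / pmax(dt, 1e-9)          # deg/s
  gap <- dt > max_gap_ms / 1000
  valid_pt <- is.finite(gaze$x) & is.finite(gaze$y)
  # a step is sub-threshold if its velocity is below threshold, it does
  # not span a data gap, and both endpoints are valid; a run of
  # sub-threshold steps i..j makes samples i..j+1 one fixation
  ok <- is.finite(vel) & vel < velocity_threshold_deg_s & !gap &
    valid_pt[-length(valid_pt)] & valid_pt[-1]
  runs <- true_runs(ok)
  if (nrow(runs) == 0) return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                                         cx = numeric(0), cy = numeric(0)))
  runs$end <- runs$end + 1            # steps -> samples
  fx <- data.frame(
    onset_s = gaze$t[runs$start], offset_s = gaze$t[runs$end],
    cx = vapply(seq_len(nrow(runs)), function(i)
      mean(gaze$x[runs$start[i]:runs$end[i]], na.rm = TRUE), 0),
    cy = vapply(seq_len(nrow(runs)), function(i)
      mean(gaze$y[runs$start[i]:runs$end[i]], na.rm = TRUE), 0))
  # merge pass
  merged <- fx[1, ]
  for (i in seq_len(nrow(fx))[-1]) {
    last <- nrow(merged)
    gap_ms <- (fx$onset_s[i] - merged$offset_s[last]) * 1000
    sep_deg <- sqrt((fx$cx[i] - merged$cx[last])^2 +
                    (fx$cy[i] - merged$cy[last])^2) / px_per_deg
    if (gap_ms < merge_gap_ms && sep_deg < merge_deg) {
      w1 <- merged$offset_s[last] - merged$onset_s[last]
      w2 <- fx$offset_s[i] - fx$onset_s[i]
      merged$cx[last] <- (merged$cx[last] * w1 + fx$cx[i] * w2) / (w1 + w2)
      merged$cy[last] <- (merged$cy[last] * w1 + fx$cy[i] * w2) / (w1 + w2)
      merged$offset_s[last] <- fx$offset_s[i]
    } else merged <- rbind(merged, fx[i, ])
  }
  merged[(merged$offset_s - merged$onset_s) * 1000 >= min_fix_ms, , drop = FALSE]
}

#' Gaze-contingent visual motion extraction
#'
#' For each successive frame pair, crops a `window_px` x `window_px`
#' region around the fixation centroid active at that instant (clamped to
#' the frame borders), takes absolute luminance differences, and averages
#' the pixels strictly exceeding `diff_threshold` (0 if none exceed).
#' The per-frame-pair values are upsampled to `out_rate` by zero-order
#' hold; instants not covered by any fixation are marked unusable.
#'
#' @param frames integer array [n_frames x H x W] of grey levels (RGB
#'   inputs must be converted to luminance beforehand).
#' @param fps frame rate.
#' @param fixations data.frame from [ivt_fixations()].
#' @param window_px crop window side (default 318).
#' @param diff_threshold luminance difference threshold (default 10).
#' @param out_rate output rate (default 1000).
#' @param average "supra" (default) averages only supra-threshold pixels;
#'   "window" divides the supra-threshold sum by all window pixels.
#' @return list with `motion` (numeric at `out_rate`), `usable_mask`
#'   (logical), `rate_hz`, and `per_frame` values.
#' @export
extract_visual_motion <- function(frames, fps, fixations, window_px = 318,
                                  diff_threshold = 10, out_rate = 1000,
                                  average = c("supra", "window")) {
  average <- match.arg(average)
  nf <- dim(frames)[1]; H <- dim(frames)[2]; W <- dim(frames)[3]
  t_pair <- (seq_len(nf - 1) - 0.5) / fps      # midpoint of each frame pair
  half <- floor(window_px / 2)
  per_frame <- rep(NA_real_, nf - 1)
  for (k in seq_len(nf - 1)) {
    fi <- which(fixations$onset_s <= t_pair[k] & fixations$offset_s >= t_pair[k])
    if (length(fi) == 0) next
    cx <- round(fixations$cx[fi[1]]); cy <- round(fixations$cy[fi[1]])
    cols <- max(1, cx - half):min(W, cx + half)
    rows <- max(1, cy - half):min(H, cy + half)
    d <- abs(frames[k + 1, rows, cols, drop = TRUE] -
             frames[k, rows, cols, drop = TRUE])
    supra <- d[d > diff_threshold]
    per_frame[k] <- if (length(supra) == 0) 0
      else if (average == "supra") mean(supra) else sum(supra) / length(d)
  }
  dur <- nf / fps
  n_out <- round(dur * out_rate)
  t_out <- (seq_len(n_out) - 1) / out_rate
  # value of pair k holds over [ (k-1)/fps, k/fps )
  idx <- pmin(nf - 1, pmax(1, floor(t_out * fps) + 1))
  motion <- per_frame[idx]
  mask <- !is.na(motion)
  motion[!mask] <- 0
  list(motion = motion, usable_mask = mask, rate_hz = out_rate,
       per_frame = per_frame)
}

#' Align and RMS-normalize stimulus features and EEG
#'
#' Divides each feature and each EEG channel by its root-mean-square over
#' usable samples (column-wise energy normalization); unusable periods
#' (EEG artifact mask or gaze gaps) are excluded from the statistics and
#' flagged in the joint mask.
#'
#' @param envelope,motion numeric vectors at the EEG rate.
#' @param eeg `eeg_recording`.
#' @param usable_mask optional logical vector (e.g. gaze coverage), ANDed
#'   with the EEG artifact mask.
#' @return list with `features` (class `stimulus_features`: `envelope`,
#'   `motion`, `rate_hz`, `usable_mask`, `flags`) and `eeg` (normalized).
#' @export
align_and_normalize <- function(envelope, motion, eeg, usable_mask = NULL) {
  n <- ncol(eeg$data)
  stopifnot(length(envelope) == n, length(motion) == n)
  mask <- eeg$artifact_mask
  if (!is.null(usable_mask)) mask <- mask & usable_mask
  flags <- character(0)
  normv <- function(x, what) {
    r <- masked_rms(x, mask)
    if (r == 0) { flags <<- c(flags, sprintf("zero RMS: %s", what)); x }
    else x / r
  }
  envelope <- normv(envelope, "envelope")
  motion <- normv(motion, "motion")
  for (ch in seq_len(nrow(eeg$data)))
    eeg$data[ch, ] <- normv(eeg$data[ch, ], sprintf("channel %d", ch))
  eeg$artifact_mask <- mask
  feats <- structure(list(envelope = envelope, motion = motion,
                          rate_hz = eeg$rate_hz, usable_mask = mask,
                          flags = flags),
                     class = "stimulus_features")
  list(features = feats, eeg = eeg)
}

#' Binned mutual information with permutation significance
#'
#' Plug-in MI in bits from the joint histogram of equipopulated
#' (rank-quantile) bins, with a p-value from random permutations of `y`.
#'
#' @param x,y numeric vectors of equal length (>= 8 * n_bins^2).
#' @param n_bins marginal bins (default 4).
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @return list (`mi_result`): `mi_bits`, `p_value`, `n_bins`, `flag`.
#' @export
mutual_information <- function(x, y, n_bins = 4, n_perm = 1000, seed = 1) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  stopifnot(n >= 8 * n_bins^2 || n >= 8)   # tiny fixtures allowed for oracles
  flag <- NULL
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: MI undefined under quantile bins, returning 0")
    return(structure(list(mi_bits = 0, p_value = 1, n_bins = n_bins,
                          flag = "constant-input"), class = "mi_result"))
  }
  bx <- quantile_bins(x, n_bins)
  by <- quantile_bins(y, n_bins)
  mi_obs <- mi_from_bins(bx, by, n_bins)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm), function(i)
    mi_from_bins(bx, by[sample.int(n)], n_bins), 0)
  p <- (1 + sum(null >= mi_obs)) / (n_perm + 1)
  structure(list(mi_bits = mi_obs, p_value = p, n_bins = n_bins, flag = flag),
            class = "mi_result")
}

# equipopulated binning by ranks (ties broken by order, deterministic)
quantile_bins <- function(x, n_bins) {
  r <- rank(x, ties.method = "first")
  ceiling(r * n_bins / length(x))
}

mi_from_bins <- function(bx, by, n_bins) {
  joint <- matrix(tabulate(bx + n_bins * (by - 1), nbins = n_bins^2), n_bins)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}
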