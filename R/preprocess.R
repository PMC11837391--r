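#' Zero-phase EEG filter chain
#'
#' Band-pass 0.1-70 Hz (fourth-order Butterworth, forward-backward),
#' 50 Hz IIR notch, and optionally the final 30 Hz low-pass.  The full
#' preprocessing sequence applies the low-pass only after interpolation
#' and re-referencing, so [preprocess_eeg()] calls this twice with
#' `lowpass = NULL` first.
#'
#' @param eeg `eeg_recording`.
#' @param band band-pass edges in Hz (default c(0.1, 70)).
#' @param notch_hz notch centre (NULL to skip).
#' @param notch_q notch quality factor.
#' @param lowpass final low-pass cutoff in Hz (NULL to skip).
#' @return filtered `eeg_recording` (DC removed).
#' @export
filter_chain <- function(eeg, band = c(0.1, 70), notch_hz = 50, notch_q = 30,
                         lowpass = NULL) {
  stopifnot(eeg$rate_hz >= 200)
  if (!is.null(band) && ncol(eeg$data) < 3 * eeg$rate_hz / band[1] / 10)
    stop("signal too short for the 0.1 Hz high-pass transient")
  for (ch in seq_len(nrow(eeg$data))) {
    x <- eeg$data[ch, ]
    x <- x - mean(x)
    if (!is.null(band)) x <- butter_filtfilt(x, eeg$rate_hz,
                                             low = band[1], high = band[2])
    if (!is.null(notch_hz)) x <- notch_filtfilt(x, eeg$rate_hz, notch_hz, notch_q)
    if (!is.null(lowpass)) x <- butter_filtfilt(x, eeg$rate_hz, high = lowpass)
    eeg$data[ch, ] <- x
  }
  eeg
}

#' Detect channels with excessive amplitude
#'
#' Robust criterion: a channel is flagged when the robust z-score (median
#' / MAD across channels) of its signal MAD exceeds the threshold.
#'
#' @param eeg `eeg_recording` (>= 8 channels).
#' @param z_amp_threshold robust z threshold (default 5).
#' @return integer vector of flagged channel indices.
#' @export
detect_bad_channels <- function(eeg, z_amp_threshold = 5) {
  stopifnot(nrow(eeg$data) >= 8)
  amp <- apply(eeg$data, 1, stats::mad)
  med <- stats::median(amp)
  # relative scale floor: focal physiological topographies make channel
  # amplitudes heterogeneous by factors of 2-4 without being artifactual;
  # the detector targets gross excess (an order of magnitude), so the
  # spread term never shrinks below the median amplitude itself (at the
  # default z = 5 a channel must exceed ~6x the median to be flagged)
  scale <- max(stats::mad(amp), med, 1e-12)
  z <- (amp - med) / scale
  bad <- which(z > z_amp_threshold)
  if (length(bad) > 0.3 * nrow(eeg$data))
    stop(sprintf("%d of %d channels flagged bad; inspect the recording",
                 length(bad), nrow(eeg$data)))
  bad
}

# Legendre polynomial sum for the Perrin spherical-spline kernel
# g(x) = (1/4pi) sum_{n=1}^{N} (2n+1)/(n(n+1))^m  P_n(x)
perrin_g <- function(x, m = 4, n_terms = 50) {
  # iterate Legendre recursion over all x simultaneously
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:n_terms) {
    p_new <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_new
    p_prev <- p_cur; p_cur <- p_new
  }
  acc / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Perrin-style interpolation (order m = 4, ridge regularization 1e-5 on
#' the spline system) reconstructing each flagged channel from the good
#' channels at every sample.
#'
#' @param eeg `eeg_recording` with unit-sphere `positions`.
#' @param bad_set integer indices of channels to rebuild.
#' @param m spline order.
#' @param reg regularization added to the kernel matrix diagonal.
#' @return `eeg_recording` with `bad_set` channels replaced and recorded
#'   in `$interpolated`.
#' @export
interpolate_channels <- function(eeg, bad_set, m = 4, reg = 1e-5) {
  if (length(bad_set) == 0) return(eeg)
  good <- setdiff(seq_len(nrow(eeg$data)), bad_set)
  # each bad channel needs enough nearby good support on the cap (the
  # spline is global, but extrapolation far from support is unreliable)
  for (b in bad_set) {
    g <- eeg$positions[good, , drop = FALSE] %*% eeg$positions[b, ]
    nb <- sum(acos(pmin(1, pmax(-1, g))) < 0.9)
    if (nb < 3) {
      warning(sprintf("channel %d has <3 good channels nearby; left as is", b))
      bad_set <- setdiff(bad_set, b)
    }
  }
  if (length(bad_set) == 0) return(eeg)
  good <- setdiff(seq_len(nrow(eeg$data)), bad_set)
  P <- eeg$positions
  cosang <- function(A, B) { g <- A %*% t(B); g[] <- pmin(1, pmax(-1, g)); g }
  G <- perrin_g(cosang(P[good, , drop = FALSE], P[good, , drop = FALSE]), m)
  G <- G + diag(reg, length(good))
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  Gb <- perrin_g(cosang(P[bad_set, , drop = FALSE], P[good, , drop = FALSE]), m)
  # spline coefficients for all samples at once
  coef <- solve(A, rbind(eeg$data[good, , drop = FALSE], 0))
  eeg$data[bad_set, ] <- cbind(Gb, 1) %*% coef
  eeg$interpolated <- sort(unique(c(eeg$interpolated, bad_set)))
  eeg$bad_channels <- setdiff(eeg$bad_channels, bad_set)
  eeg
}

#' Common average reference
#'
#' Subtracts the per-sample mean across channels; idempotent.
#'
#' @param eeg `eeg_recording` (bad channels already interpolated).
#' @return re-referenced `eeg_recording`.
#' @export
rereference_average <- function(eeg) {
  eeg$data <- sweep(eeg$data, 2, colMeans(eeg$data))
  eeg
}

#' Mask high-amplitude artifact segments
#'
#' Automated surrogate for visual artifact rejection: samples where any
#' channel exceeds `abs_amp_uv` are masked out together with `pad_ms` of
#' padding on both sides; the mask propagates to feature statistics.
#'
#' @param eeg `eeg_recording`.
#' @param abs_amp_uv absolute amplitude threshold (default 150).
#' @param pad_ms padding around flagged samples (default 200).
#' @return `eeg_recording` with updated `artifact_mask`.
#' @export
mask_artifact_segments <- function(eeg, abs_amp_uv = 150, pad_ms = 200) {
  stopifnot(abs_amp_uv > 0, pad_ms >= 0)
  hit <- apply(abs(eeg$data) > abs_amp_uv, 2, any)
  if (any(hit)) {
    pad <- round(pad_ms / 1000 * eeg$rate_hz)
    idx <- which(hit)
    lo <- pmax(1, idx - pad); hi <- pmin(length(hit), idx + pad)
    for (i in seq_along(idx)) hit[lo[i]:hi[i]] <- TRUE
  }
  mask <- eeg$artifact_mask & !hit
  if (mean(!mask) > 0.5)
    stop(sprintf("%.0f%% of samples masked; recording unusable", 100 * mean(!mask)))
  eeg$artifact_mask <- mask
  eeg
}

#' ICA hook (externally supplied decomposition)
#'
#' The pipeline accepts an externally computed unmixing matrix and a list
#' of components to reject; with neither supplied this is the identity.
#'
#' @param eeg `eeg_recording`.
#' @param unmixing optional [n_comp x n_channels] unmixing matrix.
#' @param reject integer components to zero out before remixing.
#' @return `eeg_recording`.
#' @export
ica_hook <- function(eeg, unmixing = NULL, reject = integer(0)) {
  if (is.null(unmixing) || length(reject) == 0) return(eeg)
  mixing <- solve(unmixing)
  src <- unmixing %*% eeg$data
  src[reject, ] <- 0
  eeg$data <- mixing %*% src
  eeg
}

#' Full preprocessing sequence
#'
#' Fixed, logged order: band-pass + notch -> bad-channel detection ->
#' ICA hook -> spherical-spline interpolation -> common average
#' reference -> 30 Hz low-pass -> artifact masking.
#'
#' @param eeg `eeg_recording`.
#' @param config list of stage parameters (see defaults in the code).
#' @return cleaned `eeg_recording` with a `$log` of applied steps.
#' @export
preprocess_eeg <- function(eeg, config = list()) {
  cfg <- utils::modifyList(list(
    band = c(0.1, 70), notch_hz = 50, notch_q = 30, lowpass = 30,
    z_amp_threshold = 5, abs_amp_uv = 150, pad_ms = 200,
    unmixing = NULL, ica_reject = integer(0)), config)
  log <- character(0)
  eeg <- filter_chain(eeg, band = cfg$band, notch_hz = cfg$notch_hz,
                      notch_q = cfg$notch_q, lowpass = NULL)
  log <- c(log, sprintf("bandpass %.1f-%.0f Hz + notch %.0f Hz",
                        cfg$band[1], cfg$band[2], cfg$notch_hz))
  bad <- detect_bad_channels(eeg, cfg$z_amp_threshold)
  eeg$bad_channels <- bad
  log <- c(log, sprintf("bad channels: %s",
                        if (length(bad)) paste(bad, collapse = ",") else "none"))
  eeg <- ica_hook(eeg, cfg$unmixing, cfg$ica_reject)
  log <- c(log, sprintf("ICA hook: %d components rejected", length(cfg$ica_reject)))
  eeg <- interpolate_channels(eeg, bad)
  log <- c(log, "spherical-spline interpolation")
  eeg <- rereference_average(eeg)
  log <- c(log, "common average reference")
  eeg <- filter_chain(eeg, band = NULL, notch_hz = NULL, lowpass = cfg$lowpass)
  log <- c(log, sprintf("low-pass %.0f Hz", cfg$lowpass))
  eeg <- mask_artifact_segments(eeg, cfg$abs_amp_uv, cfg$pad_ms)
  log <- c(log, sprintf("artifact mask: %.1f%% removed",
                        100 * mean(!eeg$artifact_mask)))
  eeg$log <- log
  eeg
}
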