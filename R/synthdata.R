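#' @title Synthetic audio-visual cohort generator
#' @description
#' Generators for all four recording streams (audio, video frames, gaze,
#' EEG) with known ground truth: temporal response kernels, cross-modal
#' timing, and theta-band phase offsets.  Two presets emulate the regimes
#' of interest: a "typical" profile (visual response lead, pi/2 theta
#' phase offset between the visual-motion and speech-envelope streams,
#' tightly concentrated across subjects) and an "atypical" profile
#' (auditory response lead, pi offset, broad phase dispersion).
#' @name synthdata
NULL

#' Von Mises random angles (Best & Fisher rejection sampler)
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (>= 0; 0 = uniform on the circle).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(wrap_angle(stats::runif(n, -pi, pi)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1
    }
  }
  wrap_angle(out + mu)
}

# Internal: quasiperiodic theta-band component as a dense sum of
# sinusoids with random phases, synthesized in the frequency domain
# (Gaussian amplitude taper around theta_hz, clipped to [2, 8] Hz).
# Returns a closure producing time-shifted / phase-rotated copies from
# the SAME coefficients: a shift is a phase ramp, a rotation multiplies
# every positive-frequency coefficient by exp(i rot), so the imposed
# offset holds at every theta frequency (analytic-signal rotation).
# Shifts are circular (the component is stationary band noise).  The
# phase rotation applies only at and above rot_min_hz (theta proper),
# keeping the delta portion of the shared rhythm phase-aligned.
make_theta_component <- function(n, rate_hz, theta_hz, spread_hz = 1.2,
                                 rot_min_hz = 4) {
  freqs <- (seq_len(n) - 1) * rate_hz / n
  amp <- exp(-((freqs - theta_hz)^2) / (2 * spread_hz^2))
  amp[freqs >= 1.5 & freqs < 4] <-
    pmax(amp[freqs >= 1.5 & freqs < 4], 0.55)     # shared delta floor
  amp[freqs < 1.5 | freqs > 8] <- 0
  coefs <- amp * exp(2i * pi * stats::runif(n))
  coefs[1] <- 0
  function(shift_s = 0, rot_rad = 0) {
    ramp <- exp(1i * (2 * pi * freqs * shift_s + rot_rad * (freqs >= rot_min_hz)))
    v <- Re(stats::fft(coefs * ramp, inverse = TRUE))
    v / stats::sd(v)
  }
}

#' Generate a coupled speech-envelope / visual-motion pair
#'
#' Builds two nonnegative quasiperiodic series whose theta-band components
#' have a controlled relative time lag and phase offset.  The envelope is
#' a rectified sum of theta-band sinusoids modulated by a slow amplitude
#' envelope plus a weak broadband component; the motion series is a
#' time-shifted copy whose theta component is additionally rotated by
#' `phase_shift_rad` and mixed with an independent theta component.
#'
#' Sign conventions: positive `av_lag_ms` means the motion (visual) series
#' leads the envelope (auditory) series; positive `phase_shift_rad`
#' rotates the motion theta component ahead of the envelope's, so
#' `cpsd_phase(envelope, motion)` at the theta frequency recovers
#' `2*pi*f*av_lag/1000 + phase_shift_rad`.
#'
#' @param duration_s duration in seconds (> 0).
#' @param rate_hz sampling rate (>= 4 * theta_hz).
#' @param theta_hz centre of the theta rhythm, in [2, 8] (default 5).
#' @param av_lag_ms signed lag in ms (positive = motion leads).
#' @param phase_shift_rad extra theta rotation in (-pi, pi].
#' @param seed integer RNG seed; fully determines the draw.
#' @param mix_shared fraction of motion theta variance shared with the
#'   (shifted, rotated) envelope theta component; 1 = pure copy.
#' @param noise_sd sd of additive white noise on the motion series.
#' @param am_hz,am_depth slow amplitude-modulation frequency and depth.
#' @param broadband_sd sd of the low-passed broadband component.
#' @return list with `envelope`, `motion` (nonnegative numeric vectors),
#'   `rate_hz`, and `t` (time axis, seconds).
#' @export
gen_stimulus_pair <- function(duration_s, rate_hz, theta_hz = 5,
                              av_lag_ms = 0, phase_shift_rad = 0, seed = 1,
                              mix_shared = 1, noise_sd = 0,
                              am_hz = 0.4, am_depth = 0.25,
                              broadband_sd = 0.8) {
  stopifnot(is.finite(duration_s), duration_s > 0,
            is.finite(rate_hz), is.finite(theta_hz),
            is.finite(av_lag_ms), is.finite(phase_shift_rad),
            rate_hz >= 4 * theta_hz, theta_hz >= 2, theta_hz <= 8)
  if (abs(phase_shift_rad) > pi) stop("|phase_shift_rad| must be <= pi")
  set.seed(as.integer(seed))
  n <- round(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  tau <- av_lag_ms / 1000

  theta <- make_theta_component(n, rate_hz, theta_hz)
  theta_ind <- make_theta_component(n, rate_hz, theta_hz)
  am_phase <- stats::runif(1, -pi, pi)
  slow <- function(tt) 1 + am_depth * cos(2 * pi * am_hz * tt + am_phase)
  lp_noise <- function(v) {
    v <- butter_filtfilt(v, rate_hz, high = min(15, rate_hz / 4), order = 4)
    broadband_sd * v / stats::sd(v)
  }
  bb_e <- if (broadband_sd > 0) lp_noise(stats::rnorm(n)) else numeric(n)
  bb_m <- if (broadband_sd > 0) lp_noise(stats::rnorm(n)) else numeric(n)
  dc <- 1.6

  env <- pmax(0, dc + slow(t) * theta() + bb_e)
  w_sh <- sqrt(mix_shared); w_in <- sqrt(1 - mix_shared)
  mot_theta <- w_sh * theta(shift_s = tau, rot_rad = phase_shift_rad) +
    w_in * theta_ind()
  mot <- pmax(0, dc + slow(t + tau) * mot_theta + bb_m)
  if (noise_sd > 0) mot <- pmax(0, mot + stats::rnorm(n, 0, noise_sd))
  list(envelope = env, motion = mot, rate_hz = rate_hz, t = t)
}

#' Generate synthetic video frames
#'
#' A bright square on a constant background.  With `square_speed_px > 0`
#' the square translates horizontally by that many pixels per frame,
#' wrapping at the frame edge; the number of changed pixels per frame pair
#' is then analytically `2 * side * min(speed, side)`.  With a
#' `luminance_series` the square stays at the frame centre and its
#' luminance follows the series (flicker encoding used by the cohort
#' generator so that extracted visual motion equals a known series).
#'
#' @param duration_s duration in seconds.
#' @param fps frames per second.
#' @param square_speed_px horizontal speed in pixels/frame.
#' @param seed RNG seed (start position when moving).
#' @param height,width frame size in pixels (>= 64).
#' @param side square side length in pixels.
#' @param background,luminance background and square grey levels (0-255).
#' @param luminance_series optional per-frame luminance for the static
#'   flickering square.
#' @return integer array [n_frames x height x width] of grey levels.
#' @export
gen_video_frames <- function(duration_s, fps, square_speed_px = 0, seed = 1,
                             height = 96, width = 96, side = 10,
                             background = 0, luminance = 100,
                             luminance_series = NULL) {
  stopifnot(fps > 0, height >= 64, width >= 64, side < width, side < height)
  set.seed(as.integer(seed))
  n_frames <- round(duration_s * fps)
  frames <- array(as.integer(background), dim = c(n_frames, height, width))
  if (!is.null(luminance_series)) {
    stopifnot(length(luminance_series) == n_frames)
    r0 <- floor((height - side) / 2); c0 <- floor((width - side) / 2)
    rows <- r0 + seq_len(side); cols <- c0 + seq_len(side)
    for (k in seq_len(n_frames))
      frames[k, rows, cols] <- as.integer(round(luminance_series[k]))
    return(frames)
  }
  r0 <- sample.int(height - side, 1)
  c0 <- sample.int(width, 1)
  rows <- r0 + seq_len(side) - 1
  for (k in seq_len(n_frames)) {
    cols <- ((c0 + (k - 1) * square_speed_px + seq_len(side) - 2) %% width) + 1
    frames[k, rows, cols] <- as.integer(luminance)
  }
  frames
}

#' Generate a synthetic gaze stream
#'
#' Piecewise-stationary gaze: the record is split evenly across the listed
#' fixation centres, with isotropic Gaussian dispersion within each
#' fixation and an instantaneous saccadic jump between consecutive
#' centres.
#'
#' @param duration_s duration in seconds.
#' @param rate_hz gaze sampling rate (default 300).
#' @param fixation_centers matrix/data.frame [k x 2] of (x, y) pixels.
#' @param noise_px within-fixation dispersion (sd, pixels).
#' @param seed RNG seed.
#' @param frame_w,frame_h frame bounds for clamping.
#' @return data.frame with columns `t` (s), `x`, `y` (pixels).
#' @export
gen_gaze_stream <- function(duration_s, rate_hz = 300, fixation_centers,
                            noise_px = 0, seed = 1,
                            frame_w = 96, frame_h = 96) {
  fixation_centers <- as.matrix(fixation_centers)
  if (nrow(fixation_centers) < 1) stop("need at least one fixation centre")
  stopifnot(rate_hz > 0, all(fixation_centers[, 1] >= 1),
            all(fixation_centers[, 1] <= frame_w),
            all(fixation_centers[, 2] >= 1),
            all(fixation_centers[, 2] <= frame_h))
  set.seed(as.integer(seed))
  n <- round(duration_s * rate_hz)
  k <- nrow(fixation_centers)
  seg <- rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]
  x <- fixation_centers[seg, 1] + stats::rnorm(n, 0, noise_px)
  y <- fixation_centers[seg, 2] + stats::rnorm(n, 0, noise_px)
  data.frame(t = (seq_len(n) - 1) / rate_hz,
             x = pmin(pmax(x, 1), frame_w),
             y = pmin(pmax(y, 1), frame_h))
}

#' Ground-truth response kernels and generative parameters
#'
#' Kernels are Gaussian bumps in lag (width `kernel_sd_ms`) centred on the
#' per-feature peak lags, with smooth scalp topographies: the envelope
#' (auditory) kernel projects to a fronto-central patch, the motion
#' (visual) kernel to an occipital patch.
#'
#' @param n_channels number of EEG channels.
#' @param a_peak_ms,v_peak_ms kernel peak lags (ms, positive = response
#'   follows stimulus).
#' @param lags_ms kernel lag grid in ms.
#' @param kernel_sd_ms Gaussian width of the kernel bump.
#' @param snr_db signal-to-noise ratio of the generated EEG in dB.
#' @param av_lag_ms stimulus-level lag (positive = motion leads).
#' @param theta_phase_shift_rad stimulus theta phase offset in (-pi, pi].
#' @param montage montage from [make_montage()]; built if NULL.
#' @param seed integer seed.
#' @return object of class `ground_truth`.
#' @export
make_ground_truth <- function(n_channels = 110, a_peak_ms = 200, v_peak_ms = 50,
                              lags_ms = seq(-300, 300, by = 10),
                              kernel_sd_ms = 35, snr_db = 0,
                              av_lag_ms = 0, theta_phase_shift_rad = pi / 2,
                              montage = NULL, seed = 1) {
  stopifnot(abs(theta_phase_shift_rad) <= pi, n_channels >= 4)
  if (is.null(montage)) montage <- make_montage(n_channels)
  pos <- montage$positions
  topo_a <- topography(pos, c(0, 0.35, 0.94), width_rad = 0.45)  # fronto-central
  topo_v <- topography(pos, c(0, -0.92, 0.39), width_rad = 0.45) # occipital
  bump <- function(peak) exp(-((lags_ms - peak)^2) / (2 * kernel_sd_ms^2))
  kernels <- array(0, dim = c(2, length(lags_ms), n_channels),
                   dimnames = list(feature = c("envelope", "motion"), NULL, NULL))
  kernels[1, , ] <- outer(bump(a_peak_ms), topo_a)
  kernels[2, , ] <- outer(bump(v_peak_ms), topo_v)
  structure(list(kernels = kernels, lags_ms = lags_ms,
                 av_lag_ms = av_lag_ms,
                 theta_phase_shift_rad = theta_phase_shift_rad,
                 snr_db = snr_db, montage = montage, seed = as.integer(seed),
                 a_peak_ms = a_peak_ms, v_peak_ms = v_peak_ms),
            class = "ground_truth")
}

#' Generate EEG from stimulus features and ground-truth kernels
#'
#' EEG is the sum over features of the kernel-convolved feature series
#' plus spatially correlated 1/f noise scaled to `truth$snr_db` (ratio of
#' mean signal power to mean noise power across channels).
#'
#' @param features list with `envelope` and `motion` numeric vectors (or a
#'   [n x 2] matrix), sampled at `rate_hz`.
#' @param truth `ground_truth` object.
#' @param n_channels number of channels (defaults to the truth montage).
#' @param seed RNG seed for the noise draw.
#' @param rate_hz sampling rate of features and EEG (default 1000).
#' @param output_gain_uv constant gain mapping model units to microvolts
#'   (default 4, landing channel RMS in the 10-25 uV range typical of
#'   scalp EEG); being constant, it preserves linearity in the kernels.
#' @return `eeg_recording` object: `data` [n_channels x n_samples] in uV,
#'   `rate_hz`, `positions`, `adjacency`, `labels`, `bad_channels`,
#'   `artifact_mask`.
#' @export
gen_eeg <- function(features, truth, n_channels = NULL, seed = 1,
                    rate_hz = 1000, output_gain_uv = 4) {
  if (is.list(features) && !is.null(features$envelope))
    F <- cbind(features$envelope, features$motion)
  else F <- as.matrix(features)
  n <- nrow(F)
  lag_samp <- round(truth$lags_ms / 1000 * rate_hz)
  if (max(abs(lag_samp)) >= n) stop("kernel lag span exceeds signal length")
  mont <- truth$montage
  if (is.null(n_channels)) n_channels <- nrow(mont$positions)
  stopifnot(n_channels == nrow(mont$positions))
  n_feat <- dim(truth$kernels)[1]
  n_lag <- dim(truth$kernels)[2]
  # lagged feature matrix, then one multiply against the unfolded kernels
  L <- matrix(0, n, n_feat * n_lag)
  col <- 1
  for (f in seq_len(n_feat)) {
    x <- F[, f] - mean(F[, f])
    for (l in seq_len(n_lag)) {
      s <- lag_samp[l]
      if (s >= 0) L[(s + 1):n, col] <- x[1:(n - s)]
      else L[1:(n + s), col] <- x[(1 - s):n]
      col <- col + 1
    }
  }
  W <- matrix(aperm(truth$kernels, c(2, 1, 3)), n_feat * n_lag, n_channels)
  sig <- L %*% W                       # samples x channels
  set.seed(as.integer(seed))
  noise <- pink_noise(n, n_channels)
  d <- mont$positions %*% t(mont$positions)
  d[] <- acos(pmin(1, pmax(-1, d)))
  S <- exp(-d^2 / (2 * 0.4^2))
  S <- S / sqrt(rowSums(S^2))
  noise <- noise %*% S
  p_sig <- mean(sig^2)
  p_noise <- mean(noise^2)
  if (is.finite(truth$snr_db)) {
    scale <- sqrt(p_sig / (p_noise * 10^(truth$snr_db / 10)))
    noise <- noise * scale
  } else noise <- noise * 0
  data <- t(sig + noise) * output_gain_uv
  structure(list(data = data, rate_hz = rate_hz,
                 positions = mont$positions, adjacency = mont$adjacency,
                 labels = mont$labels, bad_channels = integer(0),
                 artifact_mask = rep(TRUE, n)),
            class = "eeg_recording")
}

#' Cohort presets
#'
#' `preset_td()`: visual response lead (visual kernel peak 50 ms, auditory
#' 200 ms), theta phase offset pi/2, tight phase concentration (kappa = 8).
#' `preset_asd()`: auditory response lead (auditory 50 ms, visual 200 ms),
#' theta phase offset pi, broad dispersion (kappa = 1).
#'
#' @param ... overrides for any preset field.
#' @return named list of generator parameters.
#' @export
preset_td <- function(...) {
  p <- list(a_peak_ms = 200, v_peak_ms = 50,
            theta_phase_shift_rad = pi / 2, phase_kappa = 8,
            av_lag_ms = 0, snr_db = 0, theta_hz = 5,
            mix_shared = 0.6, peak_jitter_ms = 10, snr_jitter_db = 1)
  utils::modifyList(p, list(...))
}

#' @rdname preset_td
#' @export
preset_asd <- function(...) {
  p <- preset_td()
  p$a_peak_ms <- 50; p$v_peak_ms <- 200
  p$theta_phase_shift_rad <- pi
  p$phase_kappa <- 1
  utils::modifyList(p, list(...))
}

#' Generate one synthetic subject
#'
#' Draws subject-level parameters (theta phase offset from a von Mises
#' around the preset value, jittered kernel peaks and SNR), builds the
#' stimulus pair, and renders all four streams.  The video is a static
#' flickering square whose luminance steps encode the motion series, so
#' the gaze-contingent motion extractor recovers the generating series up
#' to an affine map; the audio is the envelope applied to a 440 Hz
#' carrier, so the envelope extractor recovers it near-exactly.
#'
#' @param preset parameter list from [preset_td()]/[preset_asd()].
#' @param duration_s record duration (s).
#' @param n_channels EEG channels.
#' @param seed integer seed (fully determines the subject).
#' @param group_label label stored with the subject.
#' @param streams "full" renders audio/video/gaze; "eeg_only" skips them
#'   (features are still returned) for model-level studies.
#' @param montage optional shared montage.
#' @param fps,audio_rate video frame rate and audio rate.
#' @return `synthetic_subject` list.
#' @export
gen_subject <- function(preset, duration_s = 60, n_channels = 16, seed = 1,
                        group_label = "A", streams = c("full", "eeg_only"),
                        montage = NULL, fps = 25, audio_rate = 8000) {
  streams <- match.arg(streams)
  set.seed(as.integer(seed))
  phase <- rvonmises(1, preset$theta_phase_shift_rad, preset$phase_kappa)
  a_peak <- preset$a_peak_ms + stats::runif(1, -1, 1) * preset$peak_jitter_ms
  v_peak <- preset$v_peak_ms + stats::runif(1, -1, 1) * preset$peak_jitter_ms
  snr <- preset$snr_db + stats::runif(1, -1, 1) * preset$snr_jitter_db
  if (is.null(montage)) montage <- make_montage(n_channels)

  stim <- gen_stimulus_pair(duration_s, 1000, theta_hz = preset$theta_hz,
                            av_lag_ms = preset$av_lag_ms,
                            phase_shift_rad = phase,
                            seed = child_seed(seed, 1),
                            mix_shared = preset$mix_shared)
  rate <- 1000
  n <- length(stim$envelope)

  # frame-level motion: sample at frame-interval midpoints and hold over
  # the interval (centred hold, zero mean group delay), so the generating
  # series equals what the video extractor recovers, without the T/2
  # phase lag a leading-edge hold would add
  n_frames <- round(duration_s * fps)
  mid_idx <- pmin(n, pmax(1, round((seq_len(n_frames) - 0.5) * rate / fps)))
  m_frames <- stim$motion[mid_idx]
  hold_idx <- pmin(n_frames, floor((seq_len(n) - 1) / rate * fps) + 1)
  motion_hold <- m_frames[hold_idx]

  truth <- make_ground_truth(n_channels = n_channels,
                             a_peak_ms = a_peak, v_peak_ms = v_peak,
                             snr_db = snr, av_lag_ms = preset$av_lag_ms,
                             theta_phase_shift_rad = phase,
                             montage = montage, seed = seed)
  eeg <- gen_eeg(list(envelope = stim$envelope, motion = motion_hold),
                 truth, seed = child_seed(seed, 2))

  subj <- list(features_true = list(envelope = stim$envelope,
                                    motion = motion_hold, rate_hz = rate),
               eeg = eeg, truth = truth, group_label = group_label,
               seed = as.integer(seed))
  if (streams == "full") {
    # audio: envelope on a tonal carrier
    ta <- (seq_len(round(duration_s * audio_rate)) - 1) / audio_rate
    env_a <- stats::approx(stim$t, stim$envelope, ta, rule = 2)$y
    subj$audio <- list(wave = env_a * sin(2 * pi * 440 * ta), rate_hz = audio_rate)
    # video: flicker luminance whose per-frame steps encode motion
    lum <- flicker_luminance(m_frames)
    subj$frames <- gen_video_frames(duration_s, fps, seed = child_seed(seed, 3),
                                    luminance_series = lum$luminance)
    subj$fps <- fps
    subj$motion_affine <- lum$affine
    ctr <- c(dim(subj$frames)[3] / 2, dim(subj$frames)[2] / 2)
    subj$gaze <- gen_gaze_stream(duration_s, 300, matrix(ctr, 1),
                                 noise_px = 3, seed = child_seed(seed, 4),
                                 frame_w = dim(subj$frames)[3],
                                 frame_h = dim(subj$frames)[2])
  }
  class(subj) <- "synthetic_subject"
  subj
}

# Map a nonnegative motion series onto luminance steps.  The extractor
# reports |L[k+1] - L[k]| over frame interval k, so the step INTO frame
# k encodes the motion value of interval k - 1; steps are kept within
# [15, 90] so every one clears the extractor threshold, bouncing off the
# 8-bit luminance bounds.
flicker_luminance <- function(m_frames) {
  n <- length(m_frames)
  lo <- 15; hi <- 90
  rng <- range(m_frames)
  if (diff(rng) < 1e-12) {
    a <- 0; b <- (lo + hi) / 2
  } else {
    a <- (hi - lo) / diff(rng); b <- lo - a * rng[1]
  }
  step <- round(a * c(m_frames[1], m_frames[-n]) + b)
  lum <- numeric(n)
  lum[1] <- 120
  dir <- 1
  for (k in 2:n) {
    cand <- lum[k - 1] + dir * step[k]
    if (cand > 250 || cand < 5) { dir <- -dir; cand <- lum[k - 1] + dir * step[k] }
    lum[k] <- cand
  }
  list(luminance = lum, affine = c(a = a, b = b), step = step)
}

#' Generate a two-group synthetic cohort
#'
#' Group A subjects are drawn from `preset_A` (default [preset_td()]),
#' group B from `preset_B` (default [preset_asd()]); per-subject jitter
#' (theta phase via von Mises, kernel peaks, SNR) is controlled by the
#' preset and seed.  Identical presets yield a null cohort for type-I
#' studies.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param preset_A,preset_B parameter lists.
#' @param seed integer master seed.
#' @param duration_s,n_channels,streams passed to [gen_subject()].
#' @param postprocess optional function applied to each subject right
#'   after generation (e.g. feature extraction that drops the heavy
#'   audio/video streams); its return value replaces the subject.
#' @return list of `synthetic_subject` (group A first), with the shared
#'   montage as attribute `montage`.
#' @export
gen_cohort <- function(n_per_group, preset_A = preset_td(),
                       preset_B = preset_asd(), seed = 1,
                       duration_s = 60, n_channels = 16,
                       streams = "eeg_only", postprocess = NULL) {
  stopifnot(n_per_group >= 2)
  montage <- make_montage(n_channels)
  subjects <- vector("list", 2 * n_per_group)
  gen1 <- function(preset, stream_seed, label) {
    s <- gen_subject(preset, duration_s, n_channels, seed = stream_seed,
                     group_label = label, streams = streams,
                     montage = montage)
    if (is.null(postprocess)) s else postprocess(s)
  }
  for (i in seq_len(n_per_group)) {
    subjects[[i]] <- gen1(preset_A, child_seed(seed, i), "A")
    subjects[[n_per_group + i]] <- gen1(preset_B, child_seed(seed, 1000 + i), "B")
  }
  attr(subjects, "montage") <- montage
  subjects
}
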