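#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the principal interval (-pi, pi].
#' @export
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is half-open on the left
  w[w <= -pi + 1e-15] <- pi
  w
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns the complex analytic signal whose real part is the input and
#' whose modulus is the instantaneous amplitude.
#'
#' @param x real numeric vector.
#' @return complex vector, same length as `x`.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# apply a real, even spectral gain (zero-phase by construction)
apply_spectral_gain <- function(x, gain) {
  n <- length(x)
  Re(stats::fft(stats::fft(x) * gain, inverse = TRUE)) / n
}

# Hamming window (periodic-symmetric form used for Welch averaging)
hamming_window <- function(n) 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Zero-phase Butterworth filter
#'
#' Equivalent of a forward-backward (filtfilt) pass of an
#' order-`order` Butterworth design, realized exactly in the frequency
#' domain: the spectrum is multiplied by the closed-form
#' magnitude-squared response 1/(1 + W(f)^(2 order)).  This is
#' numerically stable at arbitrarily low cutoffs (where transfer-
#' function-form IIR filtering with poles near unity is not), has a
#' perfectly symmetric impulse response, and exact stop-band behaviour.
#' Edge effects appear as circular wrap-around instead of filter
#' transients; both are confined to ~one filter time constant.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param low,high band edges in Hz; give only `high` for a low-pass,
#'   only `low` for a high-pass, both for a band-pass.
#' @param order order of the equivalent one-pass design (default 4).
#' @return filtered vector of the same length.
#' @export
butter_filtfilt <- function(x, rate_hz, low = NULL, high = NULL, order = 4) {
  n <- length(x)
  f <- (seq_len(n) - 1) * rate_hz / n
  f <- pmin(f, rate_hz - f)                     # two-sided grid
  if (!is.null(low) && !is.null(high)) {
    W <- ifelse(f > 0, (f^2 - low * high) / (f * (high - low)), Inf)
  } else if (!is.null(high)) {
    W <- f / high
  } else if (!is.null(low)) {
    W <- ifelse(f > 0, low / f, Inf)
  } else stop("give at least one band edge")
  gain <- 1 / (1 + W^(2 * order))
  gain[!is.finite(W)] <- 0
  apply_spectral_gain(x, gain)
}

#' Zero-phase IIR notch filter
#'
#' Frequency-domain application of the squared magnitude response of a
#' second-order (biquad) notch — the zero-phase equivalent of a
#' forward-backward pass.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate in Hz.
#' @param freq_hz notch centre frequency.
#' @param q quality factor (centre frequency / -3 dB bandwidth).
#' @return filtered vector.
#' @export
notch_filtfilt <- function(x, rate_hz, freq_hz, q = 30) {
  w0 <- 2 * pi * freq_hz / rate_hz
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  n <- length(x)
  w <- 2 * pi * (seq_len(n) - 1) / n
  z1 <- exp(-1i * w); z2 <- exp(-2i * w)
  H <- (b[1] + b[2] * z1 + b[3] * z2) / (a[1] + a[2] * z1 + a[3] * z2)
  apply_spectral_gain(x, Mod(H)^2)
}

#' Anti-aliased integer-factor decimation
#'
#' Zero-phase Butterworth low-pass at 0.4 of the output Nyquist followed by
#' subsampling, preserving the zero-phase contract of the rest of the
#' pipeline (a polyphase FIR resampler would introduce group delay).
#'
#' @param x numeric vector (or matrix, columns = channels).
#' @param factor integer decimation factor.
#' @param rate_hz input sampling rate.
#' @return decimated vector/matrix.
#' @export
decimate_zero_phase <- function(x, factor, rate_hz) {
  stopifnot(factor >= 1, factor == round(factor))
  if (factor == 1) return(x)
  cutoff <- 0.8 * (rate_hz / factor) / 2
  idx <- seq(1, NROW(x), by = factor)
  if (is.matrix(x)) {
    y <- apply(x, 2, butter_filtfilt, rate_hz = rate_hz, high = cutoff, order = 6)
    y[idx, , drop = FALSE]
  } else {
    butter_filtfilt(x, rate_hz, high = cutoff, order = 6)[idx]
  }
}

#' 1/f (pink) noise
#'
#' White Gaussian noise shaped in the frequency domain to a 1/f power
#' spectrum (amplitude 1/sqrt(f)), unit variance.
#'
#' @param n number of samples.
#' @param n_series number of independent series (columns).
#' @return numeric matrix [n x n_series].
#' @export
pink_noise <- function(n, n_series = 1) {
  out <- matrix(0, n, n_series)
  freqs <- c(1, seq_len(n - 1))         # avoid division by zero at DC
  shape <- 1 / sqrt(pmin(freqs, n - freqs + 1))
  shape[1] <- 0                          # remove DC
  for (j in seq_len(n_series)) {
    X <- stats::fft(stats::rnorm(n)) * shape
    v <- Re(stats::fft(X, inverse = TRUE)) / n
    out[, j] <- v / stats::sd(v)
  }
  out
}

#' Root-mean-square over a logical mask
#' @keywords internal
masked_rms <- function(x, mask = NULL) {
  if (!is.null(mask)) x <- x[mask]
  sqrt(mean(x^2))
}

#' Contiguous runs of TRUE in a logical vector
#'
#' @param mask logical vector.
#' @return data.frame with columns `start`, `end` (inclusive indices).
#' @keywords internal
true_runs <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' Pearson correlation per column between a vector and matrix (fast path)
#' @keywords internal
cor_cols <- function(y, M) {
  as.numeric(stats::cor(y, M))
}

# Derive a reproducible child seed from a base seed and a stream index,
# staying below 2^31.
child_seed <- function(seed, stream) {
  # double-precision modular arithmetic stays exact (< 2^53) and below 2^31
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12289) %% 2147483647)
}
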