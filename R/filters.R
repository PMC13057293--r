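# Butterworth IIR design and zero-phase filtering, implemented as cascaded
# second-order sections (SOS). Narrow normalized cutoffs (0.1 Hz at 256 Hz)
# make the expanded transfer-function polynomial numerically unstable, so
# everything stays factored. Verified against analytic magnitude responses
# in the test suite.

# Digital Butterworth low- or high-pass of even order n as an SOS matrix
# (one row per biquad: b0 b1 b2 a0 a1 a2, a0 = 1).
butter_sos <- function(n, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  if (fc <= 0 || fc >= fs / 2) stop("cutoff must lie in (0, fs/2)")
  if (n %% 2L != 0L) stop("even filter order required")
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))     # Re < 0
  warped <- 2 * fs * tan(pi * fc / fs)
  poles <- if (type == "low") warped * proto else warped / proto
  fs2 <- 2 * fs
  zd <- (fs2 + poles) / (fs2 - poles)
  zref <- if (type == "low") 1 + 0i else -1 + 0i
  b_sec <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
  sos <- matrix(0, n / 2, 6)
  for (j in seq_len(n / 2)) {
    pp <- zd[j]                                         # with conjugate pair
    a <- c(1, -2 * Re(pp), Mod(pp)^2)
    num <- sum(b_sec * zref^-(0:2))
    den <- sum(a * zref^-(0:2))
    sos[j, ] <- c(b_sec * abs(den / num), a)
  }
  sos
}

# |H(f)| of an SOS cascade at frequencies f (Hz)
sos_gain <- function(sos, f, fs) {
  z <- exp(-2i * pi * f / fs)
  vapply(z, function(zi) {
    g <- 1
    for (j in seq_len(nrow(sos)))
      g <- g * Mod(sum(sos[j, 1:3] * zi^(0:2)) / sum(sos[j, 4:6] * zi^(0:2)))
    g
  }, numeric(1))
}

# steady-state initial conditions for one biquad, per scipy's lfilter_zi
biquad_zi <- function(b, a) {
  # transposed companion form, as in scipy.signal.lfilter_zi
  A <- matrix(c(-a[2], -a[3], 1, 0), 2, 2)
  B <- b[2:3] - a[2:3] * b[1]
  solve(diag(2) - A, B)
}

sos_filter <- function(sos, x) {
  for (j in seq_len(nrow(sos))) {
    b <- sos[j, 1:3]; a <- sos[j, 4:6]
    x <- cpp_iir_filter(b, a, x, biquad_zi(b, a) * x[1])
  }
  x
}

# zero-phase forward-backward SOS filtering with odd-reflection padding
sos_filtfilt <- function(sos, x) {
  padlen <- 3L * (2L * nrow(sos) + 1L)
  n <- length(x)
  if (n <= padlen) stop("signal too short for filtfilt (need > ", padlen, " samples)")
  ext <- c(2 * x[1] - x[(padlen + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- sos_filter(sos, ext)
  y <- rev(sos_filter(sos, rev(y)))
  y[(padlen + 1L):(padlen + n)]
}

bandpass_vec <- function(x, low, high, fs, order = 4L) {
  x <- sos_filtfilt(butter_sos(order, low, fs, "high"), x)
  sos_filtfilt(butter_sos(order, high, fs, "low"), x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth high-pass at `low` Hz followed by a
#' 4th-order low-pass at `high` Hz, each forward-backward (zero phase, so
#' the effective magnitude response is squared). The DC component is
#' removed by the high-pass stage. Filters run as cascaded second-order
#' sections for numerical stability at the very low normalized high-pass
#' corner.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Filter order of each pass (default 4).
#' @return A filtered `eeg_recording` of identical shape.
#' @export
bandpass <- function(rec, low = 0.1, high = 70, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= rec$fs / 2) stop("high corner must be below Nyquist (", rec$fs / 2, " Hz)")
  out <- rec
  for (i in seq_len(nrow(rec$data)))
    out$data[i, ] <- bandpass_vec(rec$data[i, ], low, high, rec$fs, order)
  out
}

#' Two-pass band-pass amplitude gain
#'
#' Analytic magnitude response of the zero-phase band-pass used by
#' [bandpass()] (high-pass and low-pass each applied twice), evaluated at
#' the given frequencies.
#'
#' @param f Frequencies in Hz.
#' @inheritParams bandpass
#' @param fs Sampling rate in Hz.
#' @return Numeric gain values in `[0, 1]`.
#' @export
bandpass_gain <- function(f, low = 0.1, high = 70, fs = 256, order = 4L) {
  (sos_gain(butter_sos(order, low, fs, "high"), f, fs) *
     sos_gain(butter_sos(order, high, fs, "low"), f, fs))^2
}

#' Moving-average smoothing
#'
#' Convolves every channel with a centred uniform kernel of odd length
#' `window` (default 9 samples), using symmetric reflection padding at the
#' edges so the output has the same length as the input.
#'
#' @param rec An `eeg_recording`.
#' @param window Odd kernel length in samples.
#' @return A smoothed `eeg_recording` of identical shape.
#' @export
moving_average <- function(rec, window = 9L) {
  stopifnot(inherits(rec, "eeg_recording"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  n <- ncol(rec$data)
  if (window > n) stop("window exceeds signal length")
  w2 <- window %/% 2L
  kern <- rep(1 / window, window)
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    xp <- if (w2 > 0) c(x[w2:1], x, x[n:(n - w2 + 1L)]) else x
    y <- stats::filter(xp, kern, sides = 2)
    out$data[i, ] <- as.numeric(y[(w2 + 1L):(w2 + n)])
  }
  out
}
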