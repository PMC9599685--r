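#' Design a linear-phase FIR band-pass kernel
#'
#' Hamming-windowed FIR design (order + 1 taps) via [signal::fir1()].
#'
#' @param low,high Band edges in Hz, 0 < low < high < Nyquist.
#' @param sampling_rate Sampling rate in Hz.
#' @param order Filter order (number of taps minus one).
#' @return Numeric vector of order + 1 coefficients.
#' @export
fir_bandpass <- function(low, high, sampling_rate, order = 1000) {
  nyq <- sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  as.numeric(signal::fir1(order, c(low, high) / nyq, type = "pass"))
}

# centred same-length FIR convolution via FFT, columns = channels
fft_conv_same <- function(x, h) {
  n <- nrow(x); m <- length(h)
  nfft <- stats::nextn(n + m - 1, c(2, 3))
  hpad <- stats::fft(c(h, rep(0, nfft - m)))
  xpad <- rbind(x, matrix(0, nfft - n, ncol(x)))
  y <- Re(stats::mvfft(stats::mvfft(xpad) * hpad, inverse = TRUE)) / nfft
  off <- (m - 1) %/% 2
  y[(off + 1):(off + n), , drop = FALSE]
}

# zero-phase forward-backward application on a time x channels matrix;
# for a symmetric FIR this equals one convolution with the kernel's
# autocorrelation, which halves the FFT work
filtfilt_matrix <- function(x, h) {
  h2 <- stats::convolve(h, rev(h), type = "open")
  fft_conv_same(x, h2)
}

#' Zero-phase FIR band-pass filtering
#'
#' Applies a Hamming-window FIR band-pass of the given order twice
#' (forward and backward) so the net phase response is zero -- phase
#' distortion would bias downstream phase-synchrony estimates. The
#' per-channel mean is removed first: a 0.1 Hz edge at practical filter
#' orders leaves DC under-attenuated, so explicit demeaning is the
#' reliable way to take the offset out. Works on a continuous recording
#' (filters the whole signal) or on an epoch tensor (filters each trial).
#'
#' @param x An `eeg_recording` or `epoch_tensor`.
#' @param low,high Band edges in Hz.
#' @param order FIR order; the default 1000 gives a narrow transition at
#'   1000 Hz sampling.
#' @param band_label Optional band name attached to the result.
#' @return Object of the same class, filtered.
#' @export
bandpass_fir <- function(x, low, high, order = 1000, band_label = NULL) {
  UseMethod("bandpass_fir")
}

#' @export
bandpass_fir.eeg_recording <- function(x, low, high, order = 1000,
                                       band_label = NULL) {
  n <- ncol(x$samples)
  if (n <= 3 * order)
    stop("signal too short for order-", order, " zero-phase filtering; ",
         "need more than ", 3 * order, " samples, got ", n)
  h <- fir_bandpass(low, high, x$sampling_rate, order)
  x$samples <- t(filtfilt_matrix(scale(t(x$samples), scale = FALSE), h))
  x$band <- band_label %||% x$band
  x
}

#' @export
bandpass_fir.epoch_tensor <- function(x, low, high, order = 1000,
                                      band_label = NULL) {
  d <- dim(x)
  if (d[3] <= 3 * order)
    stop("epochs too short for order-", order, " zero-phase filtering; ",
         "need more than ", 3 * order, " samples, got ", d[3])
  h <- fir_bandpass(low, high, attr(x, "sampling_rate"), order)
  out <- x
  for (t in seq_len(d[1]))
    out[t, , ] <- t(filtfilt_matrix(scale(t(matrix(x[t, , ], d[2], d[3])),
                                          scale = FALSE), h))
  attr(out, "band") <- band_label %||% attr(x, "band")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
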