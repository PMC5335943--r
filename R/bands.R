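#' Clinical EEG frequency bands
#'
#' The four-band decomposition used by the recognition pipeline. The bands
#' tile the 0.5--30 Hz range without overlap: delta 0.5--4, theta 4--8,
#' alpha 8--13, beta 13--30 Hz.
#'
#' @return A tibble with columns `band`, `low_hz`, `high_hz`, one row per
#'   band in ascending frequency order.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    low_hz = c(0.5, 4, 8, 13),
    high_hz = c(4, 8, 13, 30)
  )
}

validate_bands <- function(bands, sampling_rate) {
  stopifnot(is.data.frame(bands), all(c("band", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz <= 0) || any(bands$high_hz >= sampling_rate / 2)) {
    stop("band edges must lie strictly inside (0, sampling_rate/2)", call. = FALSE)
  }
  if (any(bands$high_hz <= bands$low_hz)) {
    stop("each band needs low_hz < high_hz", call. = FALSE)
  }
  ord <- order(bands$low_hz)
  b <- bands[ord, ]
  if (nrow(b) > 1 && any(b$low_hz[-1] < b$high_hz[-nrow(b)])) {
    stop("bands must not overlap", call. = FALSE)
  }
  invisible(bands)
}

# squared magnitude of an analog Butterworth band-pass prototype at
# frequencies f (Hz); low/high are the -3 dB edges
butterworth_mag2 <- function(f, low, high, order) {
  w <- 2 * pi * f
  wl <- 2 * pi * low
  wh <- 2 * pi * high
  w0sq <- wl * wh
  bw <- wh - wl
  out <- numeric(length(f))
  nz <- w > 0
  s <- (w[nz]^2 - w0sq) / (bw * w[nz])
  out[nz] <- 1 / (1 + s^(2 * order))
  out
}

#' Zero-phase band-pass filter
#'
#' Filters a signal (or every column of a matrix) through a zero-phase
#' Butterworth band-pass, applied spectrally: the FFT of the reflect-padded
#' signal is multiplied by the squared Butterworth magnitude response, the
#' equivalent of a forward-backward (filtfilt) pass. The phase response is
#' exactly zero, so filtered peaks stay aligned with the input.
#'
#' @param x Numeric vector, or a samples-by-channels matrix filtered
#'   column-wise.
#' @param low_hz,high_hz Band edges in Hz (the -3 dB points of a single
#'   pass); must lie strictly inside (0, sampling_rate/2).
#' @param sampling_rate Samples per second.
#' @param order Butterworth prototype order for one pass (default 12; the
#'   zero-phase result has twice that roll-off).
#' @return Filtered object with the same shape as `x`.
#' @examples
#' fs <- 128
#' x <- sin(2 * pi * 10 * (0:511) / fs)
#' y <- bandpass_filter(x, 8, 13, fs) # alpha band keeps a 10 Hz tone
#' @export
bandpass_filter <- function(x, low_hz, high_hz, sampling_rate, order = 12) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be positive", call. = FALSE)
  }
  if (low_hz <= 0 || high_hz >= sampling_rate / 2 || high_hz <= low_hz) {
    stop("band edges must satisfy 0 < low_hz < high_hz < sampling_rate/2",
      call. = FALSE
    )
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, bandpass_vector,
      low = low_hz, high = high_hz,
      fs = sampling_rate, order = order
    )
    dimnames(out) <- dimnames(x)
    return(out)
  }
  bandpass_vector(as.numeric(x), low_hz, high_hz, sampling_rate, order)
}

bandpass_vector <- function(x, low, high, fs, order) {
  n <- length(x)
  if (n < 3) stop("signal too short to filter", call. = FALSE)
  np <- min(n - 1L, as.integer(3 * fs))
  xp <- c(
    2 * x[1] - rev(x[2:(np + 1)]),
    x,
    2 * x[n] - rev(x[(n - np):(n - 1)])
  )
  m <- length(xp)
  f <- (seq_len(m) - 1) / m * fs
  f <- pmin(f, fs - f)
  h <- butterworth_mag2(f, low, high, order)^2 # forward + backward pass
  y <- Re(stats::fft(stats::fft(xp) * h, inverse = TRUE)) / m
  y[(np + 1):(np + n)]
}
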