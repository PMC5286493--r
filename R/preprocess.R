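#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass (default 5-16 Hz, the
#' QRS energy band) forward and backward, so that the effective magnitude
#' response is the squared Butterworth response and the phase delay is
#' zero.  Zero phase matters here: any group delay would bias R-peak
#' timing.  Edge transients are controlled by even-reflection padding of
#' at least three filter lengths before filtering and trimming afterwards.
#'
#' @param x numeric signal.
#' @param fs sampling frequency in Hz.
#' @param low,high passband corner frequencies in Hz; `0 < low < high < fs/2`.
#' @param order analog prototype order of one pass (default 2).
#' @return Numeric vector the same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 5, high = 16, order = 2L) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("parameter error: band edges must satisfy 0 < low < high < fs/2")
  if (order < 1L) stop("parameter error: order must be >= 1")
  n <- length(x)
  flt <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  # even-reflection pad; >= 3 filter lengths, up to 1 s when available
  pad <- min(n - 1L, max(3L * (2L * order + 1L), as.integer(round(fs))))
  if (pad < 3L * (2L * order + 1L))
    stop("input error: signal too short for filter edge padding (need > ",
         3L * (2L * order + 1L), " samples)")
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  y <- signal::filter(flt, xp)
  y <- rev(signal::filter(flt, rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Normalize amplitude to [-1, 1]
#'
#' Divides by the maximum absolute value so the result has maximum
#' absolute amplitude exactly 1 with signs preserved.  The bound
#' `|a| <= 1` is what keeps the Shannon energy `-a^2 log(a^2)`
#' nonnegative downstream.
#'
#' @param f numeric signal with at least one nonzero sample.
#' @return Numeric vector `f / max(abs(f))`.
#' @export
normalize_amplitude <- function(f) {
  if (!is.numeric(f) || length(f) == 0L) stop("`f` must be non-empty numeric")
  m <- max(abs(f))
  if (m == 0)
    stop("degenerate input: signal is identically zero, cannot normalize")
  f / m
}
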