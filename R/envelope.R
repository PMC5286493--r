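#' Causal rectangular moving average
#'
#' FIR filtering with a length-`L` rectangular kernel and gain divisor
#' `L` (unity DC gain).  The startup region uses zero-prefilled state:
#' `y[n] = sum(x[max(1, n-L+1) : n]) / L`, i.e. missing history counts
#' as zero.  One pass delays the signal by `(L-1)/2` samples.
#'
#' @param x numeric vector.
#' @param L window length in samples (>= 1).
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, L) {
  if (!is.numeric(x) || length(x) < 1L) stop("`x` must be non-empty numeric")
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("parameter error: L must be >= 1")
  if (L == 1L) return(as.numeric(x))
  n <- length(x)
  y <- stats::filter(c(numeric(L - 1L), x), rep(1 / L, L), sides = 1L)
  as.numeric(y[L:(L + n - 1L)])
}

#' First difference
#'
#' `d[k] = x[k+1] - x[k]`; output one sample shorter than the input.
#'
#' @param x numeric vector of length >= 2.
#' @return Numeric vector of length `length(x) - 1`.
#' @export
difference <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stop("input error: need at least 2 samples to difference")
  diff(x)
}

#' Sign of a real number
#'
#' Returns -1, 0 or 1.  Vectorized; rejects non-finite input.
#'
#' @param x numeric vector of finite values.
#' @return Integer vector in \{-1, 0, 1\}.
#' @export
sign_of <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric")
  as.integer(sign(x))
}

#' Build the Shannon energy envelope
#'
#' Stage 3 of the detector: the standardized Shannon energy is smoothed
#' with two cascaded length-`L` moving averages (a boxcar cascade, i.e.
#' an effective triangular kernel of support `2L - 1`), merging the
#' intra-QRS energy spikes into one lobe per beat.  Each causal pass
#' delays the signal by `(L-1)/2` samples; the cascade's total group
#' delay of `L - 1` samples is removed by shifting the smoothed signal
#' left `L - 1` samples and zero-padding the tail, so envelope lobes
#' stay aligned with the QRS complexes they summarize.
#'
#' The signal is extended by even reflection at both ends before the
#' cascade and trimmed afterwards, so the envelope has no startup ramp
#' or tail cliff: a constant input yields an exactly flat envelope and
#' edge beats are smoothed symmetrically like interior ones.
#'
#' @param s_std standardized Shannon energy (numeric vector).
#' @param L smoothing window in samples; the signal must be at least
#'   `2 * L` samples long.
#' @param fs sampling frequency in Hz (carried for downstream use).
#' @return An object of class `see_envelope` with fields `m` (first
#'   pass), `m2` (second pass, delay-compensated), `d` (first difference
#'   of `m2`), `L` and `fs`.
#' @export
build_envelope <- function(s_std, L, fs = NA_real_) {
  L <- as.integer(L)
  if (is.na(L) || L < 1L) stop("parameter error: L must be >= 1")
  n <- length(s_std)
  if (n < 2L * L)
    stop("input error: signal shorter than 2*L (", n, " < ", 2L * L, ")")
  pad <- min(2L * L, n - 1L)
  xp <- if (pad > 0L)
    c(s_std[(pad + 1L):2L], s_std, s_std[(n - 1L):(n - pad)])
  else s_std
  mp <- moving_average(xp, L)
  m2p <- moving_average(mp, L)
  # remove the cascade's group delay of L-1 samples (two causal passes)
  idx <- (pad + 1L):(pad + n)
  m <- mp[idx]
  m2 <- m2p[idx + (L - 1L)]
  structure(list(m = m, m2 = m2, d = difference(m2), L = L, fs = fs),
            class = "see_envelope")
}

#' @export
print.see_envelope <- function(x, ...) {
  cat(sprintf("<see_envelope> %d samples, L = %d%s\n", length(x$m2), x$L,
              if (is.na(x$fs)) "" else sprintf(" (%.0f ms @ %g Hz)",
                                               1000 * x$L / x$fs, x$fs)))
  invisible(x)
}

#' Find candidate peaks of an envelope
#'
#' A candidate is a rising-to-falling transition of the envelope: index
#' `k` with `sign(d[k-1]) == +1` and `sign(d[k]) <= 0`.  This selects
#' strict local maxima, with flat-topped maxima resolved to the leftmost
#' sample of the plateau (a deterministic tie-break).
#'
#' @param env a `see_envelope` from [build_envelope], or a plain numeric
#'   vector treated as the envelope itself.
#' @return An object of class `candidate_peaks` with strictly increasing
#'   `indices` (1-based) and the envelope `heights` at those indices.
#' @export
find_candidates <- function(env) {
  if (inherits(env, "see_envelope")) {
    m2 <- env$m2
    d <- env$d
  } else if (is.numeric(env) && length(env) >= 2L) {
    m2 <- env
    d <- difference(env)
  } else {
    stop("`env` must be a see_envelope or a numeric vector of length >= 2")
  }
  nd <- length(d)
  k <- if (nd >= 2L) which(d[-nd] > 0 & d[-1L] <= 0) + 1L else integer(0)
  candidate_peaks(k, m2[k])
}

#' @rdname find_candidates
#' @param indices strictly increasing integer positions.
#' @param heights envelope values at `indices`.
#' @export
candidate_peaks <- function(indices, heights) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L))
    stop("`indices` must be strictly increasing")
  if (length(indices) != length(heights))
    stop("`indices` and `heights` must have equal length")
  structure(list(indices = indices, heights = as.numeric(heights)),
            class = "candidate_peaks")
}

#' @export
print.candidate_peaks <- function(x, ...) {
  cat(sprintf("<candidate_peaks> %d candidate(s)\n", length(x$indices)))
  invisible(x)
}
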