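# Fixture writers and independent brute-force oracles used across the suite.

# Write a WFDB header/signal pair (format 16, single .dat) for testing.
write_wfdb_fixture <- function(dir, record_id, leads, fs, gain = 2000,
                               baseline = 0, truncate_bytes = NULL) {
  n <- length(leads[[1L]])
  hea <- file.path(dir, paste0(record_id, ".hea"))
  dat <- paste0(record_id, ".dat")
  lines <- sprintf("%s %d %g %d", record_id, length(leads), fs, n)
  for (nm in names(leads))
    lines <- c(lines, sprintf("%s 16 %g(%d)/mV 16 0 0 0 0 %s",
                              dat, gain, baseline, nm))
  writeLines(lines, hea)
  adc <- as.integer(round(do.call(rbind, lapply(leads, function(x)
    x * gain + baseline))))
  con <- file(file.path(dir, dat), "wb")
  writeBin(adc, con, size = 2L, endian = "little")
  close(con)
  if (!is.null(truncate_bytes)) {
    sz <- file.size(file.path(dir, dat))
    con <- file(file.path(dir, dat), "r+b")
    truncate(con, sz - truncate_bytes)
    close(con)
  }
  hea
}

# Brute-force causal windowed mean with zero-prefilled history.
brute_moving_average <- function(x, L) {
  vapply(seq_along(x), function(n)
    sum(x[max(1L, n - L + 1L):n]) / L, numeric(1))
}

# Exhaustive local-maximum scan (for tie-free signals):
# x[k] > x[k-1] and x[k] > x[k+1].
brute_local_maxima <- function(x) {
  n <- length(x)
  which(vapply(2:(n - 1L), function(i)
    x[i] > x[i - 1L] && x[i] > x[i + 1L], logical(1))) + 1L
}

# Brute-force optimal one-to-one matching: maximum number of (ref, det)
# pairs with |ref - det| <= tol.  Exponential search; use only for n <= 10.
brute_optimal_tp <- function(refs, dets, tol) {
  nr <- length(refs)
  nd <- length(dets)
  if (nr == 0L || nd == 0L) return(0L)
  rec <- function(i, used) {
    if (i > nr) return(0L)
    best <- rec(i + 1L, used)  # leave ref i unmatched
    for (j in seq_len(nd)) {
      if (!used[j] && abs(refs[i] - dets[j]) <= tol) {
        used2 <- used
        used2[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used2))
      }
    }
    best
  }
  rec(1L, logical(nd))
}

# Analytic squared-magnitude response of a digital Butterworth band-pass
# (bilinear transform with frequency pre-warping), squared once more for
# the forward-backward (zero-phase) pass.
analytic_zero_phase_gain <- function(f, fs, low, high, order) {
  w <- tan(pi * f / fs)
  wl <- tan(pi * low / fs)
  wh <- tan(pi * high / fs)
  h2 <- 1 / (1 + ((w^2 - wl * wh) / ((wh - wl) * w))^(2 * order))
  h2  # amplitude gain of one pass squared = |H|^2; zero-phase applies |H|^2
}

rms <- function(x) sqrt(mean(x^2))

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))
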