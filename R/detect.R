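#' Detector configuration
#'
#' Every free constant of the detection pipeline in one place.  Defaults
#' give the standard QRS configuration for adult ECG at any sampling
#' rate:
#'
#' * `band_low`, `band_high`: 5-16 Hz passband concentrating QRS energy
#'   while suppressing baseline wander, P/T waves and line/muscle noise.
#' * `filter_order`: analog prototype order of one Butterworth pass
#'   (applied forward-backward, so the magnitude response is squared).
#' * `envelope_window_s`: moving-average window (seconds); 100 ms spans
#'   a full QRS so its energy spikes merge into one lobe while adjacent
#'   beats (>= 250 ms apart) stay separate.
#' * `kappa`: threshold scale constant of the adaptive rule
#'   `kappa * mu * (1 - sigma^2)` / `kappa * sigma * (1 - mu^2)`.
#' * `refractory_s`: minimum spacing between accepted beats (200 ms,
#'   i.e. a 300 bpm ceiling).
#' * `search_window_s`: half-width of the window around an envelope peak
#'   searched for the filtered-signal extremum (R localization).
#' * `match_tolerance_s`: evaluation matching window (ANSI/AAMI
#'   convention, 150 ms).
#' * `log_base`: base of the Shannon energy logarithm.
#'
#' @param band_low,band_high passband corners in Hz.
#' @param filter_order Butterworth order (one pass).
#' @param envelope_window_s smoothing window in seconds.
#' @param kappa threshold constant (> 0).
#' @param refractory_s refractory period in seconds.
#' @param search_window_s localization half-window in seconds.
#' @param match_tolerance_s beat-matching tolerance in seconds.
#' @param log_base `"natural"`, `"log2"` or `"log10"`.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(band_low = 5, band_high = 16, filter_order = 2L,
                            envelope_window_s = 0.10, kappa = 0.5,
                            refractory_s = 0.200, search_window_s = 0.100,
                            match_tolerance_s = 0.150,
                            log_base = c("natural", "log2", "log10")) {
  log_base <- match.arg(log_base)
  num <- c(band_low = band_low, band_high = band_high,
           filter_order = filter_order, envelope_window_s = envelope_window_s,
           kappa = kappa, refractory_s = refractory_s,
           search_window_s = search_window_s,
           match_tolerance_s = match_tolerance_s)
  if (any(!is.finite(num)) || any(num[setdiff(names(num), "search_window_s")] <= 0) ||
      search_window_s < 0)
    stop("parameter error: all configuration values must be positive ",
         "(search_window_s may be 0)")
  if (band_low >= band_high)
    stop("parameter error: band_low must be less than band_high")
  structure(list(band_low = band_low, band_high = band_high,
                 filter_order = as.integer(filter_order),
                 envelope_window_s = envelope_window_s, kappa = kappa,
                 refractory_s = refractory_s,
                 search_window_s = search_window_s,
                 match_tolerance_s = match_tolerance_s,
                 log_base = log_base),
            class = "detector_config")
}

#' @export
print.detector_config <- function(x, ...) {
  cat("<detector_config>\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' QRS detections for one lead
#'
#' @param record_id,lead_name identifiers.
#' @param r_samples strictly increasing 1-based sample indices of
#'   detected R-peaks.
#' @param envelope_heights envelope value of the accepted candidate that
#'   produced each detection.
#' @param fs sampling frequency in Hz.
#' @return An object of class `qrs_detections`.
#' @export
qrs_detections <- function(record_id, lead_name, r_samples,
                           envelope_heights = rep(NA_real_, length(r_samples)),
                           fs = NA_real_) {
  r_samples <- as.integer(r_samples)
  if (length(r_samples) > 1L && any(diff(r_samples) <= 0L))
    stop("`r_samples` must be strictly increasing")
  structure(list(record_id = as.character(record_id),
                 lead_name = as.character(lead_name),
                 r_samples = r_samples,
                 envelope_heights = as.numeric(envelope_heights),
                 fs = as.numeric(fs)),
            class = "qrs_detections")
}

#' @export
print.qrs_detections <- function(x, ...) {
  cat(sprintf("<qrs_detections> %s/%s: %d beat(s) @ %g Hz\n",
              x$record_id, x$lead_name, length(x$r_samples), x$fs))
  invisible(x)
}

#' Adaptive envelope threshold
#'
#' With `mu` and `sigma` the mean and population standard deviation of
#' the envelope, the threshold is `kappa * mu * (1 - sigma^2)` when
#' `sigma < mu` and `kappa * sigma * (1 - mu^2)` otherwise.  At
#' `sigma == mu` both branches coincide (`kappa * mu * (1 - mu^2)`), so
#' the tie is well-defined.
#'
#' @param env_values numeric envelope values (nonempty).
#' @param kappa threshold constant.
#' @return Scalar threshold.
#' @export
compute_threshold <- function(env_values, kappa) {
  if (!is.numeric(env_values) || length(env_values) == 0L)
    stop("input error: env_values must be non-empty numeric")
  mu <- mean(env_values)
  sigma <- pop_sd(env_values)
  if (sigma < mu) kappa * mu * (1 - sigma^2) else kappa * sigma * (1 - mu^2)
}

#' Keep candidates above a threshold
#'
#' Retains candidates whose envelope height is strictly greater than
#' `thr`, preserving order.
#'
#' @param cands a [candidate_peaks] object.
#' @param thr finite scalar threshold (or `-Inf` for the identity).
#' @return A [candidate_peaks] object.
#' @export
apply_threshold <- function(cands, thr) {
  stopifnot(inherits(cands, "candidate_peaks"))
  keep <- cands$heights > thr
  candidate_peaks(cands$indices[keep], cands$heights[keep])
}

#' Enforce a refractory period between candidates
#'
#' Greedy left-to-right scan: when the next candidate falls closer than
#' `refractory` samples to the last accepted one, the taller of the two
#' survives (ties keep the earlier).  The result is strictly separated
#' by at least `refractory` samples, suppressing double detections of a
#' single beat.
#'
#' @param cands a [candidate_peaks] object (sorted).
#' @param refractory minimum spacing in samples.
#' @return A [candidate_peaks] object.
#' @export
enforce_refractory <- function(cands, refractory) {
  stopifnot(inherits(cands, "candidate_peaks"))
  n <- length(cands$indices)
  if (n <= 1L) return(cands)
  keep_idx <- integer(0)
  keep_h <- numeric(0)
  for (k in seq_len(n)) {
    i <- cands$indices[[k]]
    h <- cands$heights[[k]]
    if (length(keep_idx) && i - keep_idx[length(keep_idx)] < refractory) {
      if (h > keep_h[length(keep_h)]) {        # taller wins; tie keeps earlier
        keep_idx[length(keep_idx)] <- i
        keep_h[length(keep_h)] <- h
      }
    } else {
      keep_idx <- c(keep_idx, i)
      keep_h <- c(keep_h, h)
    }
  }
  candidate_peaks(keep_idx, keep_h)
}

#' Localize R-peaks in the filtered signal
#'
#' Refines each accepted envelope peak to the position of maximum
#' absolute filtered amplitude within `+/- window` samples.  Using
#' `abs(f)` makes negative-polarity QRS complexes localize the same way
#' as positive ones.  Ties resolve to the leftmost sample; refined
#' indices are re-sorted and deduplicated (keeping the first occurrence).
#'
#' @param cands accepted [candidate_peaks].
#' @param f band-pass filtered signal (numeric vector).
#' @param window half-window in samples (>= 0; 0 is the identity).
#' @param record_id,lead_name,fs metadata for the returned object.
#' @return A [qrs_detections] object.
#' @export
localize_r_peaks <- function(cands, f, window, record_id = "record",
                             lead_name = "i", fs = NA_real_) {
  stopifnot(inherits(cands, "candidate_peaks"))
  window <- as.integer(window)
  if (is.na(window) || window < 0L) stop("parameter error: window must be >= 0")
  n <- length(f)
  refined <- vapply(cands$indices, function(i) {
    lo <- max(1L, i - window)
    hi <- min(n, i + window)
    lo + which.max(abs(f[lo:hi])) - 1L
  }, integer(1))
  ord <- order(refined)
  refined <- refined[ord]
  h <- cands$heights[ord]
  dup <- duplicated(refined)
  qrs_detections(record_id, lead_name, refined[!dup], h[!dup], fs)
}

#' Detect QRS complexes in one lead
#'
#' Runs the full four-stage pipeline on a single lead:
#' band-pass filter and amplitude normalization; per-sample Shannon
#' energy and z-standardization; cascaded moving-average envelope with
#' group-delay compensation and candidate peak picking; adaptive
#' thresholding (one global threshold per lead, computed over the
#' smoothed envelope), refractory enforcement, and R-peak localization
#' in the filtered signal.
#'
#' @param rec an [ecg_record].
#' @param lead lead name (default: first lead).
#' @param cfg a [detector_config].
#' @param keep_stages if `TRUE`, attach the intermediate signals
#'   (`f`, `a`, `s`, `s_std`, `m2`) as attribute `"stages"` for
#'   inspection or stage dumps.
#' @return A [qrs_detections] object.
#' @export
detect_qrs <- function(rec, lead = rec$lead_names[[1L]],
                       cfg = detector_config(), keep_stages = FALSE) {
  stopifnot(inherits(rec, "ecg_record"), inherits(cfg, "detector_config"))
  if (!lead %in% rec$lead_names) stop("lead not present in record: ", lead)
  x <- rec$samples[[lead]]
  if (all(x == 0))
    stop("degenerate input: lead ", lead, " is flat (all zero)")
  fs <- rec$fs
  L <- max(1L, as.integer(round(cfg$envelope_window_s * fs)))
  if (rec$n_samples <= 2L * L)
    stop("input error: record shorter than twice the envelope window")

  f <- bandpass_filter(x, fs, cfg$band_low, cfg$band_high, cfg$filter_order)
  if (all(f == 0))
    stop("degenerate input: filtered lead ", lead, " is identically zero")
  a <- normalize_amplitude(f)
  s <- shannon_energy(a, cfg$log_base)
  s_std <- standardize(s)
  env <- build_envelope(s_std, L, fs)
  cands <- find_candidates(env)
  thr <- compute_threshold(env$m2, cfg$kappa)
  cands <- apply_threshold(cands, thr)
  cands <- enforce_refractory(cands, round(cfg$refractory_s * fs))
  dets <- localize_r_peaks(cands, f, round(cfg$search_window_s * fs),
                           record_id = rec$record_id, lead_name = lead,
                           fs = fs)
  if (keep_stages)
    attr(dets, "stages") <- list(f = f, a = a, s = s, s_std = s_std,
                                 m2 = env$m2, threshold = thr)
  dets
}
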