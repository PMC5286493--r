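#' Default P-QRS-T wave parameters
#'
#' One Gaussian bump per wave, summed per beat.  `offset` is the bump
#' center relative to the R-peak (seconds), `width` its full width at
#' half maximum (seconds), `amplitude` in mV.  These are textbook adult
#' resting-ECG proportions: sharp Q/R/S deflections (25 ms FWHM each)
#' and smooth, low-frequency P and T waves.  The T width of 140 ms FWHM
#' (about 200 ms at the base) matters: a much sharper T would carry
#' QRS-like energy into the 5-16 Hz band and stop being a T wave
#' spectrally.  All parameters can be overridden through [synth_config].
#'
#' @return A data.frame with columns `wave, amplitude, offset, width`.
#' @export
default_wave_params <- function() {
  data.frame(
    wave      = c("P",   "Q",     "R",   "S",    "T"),
    amplitude = c(0.15,  -0.10,   1.00,  -0.20,  0.30),
    offset    = c(-0.200, -0.025, 0.000, 0.025,  0.200),
    width     = c(0.060,  0.025,  0.025, 0.025,  0.140),
    stringsAsFactors = FALSE)
}

#' Synthetic-ECG configuration
#'
#' Parameters of the seeded generator: beat morphology (Gaussian P, Q,
#' R, S, T bumps), rhythm (mean heart rate with fractional RR jitter,
#' truncated so RR >= 0.25 s), and the four additive noise classes seen
#' in practice: baseline wander (slow sinusoid), powerline interference
#' (48-60 Hz sinusoid), muscle noise (white noise band-limited to
#' 38-45 Hz) and broadband white noise.  Noise amplitudes are standard
#' deviations/amplitudes in mV; set to 0 to disable a class.
#'
#' @param fs sampling frequency in Hz.
#' @param duration_s record length in seconds.
#' @param heart_rate_bpm mean heart rate.
#' @param rr_jitter_frac fractional standard deviation of RR intervals.
#' @param wave_params data.frame as in [default_wave_params].
#' @param t_over_r_ratio if not `NULL`, the T amplitude is set to this
#'   fraction of the R amplitude (tall-T scenarios).
#' @param qrs_polarity `+1` or `-1`; `-1` flips the Q, R and S bumps
#'   while leaving P and T unchanged.
#' @param baseline_amp,baseline_freq baseline-wander sinusoid (mV, Hz).
#' @param line_amp,line_freq powerline sinusoid (mV, Hz in 48-60).
#' @param muscle_amp standard deviation of 38-45 Hz band-limited noise (mV).
#' @param white_noise_sd standard deviation of white noise (mV).
#' @param seed integer seed; a fixed seed reproduces the record
#'   bit-for-bit.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(fs = 1000, duration_s = 60, heart_rate_bpm = 60,
                         rr_jitter_frac = 0.02,
                         wave_params = default_wave_params(),
                         t_over_r_ratio = NULL, qrs_polarity = 1,
                         baseline_amp = 0, baseline_freq = 0.3,
                         line_amp = 0, line_freq = 50,
                         muscle_amp = 0, white_noise_sd = 0,
                         seed = 1L) {
  if (fs <= 0 || duration_s <= 0 || heart_rate_bpm <= 0)
    stop("parameter error: fs, duration_s and heart_rate_bpm must be positive")
  if (rr_jitter_frac < 0 || any(wave_params$width <= 0))
    stop("parameter error: jitter must be >= 0 and wave widths positive")
  if (!qrs_polarity %in% c(-1, 1))
    stop("parameter error: qrs_polarity must be +1 or -1")
  if (!is.null(t_over_r_ratio) && t_over_r_ratio <= 0)
    stop("parameter error: t_over_r_ratio must be positive")
  if (line_freq < 48 || line_freq > 60)
    stop("parameter error: line_freq must lie in 48-60 Hz")
  structure(list(fs = fs, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_frac = rr_jitter_frac,
                 wave_params = wave_params,
                 t_over_r_ratio = t_over_r_ratio,
                 qrs_polarity = qrs_polarity,
                 baseline_amp = baseline_amp, baseline_freq = baseline_freq,
                 line_amp = line_amp, line_freq = line_freq,
                 muscle_amp = muscle_amp, white_noise_sd = white_noise_sd,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# run expr with the RNG seeded from `seed`, restoring global RNG state after
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic single-lead ECG record
#'
#' Clean signal: for each beat, the sum of five Gaussian bumps (P, Q,
#' R, S, T) at configured offsets from the R center.  R centers are
#' placed at RR intervals drawn from
#' `Normal(60/heart_rate_bpm, rr_jitter_frac * 60/heart_rate_bpm)`,
#' truncated at 0.25 s; the first beat sits half a mean RR into the
#' record.  Configured noise classes are added on top.  Ground-truth
#' annotations are the exact R-center sample indices.
#'
#' @param cfg a [synth_config].
#' @param record_id identifier for the generated record.
#' @param lead_name label of the single generated lead.
#' @return A list with elements `record` ([ecg_record]) and
#'   `annotations` ([beat_annotations]); attribute `"clean"` holds the
#'   noise-free signal for component-wise inspection.
#' @export
generate_record <- function(cfg, record_id = "synthetic", lead_name = "ii") {
  stopifnot(inherits(cfg, "synth_config"))
  with_local_seed(cfg$seed, {
    fs <- cfg$fs
    n <- as.integer(round(cfg$duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    rr_mean <- 60 / cfg$heart_rate_bpm

    # rhythm: R centers at jittered RR intervals
    centers <- numeric(0)
    tc <- 0.5 * rr_mean
    while (tc < cfg$duration_s) {
      centers <- c(centers, tc)
      rr <- stats::rnorm(1L, rr_mean, cfg$rr_jitter_frac * rr_mean)
      tc <- tc + max(rr, 0.25)
    }

    wp <- cfg$wave_params
    if (!is.null(cfg$t_over_r_ratio))
      wp$amplitude[wp$wave == "T"] <-
        cfg$t_over_r_ratio * wp$amplitude[wp$wave == "R"]
    if (cfg$qrs_polarity < 0)
      wp$amplitude[wp$wave %in% c("Q", "R", "S")] <-
        -wp$amplitude[wp$wave %in% c("Q", "R", "S")]

    clean <- numeric(n)
    for (w in seq_len(nrow(wp))) {
      sigma <- wp$width[w] / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian sd
      half <- 4 * sigma
      for (tc in centers) {
        c0 <- tc + wp$offset[w]
        i0 <- max(1L, as.integer(floor((c0 - half) * fs)) + 1L)
        i1 <- min(n, as.integer(floor((c0 + half) * fs)) + 1L)
        if (i0 > i1) next
        tt <- t[i0:i1]
        clean[i0:i1] <- clean[i0:i1] +
          wp$amplitude[w] * exp(-(tt - c0)^2 / (2 * sigma^2))
      }
    }

    x <- clean
    if (cfg$baseline_amp > 0)
      x <- x + cfg$baseline_amp *
        sin(2 * pi * cfg$baseline_freq * t + stats::runif(1L, 0, 2 * pi))
    if (cfg$line_amp > 0)
      x <- x + cfg$line_amp *
        sin(2 * pi * cfg$line_freq * t + stats::runif(1L, 0, 2 * pi))
    if (cfg$muscle_amp > 0) {
      w <- stats::rnorm(n)
      w <- bandpass_filter(w, fs, 38, 45, order = 2L)
      x <- x + cfg$muscle_amp * w / stats::sd(w)
    }
    if (cfg$white_noise_sd > 0)
      x <- x + stats::rnorm(n, 0, cfg$white_noise_sd)

    samples <- list(x)
    names(samples) <- lead_name
    rec <- ecg_record(record_id, fs, samples)
    ann <- beat_annotations(record_id, lead_name,
                            floor(centers * fs) + 1L, fs)
    out <- list(record = rec, annotations = ann)
    attr(out, "clean") <- clean
    out
  })
}

#' Named synthetic scenario configuration
#'
#' The fixed test-bed scenarios, each a [synth_config] at 60 bpm:
#' `clean` (no noise), `baseline-drift` (0.2 mV at 0.3 Hz),
#' `line-noise` (0.05 mV at 50 Hz), `muscle-noise` (0.05 mV in
#' 38-45 Hz), `tall-T` (T amplitude 0.8 x R), `negative-QRS`,
#' `irregular-RR` (RR jitter 0.15), and `low-SNR` (all noise classes
#' plus 0.05 mV white noise at once).
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param duration_s record length in seconds (default 60).
#' @return A [synth_config].
#' @export
scenario_config <- function(name, seed = 1L, duration_s = 60) {
  base <- list(fs = 1000, duration_s = duration_s, heart_rate_bpm = 60,
               seed = seed)
  extra <- switch(name,
    "clean"          = list(),
    "baseline-drift" = list(baseline_amp = 0.2, baseline_freq = 0.3),
    "line-noise"     = list(line_amp = 0.05, line_freq = 50),
    "muscle-noise"   = list(muscle_amp = 0.05),
    "tall-T"         = list(t_over_r_ratio = 0.8),
    "negative-QRS"   = list(qrs_polarity = -1),
    "irregular-RR"   = list(rr_jitter_frac = 0.15),
    "low-SNR"        = list(baseline_amp = 0.2, baseline_freq = 0.3,
                            line_amp = 0.05, line_freq = 50,
                            muscle_amp = 0.05, white_noise_sd = 0.05),
    stop("usage error: unknown scenario: ", name))
  do.call(synth_config, c(base, extra))
}

#' Names of the bundled scenarios
#' @return Character vector of scenario names.
#' @export
scenario_names <- function() {
  c("clean", "baseline-drift", "line-noise", "muscle-noise", "tall-T",
    "negative-QRS", "irregular-RR", "low-SNR")
}

#' Generate the full scenario suite
#'
#' Generates all eight named scenarios (60 s each), with per-scenario
#' seeds derived deterministically from the suite seed, so the whole
#' corpus reproduces from one integer.
#'
#' @param seed suite seed.
#' @param duration_s per-scenario duration (default 60 s).
#' @return A named list; each element has `record`, `annotations` and
#'   `scenario`.
#' @export
scenario_suite <- function(seed = 1L, duration_s = 60) {
  nms <- scenario_names()
  out <- vector("list", length(nms))
  names(out) <- nms
  for (k in seq_along(nms)) {
    sub_seed <- (as.integer(seed) * 97L + k) %% 2147483647L
    g <- generate_record(scenario_config(nms[k], sub_seed, duration_s),
                         record_id = nms[k])
    g$scenario <- nms[k]
    out[[k]] <- g
  }
  out
}
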