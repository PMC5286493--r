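#' Construct an ECG record
#'
#' An `ecg_record` holds one or more simultaneously sampled leads at a common
#' sampling frequency, with amplitudes in millivolts.  Sample indices are
#' 1-based throughout the package, both in memory and in annotation files;
#' time `t` (seconds) maps to index `floor(t * fs) + 1` and segments are
#' half-open.
#'
#' @param record_id character scalar identifying the record.
#' @param fs sampling frequency in Hz (> 0).
#' @param samples named list of numeric vectors, one per lead, all the same
#'   length; names are the lead labels and must be unique.
#' @return An object of class `ecg_record` with fields `record_id`, `fs`,
#'   `lead_names`, `samples` and `n_samples`.
#' @export
ecg_record <- function(record_id, fs, samples) {
  if (!is.list(samples) || length(samples) == 0L)
    stop("`samples` must be a non-empty named list of numeric vectors")
  lead_names <- names(samples)
  if (is.null(lead_names) || any(!nzchar(lead_names)))
    stop("every lead in `samples` must be named")
  if (anyDuplicated(lead_names))
    stop("lead names must be unique within a record")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  lens <- lengths(samples)
  if (length(unique(lens)) != 1L)
    stop("all leads must have the same number of samples")
  if (lens[[1L]] < 1L)
    stop("record must contain at least one sample")
  structure(
    list(record_id = as.character(record_id), fs = as.numeric(fs),
         lead_names = lead_names,
         samples = lapply(samples, as.numeric),
         n_samples = as.integer(lens[[1L]])),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d lead(s), %d samples @ %g Hz (%.1f s)\n",
              x$record_id, length(x$lead_names), x$n_samples, x$fs,
              x$n_samples / x$fs))
  cat("  leads:", paste(x$lead_names, collapse = ", "), "\n")
  invisible(x)
}

#' Construct beat annotations
#'
#' Reference R-peak locations for one lead of one record, as strictly
#' increasing 1-based sample indices.
#'
#' @param record_id,lead_name character identifiers.
#' @param r_samples strictly increasing integer sample indices (1-based).
#' @param fs sampling frequency in Hz.
#' @return An object of class `beat_annotations`.
#' @export
beat_annotations <- function(record_id, lead_name, r_samples, fs) {
  r_samples <- as.integer(round(r_samples))
  if (length(r_samples) > 1L && any(diff(r_samples) <= 0L))
    stop("`r_samples` must be strictly increasing")
  if (length(r_samples) && any(r_samples < 1L))
    stop("`r_samples` must be positive (1-based) indices")
  structure(
    list(record_id = as.character(record_id),
         lead_name = as.character(lead_name),
         r_samples = r_samples, fs = as.numeric(fs)),
    class = "beat_annotations")
}

#' Read a WFDB record (header + signal file)
#'
#' Minimal reader for the PhysioNet WFDB format as used by 1 kHz
#' diagnostic ECG databases: a text header (`.hea`) describing the signals
#' and a binary signal file in format 16 (16-bit little-endian two's
#' complement, samples interleaved across channels).  ADC units are
#' converted to physical millivolts as `(adc - baseline) / gain`.
#'
#' All channels present in the header are returned, including Frank leads
#' if recorded.
#'
#' @param header_path path to the `.hea` header file.
#' @return An [ecg_record] with one element of `samples` per channel.
#' @export
read_wfdb_record <- function(header_path) {
  if (!file.exists(header_path))
    stop("input error: header file not found: ", header_path)
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("format error: header has no signal specification lines: ",
         header_path)
  rec_line <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec_line) < 3L)
    stop("format error: malformed record line in ", header_path)
  record_id <- sub("/.*$", "", rec_line[[1L]])
  n_sig <- as.integer(rec_line[[2L]])
  fs <- as.numeric(sub("/.*$", "", rec_line[[3L]]))  # strip counter freq
  n_samp <- if (length(rec_line) >= 4L) as.integer(rec_line[[4L]]) else NA_integer_
  if (is.na(n_sig) || n_sig < 1L)
    stop("format error: invalid signal count in ", header_path)
  if (is.na(fs) || fs <= 0) fs <- 250  # WFDB default sampling frequency

  sig_lines <- lines[2:(1L + n_sig)]
  spec <- lapply(sig_lines, parse_wfdb_signal_line)
  dat_files <- vapply(spec, `[[`, "", "file")
  if (length(unique(dat_files)) != 1L)
    stop("format error: multi-file records are not supported (",
         header_path, ")")
  fmt <- vapply(spec, `[[`, 0, "format")
  if (any(fmt != 16))
    stop("format error: only WFDB signal format 16 is supported, got ",
         paste(unique(fmt), collapse = ", "))

  dat_path <- file.path(dirname(header_path), dat_files[[1L]])
  if (!file.exists(dat_path))
    stop("input error: signal file not found: ", dat_path)
  n_int <- file.size(dat_path) / 2
  if (n_int != floor(n_int) || (n_int %% n_sig) != 0)
    stop("format error: signal file length is not a whole number of ",
         n_sig, "-channel frames: ", dat_path)
  raw <- readBin(dat_path, what = "integer", n = n_int, size = 2L,
                 signed = TRUE, endian = "little")
  frames <- length(raw) %/% n_sig
  if (!is.na(n_samp) && n_samp > 0L && frames != n_samp)
    stop("format error: header declares ", n_samp, " samples but signal ",
         "file holds ", frames, ": ", dat_path)
  mat <- matrix(raw, nrow = n_sig)

  samples <- vector("list", n_sig)
  nm <- character(n_sig)
  for (k in seq_len(n_sig)) {
    sp <- spec[[k]]
    samples[[k]] <- (mat[k, ] - sp$baseline) / sp$gain
    nm[[k]] <- sp$description
  }
  nm[!nzchar(nm)] <- paste0("ch", which(!nzchar(nm)))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  names(samples) <- nm
  ecg_record(record_id, fs, samples)
}

# One WFDB header signal-spec line:
#   file format[xN] gain[(baseline)][/units] [adc_res adc_zero init chks blk desc]
parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1L]]
  if (length(tok) < 2L) stop("format error: malformed signal line: ", line)
  fmt <- as.numeric(sub("[x:+].*$", "", tok[[2L]]))
  gain_field <- if (length(tok) >= 3L) tok[[3L]] else "200"
  gain_field <- sub("/.*$", "", gain_field)          # strip units
  baseline <- NA_real_
  if (grepl("\\(", gain_field)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    gain_field <- sub("\\(.*$", "", gain_field)
  }
  gain <- as.numeric(gain_field)
  if (is.na(gain) || gain == 0) gain <- 200  # WFDB default ADC gain
  adc_zero <- if (length(tok) >= 5L) suppressWarnings(as.numeric(tok[[5L]])) else 0
  if (is.na(baseline)) baseline <- if (is.na(adc_zero)) 0 else adc_zero
  desc <- if (length(tok) >= 9L) paste(tok[9:length(tok)], collapse = " ") else ""
  list(file = tok[[1L]], format = fmt, gain = gain, baseline = baseline,
       description = desc)
}

#' Read a single-lead signal from a plain-text file
#'
#' One numeric sample per row, decimal point notation; lines starting with
#' `#` are ignored.  The sampling frequency is not stored in the file and
#' must be supplied.
#'
#' @param path file path.
#' @param fs sampling frequency in Hz.
#' @param lead_name label for the single lead (default `"i"`).
#' @param record_id record identifier (default: file name without extension).
#' @return An [ecg_record] with a single lead.
#' @export
read_csv_signal <- function(path, fs, lead_name = "i",
                            record_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("input error: no samples in ", path)
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(keep)[which(is.na(x))[1L]]
    stop("format error: non-numeric value at row ", bad, " of ", path)
  }
  samples <- list(x)
  names(samples) <- lead_name
  ecg_record(record_id, fs, samples)
}

#' Write a single lead to a plain-text signal file
#'
#' @param rec an [ecg_record].
#' @param path output file path.
#' @param lead lead name (default: first lead).
#' @param digits significant digits used for formatting (default 10).
#' @return `path`, invisibly.
#' @export
write_csv_signal <- function(rec, path, lead = rec$lead_names[[1L]],
                             digits = 10L) {
  stopifnot(inherits(rec, "ecg_record"))
  if (!lead %in% rec$lead_names) stop("lead not present: ", lead)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s %s fs=%g", rec$record_id, lead, rec$fs), con)
  writeLines(formatC(rec$samples[[lead]], digits = digits, format = "g"), con)
  invisible(path)
}

#' Extract a time segment from a record
#'
#' Cuts every lead to the half-open interval
#' `[floor(start_s * fs), min(N, floor(end_s * fs)))` in 0-based sample time,
#' i.e. R indices `floor(start_s * fs) + 1` up to `min(N, floor(end_s * fs))`.
#' Annotations are not adjusted; callers shift them separately.
#'
#' @param rec an [ecg_record].
#' @param start_s segment start in seconds (>= 0).
#' @param end_s segment end in seconds, or `"end"` for the end of the record.
#' @return An [ecg_record] covering the requested segment.
#' @export
select_segment <- function(rec, start_s = 0, end_s = "end") {
  stopifnot(inherits(rec, "ecg_record"))
  dur <- rec$n_samples / rec$fs
  if (!is.numeric(start_s) || start_s < 0 || start_s >= dur)
    stop("range error: start_s must lie in [0, ", format(dur), ")")
  if (identical(end_s, "end")) end_s <- dur
  if (!is.numeric(end_s) || end_s <= start_s)
    stop("range error: end_s must exceed start_s (or be \"end\")")
  i0 <- floor(start_s * rec$fs) + 1
  i1 <- min(rec$n_samples, floor(end_s * rec$fs))
  samples <- lapply(rec$samples, function(x) x[i0:i1])
  ecg_record(rec$record_id, rec$fs, samples)
}

#' Write detections to a plain-text annotation file
#'
#' Format: a header line `# <record> <lead> <fs>` followed by one 1-based
#' sample index per line.  Integer round-trip through [read_detections] is
#' exact.
#'
#' @param dets a [qrs_detections] or [beat_annotations] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detections <- function(dets, path) {
  if (!inherits(dets, c("qrs_detections", "beat_annotations")))
    stop("`dets` must be a qrs_detections or beat_annotations object")
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("I/O error: cannot write ", path))
  on.exit(close(con))
  writeLines(sprintf("# %s %s %g", dets$record_id, dets$lead_name, dets$fs), con)
  if (length(dets$r_samples))
    writeLines(format(dets$r_samples, scientific = FALSE, trim = TRUE), con)
  invisible(path)
}

#' Read a detection/annotation file written by [write_detections]
#'
#' @param path file path.
#' @return A [beat_annotations] object.
#' @export
read_detections <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^#", lines[[1L]]))
    stop("format error: missing '# record lead fs' header in ", path)
  hdr <- strsplit(sub("^#\\s*", "", lines[[1L]]), "\\s+")[[1L]]
  if (length(hdr) < 3L)
    stop("format error: malformed header line in ", path)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  idx <- if (length(body)) as.integer(body) else integer(0)
  if (anyNA(idx)) stop("format error: non-integer index in ", path)
  beat_annotations(hdr[[1L]], hdr[[2L]], idx, as.numeric(hdr[[3L]]))
}
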