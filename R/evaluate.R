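#' Beat-detection counts
#'
#' @param tp,fn,fp nonnegative integer counts: true positives (matched
#'   beats), false negatives (missed reference beats) and false
#'   positives (spurious detections).
#' @return An object of class `detection_counts`.
#' @export
detection_counts <- function(tp, fn, fp) {
  v <- c(tp = tp, fn = fn, fp = fp)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("counts must be nonnegative integers")
  structure(list(tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp)),
            class = "detection_counts")
}

#' @export
print.detection_counts <- function(x, ...) {
  cat(sprintf("<detection_counts> TP=%d FN=%d FP=%d\n", x$tp, x$fn, x$fp))
  invisible(x)
}

#' Match detections against reference beats
#'
#' One-to-one matching, initialized greedily in order of increasing time
#' distance (each reference beat pairs with the nearest unmatched
#' detection within `+/- tolerance` samples, ties broken by earlier
#' reference, then earlier detection) and then repaired by augmenting
#' paths so the result is a maximum-cardinality matching — plain
#' nearest-first greedy can strand a pairable beat when match windows
#' cross.  Matched pairs are TP, unmatched references FN, unmatched
#' detections FP.  The test suite verifies optimality against
#' brute-force enumeration on small instances.
#'
#' @param dets a [qrs_detections] object, or an integer vector of
#'   detected sample indices.
#' @param refs a [beat_annotations] object, or an integer vector of
#'   reference sample indices.
#' @param tolerance matching half-window in samples.
#' @return A [detection_counts] object; attribute `"pairs"` holds a
#'   two-column matrix (`ref`, `det`) of matched sample indices.
#' @export
match_beats <- function(dets, refs, tolerance) {
  d_fs <- if (inherits(dets, "qrs_detections")) dets$fs else NA_real_
  r_fs <- if (inherits(refs, "beat_annotations")) refs$fs else NA_real_
  if (!is.na(d_fs) && !is.na(r_fs) && d_fs != r_fs)
    stop("input error: sampling frequencies differ (", d_fs, " vs ", r_fs, ")")
  d <- if (is.list(dets)) dets$r_samples else as.integer(dets)
  r <- if (is.list(refs)) refs$r_samples else as.integer(refs)
  if (is.unsorted(d, strictly = FALSE) || is.unsorted(r, strictly = FALSE))
    stop("input error: sequences must be sorted")
  if (!is.finite(tolerance) || tolerance < 0)
    stop("parameter error: tolerance must be a nonnegative number")

  nd <- length(d)
  nr <- length(r)
  if (nd == 0L || nr == 0L) {
    cnt <- detection_counts(0L, nr, nd)
    attr(cnt, "pairs") <- cbind(ref = integer(0), det = integer(0))
    return(cnt)
  }
  # all candidate pairs within tolerance, nearest-first
  dist <- abs(outer(r, d, "-"))
  ok <- which(dist <= tolerance, arr.ind = TRUE)
  if (nrow(ok)) {
    ord <- order(dist[ok], ok[, 1L], ok[, 2L])
    ok <- ok[ord, , drop = FALSE]
  }
  owner <- integer(nd)        # ref index owning each detection (0 = free)
  match_of <- integer(nr)     # detection index matched to each ref (0 = none)
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1L]
    j <- ok[k, 2L]
    if (match_of[i] == 0L && owner[j] == 0L) {
      match_of[i] <- j
      owner[j] <- i
    }
  }
  # augmenting-path repair (Kuhn): adjacency per ref, nearest first
  adj <- lapply(seq_len(nr), function(i) {
    js <- which(dist[i, ] <= tolerance)
    js[order(dist[i, js], js)]
  })
  st <- new.env()
  st$owner <- owner
  st$match_of <- match_of
  augment <- function(i) {
    for (j in adj[[i]]) {
      if (!st$visited[j]) {
        st$visited[j] <- TRUE
        if (st$owner[j] == 0L || augment(st$owner[j])) {
          st$owner[j] <- i
          st$match_of[i] <- j
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (i in which(st$match_of == 0L)) {
    st$visited <- logical(nd)
    augment(i)
  }
  matched <- which(st$match_of > 0L)
  cnt <- detection_counts(length(matched), nr - length(matched),
                          nd - length(matched))
  attr(cnt, "pairs") <- cbind(ref = r[matched], det = d[st$match_of[matched]])
  cnt
}

#' Beat-detection performance metrics
#'
#' Computes the four standard percentages from TP/FN/FP counts:
#' sensitivity `Se = TP/(TP+FN) * 100`, positive predictivity
#' `+P = TP/(TP+FP) * 100`, accuracy `Acc = TP/(TP+FN+FP) * 100`, and
#' detection error rate `DER = (FP+FN)/TP * 100`.  Values are kept at
#' full precision internally; report output renders them to 3 decimals
#' (round-half-even).  When `tp == 0` with any errors present, DER is
#' undefined and reported as `Inf`.
#'
#' @param counts a [detection_counts] object.
#' @return An object of class `detection_metrics` with fields `se`,
#'   `pp`, `acc`, `der` (percent).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  tp <- counts$tp; fn <- counts$fn; fp <- counts$fp
  if (tp + fn + fp == 0L)
    stop("input error: all counts are zero, metrics undefined")
  se  <- if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_
  pp  <- if (tp + fp > 0L) 100 * tp / (tp + fp) else NA_real_
  acc <- 100 * tp / (tp + fn + fp)
  der <- if (tp > 0L) 100 * (fp + fn) / tp else Inf
  structure(list(se = se, pp = pp, acc = acc, der = der),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> Se=%s%% +P=%s%% Acc=%s%% DER=%s%%\n",
              fmt_pct(x$se), fmt_pct(x$pp), fmt_pct(x$acc), fmt_pct(x$der)))
  invisible(x)
}

# render a percentage to 3 decimals (round-half-even), full precision kept
# upstream; Inf/NA pass through as text
fmt_pct <- function(x) {
  ifelse(is.finite(x), sprintf("%.3f", round(x, 3L)), as.character(x))
}

#' Sum detection counts
#'
#' Elementwise sum of TP/FN/FP over leads or records.  Associative: the
#' sum of per-record sums equals the sum over all leads at once.
#'
#' @param counts a list of [detection_counts] objects (nonempty).
#' @return A single [detection_counts] object.
#' @export
aggregate_counts <- function(counts) {
  if (inherits(counts, "detection_counts")) counts <- list(counts)
  if (!is.list(counts) || length(counts) == 0L)
    stop("`counts` must be a non-empty list of detection_counts")
  stopifnot(all(vapply(counts, inherits, TRUE, "detection_counts")))
  detection_counts(sum(vapply(counts, `[[`, 0L, "tp")),
                   sum(vapply(counts, `[[`, 0L, "fn")),
                   sum(vapply(counts, `[[`, 0L, "fp")))
}

#' Per-record performance report
#'
#' Builds the standard evaluation table: one row per record with columns
#' `Case, TP, FN, FP, DER, Se, PP, Acc` (percentages rendered to 3
#' decimals) and a `Total` row aggregating all counts.
#'
#' @param per_record named list mapping record id to [detection_counts].
#' @param file optional path; when given, the table is written as CSV.
#' @return A data.frame (invisibly when `file` is given).
#' @export
report_table <- function(per_record, file = NULL) {
  stopifnot(is.list(per_record))
  row_of <- function(case, cnt) {
    und <- cnt$tp + cnt$fn + cnt$fp == 0L
    m <- if (und) list(se = NA_real_, pp = NA_real_, acc = NA_real_,
                       der = NA_real_) else compute_metrics(cnt)
    data.frame(Case = case, TP = cnt$tp, FN = cnt$fn, FP = cnt$fp,
               DER = fmt_pct(m$der), Se = fmt_pct(m$se),
               PP = fmt_pct(m$pp), Acc = fmt_pct(m$acc),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(names(per_record),
                 function(nm) row_of(nm, per_record[[nm]]))
  total <- if (length(per_record)) aggregate_counts(per_record)
           else detection_counts(0L, 0L, 0L)
  tab <- do.call(rbind, c(rows, list(row_of("Total", total))))
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Published reference counts for the PTB evaluation
#'
#' Per-record beat-detection counts (TP, FN, FP) and the corresponding
#' reported percentages for the 72-record, 12-lead PTB Diagnostic ECG
#' Database evaluation of this detector, as published, plus the reported
#' corpus total.  Used by [run_reproduce_table] to verify that
#' [compute_metrics] reproduces every reported percentage from its
#' counts.
#'
#' @param path fixture path; defaults to the copy bundled with the
#'   package.
#' @return A data.frame with columns `case, tp, fn, fp, der, se, pp, acc`.
#' @export
ptb_reference_counts <- function(path = system.file("extdata",
                                                    "ptb_reference_counts.csv",
                                                    package = "seeqrs")) {
  if (!nzchar(path) || !file.exists(path))
    stop("packaging error: reference counts fixture not found")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Published per-lead reference counts for one PTB record
#'
#' Per-lead (12 conventional leads) TP/FN/FP counts as published for a
#' single record, whose column sums equal that record's row in
#' [ptb_reference_counts].
#'
#' @param record record identifier (bundled: `"s0020arem"`).
#' @return A data.frame with columns `lead, tp, fn, fp`.
#' @export
ptb_reference_lead_counts <- function(record = "s0020arem") {
  path <- system.file("extdata",
                      paste0("ptb_reference_leads_", record, ".csv"),
                      package = "seeqrs")
  if (!nzchar(path) || !file.exists(path))
    stop("packaging error: no bundled per-lead counts for record ", record)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
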