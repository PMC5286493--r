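test_that("beat matching pairs nearest-first within tolerance", {
  c1 <- match_beats(c(110L, 900L), c(100L, 500L), 150)
  expect_identical(c(c1$tp, c1$fn, c1$fp), c(1L, 1L, 1L))
  # identity
  idx <- c(100L, 400L, 800L)
  c2 <- match_beats(idx, idx, 150)
  expect_identical(c(c2$tp, c2$fn, c2$fp), c(3L, 0L, 0L))
  # nearest-first: 130 (distance 30) wins over 60 (distance 40)
  c3 <- match_beats(c(60L, 130L), 100L, 50)
  expect_identical(c(c3$tp, c3$fn, c3$fp), c(1L, 0L, 1L))
  expect_equal(unname(attr(c3, "pairs")[, "det"]), 130L)
  # fs mismatch between carriers
  d <- qrs_detections("r", "i", 100L, fs = 500)
  a <- beat_annotations("r", "i", 100L, fs = 1000)
  expect_error(match_beats(d, a, 150), "input error")
})

test_that("greedy matching equals brute-force optimal on small instances", {
  set.seed(31)
  for (k in 1:60) {
    nr <- sample(0:8, 1)
    nd <- sample(0:8, 1)
    refs <- sort(sample.int(2000, nr))
    dets <- sort(sample.int(2000, nd))
    tol <- sample(c(50, 150, 400), 1)
    got <- match_beats(dets, refs, tol)
    expect_identical(got$tp, brute_optimal_tp(refs, dets, tol),
                     info = sprintf("case %d", k))
    expect_identical(got$tp + got$fn, nr)
    expect_identical(got$tp + got$fp, nd)
  }
})

test_that("matching is invariant under a global time shift", {
  set.seed(32)
  refs <- sort(sample.int(50000, 30))
  dets <- sort(refs + sample(-120:120, 30, replace = TRUE))
  c0 <- match_beats(dets, refs, 150)
  for (shift in c(100L, 5000L)) {
    cs <- match_beats(dets + shift, refs + shift, 150)
    expect_identical(c(cs$tp, cs$fn, cs$fp), c(c0$tp, c0$fn, c0$fp))
  }
})

test_that("metrics reproduce reported corpus and record values to 3 decimals", {
  m <- compute_metrics(detection_counts(119054, 91, 93))
  expect_identical(sprintf("%.3f", round(m$se, 3)), "99.924")
  expect_identical(sprintf("%.3f", round(m$pp, 3)), "99.922")
  expect_identical(sprintf("%.3f", round(m$acc, 3)), "99.846")
  expect_identical(sprintf("%.3f", round(m$der, 3)), "0.155")

  m <- compute_metrics(detection_counts(1906, 4, 21))
  expect_identical(sprintf("%.3f", round(m$der, 3)), "1.312")
  expect_identical(sprintf("%.3f", round(m$se, 3)), "99.791")
  expect_identical(sprintf("%.3f", round(m$pp, 3)), "98.910")
  expect_identical(sprintf("%.3f", round(m$acc, 3)), "98.705")

  m <- compute_metrics(detection_counts(500, 0, 0))
  expect_equal(c(m$se, m$pp, m$acc, m$der), c(100, 100, 100, 0))
})

test_that("metric edge cases are handled", {
  expect_error(compute_metrics(detection_counts(0, 0, 0)), "input error")
  m <- compute_metrics(detection_counts(0, 3, 2))
  expect_identical(m$der, Inf)
  expect_equal(m$se, 0)
  expect_error(detection_counts(-1, 0, 0), "nonnegative")
})

test_that("accuracy never exceeds sensitivity or positive predictivity", {
  set.seed(33)
  for (k in 1:50) {
    cnt <- detection_counts(sample(1:5000, 1), sample(0:50, 1),
                            sample(0:50, 1))
    m <- compute_metrics(cnt)
    expect_lte(m$acc, min(m$se, m$pp) + 1e-12)
  }
})

test_that("count aggregation is an elementwise associative sum", {
  a <- detection_counts(10, 1, 2)
  b <- detection_counts(5, 0, 3)
  d <- detection_counts(7, 2, 0)
  tot <- aggregate_counts(list(a, b, d))
  expect_identical(c(tot$tp, tot$fn, tot$fp), c(22L, 3L, 5L))
  expect_identical(aggregate_counts(list(a)), a)
  # sum of sums == sum of concatenation over random partitions
  set.seed(34)
  pool <- lapply(1:12, function(i)
    detection_counts(sample(0:100, 1), sample(0:10, 1), sample(0:10, 1)))
  whole <- aggregate_counts(pool)
  cut <- sort(sample(2:11, 2))
  parts <- list(pool[1:(cut[1] - 1)], pool[cut[1]:(cut[2] - 1)],
                pool[cut[2]:12])
  nested <- aggregate_counts(lapply(parts, aggregate_counts))
  expect_identical(unclass(nested)[c("tp", "fn", "fp")],
                   unclass(whole)[c("tp", "fn", "fp")])
})

test_that("per-lead reference rows for s0020arem sum to the record totals", {
  leads <- ptb_reference_lead_counts("s0020arem")
  expect_identical(nrow(leads), 12L)
  tot <- aggregate_counts(lapply(seq_len(12), function(i)
    detection_counts(leads$tp[i], leads$fn[i], leads$fp[i])))
  expect_identical(c(tot$tp, tot$fn, tot$fp), c(1906L, 4L, 21L))
  # and those totals match the record's row in the per-record table
  tab <- ptb_reference_counts()
  row <- tab[tab$case == "s0020arem", ]
  expect_identical(c(row$tp, row$fn, row$fp), c(1906L, 4L, 21L))
})

test_that("report_table renders percentages and a consistent Total row", {
  tab <- report_table(list(s0010_rem = detection_counts(624, 0, 0)))
  expect_identical(unname(unlist(tab[1, ])),
                   c("s0010_rem", "624", "0", "0", "0.000", "100.000",
                     "100.000", "100.000"))
  # Total row equals the aggregate of all rows
  pr <- list(a = detection_counts(100, 2, 1), b = detection_counts(50, 0, 4))
  tab <- report_table(pr)
  tot <- tab[tab$Case == "Total", ]
  expect_identical(c(tot$TP, tot$FN, tot$FP), c(150L, 2L, 5L))
  m <- compute_metrics(aggregate_counts(pr))
  expect_identical(tot$Se, sprintf("%.3f", round(m$se, 3)))
  # empty mapping: Total row of zeros with undefined percentages
  tab0 <- report_table(list())
  expect_identical(nrow(tab0), 1L)
  expect_identical(tab0$TP, 0L)
  expect_true(is.na(tab0$Se))
  # CSV writing round-trips
  p <- withr::local_tempfile(fileext = ".csv")
  report_table(pr, file = p)
  back <- read.csv(p, colClasses = c(Se = "character"))
  expect_identical(back$Se[3], tot$Se)
})
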