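test_that("recordings without flags tile into 5-min pieces", {
  seg <- build_deferral_segments(1500, tibble::tibble(
    flag_start_s = numeric(), flag_end_s = numeric()
  ))
  expect_equal(nrow(seg), 5L)
  expect_true(all(seg$end_s - seg$start_s == 300))
  expect_false(any(seg$contains_flag))
})

test_that("a flag is centred in a 5-min segment and the tiling is exact", {
  fl <- tibble::tibble(flag_start_s = 600, flag_end_s = 611)
  seg <- build_deferral_segments(3600, fl)
  fseg <- seg[seg$contains_flag, ]
  # centre 605.5, so the flag segment is [455.5, 755.5]
  expect_equal(fseg$start_s, 455.5)
  expect_equal(fseg$end_s, 755.5)
  # exact non-overlapping cover of [0, 3600]
  expect_equal(seg$start_s[1], 0)
  expect_equal(seg$end_s[nrow(seg)], 3600)
  expect_true(all(abs(seg$start_s[-1] - seg$end_s[-nrow(seg)]) < 1e-9))
  expect_equal(sum(seg$end_s - seg$start_s), 3600)
})

test_that("nearby flag segments merge and boundaries shift inward", {
  fl <- tibble::tibble(flag_start_s = c(1000, 1200),
                       flag_end_s = c(1011, 1211))
  seg <- build_deferral_segments(3600, fl)
  expect_equal(sum(seg$contains_flag), 1L)
  merged <- seg[seg$contains_flag, ]
  expect_equal(merged$start_s, 1005.5 - 150)
  expect_equal(merged$end_s, 1205.5 + 150)
  # a flag at the very start keeps the full 300-s length
  seg2 <- build_deferral_segments(3600, tibble::tibble(
    flag_start_s = 5, flag_end_s = 16
  ))
  f2 <- seg2[seg2$contains_flag, ]
  expect_equal(c(f2$start_s, f2$end_s), c(0, 300))
})

test_that("the tiling is exact for random flag sets", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      dur <- sample(1200:7200, 1)
      starts <- sort(sample(0:(dur - 12), sample(0:6, 1)))
      fl <- tibble::tibble(flag_start_s = starts, flag_end_s = starts + 11)
      seg <- build_deferral_segments(dur, fl)
      expect_equal(seg$start_s[1], 0)
      expect_equal(seg$end_s[nrow(seg)], dur)
      expect_true(all(abs(seg$start_s[-1] - seg$end_s[-nrow(seg)]) < 1e-9))
      expect_true(all(seg$end_s > seg$start_s))
      # every flag is inside a flag segment
      for (s in starts) {
        expect_true(any(seg$contains_flag & seg$start_s <= s &
                          seg$end_s >= s + 11))
      }
    }
  })
})

test_that("the lowest-p_low confidence aggregation matches a sorting oracle", {
  withr::with_seed(17, {
    grid <- segment_grid(600)
    sc <- runif(length(grid))
    # full percentage: plain mean over the n = 299 interior segments
    inside <- grid >= 0 & grid + 2 <= 300
    expect_equal(aggregate_confidence(sc, grid, 0, 300, p_low = 100),
                 mean(sc[inside]))
    # p_low = 5 over 299 segments averages the ceiling(14.95) = 15 lowest
    expect_equal(aggregate_confidence(sc, grid, 0, 300, p_low = 5),
                 mean(sort(sc[inside])[1:15]))
    # a single-segment piece returns that score for any p_low
    expect_equal(aggregate_confidence(sc, grid, 10, 12, p_low = 5), sc[11])
    expect_error(aggregate_confidence(sc, grid, 10, 11), "complete")
    expect_error(aggregate_confidence(sc, grid, 0, 300, p_low = 0), "p_low")
  })
})

make_scored_segments <- function(scores) {
  n <- length(scores)
  tibble::tibble(
    start_s = (0:(n - 1)) * 300, end_s = (1:n) * 300,
    contains_flag = FALSE, score = scores
  )
}

test_that("deferral selection follows the flags-first greedy order", {
  seg <- make_scored_segments(c(5, 3, 9, 1, 7, 2, 8, 4, 6, 10))
  # fraction 0.3 of ten equal segments: the three lowest scores
  sel <- select_deferrals(seg, 0.3, "flags_first")
  expect_equal(which(sel$deferred), which(seg$score %in% c(1, 2, 3)))
  # everything at fraction 1, nothing but flags at fraction 0
  expect_true(all(select_deferrals(seg, 1, "flags_first")$deferred))
  expect_false(any(select_deferrals(seg, 0, "flags_first")$deferred))
  seg$contains_flag[4] <- TRUE
  sel0 <- select_deferrals(seg, 0, "flags_first")
  expect_equal(which(sel0$deferred), 4L)
})

test_that("the perfect annotator yields perfect metrics at full deferral", {
  ev <- tibble::tibble(onset_s = 500, end_s = 560, clear_ictal_start_s = 500)
  fl <- tibble::tibble(flag_start_s = c(520, 2000), flag_end_s = c(531, 2011))
  all_def <- tibble::tibble(start_s = 0, end_s = 3600)
  m <- evaluate_with_deferral(ev, fl, all_def, 3600, "flags_first")
  expect_equal(m$ds, 100)
  expect_equal(m$fdr_per_24h, 0)
  expect_equal(m$ppv, 100)
  expect_equal(m$f1, 100)
})

test_that("deferring exactly the flag segments removes every false positive", {
  ev <- tibble::tibble(onset_s = 500, end_s = 560, clear_ictal_start_s = 500)
  fl <- tibble::tibble(flag_start_s = c(520, 2000, 2600),
                       flag_end_s = c(531, 2011, 2611))
  seg <- build_deferral_segments(3600, fl) |>
    score_deferral_segments(runif(3599), segment_grid(3600), p_low = 5)
  sel <- select_deferrals(seg, 0, "flags_first")
  m <- evaluate_with_deferral(ev, fl, sel, 3600, "flags_first")
  expect_equal(m$fdr_per_24h, 0)
  expect_equal(m$fp, 0L)
  expect_equal(m$ds, 100)  # the genuine flag is reviewed and confirmed
})

test_that("a seizure split below 10 s on both sides stays undetected", {
  ev <- tibble::tibble(onset_s = 591, end_s = 609, clear_ictal_start_s = 591)
  no_flags <- tibble::tibble(flag_start_s = numeric(),
                             flag_end_s = numeric())
  deferred <- tibble::tibble(start_s = 300, end_s = 600)
  m <- evaluate_with_deferral(ev, no_flags, deferred, 1200, "flags_first")
  expect_equal(m$tp, 0)
  expect_equal(m$fn, 1)
  # with >= 10 s deferred the human annotator catches it
  deferred2 <- tibble::tibble(start_s = 300, end_s = 602)
  m2 <- evaluate_with_deferral(ev, no_flags, deferred2, 1200, "flags_first")
  expect_equal(m2$tp, 1)
  expect_true(is.na(m2$mean_delay_s))  # human detections carry no delay
})

test_that("deferral curves are monotone and hit perfect endpoints", {
  co <- tiny_cohort(n_patients = 3, duration_s = 1800, seed = 23,
                    seizure_rate = 2, artifact_rate = 20)
  preds <- classify_cohort(co, "ci", seed = 1)
  conf <- purrr::map(preds$distances, abs)
  prep <- prepare_deferral(co, preds$predictions, conf, p_low = 5)
  curve <- deferral_curve(prep, seq(0, 1, by = 0.25), "flags_first")
  expect_s3_class(curve, "deferral_curve")
  expect_true(all(diff(curve$ds) >= 0 | is.na(diff(curve$ds))))
  expect_true(all(curve$fdr_per_24h == 0))  # flags always deferred
  expect_equal(curve$ds[curve$defer_fraction == 1], 100)
  expect_true(curve$deferred_time_fraction[nrow(curve)] == 1)
})

test_that("score-only deferral reviews flags only when overlapped", {
  # one FP flag, deferral elsewhere: the flag survives review
  fl <- tibble::tibble(flag_start_s = 1000, flag_end_s = 1011)
  no_ev <- tibble::tibble(onset_s = numeric(), end_s = numeric())
  far <- tibble::tibble(start_s = 0, end_s = 300)
  m <- evaluate_with_deferral(no_ev, fl, far, 3600, "score_only")
  expect_equal(m$fp, 1L)
  # overlapping the flag by >= 1 s has it reviewed and removed
  near <- tibble::tibble(start_s = 900, end_s = 1001)
  m2 <- evaluate_with_deferral(no_ev, fl, near, 3600, "score_only")
  expect_equal(m2$fp, 0L)
})
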