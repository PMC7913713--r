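#' Partition a recording into reviewable deferral segments
#'
#' Every seizure flag is put in the middle of a 5-min (300-s) segment,
#' shifted inward at recording boundaries so the 300-s length is
#' preserved where possible.  Flag segments separated by less than
#' 5 min are merged.  The remaining signal is tiled left-to-right with
#' 300-s segments; the last remainder piece of each gap may be shorter.
#' The returned segments tile `[0, duration_s]` exactly and without
#' overlap.
#'
#' @param duration_s Recording length in seconds.
#' @param flags Flag tibble (`flag_start_s`, `flag_end_s`).
#' @return A tibble with `start_s`, `end_s`, `contains_flag`.
#' @export
#' @examples
#' build_deferral_segments(3600, tibble::tibble(flag_start_s = 600,
#'                                              flag_end_s = 611))
build_deferral_segments <- function(duration_s, flags) {
  seg_len <- 300
  tile <- function(lo, hi) {
    if (hi - lo <= 0) return(NULL)
    starts <- seq(lo, hi, by = seg_len)
    starts <- starts[starts < hi]
    tibble(start_s = starts, end_s = pmin(starts + seg_len, hi),
           contains_flag = FALSE)
  }
  if (nrow(flags) == 0L) {
    out <- tile(0, duration_s)
  } else {
    centre <- (flags$flag_start_s + flags$flag_end_s) / 2
    lo <- centre - seg_len / 2
    hi <- centre + seg_len / 2
    # preserve the 300-s length by shifting into the recording
    shift_r <- pmax(0, -lo)
    lo <- lo + shift_r
    hi <- hi + shift_r
    shift_l <- pmax(0, hi - duration_s)
    lo <- pmax(0, lo - shift_l)
    hi <- hi - shift_l
    m <- merge_interval_set(lo, hi, gap = seg_len)
    fseg <- tibble(start_s = m$lo, end_s = m$hi, contains_flag = TRUE)
    gaps_lo <- c(0, m$hi)
    gaps_hi <- c(m$lo, duration_s)
    out <- dplyr::bind_rows(
      fseg,
      purrr::map2(gaps_lo, gaps_hi, tile) |> dplyr::bind_rows()
    )
  }
  dplyr::arrange(out, .data$start_s)
}

#' Aggregated confidence score of one deferral segment
#'
#' Takes the `p_low` percent lowest per-2-s-segment scores among the
#' segments fully inside the deferral segment and averages them
#' (`k = max(1, ceiling(p_low/100 * n))` lowest scores).  `p_low = 100`
#' is the plain mean.
#'
#' @param scores Per-2-s-segment confidence or trust scores for the
#'   whole recording, aligned with `start_s`.
#' @param start_s Segment start times.
#' @param seg_start_s,seg_end_s Deferral-segment boundaries.
#' @param p_low Percentage in (0, 100].
#' @return The aggregated score (scalar).
#' @export
aggregate_confidence <- function(scores, start_s, seg_start_s, seg_end_s,
                                 p_low = 5) {
  if (p_low <= 0 || p_low > 100) abort("`p_low` must be in (0, 100].")
  inside <- start_s >= seg_start_s & start_s + 2 <= seg_end_s
  n <- sum(inside)
  if (n == 0L) abort("deferral segment contains no complete 2-s segment.")
  k <- max(1L, ceiling(p_low / 100 * n))
  mean(sort(scores[inside])[seq_len(k)])
}

#' Score every deferral segment of a recording
#'
#' Batch version of [aggregate_confidence()].  Boundary slivers too
#' short to contain a complete 2-s segment receive `+Inf` (maximal
#' confidence: they are deferred last).
#'
#' @param segments Deferral-segment tibble from
#'   [build_deferral_segments()].
#' @inheritParams aggregate_confidence
#' @return `segments` with an added `score` column.
#' @export
score_deferral_segments <- function(segments, scores, start_s, p_low = 5) {
  sc <- purrr::map2_dbl(segments$start_s, segments$end_s, function(lo, hi) {
    if (!any(start_s >= lo & start_s + 2 <= hi)) return(Inf)
    aggregate_confidence(scores, start_s, lo, hi, p_low)
  })
  dplyr::mutate(segments, score = sc)
}

#' Select which segments to defer to the human annotator
#'
#' In the default `"flags_first"` mode every flag-containing segment is
#' deferred unconditionally; the remaining segments are then deferred in
#' order of increasing aggregated confidence until the deferred time
#' reaches `defer_fraction` of the recording (the first segment crossing
#' the quota is included).  In `"score_only"` mode flags are not
#' prioritized and all segments compete purely by score; in `"random"`
#' mode segments are deferred in random order (the baseline strategy).
#' The same fraction is used for every patient.
#'
#' @param segments Scored deferral segments
#'   ([score_deferral_segments()]; `score` may be `NA` for flag
#'   segments in `"flags_first"` mode).
#' @param defer_fraction Fraction of recording time to defer, in
#'   `[0, 1]`.
#' @param mode `"flags_first"`, `"score_only"` or `"random"`.
#' @param seed Seed for `"random"` mode.
#' @return `segments` with an added logical `deferred` column.
#' @export
select_deferrals <- function(segments, defer_fraction,
                             mode = c("flags_first", "score_only", "random"),
                             seed = 1L) {
  mode <- match.arg(mode)
  check_fraction(defer_fraction, "defer_fraction")
  duration <- sum(segments$end_s - segments$start_s)
  budget <- defer_fraction * duration
  seg <- dplyr::mutate(segments, .len = .data$end_s - .data$start_s,
                       deferred = FALSE)
  if (mode == "flags_first") {
    seg$deferred <- seg$contains_flag
    pool <- which(!seg$contains_flag)
    ord <- pool[order(seg$score[pool], seg$start_s[pool])]
  } else if (mode == "score_only") {
    ord <- order(seg$score, seg$start_s)
  } else {
    ord <- withr::with_seed(seed, sample.int(nrow(seg)))
  }
  time_deferred <- sum(seg$.len[seg$deferred])
  for (i in ord) {
    if (time_deferred >= budget) break
    seg$deferred[i] <- TRUE
    time_deferred <- time_deferred + seg$.len[i]
  }
  seg$.len <- NULL
  seg
}

# union of deferred segments as merged intervals (adjacent merged)
merged_deferred_intervals <- function(segments) {
  d <- segments[segments$deferred, , drop = FALSE]
  m <- merge_interval_set(d$start_s, d$end_s, gap = 0)
  tibble(start_s = m$lo, end_s = m$hi)
}

#' Evaluate detection performance under deferral to a perfect annotator
#'
#' The human annotator is modelled as perfect: every false-positive flag
#' that the annotator reviews is removed, and every seizure with at
#' least 10 s of its extent inside deferred time is detected.  A seizure
#' is counted as detected iff (a) at least 10 s of it lies in deferred
#' time, or (b) a seizure flag overlaps it (a reviewed genuine flag is
#' confirmed by the annotator; an unreviewed one stands as an
#' algorithmic detection).  A seizure split such that both the deferred
#' and non-deferred parts hold less than 10 s and no flag overlaps it
#' stays undetected.  In `"flags_first"` mode every flag lies inside a
#' deferred segment and is therefore reviewed, which zeroes the FDR; in
#' `"score_only"` (the alternative deferral analysis) a flag counts as
#' reviewed when it overlaps deferred time by at least 1 s.
#' Detection delays are only averaged over events detected by a flag;
#' purely human-detected events have no algorithmic delay.
#'
#' @param events Event tibble (`onset_s`, `end_s`).
#' @param flags Flag tibble (`flag_start_s`, `flag_end_s`).
#' @param deferred Deferred intervals: either the output of
#'   [select_deferrals()] or a tibble of merged intervals.
#' @param duration_s Recording length in seconds.
#' @param mode `"flags_first"` or `"score_only"` (see
#'   [select_deferrals()]).
#' @param patient_id Optional id carried into the output.
#' @return A one-row metrics tibble as in [patient_metrics()].
#' @export
evaluate_with_deferral <- function(events, flags, deferred, duration_s,
                                   mode = c("flags_first", "score_only"),
                                   patient_id = NA_character_) {
  mode <- match.arg(mode)
  if ("deferred" %in% names(deferred)) {
    deferred <- merged_deferred_intervals(deferred)
  }
  n_ev <- nrow(events)
  n_fl <- nrow(flags)
  def_ov_flag <- if (n_fl > 0) {
    vapply(seq_len(n_fl), function(i) {
      overlap_with_set(flags$flag_start_s[i], flags$flag_end_s[i],
                       deferred$start_s, deferred$end_s)
    }, numeric(1))
  } else numeric(0)
  reviewed <- if (mode == "flags_first") def_ov_flag > 0 else def_ov_flag >= 1

  genuine <- rep(FALSE, n_fl)
  detected <- logical(n_ev)
  delays <- rep(NA_real_, n_ev)
  if (n_ev > 0) {
    for (i in seq_len(n_ev)) {
      ov_def <- overlap_with_set(events$onset_s[i], events$end_s[i],
                                 deferred$start_s, deferred$end_s)
      fl_ov <- if (n_fl > 0) {
        overlap_length(flags$flag_start_s, flags$flag_end_s,
                       events$onset_s[i], events$end_s[i]) > 0
      } else logical(0)
      genuine[fl_ov] <- TRUE
      if (ov_def >= 10 || any(fl_ov)) {
        detected[i] <- TRUE
        if (any(fl_ov)) {
          delays[i] <- min(flags$flag_start_s[fl_ov]) - events$onset_s[i]
        }
      }
    }
  }
  surviving_fp <- !reviewed & !genuine
  fp <- merge_fp_count(flags$flag_start_s[surviving_fp])
  metrics_row(sum(detected), fp, sum(!detected),
              delays[detected & !is.na(delays)], duration_s, patient_id)
}

#' Sweep the deferred fraction over a cohort
#'
#' For each requested fraction, selects deferrals per patient, evaluates
#' performance under the perfect-annotator model, and aggregates across
#' patients (DS/PPV/F1 over patients with seizures, FDR over all
#' patients).  Also reports the number and mean length of merged
#' deferred segments, normalised per patient and per 24 h.
#'
#' @param cohort_results Tibble with one row per patient and columns
#'   `patient_id`, `duration_s`, `events`, `flags` (list of flag
#'   tibbles) and `segments` (list of scored deferral-segment tibbles).
#'   Build it with [prepare_deferral()].
#' @param fractions Numeric vector of deferred fractions to sweep.
#' @param mode,seed Passed to [select_deferrals()].
#' @return A tibble of class `"deferral_curve"`: one row per fraction
#'   with aggregated metrics and deferred-segment statistics.
#' @export
deferral_curve <- function(cohort_results, fractions,
                           mode = c("flags_first", "score_only", "random"),
                           seed = 1L) {
  mode <- match.arg(mode)
  eval_mode <- if (mode == "flags_first") "flags_first" else "score_only"
  rows <- purrr::map(fractions, function(f) {
    per <- purrr::map(seq_len(nrow(cohort_results)), function(i) {
      sel <- select_deferrals(cohort_results$segments[[i]], f, mode,
                              seed = seed + i)
      ivs <- merged_deferred_intervals(sel)
      m <- evaluate_with_deferral(
        cohort_results$events[[i]], cohort_results$flags[[i]], ivs,
        cohort_results$duration_s[i], eval_mode,
        cohort_results$patient_id[i]
      )
      days <- cohort_results$duration_s[i] / 86400
      m$n_deferred_per_24h <- nrow(ivs) / days
      m$mean_deferred_len_s <- if (nrow(ivs) > 0) {
        mean(ivs$end_s - ivs$start_s)
      } else NA_real_
      m$deferred_time_fraction <-
        sum(ivs$end_s - ivs$start_s) / cohort_results$duration_s[i]
      m
    }) |> dplyr::bind_rows()
    tibble(
      defer_fraction = f,
      ds = mean(per$ds, na.rm = TRUE),
      fdr_per_24h = mean(per$fdr_per_24h),
      ppv = mean(per$ppv, na.rm = TRUE),
      f1 = mean(per$f1, na.rm = TRUE),
      mean_delay_s = mean(per$mean_delay_s, na.rm = TRUE),
      n_deferred_per_24h = mean(per$n_deferred_per_24h),
      mean_deferred_len_s = mean(per$mean_deferred_len_s, na.rm = TRUE),
      deferred_time_fraction = mean(per$deferred_time_fraction)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("deferral_curve", class(out))
  attr(out, "mode") <- mode
  out
}

#' Prepare a cohort for deferral analysis
#'
#' Computes, per patient, the seizure flags from the per-segment
#' predictions and the scored deferral segments from the per-segment
#' confidence (or trust) scores.
#'
#' @param cohort Cohort tibble (`patient_id`, `duration_s`, `events`).
#' @param predictions List of per-patient binary prediction vectors.
#' @param scores List of per-patient per-segment score vectors.
#' @param p_low Percentage of lowest scores averaged per segment.
#' @return A tibble suitable for [deferral_curve()].
#' @export
prepare_deferral <- function(cohort, predictions, scores, p_low = 5) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    grid <- segment_grid(cohort$duration_s[i])
    fl <- seizure_flags(predictions[[i]], grid)
    seg <- build_deferral_segments(cohort$duration_s[i], fl) |>
      score_deferral_segments(scores[[i]], grid, p_low)
    tibble(
      patient_id = cohort$patient_id[i],
      duration_s = cohort$duration_s[i],
      events = list(cohort$events[[i]]),
      flags = list(fl),
      segments = list(seg)
    )
  })
  dplyr::bind_rows(rows)
}
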