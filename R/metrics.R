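#' Match seizure flags against annotated events
#'
#' Event-based scoring: a flag whose interval overlaps an annotated
#' event (between onset and end) detects that event; an event with at
#' least one overlapping flag is a true positive (multiple flags on one
#' event still count as one TP), an event with none is a false
#' negative, and flags overlapping no event are false positives.  False
#' positives whose flag starts lie within 10 s of each other are
#' counted as a single FP (chained merging on sorted starts).  The
#' detection delay of a detected event is the start of its first
#' overlapping flag minus the event onset.
#'
#' @param flags Flag tibble (`flag_start_s`, `flag_end_s`), e.g. from
#'   [seizure_flags()].
#' @param events Event tibble (`onset_s`, `end_s`).
#' @param duration_s Recording length in seconds (flags must lie within
#'   it).
#' @return A list with counts `tp`, `fp` (after 10-s merging), `fn`,
#'   `fp_raw`, and `delays` (seconds, one per detected event).
#' @export
match_events <- function(flags, events, duration_s) {
  if (nrow(flags) > 0 &&
      (min(flags$flag_start_s) < 0 || max(flags$flag_start_s) > duration_s)) {
    abort("flags must lie within the recording.")
  }
  flags <- dplyr::arrange(flags, .data$flag_start_s)
  n_ev <- nrow(events)
  detected <- logical(n_ev)
  delays <- rep(NA_real_, n_ev)
  is_fp <- rep(TRUE, nrow(flags))
  if (nrow(flags) > 0 && n_ev > 0) {
    for (i in seq_len(n_ev)) {
      ov <- overlap_length(flags$flag_start_s, flags$flag_end_s,
                           events$onset_s[i], events$end_s[i]) > 0
      if (any(ov)) {
        detected[i] <- TRUE
        delays[i] <- flags$flag_start_s[which(ov)[1]] - events$onset_s[i]
        is_fp[ov] <- FALSE
      }
    }
  }
  fp_starts <- flags$flag_start_s[is_fp]
  list(
    tp = sum(detected),
    fp = merge_fp_count(fp_starts),
    fn = sum(!detected),
    fp_raw = length(fp_starts),
    delays = delays[detected]
  )
}

# chained merging of false positives whose starts are within 10 s
merge_fp_count <- function(fp_starts, within_s = 10) {
  if (length(fp_starts) == 0L) return(0L)
  s <- sort(fp_starts)
  sum(c(TRUE, diff(s) > within_s))
}

#' Per-patient event-based performance metrics
#'
#' Computes the standard per-patient summary from matched flags:
#' detection sensitivity `DS = 100 TP / (TP + FN)`, false detection
#' rate `FDR = FP / recording days` (FPs merged within 10 s),
#' `PPV = 100 TP / (TP + FP)`, `F1 = 100 * 2 TP / (2 TP + FP + FN)`,
#' and the mean detection delay.  DS, PPV, F1 and delay are `NA` for
#' patients without seizures (they are excluded from cohort averages of
#' those metrics; the FDR is defined for every patient).
#'
#' @inheritParams match_events
#' @param patient_id Optional id carried into the output.
#' @return A one-row tibble with columns `patient_id`, `tp`, `fp`,
#'   `fn`, `ds`, `fdr_per_24h`, `ppv`, `f1`, `mean_delay_s`,
#'   `recording_days`.
#' @export
patient_metrics <- function(flags, events, duration_s,
                            patient_id = NA_character_) {
  m <- match_events(flags, events, duration_s)
  metrics_row(m$tp, m$fp, m$fn, m$delays, duration_s, patient_id)
}

metrics_row <- function(tp, fp, fn, delays, duration_s, patient_id) {
  days <- duration_s / 86400
  has_sz <- (tp + fn) > 0
  tibble(
    patient_id = patient_id,
    tp = tp, fp = fp, fn = fn,
    ds = if (has_sz) 100 * tp / (tp + fn) else NA_real_,
    fdr_per_24h = fp / days,
    ppv = if (has_sz && (tp + fp) > 0) 100 * tp / (tp + fp)
          else if (has_sz) NA_real_ else NA_real_,
    f1 = if (has_sz) 100 * 2 * tp / (2 * tp + fp + fn) else NA_real_,
    mean_delay_s = if (length(delays) > 0) mean(delays) else NA_real_,
    recording_days = days
  )
}

#' Aggregate per-patient metrics over a cohort
#'
#' Averages each metric per patient and then across patients: DS, PPV,
#' F1 and delay over patients with at least one seizure, the FDR over
#' all patients.  Both mean (sd) and median [range] summaries are
#' returned.
#'
#' @param per_patient Tibble of [patient_metrics()] rows.
#' @return A tibble with one row per metric and columns `metric`,
#'   `mean`, `sd`, `median`, `min`, `max`, `n`.
#' @export
aggregate_cohort <- function(per_patient) {
  per_patient |>
    dplyr::select("patient_id", "ds", "fdr_per_24h", "ppv", "f1",
                  "mean_delay_s") |>
    tidyr::pivot_longer(-"patient_id", names_to = "metric") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      median = median(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether a performance metric is larger (or smaller) under
#' condition `a` than under condition `b` across patients, using the
#' paired Wilcoxon signed-rank test at the conventional 0.05 level.
#' Pairs with missing values are dropped; if every difference is zero
#' the p-value is 1.
#'
#' @param a,b Paired per-patient metric vectors.
#' @param alternative `"greater"` (a > b) or `"less"`.
#' @return The one-sided p-value.
#' @export
paired_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) == 0L) abort("no complete pairs to test.")
  if (all(a == b)) return(1)
  suppressWarnings(
    wilcox.test(a, b, paired = TRUE, alternative = alternative)$p.value
  )
}

#' Agreement between confidence and trust rankings
#'
#' Kendall rank correlation between classifier confidences and trust
#' scores, computed per patient and then averaged.  Low values mean the
#' two uncertainty rankings disagree notably.
#'
#' @param data Tibble with one row per 2-s segment.
#' @param confidence,trust,patient Column names (tidy-eval) holding the
#'   classifier confidence, the trust score and the patient id.
#' @return A list with `krcc` (the cohort average) and `per_patient`
#'   (tibble of per-patient coefficients).
#' @export
ranking_agreement <- function(data, confidence = "confidence",
                              trust = "trust", patient = "patient_id") {
  per <- data |>
    dplyr::group_by(.data[[patient]]) |>
    dplyr::summarise(
      krcc = cor(.data[[confidence]], .data[[trust]], method = "kendall"),
      .groups = "drop"
    )
  list(krcc = mean(per$krcc), per_patient = per)
}
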