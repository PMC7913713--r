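# internal label vectors on an explicit segment grid ------------------------

# full-seizure labels: a 2-s segment is ictal iff it overlaps any event
# by >= 1 s (half a segment)
fs_label_vector <- function(grid, events) {
  lab <- integer(length(grid))
  for (i in seq_len(nrow(events))) {
    ov <- overlap_length(grid, grid + 2, events$onset_s[i], events$end_s[i])
    lab[ov >= 1] <- 1L
  }
  lab
}

# clear-ictal labels: a 2-s segment is ictal iff it lies entirely inside
# the event's 10-s clear-ictal window
ci_label_vector <- function(grid, events) {
  lab <- integer(length(grid))
  for (i in seq_len(nrow(events))) {
    ci <- events$clear_ictal_start_s[i]
    if (is.na(ci)) ci <- events$onset_s[i]
    lab[grid >= ci & grid + 2 <= ci + 10] <- 1L
  }
  lab
}

#' Derive per-segment labels from seizure annotations
#'
#' Produces the two label regimes used throughout the pipeline.  Under
#' the full-seizure (`"fs"`) regime a 2-s segment is labelled 1 iff it
#' overlaps any annotated event by at least 1 s.  Under the clear-ictal
#' (`"ci"`) regime a segment is labelled 1 iff it lies entirely inside
#' the event's designated 10-s clear-ictal window, so each event
#' contributes exactly nine positive segments (starts `ci`..`ci + 8` on
#' the 1-s hop grid).  CI support is always a subset of FS support.
#'
#' @param events Tibble with `onset_s`, `end_s` and (for `"ci"`)
#'   `clear_ictal_start_s`; events must be sorted and non-overlapping.
#' @param duration_s Recording length in seconds.
#' @param regime `"fs"` or `"ci"`.
#' @return A tibble with columns `start_s` and `label` (integer 0/1) and
#'   a `regime` attribute.
#' @export
#' @examples
#' ev <- tibble::tibble(onset_s = 100, end_s = 160, clear_ictal_start_s = 120)
#' sum(derive_labels(ev, 600, "ci")$label) # 9
derive_labels <- function(events, duration_s, regime = c("fs", "ci")) {
  regime <- match.arg(regime)
  if (nrow(events) > 1) {
    o <- order(events$onset_s)
    events <- events[o, ]
    if (any(events$onset_s[-1] < events$end_s[-nrow(events)])) {
      abort("events overlap; annotations must be non-overlapping.")
    }
  }
  if (nrow(events) > 0 &&
      (min(events$onset_s) < 0 || max(events$end_s) > duration_s)) {
    abort("events must lie within [0, duration_s].")
  }
  grid <- segment_grid(duration_s)
  lab <- if (regime == "fs") fs_label_vector(grid, events)
         else ci_label_vector(grid, events)
  out <- tibble(start_s = grid, label = lab)
  attr(out, "regime") <- regime
  out
}

#' Select the clear-ictal 10-s window of a seizure
#'
#' Scans the 10-s windows inside one annotated event (window starts on
#' the 1-s grid from onset to `end - 10`) and returns the start of the
#' first window whose mean amplitude-proxy value, over the nine 2-s
#' segments fully inside it, exceeds the pre-event background mean by
#' `amp_factor` background standard deviations.  If no window shows an
#' amplitude rise, the first window whose frequency-change proxy exceeds
#' its background threshold is returned; if neither criterion fires, the
#' event onset is returned (the priority order is amplitude, then
#' frequency change, then onset).
#'
#' @param amplitude,freq_change Per-2-s-segment proxy series aligned
#'   with `start_s`.
#' @param start_s Segment start times (the grid the series live on).
#' @param onset_s,end_s Event boundaries in seconds; the event must span
#'   at least 10 s.
#' @param background Optional list with `amp_mean`, `amp_sd`,
#'   `freq_mean`, `freq_sd`.  When `NULL`, estimated from all segments
#'   that end before the event onset (falling back to the whole series
#'   if the event starts at 0).
#' @param amp_factor,freq_factor Threshold factors in background SDs.
#' @return The selected window start in seconds (numeric scalar).
#' @export
select_clear_ictal_window <- function(amplitude, freq_change, start_s,
                                      onset_s, end_s, background = NULL,
                                      amp_factor = 2, freq_factor = 2) {
  if (end_s - onset_s < 10) {
    abort("event shorter than 10 s: cannot select a clear-ictal window.")
  }
  stopifnot(length(amplitude) == length(start_s),
            length(freq_change) == length(start_s))
  if (is.null(background)) {
    pre <- start_s + 2 <= onset_s
    if (!any(pre)) pre <- rep(TRUE, length(start_s))
    background <- list(
      amp_mean = mean(amplitude[pre]), amp_sd = stats::sd(amplitude[pre]),
      freq_mean = mean(freq_change[pre]), freq_sd = stats::sd(freq_change[pre])
    )
  }
  w_starts <- seq(ceiling(onset_s), floor(end_s) - 10)
  window_mean <- function(series, w) {
    inside <- start_s >= w & start_s + 2 <= w + 10
    if (!any(inside)) return(NA_real_)
    mean(series[inside])
  }
  amp_thr <- background$amp_mean + amp_factor * background$amp_sd
  for (w in w_starts) {
    m <- window_mean(amplitude, w)
    if (!is.na(m) && m > amp_thr) return(as.numeric(w))
  }
  freq_thr <- background$freq_mean + freq_factor * background$freq_sd
  for (w in w_starts) {
    m <- window_mean(freq_change, w)
    if (!is.na(m) && m > freq_thr) return(as.numeric(w))
  }
  as.numeric(onset_s)
}

#' Apply the clear-ictal selection rule to every event of a patient
#'
#' Convenience wrapper around [select_clear_ictal_window()] using the
#' cohort's designated proxy features (feature 1 = amplitude, feature
#' 2 = frequency change).
#'
#' @param events Event tibble (`onset_s`, `end_s`).
#' @param features Per-segment feature matrix for the patient.
#' @param duration_s Recording length in seconds.
#' @inheritParams select_clear_ictal_window
#' @return `events` with an added `clear_ictal_detected_s` column.
#' @export
annotate_clear_ictal <- function(events, features, duration_s,
                                 amp_factor = 2, freq_factor = 2) {
  grid <- segment_grid(duration_s)
  det <- vapply(seq_len(nrow(events)), function(i) {
    select_clear_ictal_window(
      features[, 1], features[, 2], grid,
      events$onset_s[i], events$end_s[i],
      amp_factor = amp_factor, freq_factor = freq_factor
    )
  }, numeric(1))
  dplyr::mutate(events, clear_ictal_detected_s = det)
}
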