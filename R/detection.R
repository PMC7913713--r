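#' Raise 10-s seizure flags from per-segment predictions
#'
#' Slides a window of 10 consecutive 2-s segments (1-segment hop) over
#' the binary prediction series and flags a window when at least 8 of
#' the 10 segments are predicted ictal ("more than 7 out of 10").
#' Within each maximal run of consecutive flagged windows only the first
#' is retained.  Because the segments overlap by 50%, the 10-window
#' block physically spans 11 s; the flag interval is stored as
#' `[start, start + 11]` although it is conventionally called a 10-s
#' flag.
#'
#' @param predictions Integer/logical vector of per-2-s-segment
#'   predictions on the 1-s hop grid.
#' @param start_s Segment start times; defaults to `0, 1, ...`.
#' @param min_count Minimum number of ictal segments per window
#'   (default 8).
#' @return A tibble with `flag_start_s` and `flag_end_s` (one row per
#'   retained flag); zero rows if the series is shorter than 10
#'   segments.
#' @export
#' @examples
#' seizure_flags(c(rep(0, 5), rep(1, 15), rep(0, 5)))
seizure_flags <- function(predictions, start_s = NULL, min_count = 8L) {
  pred <- as.integer(predictions)
  n <- length(pred)
  start_s <- start_s %||% (seq_len(n) - 1)
  if (length(start_s) != n) abort("`start_s` must match `predictions`.")
  if (n < 10L) {
    return(tibble(flag_start_s = numeric(), flag_end_s = numeric()))
  }
  flagged <- roll_sum(pred, 10L) >= min_count
  collapse_flag_runs(flagged, start_s)
}

# keep only the first window of each maximal run of flagged windows
collapse_flag_runs <- function(flagged, start_s) {
  first <- flagged & !c(FALSE, flagged[-length(flagged)])
  ws <- start_s[seq_along(flagged)][first]
  tibble(flag_start_s = as.numeric(ws), flag_end_s = as.numeric(ws) + 11)
}

#' Mark the per-patient fraction of least-trusted segments
#'
#' Marks the `floor(q * n)` segments with the lowest scores (trust
#' scores or classifier confidences) as untrustworthy.  Ties are broken
#' in favour of earlier segments.  The same fraction `q` is applied to
#' every patient.
#'
#' @param scores Per-segment score vector (lower = less trusted).
#' @param q Fraction in `[0, 1)` of segments to mark.
#' @return Logical mask, `TRUE` for untrustworthy segments.
#' @export
mark_untrustworthy <- function(scores, q) {
  check_fraction(q, "q", allow_one = FALSE)
  n <- length(scores)
  k <- floor(q * n)
  mask <- logical(n)
  if (k > 0) mask[order(scores, seq_len(n))[seq_len(k)]] <- TRUE
  mask
}

#' Seizure flags after low-trust filtering
#'
#' Re-evaluates every 10-segment window with the untrustworthy
#' predictions removed.  If fewer than 5 of the 10 predictions are
#' masked, the window is flagged when the mean of the remaining
#' predictions exceeds 0.7; if 5 or more are masked, the window is
#' flagged when the mean of the 5 highest-trusted predictions (taken
#' from all 10, masked or not, ties to earlier segments) exceeds 0.7.
#' Runs of flagged windows collapse to their first window exactly as in
#' [seizure_flags()].  With an empty mask this reduces to the plain
#' 8-of-10 rule, since `mean > 0.7` over 10 binary predictions is
#' equivalent to at least 8 ones.
#'
#' @param predictions Binary per-segment predictions.
#' @param mask Logical mask from [mark_untrustworthy()].
#' @param trust Per-segment trust ranking scores (higher = more
#'   trusted), used both for the mask fallback selection.
#' @param start_s Segment start times; defaults to `0, 1, ...`.
#' @param threshold Mean-prediction threshold (default 0.7).
#' @return Flag tibble as in [seizure_flags()].
#' @export
ltf_flags <- function(predictions, mask, trust, start_s = NULL,
                      threshold = 0.7) {
  pred <- as.integer(predictions)
  n <- length(pred)
  if (length(mask) != n || length(trust) != n) {
    abort("`mask` and `trust` must align with `predictions`.")
  }
  start_s <- start_s %||% (seq_len(n) - 1)
  if (n < 10L) {
    return(tibble(flag_start_s = numeric(), flag_end_s = numeric()))
  }
  n_masked <- roll_sum(mask, 10L)
  kept_pos <- roll_sum(pred * (!mask), 10L)
  flagged <- kept_pos / (10 - n_masked) > threshold
  heavy <- which(n_masked >= 5)
  for (i in heavy) {
    w <- i:(i + 9L)
    top5 <- w[order(-trust[w], w)[1:5]]
    flagged[i] <- mean(pred[top5]) > threshold
  }
  collapse_flag_runs(flagged, start_s)
}
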