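# Independent brute-force oracles used to freeze expected values.
# These deliberately re-derive every rule by direct enumeration and never
# call the package implementation they check.

# number of complete 2-s windows at a 1-s hop inside [0, duration]
oracle_segment_count <- function(duration_s) {
  sum(vapply(0:duration_s, function(s) s + 2 <= duration_s, logical(1)))
}

# full-seizure labels by per-segment overlap enumeration
oracle_fs_labels <- function(grid, events) {
  vapply(grid, function(s) {
    any(vapply(seq_len(nrow(events)), function(i) {
      lo <- max(s, events$onset_s[i])
      hi <- min(s + 2, events$end_s[i])
      hi - lo >= 1
    }, logical(1)))
  }, logical(1)) |> as.integer()
}

# clear-ictal labels by full-containment enumeration
oracle_ci_labels <- function(grid, events) {
  vapply(grid, function(s) {
    any(vapply(seq_len(nrow(events)), function(i) {
      ci <- events$clear_ictal_start_s[i]
      s >= ci && s + 2 <= ci + 10
    }, logical(1)))
  }, logical(1)) |> as.integer()
}

# flag starts from the 8-of-10 rule, first-of-run retained
oracle_flags <- function(pred, start_s = seq_along(pred) - 1) {
  n <- length(pred)
  if (n < 10) return(numeric(0))
  flagged <- vapply(1:(n - 9), function(i) sum(pred[i:(i + 9)]) >= 8,
                    logical(1))
  keep <- which(flagged & !c(FALSE, head(flagged, -1)))
  start_s[keep]
}

# LTF decision for a single 10-segment window, straight from the rule text
oracle_ltf_window <- function(pred10, mask10, trust10, threshold = 0.7) {
  r <- sum(mask10)
  if (r < 5) {
    mean(pred10[!mask10]) > threshold
  } else {
    top5 <- order(-trust10, seq_len(10))[1:5]
    mean(pred10[top5]) > threshold
  }
}

oracle_ltf_flags <- function(pred, mask, trust, start_s = seq_along(pred) - 1) {
  n <- length(pred)
  if (n < 10) return(numeric(0))
  flagged <- vapply(1:(n - 9), function(i) {
    w <- i:(i + 9)
    oracle_ltf_window(pred[w], mask[w], trust[w])
  }, logical(1))
  keep <- which(flagged & !c(FALSE, head(flagged, -1)))
  start_s[keep]
}

# all-pairs nearest-neighbour trust score in a given projected space
oracle_trust_score <- function(x_proj, refs0, refs1, predicted) {
  dist_to <- function(R) min(sqrt(colSums((t(R) - x_proj)^2)))
  d0 <- dist_to(refs0)
  d1 <- dist_to(refs1)
  num <- if (predicted == 1) d0 else d1
  den <- if (predicted == 1) d1 else d0
  if (den == 0) {
    if (num > 0) Inf else 1
  } else num / den
}

# chained 10-s merging of false-positive flag starts
oracle_fp_merge <- function(starts, within_s = 10) {
  if (length(starts) == 0) return(0L)
  s <- sort(starts)
  groups <- 1L
  for (i in seq_along(s)[-1]) {
    if (s[i] - s[i - 1] > within_s) groups <- groups + 1L
  }
  groups
}

# Kendall tau by exhaustive concordant/discordant counting (no ties)
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- 0
  disc <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# small cohort used by several suites
tiny_cohort <- function(n_patients = 3, duration_s = 1800, seed = 1,
                        seizure_rate = 3,
                        fraction_patients_with_seizures = 1, ...) {
  generate_cohort(sim_config(
    n_patients = n_patients, duration_s = duration_s, seed = seed,
    seizure_rate = seizure_rate,
    fraction_patients_with_seizures = fraction_patients_with_seizures,
    seizure_duration_range = c(20, 60), ...
  ))
}
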