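#' Subsample a cohort for trust-model fitting
#'
#' Fitting a nearest-neighbour trust model on every 2-s segment of a
#' multi-day cohort is unnecessary and slow, so the reference data are
#' subsampled: all seizure-labelled segments are kept, and per patient
#' the non-seizure background is represented by one-minute windows
#' picked on a 15-min-spaced grid (each window contributing 30
#' non-overlapping 2-s segments).  Up to 100 windows are drawn uniformly
#' without replacement per patient; when fewer than 100 candidates exist
#' on the 15-min grid, the grid spacing falls back to 5 min, and if even
#' that yields fewer than 100 windows all of them are taken.  Candidate
#' windows never overlap an annotated event.
#'
#' @param cohort Cohort tibble (`patient_id`, `duration_s`, `events`,
#'   `features`).
#' @param regime Label regime ("ci" or "fs") used for the seizure class.
#' @param seed Integer seed making the draw reproducible.
#' @param windows_per_patient Number of one-minute windows to draw.
#' @param spacing_s,fallback_spacing_s Grid spacings in seconds.
#' @return A list with `features` (matrix), `labels` (0/1), `patient_id`
#'   and `start_s` vectors, one entry per subsampled 2-s segment.
#' @export
subsample_training_set <- function(cohort, regime = c("ci", "fs"),
                                   seed = 1L, windows_per_patient = 100L,
                                   spacing_s = 900, fallback_spacing_s = 300) {
  regime <- match.arg(regime)
  withr::with_seed(seed, {
    parts <- purrr::map(seq_len(nrow(cohort)), function(i) {
      subsample_patient(
        cohort$patient_id[i], cohort$duration_s[i], cohort$events[[i]],
        cohort$features[[i]], regime, windows_per_patient,
        spacing_s, fallback_spacing_s
      )
    })
  })
  list(
    features = do.call(rbind, purrr::map(parts, "features")),
    labels = unlist(purrr::map(parts, "labels")),
    patient_id = unlist(purrr::map(parts, "patient_id")),
    start_s = unlist(purrr::map(parts, "start_s"))
  )
}

subsample_patient <- function(id, duration_s, events, features, regime,
                              n_windows, spacing_s, fallback_spacing_s) {
  grid <- segment_grid(duration_s)
  lab <- derive_labels(events, duration_s, regime)$label

  candidate_windows <- function(spacing) {
    starts <- seq(0, duration_s - 60, by = spacing)
    if (nrow(events) > 0) {
      clear <- vapply(starts, function(s) {
        all(overlap_length(s, s + 60, events$onset_s, events$end_s) == 0)
      }, logical(1))
      starts <- starts[clear]
    }
    starts
  }
  cand <- candidate_windows(spacing_s)
  if (length(cand) < n_windows) cand <- candidate_windows(fallback_spacing_s)
  if (length(cand) == 0L) {
    abort(sprintf("patient %s has no seizure-free one-minute window.", id))
  }
  drawn <- sort(sample(cand, min(n_windows, length(cand))))
  nonseiz_starts <- as.vector(outer(seq(0, 58, by = 2), drawn, "+"))
  seiz_starts <- grid[lab == 1L]
  starts <- c(seiz_starts, nonseiz_starts)
  labels <- c(rep(1L, length(seiz_starts)), rep(0L, length(nonseiz_starts)))
  idx <- match(starts, grid)
  list(
    features = features[idx, , drop = FALSE],
    labels = labels,
    patient_id = rep(id, length(starts)),
    start_s = starts
  )
}

#' Fit a trust model: linear projection plus class reference sets
#'
#' Reduces the training features to (at most) 20 principal components
#' and stores the projected class members as reference point sets.  No
#' density-based filtering of the reference sets is applied: the
#' reference sets are the full projected classes.
#'
#' @param features Numeric matrix of training segments (typically the
#'   output of [subsample_training_set()]).
#' @param labels 0/1 labels; both classes must be present.
#' @param n_components Projection dimension (default 20; capped at the
#'   feature dimension).
#' @param regime Optional label-regime tag stored for bookkeeping.
#' @return An object of class `"trust_model"`.
#' @seealso [trust_score()], [score_series()]
#' @export
fit_trust_model <- function(features, labels, n_components = 20L,
                            regime = NA_character_) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    abort("trust-model fitting requires both classes in the subsample.")
  }
  k <- min(n_components, ncol(X), nrow(X) - 1L)
  pca <- prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  proj <- pca$x[, seq_len(k), drop = FALSE]
  structure(
    list(
      rotation = pca$rotation[, seq_len(k), drop = FALSE],
      center = pca$center,
      sdev = pca$sdev[seq_len(k)],
      n_components = k,
      class0 = proj[y == 0L, , drop = FALSE],
      class1 = proj[y == 1L, , drop = FALSE],
      regime = regime
    ),
    class = "trust_model"
  )
}

#' @export
print.trust_model <- function(x, ...) {
  cat("Trust model (projection + nearest-neighbour reference sets)\n")
  cat(sprintf("  %d components; reference sets: %d non-seizure, %d seizure; regime %s\n",
              x$n_components, nrow(x$class0), nrow(x$class1), x$regime))
  invisible(x)
}

project_points <- function(model, features) {
  X <- as.matrix(features)
  sweep(X, 2, model$center) %*% model$rotation
}

#' Trust score of a single prediction
#'
#' The trust score of a test point is its Euclidean distance (in the
#' projected space) to the closest reference point of the *other* class,
#' divided by the distance to the closest reference point of the
#' *predicted* class.  Scores above 1 mean the point looks typical for
#' its predicted class; low scores mark atypical, untrustworthy
#' predictions.  If the point coincides with a reference point of its
#' predicted class the score is `+Inf` (or 1 when it also coincides
#' with a point of the other class).
#'
#' @param model A `"trust_model"`.
#' @param x A single feature vector (original feature space).
#' @param predicted The classifier's predicted class for `x` (0 or 1).
#' @return A positive scalar.
#' @export
#' @examples
#' m <- fit_trust_model(matrix(c(0, 10), ncol = 1), c(0, 1), n_components = 1)
#' trust_score(m, 2, predicted = 0) # 8 / 2 = 4
trust_score <- function(model, x, predicted) {
  score_series(model, matrix(x, nrow = 1), predicted)
}

#' Trust scores for a series of segments
#'
#' Vectorized [trust_score()] over all 2-s segments of a recording,
#' evaluated against each segment's predicted class.
#'
#' @param model A `"trust_model"`.
#' @param features Feature matrix, one row per segment.
#' @param predictions 0/1 predicted class per segment (length 1 is
#'   recycled).
#' @param chunk Rows per block in the chunked nearest-neighbour search.
#' @return Numeric vector of positive trust scores.
#' @export
score_series <- function(model, features, predictions, chunk = 4096L) {
  stopifnot(inherits(model, "trust_model"))
  X <- as.matrix(features)
  if (length(predictions) == 1L) {
    predictions <- rep(predictions, nrow(X))
  }
  if (length(predictions) != nrow(X)) {
    abort("`predictions` must have one entry per segment.")
  }
  proj <- project_points(model, X)
  d0 <- sqrt(min_dist_sq(proj, model$class0, chunk))
  d1 <- sqrt(min_dist_sq(proj, model$class1, chunk))
  num <- ifelse(predictions == 1L, d0, d1)
  den <- ifelse(predictions == 1L, d1, d0)
  out <- num / den
  zero_den <- den == 0
  out[zero_den & num > 0] <- Inf
  out[zero_den & num == 0] <- 1
  out
}
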