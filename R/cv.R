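#' Patient-independent per-segment predictions for a whole cohort
#'
#' Leave-one-patient-out training loop: for every patient, a margin
#' classifier is trained on a subsample of all *other* patients
#' (all their seizure-labelled segments plus drawn background windows,
#' see [subsample_training_set()]) and applied to every 2-s segment of
#' the held-out patient.  No patient's predictions ever come from a
#' model that saw their own data.
#'
#' @param cohort Cohort tibble.
#' @param regime Label regime used to train the classifier ("ci" or
#'   "fs").
#' @param seed Integer seed (subsampling only; the fit itself is
#'   deterministic).
#' @param lambda L2 penalty for [train_classifier()].
#' @param windows_per_patient Background windows per patient in the
#'   training subsample.
#' @return A tibble with `patient_id`, `distances` and `predictions`
#'   list-columns (one numeric/integer vector per patient, aligned with
#'   [segment_grid()]).
#' @export
classify_cohort <- function(cohort, regime = c("ci", "fs"), seed = 1L,
                            lambda = 1e-3, windows_per_patient = 100L) {
  regime <- match.arg(regime)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    sub <- subsample_training_set(cohort[-i, ], regime, seed = seed + i,
                                  windows_per_patient = windows_per_patient)
    model <- train_classifier(sub$features, sub$labels, regime = regime,
                              lambda = lambda)
    d <- decision_distance(model, cohort$features[[i]])
    tibble(patient_id = cohort$patient_id[i],
           distances = list(d), predictions = list(as.integer(d > 0)))
  })
  dplyr::bind_rows(rows)
}

# per-patient seizure load (number of complete 10-s seizure blocks) and
# recording days, used to balance folds
patient_load <- function(cohort) {
  tibble(
    patient_id = cohort$patient_id,
    seizure_segments_10s = vapply(cohort$events, function(ev) {
      if (nrow(ev) == 0L) return(0)
      sum(floor((ev$end_s - ev$onset_s) / 10))
    }, numeric(1)),
    days = cohort$duration_s / 86400
  )
}

#' Randomly partition patients into balanced folds
#'
#' Rejection-samples random partitions of the cohort into `n_folds`
#' folds of (near-)equal patient count until every fold's seizure load
#' and recording time fall inside the given bounds.  Default bounds are
#' the clinical fold-balance bounds (65-96 ten-second seizure segments
#' and 23.1-48.6 days per fold of a 6-fold, 490-segment, 220-day
#' cohort) rescaled to this cohort's totals.
#'
#' @param cohort Cohort tibble.
#' @param n_folds Number of folds (default 6).
#' @param seizure_bounds,days_bounds Length-2 numeric bounds per fold;
#'   `NULL` for rescaled defaults.
#' @param seed Integer seed.
#' @param max_attempts Attempt budget before giving up with an error.
#' @return A list of class `"fold_plan"`: `folds` (list of patient-id
#'   vectors), `summary` (per-fold loads), `attempts`.
#' @export
make_folds <- function(cohort, n_folds = 6L, seizure_bounds = NULL,
                       days_bounds = NULL, seed = 1L, max_attempts = 1000L) {
  load <- patient_load(cohort)
  n <- nrow(load)
  if (n_folds < 2L || n_folds > n) abort("invalid `n_folds`.")
  per_fold_seiz <- sum(load$seizure_segments_10s) / n_folds
  per_fold_days <- sum(load$days) / n_folds
  seizure_bounds <- seizure_bounds %||%
    (c(65, 96) / (490 / 6) * per_fold_seiz)
  days_bounds <- days_bounds %||% (c(23.1, 48.6) / (220 / 6) * per_fold_days)
  fold_sizes <- rep(n %/% n_folds, n_folds) +
    c(rep(1L, n %% n_folds), rep(0L, n_folds - n %% n_folds))
  withr::with_seed(seed, {
    for (attempt in seq_len(max_attempts)) {
      perm <- sample.int(n)
      fold_of <- rep(seq_len(n_folds), times = fold_sizes)
      folds <- split(load$patient_id[perm], fold_of)
      summ <- purrr::map2(folds, seq_along(folds), function(ids, k) {
        sub <- load[load$patient_id %in% ids, ]
        tibble(fold = k, n_patients = length(ids),
               seizure_segments_10s = sum(sub$seizure_segments_10s),
               days = sum(sub$days))
      }) |> dplyr::bind_rows()
      ok <- all(summ$seizure_segments_10s >= seizure_bounds[1] &
                  summ$seizure_segments_10s <= seizure_bounds[2] &
                  summ$days >= days_bounds[1] & summ$days <= days_bounds[2])
      if (ok) {
        return(structure(
          list(folds = unname(folds), summary = summ, attempts = attempt,
               seizure_bounds = seizure_bounds, days_bounds = days_bounds),
          class = "fold_plan"
        ))
      }
    }
  })
  abort(sprintf(
    "no fold plan satisfying the balance bounds found in %d attempts.",
    max_attempts
  ))
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Fold plan: %d folds (accepted after %d attempt(s))\n",
              length(x$folds), x$attempts))
  print(x$summary)
  invisible(x)
}

# arrange the non-test folds into two inner half-cohorts: merge fold
# pairs, split the leftover fold in half (balancing seizure load
# greedily) and attach one half to each side
inner_halves <- function(rem_folds, load) {
  seiz_of <- function(ids) {
    sum(load$seizure_segments_10s[load$patient_id %in% ids])
  }
  m <- length(rem_folds)
  if (m %% 2L == 0L) {
    half <- m %/% 2L
    a <- unlist(rem_folds[seq_len(half)])
    b <- unlist(rem_folds[half + seq_len(half)])
    return(list(a = a, b = b))
  }
  pair_count <- (m - 1L) %/% 2L
  a <- unlist(rem_folds[seq_len(pair_count)])
  b <- unlist(rem_folds[pair_count + seq_len(pair_count)])
  leftover <- rem_folds[[m]]
  # greedy split of the leftover fold: walk patients by decreasing
  # seizure load, always adding to the lighter half (sizes kept within 1)
  ids <- leftover[order(-vapply(leftover, seiz_of, numeric(1)))]
  h1 <- character(0)
  h2 <- character(0)
  for (p in ids) {
    if (length(h1) > length(h2)) {
      h2 <- c(h2, p)
    } else if (length(h2) > length(h1)) {
      h1 <- c(h1, p)
    } else if (seiz_of(h1) <= seiz_of(h2)) {
      h1 <- c(h1, p)
    } else {
      h2 <- c(h2, p)
    }
  }
  # attach the seizure-heavier half to the seizure-lighter side
  if (seiz_of(a) <= seiz_of(b)) {
    list(a = c(a, if (seiz_of(h1) >= seiz_of(h2)) h1 else h2),
         b = c(b, if (seiz_of(h1) >= seiz_of(h2)) h2 else h1))
  } else {
    list(a = c(a, if (seiz_of(h1) >= seiz_of(h2)) h2 else h1),
         b = c(b, if (seiz_of(h1) >= seiz_of(h2)) h1 else h2))
  }
}

ltf_f1_for_grid <- function(cohort, predictions, ids, trust_model, q_grid) {
  rows <- purrr::map(ids, function(pid) {
    i <- match(pid, cohort$patient_id)
    j <- match(pid, predictions$patient_id)
    pred <- predictions$predictions[[j]]
    grid <- segment_grid(cohort$duration_s[i])
    sc <- score_series(trust_model, cohort$features[[i]], pred)
    purrr::map(q_grid, function(q) {
      fl <- ltf_flags(pred, mark_untrustworthy(sc, q), sc, grid)
      m <- patient_metrics(fl, cohort$events[[i]], cohort$duration_s[i], pid)
      tibble(patient_id = pid, q = q, f1 = m$f1)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Nested cross-validation for trust-based low-trust filtering
#'
#' Chooses the percentage `q` of lowest-trust segments to filter
#' without ever letting a test patient influence the choice.  For each
#' test fold the remaining folds are rearranged into two inner
#' half-cohorts; a trust model is fitted on one half and the `q`
#' maximising the patient-averaged F1 score is found on the other half,
#' and vice versa.  The test-fold `q` is the mean of the two inner
#' optima (it may fall off-grid and is applied as-is).  Final test
#' predictions for each patient use a trust model fitted on all other
#' patients of the cohort.
#'
#' @param cohort Cohort tibble.
#' @param predictions Output of [classify_cohort()].
#' @param trust_regime Label regime for trust-model fitting.
#' @param q_grid Candidate filtering fractions (default 0, 0.01, ...,
#'   0.20).
#' @param fold_plan Optional [make_folds()] result; built with default
#'   bounds when `NULL`.
#' @param n_folds,seed,... Passed to [make_folds()] /
#'   [subsample_training_set()] when needed.
#' @param n_components Trust-model projection dimension.
#' @param windows_per_patient Background windows per patient for trust
#'   subsampling.
#' @return An object of class `"ltf_cv"`: a list with `fold_plan`,
#'   `chosen_q` (per-fold inner optima and test value), and `metrics`
#'   (per-patient baseline and LTF rows).
#' @export
nested_cv_ltf <- function(cohort, predictions, trust_regime = c("fs", "ci"),
                          q_grid = seq(0, 0.20, by = 0.01),
                          fold_plan = NULL, n_folds = 6L, seed = 1L,
                          n_components = 20L, windows_per_patient = 100L,
                          ...) {
  trust_regime <- match.arg(trust_regime)
  if (length(q_grid) == 0L) abort("`q_grid` must be non-empty.")
  fold_plan <- fold_plan %||%
    make_folds(cohort, n_folds = n_folds, seed = seed, ...)
  load <- patient_load(cohort)
  folds <- fold_plan$folds

  pick_q <- function(f1_tbl) {
    by_q <- f1_tbl |>
      dplyr::group_by(.data$q) |>
      dplyr::summarise(f1 = mean(.data$f1, na.rm = TRUE), .groups = "drop")
    if (all(is.nan(by_q$f1))) return(min(f1_tbl$q))
    by_q$q[which.max(by_q$f1)]
  }

  chosen <- list()
  metric_rows <- list()
  for (t in seq_along(folds)) {
    halves <- inner_halves(folds[-t], load)
    inner_q <- purrr::map2_dbl(
      list(halves$a, halves$b), list(halves$b, halves$a),
      function(fit_ids, val_ids) {
        sub <- subsample_training_set(
          cohort[cohort$patient_id %in% fit_ids, ], trust_regime,
          seed = seed, windows_per_patient = windows_per_patient
        )
        tm <- fit_trust_model(sub$features, sub$labels, n_components,
                              trust_regime)
        pick_q(ltf_f1_for_grid(cohort, predictions, val_ids, tm, q_grid))
      }
    )
    q_t <- mean(inner_q)
    chosen[[t]] <- tibble(fold = t, q_inner_a = inner_q[1],
                          q_inner_b = inner_q[2], q_test = q_t)
    for (pid in folds[[t]]) {
      i <- match(pid, cohort$patient_id)
      j <- match(pid, predictions$patient_id)
      pred <- predictions$predictions[[j]]
      grid <- segment_grid(cohort$duration_s[i])
      sub <- subsample_training_set(
        cohort[cohort$patient_id != pid, ], trust_regime, seed = seed,
        windows_per_patient = windows_per_patient
      )
      tm <- fit_trust_model(sub$features, sub$labels, n_components,
                            trust_regime)
      sc <- score_series(tm, cohort$features[[i]], pred)
      base <- patient_metrics(seizure_flags(pred, grid),
                              cohort$events[[i]], cohort$duration_s[i], pid)
      ltf <- patient_metrics(
        ltf_flags(pred, mark_untrustworthy(sc, q_t), sc, grid),
        cohort$events[[i]], cohort$duration_s[i], pid
      )
      metric_rows[[length(metric_rows) + 1L]] <- dplyr::bind_rows(
        dplyr::mutate(base, model = "baseline", fold = t, q = 0),
        dplyr::mutate(ltf, model = "ltf", fold = t, q = q_t)
      )
    }
  }
  structure(
    list(
      fold_plan = fold_plan,
      chosen_q = dplyr::bind_rows(chosen),
      metrics = dplyr::bind_rows(metric_rows),
      trust_regime = trust_regime,
      q_grid = q_grid
    ),
    class = "ltf_cv"
  )
}

#' @export
print.ltf_cv <- function(x, ...) {
  cat(sprintf("Nested CV for low-trust filtering (trust regime %s)\n",
              x$trust_regime))
  print(x$chosen_q)
  print(glance(x))
  invisible(x)
}

#' Leave-one-patient-out grid search for confidence-based filtering
#'
#' For filtering driven by the classifier's own confidence there is no
#' trust model to fit, so a plain leave-one-patient-out search is used:
#' for each held-out patient the temperature `a` and filtering fraction
#' `q` maximising the patient-averaged F1 over all other patients are
#' selected and applied to the held-out patient.  Because the
#' confidence ranking is invariant to `a`, the selected `q` (and the
#' resulting flags) cannot depend on `a`; the raw-distance mode
#' (`raw_distance = TRUE`) skips temperature scaling entirely and gives
#' the same filtering decisions.
#'
#' @param cohort Cohort tibble.
#' @param predictions Output of [classify_cohort()] (its `distances`
#'   are used).
#' @param a_grid Positive temperatures to search.
#' @param q_grid Candidate filtering fractions.
#' @param raw_distance Use `|d|` directly instead of `|p_a - 0.5|`.
#' @return An object of class `"lopo_cv"`: list with `metrics`
#'   (per-patient baseline and LTF rows) and `chosen` (per-patient `a`,
#'   `q`).
#' @export
lopo_cv_svmconf <- function(cohort, predictions,
                            a_grid = c(0.1, 1, 10),
                            q_grid = seq(0, 0.20, by = 0.01),
                            raw_distance = FALSE) {
  if (length(q_grid) == 0L || length(a_grid) == 0L) {
    abort("grids must be non-empty.")
  }
  n <- nrow(cohort)
  conf_of <- function(d, a) {
    if (raw_distance) abs(d) else svm_confidence(temperature_scale(d, a))
  }
  # F1 of every (patient, a, q) cell, computed once
  cells <- purrr::map(seq_len(n), function(i) {
    j <- match(cohort$patient_id[i], predictions$patient_id)
    d <- predictions$distances[[j]]
    pred <- predictions$predictions[[j]]
    grid <- segment_grid(cohort$duration_s[i])
    purrr::map(a_grid, function(a) {
      cf <- conf_of(d, a)
      purrr::map(q_grid, function(q) {
        fl <- ltf_flags(pred, mark_untrustworthy(cf, q), cf, grid)
        m <- patient_metrics(fl, cohort$events[[i]], cohort$duration_s[i],
                             cohort$patient_id[i])
        dplyr::mutate(m, a = a, q = q)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  all_cells <- dplyr::bind_rows(cells)
  rows <- purrr::map(seq_len(n), function(i) {
    pid <- cohort$patient_id[i]
    others <- all_cells |>
      dplyr::filter(.data$patient_id != pid) |>
      dplyr::group_by(.data$a, .data$q) |>
      dplyr::summarise(f1 = mean(.data$f1, na.rm = TRUE), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$f1), .data$q, .data$a)
    best <- others[1, ]
    held <- all_cells |>
      dplyr::filter(.data$patient_id == pid, .data$a == best$a,
                    .data$q == best$q)
    j <- match(pid, predictions$patient_id)
    base <- patient_metrics(
      seizure_flags(predictions$predictions[[j]],
                    segment_grid(cohort$duration_s[i])),
      cohort$events[[i]], cohort$duration_s[i], pid
    )
    dplyr::bind_rows(
      dplyr::mutate(base, model = "baseline", a = NA_real_, q = 0),
      dplyr::mutate(held, model = "ltf_svmconf")
    )
  })
  structure(
    list(metrics = dplyr::bind_rows(rows),
         chosen = dplyr::bind_rows(rows) |>
           dplyr::filter(.data$model == "ltf_svmconf") |>
           dplyr::select("patient_id", "a", "q"),
         raw_distance = raw_distance),
    class = "lopo_cv"
  )
}
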