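#' Simulation configuration for a synthetic seizure-monitoring cohort
#'
#' Builds the configuration object consumed by [generate_cohort()].  The
#' generator emulates the statistical structure that the post-processing
#' pipeline assumes: long multi-day (or multi-hour) recordings cut into
#' 2-s segments at a 1-s hop, heavy class imbalance, a designated 10-s
#' clear-ictal window inside every seizure, and intermittent artifact
#' bursts whose feature values are atypical for both classes (they sit
#' off both class means along the amplitude/frequency proxy axes) while
#' still falling on the seizure side of the decision boundary, so that
#' they produce false positives that trust scores can filter out.
#'
#' Features are class-conditional Gaussian with identity covariance.
#' Feature 1 is reserved as an "amplitude" proxy and feature 2 as a
#' "frequency-change" proxy; the class-separation direction spans the
#' remaining features, so the clear-ictal selection rule operates on
#' proxies that are not confounded with the bulk separation.
#'
#' @param preset `"desk"` (12 patients x 6 h, the default, sized for
#'   laptop-scale runs) or `"full"` (54 patients, 42 with seizures,
#'   4 days each, mirroring the shape of the clinical cohort the method
#'   was developed on).
#' @param n_patients Number of patients.
#' @param duration_s Recording length per patient in seconds (recycled
#'   across patients; must be >= 600).
#' @param seizure_rate Expected number of seizure events per patient
#'   with seizures (Poisson).
#' @param seizure_duration_range Length-2 numeric, uniform range of
#'   seizure durations in seconds; minimum >= 10.
#' @param fraction_patients_with_seizures Proportion of patients that
#'   have any seizures, in `[0, 1]`.
#' @param feature_dim Number of features per 2-s segment (default 67).
#' @param class_separation Euclidean distance between the seizure and
#'   non-seizure feature means, in within-class standard deviations.
#' @param artifact_rate Expected artifact bursts per 24 h of recording.
#' @param artifact_duration_s Length of one artifact burst in seconds.
#' @param artifact_shift Displacement of the artifact feature
#'   distribution from both class means (along the proxy axes).
#' @param artifact_duty Fraction of each 5-s artifact cycle that is
#'   contaminated: bursts are rhythmic (as chewing/movement artifacts
#'   are), alternating contaminated and clean seconds, so flagged
#'   artifact windows retain a couple of clean, well-trusted
#'   non-seizure predictions.
#' @param clear_ictal_boost Amplitude/frequency proxy elevation (in SD
#'   units) inside the clear-ictal part of a seizure.
#' @param seed Integer seed; [generate_cohort()] is deterministic given
#'   the config (including the seed).
#' @return A list of class `"sim_config"`.
#' @seealso [generate_cohort()]
#' @export
sim_config <- function(preset = c("desk", "full"),
                       n_patients = NULL,
                       duration_s = NULL,
                       seizure_rate = NULL,
                       seizure_duration_range = c(20, 120),
                       fraction_patients_with_seizures = 42 / 54,
                       feature_dim = 67,
                       class_separation = 4,
                       artifact_rate = 10,
                       artifact_duration_s = 30,
                       artifact_shift = 6,
                       artifact_duty = 0.8,
                       clear_ictal_boost = 3,
                       seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    n_patients <- n_patients %||% 12L
    duration_s <- duration_s %||% (6 * 3600)
    seizure_rate <- seizure_rate %||% 2.5
  } else {
    n_patients <- n_patients %||% 54L
    duration_s <- duration_s %||% (4 * 86400)
    seizure_rate <- seizure_rate %||% (114 / 42)
  }
  cfg <- list(
    preset = preset,
    n_patients = as.integer(n_patients),
    duration_s = as.integer(duration_s),
    seizure_rate = seizure_rate,
    seizure_duration_range = as.numeric(seizure_duration_range),
    fraction_patients_with_seizures = fraction_patients_with_seizures,
    feature_dim = as.integer(feature_dim),
    class_separation = class_separation,
    artifact_rate = artifact_rate,
    artifact_duration_s = artifact_duration_s,
    artifact_shift = artifact_shift,
    artifact_duty = artifact_duty,
    clear_ictal_boost = clear_ictal_boost,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_patients < 1L) abort("`n_patients` must be >= 1.")
    if (any(duration_s < 600)) abort("`duration_s` must be >= 600 s.")
    if (seizure_rate < 0 || artifact_rate < 0) {
      abort("rates must be >= 0.")
    }
    if (length(seizure_duration_range) != 2L ||
        seizure_duration_range[1] < 10 ||
        seizure_duration_range[2] < seizure_duration_range[1] ||
        seizure_duration_range[2] >= min(duration_s)) {
      abort("`seizure_duration_range` must be [min, max] with min >= 10 and max < duration_s.")
    }
    check_fraction(fraction_patients_with_seizures,
                   "fraction_patients_with_seizures")
    check_fraction(artifact_duty, "artifact_duty")
    if (feature_dim < 3L) abort("`feature_dim` must be >= 3 (features 1-2 are proxies).")
    if (artifact_duration_s <= 0) abort("`artifact_duration_s` must be > 0.")
  })
  invisible(cfg)
}

# class mean geometry shared by the generator and documented in the vignette:
# m0 = 0; m1 = class_separation along a unit vector spanning features 3..p;
# artifact mean = m1 + artifact_shift / sqrt(2) * (e1 + e2), i.e. exactly
# artifact_shift away from the seizure mean (and further from the
# non-seizure mean) along the amplitude/frequency proxy axes: contaminated
# segments are confidently predicted ictal yet atypical for both classes
sim_means <- function(cfg) {
  p <- cfg$feature_dim
  u <- c(0, 0, rep(1 / sqrt(p - 2), p - 2))
  m1 <- cfg$class_separation * u
  m_art <- m1
  m_art[1:2] <- m_art[1:2] + cfg$artifact_shift / sqrt(2)
  list(m0 = rep(0, p), m1 = m1, m_art = m_art)
}

#' Generate a synthetic multi-patient cohort
#'
#' Draws per-patient seizure events, clear-ictal windows, artifact
#' bursts and the full 2-s segment feature series, deterministically
#' given the config seed.  See [sim_config()] for the data model.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with one row per patient and columns
#'   `patient_id`, `duration_s`, `events` (list of tibbles with
#'   `onset_s`, `end_s`, `clear_ictal_start_s`, `mechanism`),
#'   `features` (list of numeric matrices, one row per 2-s segment on
#'   [segment_grid()]), and `artifacts` (list of tibbles with
#'   `start_s`, `end_s`).
#' @export
#' @examples
#' cohort <- generate_cohort(sim_config(n_patients = 2, duration_s = 900,
#'                                      seed = 7))
#' nrow(cohort$features[[1]]) # 899 segments
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  validate_sim_config(config)
  withr::with_seed(config$seed, {
    n <- config$n_patients
    durations <- rep_len(config$duration_s, n)
    n_sz <- round(config$fraction_patients_with_seizures * n)
    sz_ids <- sort(sample.int(n, n_sz))
    ids <- sprintf("P%02d", seq_len(n))
    rows <- purrr::map(seq_len(n), function(i) {
      simulate_patient(config, ids[i], durations[i], i %in% sz_ids)
    })
    dplyr::bind_rows(rows)
  })
}

simulate_patient <- function(cfg, id, duration_s, has_seizures) {
  events <- draw_events(cfg, duration_s, has_seizures)
  artifacts <- draw_artifacts(cfg, duration_s, events)
  features <- draw_features(cfg, duration_s, events, artifacts)
  tibble(
    patient_id = id,
    duration_s = as.numeric(duration_s),
    events = list(events),
    features = list(features),
    artifacts = list(artifacts)
  )
}

draw_events <- function(cfg, duration_s, has_seizures) {
  empty <- tibble(onset_s = numeric(), end_s = numeric(),
                  clear_ictal_start_s = numeric(), mechanism = character())
  if (!has_seizures || cfg$seizure_rate == 0) return(empty)
  k <- rpois(1L, cfg$seizure_rate)
  if (k == 0L) return(empty)
  durs <- runif(k, cfg$seizure_duration_range[1], cfg$seizure_duration_range[2])
  durs <- round(durs)
  if (sum(durs) >= 0.5 * duration_s) {
    abort(paste0(
      "drawn seizure time is >= 50% of the recording for one patient; ",
      "this imbalance regime is outside what the pipeline assumes. ",
      "Lower `seizure_rate` or `seizure_duration_range`."
    ))
  }
  # greedy non-overlapping placement with a 120-s guard between events
  onsets <- numeric(0)
  ends <- numeric(0)
  attempts <- 0L
  for (d in durs) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 1000L) break
      cand <- round(runif(1, 60, duration_s - d - 60))
      ok <- all(cand >= ends + 120 | cand + d <= onsets - 120)
      if (ok) {
        onsets <- c(onsets, cand)
        ends <- c(ends, cand + d)
        break
      }
    }
    if (attempts > 1000L) break
  }
  o <- order(onsets)
  onsets <- onsets[o]
  ends <- ends[o]
  k <- length(onsets)
  mech <- sample(c("amplitude", "frequency", "none"), k, replace = TRUE,
                 prob = c(0.7, 0.2, 0.1))
  ci <- vapply(seq_len(k), function(i) {
    if (mech[i] == "none") return(onsets[i])
    max_off <- min(20, (ends[i] - onsets[i]) - 10)
    onsets[i] + sample.int(max_off + 1L, 1L) - 1L
  }, numeric(1))
  tibble(onset_s = onsets, end_s = ends,
         clear_ictal_start_s = ci, mechanism = mech)
}

draw_artifacts <- function(cfg, duration_s, events) {
  empty <- tibble(start_s = numeric(), end_s = numeric())
  if (cfg$artifact_rate == 0) return(empty)
  k <- rpois(1L, cfg$artifact_rate * duration_s / 86400)
  if (k == 0L) return(empty)
  len <- cfg$artifact_duration_s
  starts <- numeric(0)
  attempts <- 0L
  while (length(starts) < k && attempts < 1000L) {
    attempts <- attempts + 1L
    cand <- round(runif(1, 0, duration_s - len))
    hits_event <- nrow(events) > 0 &&
      any(overlap_length(cand, cand + len, events$onset_s, events$end_s) > 0)
    hits_other <- length(starts) > 0 &&
      any(overlap_length(cand, cand + len, starts, starts + len) > 0)
    if (!hits_event && !hits_other) starts <- c(starts, cand)
  }
  starts <- sort(starts)
  tibble(start_s = starts, end_s = starts + len)
}

draw_features <- function(cfg, duration_s, events, artifacts) {
  grid <- segment_grid(duration_s)
  n <- length(grid)
  p <- cfg$feature_dim
  mu <- sim_means(cfg)
  X <- matrix(rnorm(n * p), nrow = n, ncol = p)
  colnames(X) <- sprintf("f%02d", seq_len(p))

  # seizure segments: >= 1 s overlap with an event (same rule as FS labels)
  if (nrow(events) > 0) {
    sz <- fs_label_vector(grid, events)
    X[sz == 1L, ] <- X[sz == 1L, , drop = FALSE] +
      matrix(mu$m1, nrow = sum(sz), ncol = p, byrow = TRUE)
    # clear-ictal proxy elevation from the clear-ictal start to seizure end
    for (i in seq_len(nrow(events))) {
      if (events$mechanism[i] == "none") next
      feat <- if (events$mechanism[i] == "amplitude") 1L else 2L
      hit <- grid + 1 >= events$clear_ictal_start_s[i] &
        grid + 1 <= events$end_s[i]  # segment midpoint inside boosted span
      X[hit, feat] <- X[hit, feat] + cfg$clear_ictal_boost
    }
  }

  # artifact bursts overwrite non-seizure segments (label stays 0) with a
  # distribution displaced from both class means; bursts are rhythmic,
  # cycling `5 * artifact_duty` contaminated seconds then clean seconds
  if (nrow(artifacts) > 0) {
    for (i in seq_len(nrow(artifacts))) {
      inside <- which(grid + 1 >= artifacts$start_s[i] &
                        grid + 1 <= artifacts$end_s[i])
      offset <- (grid[inside] + 1 - artifacts$start_s[i]) %% 5
      hit <- inside[offset < 5 * cfg$artifact_duty]
      if (length(hit) > 0) {
        X[hit, ] <- matrix(rnorm(length(hit) * p), ncol = p) +
          matrix(mu$m_art, nrow = length(hit), ncol = p, byrow = TRUE)
      }
    }
  }
  X
}

#' Write / read a cohort as plain-text files
#'
#' One feature CSV per patient (one row per 2-s segment) plus a single
#' annotation CSV `annotations.csv` with columns
#' `patient_id,onset_s,end_s,clear_ictal_start_s` and a `recordings.csv`
#' with per-patient durations.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a cohort tibble (without the simulation-only `artifacts`
#'   and `mechanism` columns).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort |>
    dplyr::select("patient_id", "events") |>
    tidyr::unnest("events")
  ann$mechanism <- NULL
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  utils::write.csv(
    cohort |> dplyr::select("patient_id", "duration_s"),
    file.path(dir, "recordings.csv"), row.names = FALSE
  )
  purrr::walk2(cohort$patient_id, cohort$features, function(id, X) {
    utils::write.csv(as.data.frame(X),
                     file.path(dir, paste0(id, "_features.csv")),
                     row.names = FALSE)
  })
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rec <- utils::read.csv(file.path(dir, "recordings.csv"),
                         stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"),
                         stringsAsFactors = FALSE)
  rows <- purrr::map(seq_len(nrow(rec)), function(i) {
    id <- rec$patient_id[i]
    X <- as.matrix(utils::read.csv(file.path(dir, paste0(id, "_features.csv"))))
    ev <- ann[ann$patient_id == id,
              c("onset_s", "end_s", "clear_ictal_start_s"), drop = FALSE]
    tibble(patient_id = id, duration_s = rec$duration_s[i],
           events = list(as_tibble(ev)), features = list(X))
  })
  dplyr::bind_rows(rows)
}
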