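#' Experiment configuration
#'
#' Bundles every choice of a full synthetic-cohort experiment: the
#' cohort simulation, the label regimes for classifier and trust model
#' (the 2 x 2 comparison), the deferral settings and the CV grids.
#' Every stochastic step derives its seed from `seed`, so two runs with
#' the same config are identical.
#'
#' @param sim A [sim_config()].
#' @param classifier_regimes,trust_regimes Label regimes to cross.
#' @param p_low Percentage of lowest-confidence 2-s segments averaged
#'   per deferral segment (the reporting default is 5).
#' @param defer_fractions Fractions swept by [deferral_curve()].
#' @param q_grid,a_grid CV grids for the filtering fraction and the
#'   temperature.
#' @param n_folds Folds for [nested_cv_ltf()].
#' @param do_ltf_cv,do_lopo_svmconf,do_deferral,do_random_baseline,do_krcc
#'   Stage switches (the CV stages dominate the runtime).
#' @param krcc_max_segments Per-patient segment cap when computing the
#'   Kendall rank correlation (it is quadratic in the series length).
#' @param seed Master seed.
#' @param ... Extra arguments stored as-is (e.g. fold bounds).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = sim_config(),
                       classifier_regimes = c("ci", "fs"),
                       trust_regimes = c("ci", "fs"),
                       p_low = 5,
                       defer_fractions = seq(0, 1, by = 0.1),
                       q_grid = seq(0, 0.2, by = 0.01),
                       a_grid = c(0.1, 1, 10),
                       n_folds = 6L,
                       do_ltf_cv = TRUE,
                       do_lopo_svmconf = FALSE,
                       do_deferral = TRUE,
                       do_random_baseline = FALSE,
                       do_krcc = TRUE,
                       krcc_max_segments = 5000L,
                       seed = 1L,
                       ...) {
  structure(
    c(list(
      sim = sim, classifier_regimes = classifier_regimes,
      trust_regimes = trust_regimes, p_low = p_low,
      defer_fractions = defer_fractions, q_grid = q_grid, a_grid = a_grid,
      n_folds = n_folds, do_ltf_cv = do_ltf_cv,
      do_lopo_svmconf = do_lopo_svmconf, do_deferral = do_deferral,
      do_random_baseline = do_random_baseline, do_krcc = do_krcc,
      krcc_max_segments = krcc_max_segments, seed = as.integer(seed)
    ), list(...)),
    class = "run_config"
  )
}

#' Write / read a run configuration
#'
#' YAML when the `yaml` package is installed, JSON otherwise (the
#' format is chosen from the file extension).  Configs round-trip
#' losslessly.
#'
#' @param config A [run_config()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_run_config()` returns the `"run_config"` object.
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  plain$sim <- unclass(config$sim)
  if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required for YAML configs.")
    }
    yaml::write_yaml(plain, path, precision = 15L)
  } else {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  plain <- if (grepl("[.]ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the yaml package is required for YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sim <- do.call(sim_config, plain$sim[setdiff(names(plain$sim), "preset")])
  sim$preset <- plain$sim$preset
  plain$sim <- NULL
  do.call(run_config, c(list(sim = sim), plain))
}

#' Run a full synthetic-cohort experiment
#'
#' End-to-end orchestration: simulate the cohort, produce
#' patient-independent predictions for each classifier regime, run the
#' nested-CV low-trust-filtering comparison for each classifier x trust
#' regime pair, sweep the deferral curves (flags-first and, optionally,
#' the score-only and random-baseline variants) and compute the
#' confidence/trust ranking agreement.
#'
#' @param config A [run_config()].
#' @return A list of class `"seizure_experiment"` with elements
#'   `cohort`, `predictions`, `ltf` (named by "clf_trust" regime pair),
#'   `lopo_svmconf`, `deferral` (named by regime and score type),
#'   `krcc`, plus the `config`, its hash and the seed.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- generate_cohort(config$sim)
  out <- list(config = config, config_hash = rlang::hash(unclass(config)),
              seed = seed, cohort = cohort)

  out$predictions <- purrr::map(
    rlang::set_names(config$classifier_regimes),
    function(rg) classify_cohort(cohort, rg, seed = seed)
  )

  if (isTRUE(config$do_ltf_cv)) {
    combos <- expand.grid(clf = config$classifier_regimes,
                          trust = config$trust_regimes,
                          stringsAsFactors = FALSE)
    out$ltf <- purrr::map(
      rlang::set_names(seq_len(nrow(combos)),
                       paste(combos$clf, combos$trust, sep = "_")),
      function(k) {
        nested_cv_ltf(cohort, out$predictions[[combos$clf[k]]],
                      trust_regime = combos$trust[k],
                      q_grid = config$q_grid, n_folds = config$n_folds,
                      seed = seed,
                      seizure_bounds = config$seizure_bounds,
                      days_bounds = config$days_bounds)
      }
    )
  }

  if (isTRUE(config$do_lopo_svmconf)) {
    out$lopo_svmconf <- purrr::map(
      rlang::set_names(config$classifier_regimes),
      function(rg) {
        lopo_cv_svmconf(cohort, out$predictions[[rg]],
                        a_grid = config$a_grid, q_grid = config$q_grid)
      }
    )
  }

  if (isTRUE(config$do_deferral)) {
    out$deferral <- purrr::map(
      rlang::set_names(config$classifier_regimes),
      function(rg) {
        preds <- out$predictions[[rg]]
        conf <- purrr::map(preds$distances, abs)
        prep <- prepare_deferral(cohort, preds$predictions, conf,
                                 p_low = config$p_low)
        res <- list(
          svmconf = deferral_curve(prep, config$defer_fractions,
                                   "flags_first", seed = seed),
          # alternative analysis: flags not prioritized, pure score order
          score_only = deferral_curve(prep, config$defer_fractions,
                                      "score_only", seed = seed)
        )
        if (isTRUE(config$do_random_baseline)) {
          res$random <- deferral_curve(prep, config$defer_fractions,
                                       "random", seed = seed)
        }
        res
      }
    )
  }

  if (isTRUE(config$do_krcc)) {
    out$krcc <- purrr::map(
      rlang::set_names(config$classifier_regimes),
      function(rg) {
        preds <- out$predictions[[rg]]
        purrr::map(rlang::set_names(config$trust_regimes), function(tr) {
          krcc_cohort(cohort, preds, tr, seed,
                      max_segments = config$krcc_max_segments)
        })
      }
    )
  }
  class(out) <- "seizure_experiment"
  out
}

# patient-wise Kendall agreement between |d| confidences and trust scores
# from a leave-one-patient-out trust model; long series are subsampled
# (Kendall's tau is quadratic in length)
krcc_cohort <- function(cohort, predictions, trust_regime, seed,
                        max_segments = 5000L) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    pid <- cohort$patient_id[i]
    j <- match(pid, predictions$patient_id)
    sub <- subsample_training_set(cohort[cohort$patient_id != pid, ],
                                  trust_regime, seed = seed)
    tm <- fit_trust_model(sub$features, sub$labels, regime = trust_regime)
    n <- length(predictions$distances[[j]])
    keep <- if (n > max_segments) {
      withr::with_seed(seed + i, sort(sample.int(n, max_segments)))
    } else seq_len(n)
    sc <- score_series(tm, cohort$features[[i]][keep, , drop = FALSE],
                       predictions$predictions[[j]][keep])
    tibble(patient_id = pid,
           confidence = abs(predictions$distances[[j]][keep]),
           trust = sc)
  }) |> dplyr::bind_rows()
  ranking_agreement(rows)
}

#' Write an experiment bundle to disk
#'
#' Per-run JSON bundle (metrics, chosen parameters, curves; each file
#' embeds the config hash and seed) plus CSV metric tables.
#'
#' @param experiment A `"seizure_experiment"`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- list(config_hash = experiment$config_hash,
                seed = experiment$seed)
  bundle <- list(stamp = stamp)
  if (!is.null(experiment$ltf)) {
    bundle$ltf <- purrr::map(experiment$ltf, function(x) {
      list(chosen_q = x$chosen_q, summary = glance(x),
           fold_summary = x$fold_plan$summary)
    })
    purrr::iwalk(experiment$ltf, function(x, nm) {
      utils::write.csv(tidy(x),
                       file.path(dir, sprintf("ltf_metrics_%s.csv", nm)),
                       row.names = FALSE)
    })
  }
  if (!is.null(experiment$deferral)) {
    bundle$deferral <- purrr::map(
      experiment$deferral,
      function(x) purrr::map(x, as_tibble)
    )
  }
  if (!is.null(experiment$krcc)) {
    bundle$krcc <- purrr::map(experiment$krcc,
                              function(x) purrr::map(x, "krcc"))
  }
  jsonlite::write_json(bundle, file.path(dir, "experiment.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(dir)
}
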