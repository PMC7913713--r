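#' Tidy a fitted margin classifier
#'
#' @param x A `"decision_model"`.
#' @param ... Unused.
#' @return A tibble with one row per feature: `term` and `estimate`
#'   (the weight on the standardized feature scale).
#' @method tidy decision_model
#' @export
tidy.decision_model <- function(x, ...) {
  terms <- x$feature_names %||% sprintf("f%02d", seq_along(x$w))
  tibble(term = terms, estimate = x$w)
}

#' @rdname tidy.decision_model
#' @return `glance()` returns a one-row fit summary.
#' @method glance decision_model
#' @export
glance.decision_model <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_nonseizure = unname(x$class_counts["n0"]),
    n_seizure = unname(x$class_counts["n1"]),
    lambda = x$lambda,
    w_norm = x$w_norm,
    regime = x$regime,
    converged = x$convergence == 0L
  )
}

#' Tidy a trust model
#'
#' @param x A `"trust_model"`.
#' @param ... Unused.
#' @return One row per retained principal component with its standard
#'   deviation and variance share.
#' @method tidy trust_model
#' @export
tidy.trust_model <- function(x, ...) {
  tibble(
    component = seq_len(x$n_components),
    sdev = x$sdev,
    prop_variance = x$sdev^2 / sum(x$sdev^2)
  )
}

#' @rdname tidy.trust_model
#' @method glance trust_model
#' @export
glance.trust_model <- function(x, ...) {
  tibble(
    n_components = x$n_components,
    n_ref_nonseizure = nrow(x$class0),
    n_ref_seizure = nrow(x$class1),
    regime = x$regime
  )
}

#' Tidy nested-CV low-trust-filtering results
#'
#' @param x An `"ltf_cv"` object from [nested_cv_ltf()].
#' @param ... Unused.
#' @return Per-patient held-out metrics for the baseline and LTF
#'   models.
#' @method tidy ltf_cv
#' @export
tidy.ltf_cv <- function(x, ...) {
  as_tibble(x$metrics)
}

#' @rdname tidy.ltf_cv
#' @return `glance()` returns one row per model with patient-averaged
#'   metrics, the mean chosen filtering fraction, and one-sided paired
#'   Wilcoxon p-values for the FDR decrease and DS change under LTF.
#' @method glance ltf_cv
#' @export
glance.ltf_cv <- function(x, ...) {
  m <- x$metrics
  base <- m[m$model == "baseline", ]
  ltf <- m[m$model == "ltf", ]
  summarise_one <- function(d) {
    tibble(
      ds = mean(d$ds, na.rm = TRUE),
      fdr_per_24h = mean(d$fdr_per_24h),
      ppv = mean(d$ppv, na.rm = TRUE),
      f1 = mean(d$f1, na.rm = TRUE),
      mean_q = mean(d$q)
    )
  }
  dplyr::bind_rows(
    dplyr::mutate(summarise_one(base), model = "baseline",
                  p_fdr_less = NA_real_, p_ds_less = NA_real_),
    dplyr::mutate(summarise_one(ltf), model = "ltf",
                  p_fdr_less = paired_test(ltf$fdr_per_24h,
                                           base$fdr_per_24h, "less"),
                  p_ds_less = paired_test(ltf$ds, base$ds, "less"))
  ) |>
    dplyr::relocate("model")
}

#' @method tidy lopo_cv
#' @export
tidy.lopo_cv <- function(x, ...) {
  as_tibble(x$metrics)
}

#' @method glance lopo_cv
#' @export
glance.lopo_cv <- function(x, ...) {
  x$metrics |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      ds = mean(.data$ds, na.rm = TRUE),
      fdr_per_24h = mean(.data$fdr_per_24h),
      ppv = mean(.data$ppv, na.rm = TRUE),
      f1 = mean(.data$f1, na.rm = TRUE),
      mean_q = mean(.data$q),
      .groups = "drop"
    )
}

#' Plot a deferral curve
#'
#' Detection sensitivity, false detection rate and the deferred-segment
#' statistics as functions of the deferred fraction of the data.
#'
#' @param object A `"deferral_curve"` from [deferral_curve()].
#' @param metrics Which columns to facet.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot deferral_curve
#' @export
autoplot.deferral_curve <- function(object,
                                    metrics = c("ds", "fdr_per_24h",
                                                "n_deferred_per_24h",
                                                "mean_deferred_len_s"),
                                    ...) {
  long <- object |>
    dplyr::select("defer_fraction", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"defer_fraction", names_to = "metric")
  ggplot2::ggplot(long,
                  ggplot2::aes(.data$defer_fraction, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fraction of data deferred", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot held-out LTF results patient by patient
#'
#' Paired per-patient comparison of the baseline flag rule and
#' low-trust filtering on the held-out folds.
#'
#' @param object An `"ltf_cv"` object.
#' @param metric Metric column to compare (default FDR per 24 h).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ltf_cv
#' @export
autoplot.ltf_cv <- function(object, metric = "fdr_per_24h", ...) {
  d <- object$metrics
  ggplot2::ggplot(d, ggplot2::aes(.data$model, .data[[metric]],
                                  group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = metric,
                  title = "Held-out performance with and without low-trust filtering") +
    ggplot2::theme_minimal()
}
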