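test_that("fold plans satisfy their balance constraints by construction", {
  co <- tiny_cohort(n_patients = 8, duration_s = 3600, seed = 33,
                    seizure_rate = 3)
  plan <- make_folds(co, n_folds = 4, seizure_bounds = c(0, Inf),
                     days_bounds = c(0, Inf), seed = 1)
  # folds partition the cohort
  expect_setequal(unlist(plan$folds), co$patient_id)
  expect_equal(sum(lengths(plan$folds)), nrow(co))
  # re-validate the accepted plan with an independent recount
  load <- seizedefer:::patient_load(co)
  for (k in seq_along(plan$folds)) {
    ids <- plan$folds[[k]]
    expect_equal(
      plan$summary$seizure_segments_10s[k],
      sum(load$seizure_segments_10s[load$patient_id %in% ids])
    )
    expect_equal(plan$summary$days[k],
                 sum(load$days[load$patient_id %in% ids]))
  }
  # constrained plan really honours its bounds
  tot <- sum(load$seizure_segments_10s)
  plan2 <- make_folds(co, n_folds = 2, seed = 2,
                      seizure_bounds = c(0.2, 0.8) * tot,
                      days_bounds = c(0, Inf))
  expect_true(all(plan2$summary$seizure_segments_10s >= 0.2 * tot &
                    plan2$summary$seizure_segments_10s <= 0.8 * tot))
})

test_that("infeasible fold bounds exhaust the attempt budget", {
  co <- tiny_cohort(n_patients = 4, duration_s = 3600, seed = 34)
  expect_error(
    make_folds(co, n_folds = 2, seizure_bounds = c(1e6, 2e6),
               days_bounds = c(0, Inf), max_attempts = 25),
    "attempts"
  )
})

test_that("inner halves partition the remaining folds and balance load", {
  co <- tiny_cohort(n_patients = 10, duration_s = 3600, seed = 35,
                    seizure_rate = 3)
  load <- seizedefer:::patient_load(co)
  folds <- split(co$patient_id, rep(1:5, each = 2))
  halves <- seizedefer:::inner_halves(unname(folds), load)
  expect_setequal(c(halves$a, halves$b), co$patient_id)
  expect_equal(abs(length(halves$a) - length(halves$b)) <= 1, TRUE)
})

test_that("patient-independent predictions are seed-stable", {
  co <- tiny_cohort(n_patients = 3, duration_s = 1200, seed = 36,
                    seizure_rate = 2)
  p1 <- classify_cohort(co, "ci", seed = 5)
  p2 <- classify_cohort(co, "ci", seed = 5)
  expect_identical(p1, p2)
  expect_equal(lengths(p1$predictions), rep(1199L, 3))
})

test_that("a degenerate filtering grid reproduces the baseline exactly", {
  co <- tiny_cohort(n_patients = 6, duration_s = 1800, seed = 37,
                    seizure_rate = 2, artifact_rate = 20)
  preds <- classify_cohort(co, "ci", seed = 1)
  cv <- nested_cv_ltf(co, preds, trust_regime = "fs", q_grid = 0,
                      n_folds = 3, seed = 2,
                      seizure_bounds = c(0, Inf), days_bounds = c(0, Inf))
  expect_s3_class(cv, "ltf_cv")
  m <- tidy(cv)
  base <- m[m$model == "baseline", ]
  ltf <- m[m$model == "ltf", ]
  expect_equal(ltf$tp, base$tp)
  expect_equal(ltf$fp, base$fp)
  expect_equal(ltf$fdr_per_24h, base$fdr_per_24h)
  # the averaged test q is the mean of the two inner optima
  expect_equal(cv$chosen_q$q_test,
               (cv$chosen_q$q_inner_a + cv$chosen_q$q_inner_b) / 2)
  expect_true(all(cv$chosen_q$q_test == 0))
  g <- glance(cv)
  expect_equal(g$fdr_per_24h[g$model == "ltf"],
               g$fdr_per_24h[g$model == "baseline"])
})

test_that("confidence-driven filtering decisions are temperature-invariant", {
  co <- tiny_cohort(n_patients = 4, duration_s = 1200, seed = 38,
                    seizure_rate = 2, artifact_rate = 0)
  preds <- classify_cohort(co, "ci", seed = 1)
  cv <- lopo_cv_svmconf(co, preds, a_grid = c(0.5, 2),
                        q_grid = c(0, 0.05, 0.1))
  # per-cell F1 must be identical across temperatures at fixed q
  m <- cv$metrics[cv$metrics$model == "ltf_svmconf", ]
  raw <- lopo_cv_svmconf(co, preds, a_grid = 1, q_grid = c(0, 0.05, 0.1),
                         raw_distance = TRUE)
  mr <- raw$metrics[raw$metrics$model == "ltf_svmconf", ]
  expect_equal(m$q, mr$q)  # same filtering fraction chosen
  expect_equal(m$f1, mr$f1)
  expect_equal(m$fp, mr$fp)
  # on a clean separable cohort no filtering helps, so q = 0 is selected
  expect_true(all(m$q == 0))
})

test_that("a single-point grid is selected trivially", {
  co <- tiny_cohort(n_patients = 3, duration_s = 1200, seed = 39,
                    seizure_rate = 2)
  preds <- classify_cohort(co, "ci", seed = 1)
  cv <- lopo_cv_svmconf(co, preds, a_grid = 1, q_grid = 0.02)
  expect_true(all(cv$chosen$q == 0.02))
  expect_true(all(cv$chosen$a == 1))
  expect_error(lopo_cv_svmconf(co, preds, a_grid = numeric(0)), "non-empty")
})
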