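test_that("cohort generation is deterministic given the seed", {
  cfg <- sim_config(n_patients = 3, duration_s = 900, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_equal(a, b)
  expect_equal(nrow(a), 3L)
  # a different seed changes the draw
  c2 <- generate_cohort(sim_config(n_patients = 3, duration_s = 900,
                                   seed = 8))
  expect_false(identical(a$features[[1]], c2$features[[1]]))
})

test_that("segment grid covers the recording at a 1-s hop", {
  for (dur in c(600, 901, 3600)) {
    expect_length(segment_grid(dur), oracle_segment_count(dur))
    expect_equal(length(segment_grid(dur)), dur - 1)
  }
  co <- tiny_cohort(n_patients = 2, duration_s = 700)
  expect_equal(nrow(co$features[[1]]), 699)
})

test_that("zero seizure rate yields empty event lists and all-zero labels", {
  co <- generate_cohort(sim_config(n_patients = 3, duration_s = 900,
                                   seizure_rate = 0, seed = 2))
  expect_true(all(vapply(co$events, nrow, integer(1)) == 0L))
  labs <- derive_labels(co$events[[1]], co$duration_s[1], "fs")
  expect_true(all(labs$label == 0L))
})

test_that("drawn events respect the stated invariants", {
  co <- tiny_cohort(n_patients = 8, duration_s = 7200, seed = 3,
                    seizure_rate = 4)
  for (ev in co$events) {
    if (nrow(ev) < 1) next
    expect_true(all(ev$onset_s >= 0 & ev$end_s <= 7200))
    expect_true(all(ev$end_s - ev$onset_s >= 10))
    expect_true(all(ev$end_s - ev$onset_s <= 60))
    if (nrow(ev) > 1) {
      expect_true(all(diff(ev$onset_s) > 0))
      expect_true(all(ev$onset_s[-1] >= ev$end_s[-nrow(ev)]))
    }
    # clear-ictal window inside the event
    expect_true(all(ev$clear_ictal_start_s >= ev$onset_s))
    expect_true(all(ev$clear_ictal_start_s + 10 <= ev$end_s))
  }
})

test_that("an unusable imbalance regime is rejected", {
  cfg <- sim_config(n_patients = 1, duration_s = 700,
                    seizure_duration_range = c(290, 299),
                    seizure_rate = 30, fraction_patients_with_seizures = 1,
                    seed = 5)
  expect_error(generate_cohort(cfg), "50%")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration_s = 100), "600")
  expect_error(sim_config(seizure_rate = -1), "rates")
  expect_error(sim_config(seizure_duration_range = c(5, 50)), "min")
  expect_error(sim_config(n_patients = 2, duration_s = 900,
                          seizure_duration_range = c(20, 1000)))
})

test_that("a well-separated artifact-free cohort is almost perfectly classifiable", {
  # train on one half of the cohort, evaluate per-segment accuracy on the
  # other half: with a large class separation accuracy must exceed 99%
  co <- generate_cohort(sim_config(
    n_patients = 6, duration_s = 3600, class_separation = 6,
    artifact_rate = 0, fraction_patients_with_seizures = 1,
    seizure_rate = 3, seizure_duration_range = c(20, 60), seed = 42
  ))
  sub <- subsample_training_set(co[1:3, ], "fs", seed = 1)
  model <- train_classifier(sub$features, sub$labels, regime = "fs")
  accs <- vapply(4:6, function(i) {
    pred <- predict(model, co$features[[i]])
    lab <- derive_labels(co$events[[i]], co$duration_s[i], "fs")$label
    mean(pred == lab)
  }, numeric(1))
  expect_gt(mean(accs), 0.99)
})

test_that("amplitude-mechanism clear-ictal windows are recoverable from the proxies", {
  co <- tiny_cohort(n_patients = 6, duration_s = 3600, seed = 9,
                    seizure_rate = 3)
  hits <- 0L
  total <- 0L
  for (i in seq_len(nrow(co))) {
    ev <- co$events[[i]]
    amp <- ev$mechanism == "amplitude"
    if (!any(amp)) next
    det <- annotate_clear_ictal(ev, co$features[[i]], co$duration_s[i])
    total <- total + sum(amp)
    # the 2-sd threshold fires once ~6 of 9 window segments are elevated
    # (6/9 * 3 = 2 plus noise), and the proxy elevation starts one second
    # early under the midpoint rule, so detection leads by up to ~6 s
    off <- det$clear_ictal_detected_s[amp] - ev$clear_ictal_start_s[amp]
    hits <- hits + sum(off >= -6 & off <= 1)
  }
  expect_gt(total, 3)
  expect_gte(hits / total, 0.8)
})

test_that("cohort round-trips through plain-text files", {
  co <- tiny_cohort(n_patients = 2, duration_s = 700, seed = 4)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  back <- read_cohort(dir)
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(back$features[[1]], co$features[[1]], tolerance = 1e-6)
  expect_equal(back$events[[2]]$onset_s, co$events[[2]]$onset_s)
})
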