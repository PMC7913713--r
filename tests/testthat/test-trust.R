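make_patient <- function(duration_s, events = NULL, p = 3, seed = 1) {
  events <- events %||%
    tibble::tibble(onset_s = numeric(), end_s = numeric(),
                   clear_ictal_start_s = numeric())
  withr::with_seed(seed, {
    tibble::tibble(
      patient_id = "PX",
      duration_s = duration_s,
      events = list(events),
      features = list(matrix(rnorm((duration_s - 1) * p), ncol = p))
    )
  })
}

test_that("background windows are drawn on the 15-min grid when possible", {
  # a 25-h seizure-free recording has exactly 100 candidate windows at
  # 15-min spacing, so all of them are drawn
  pat <- make_patient(25 * 3600)
  sub <- subsample_training_set(pat, "fs", seed = 1)
  starts <- sort(unique(sub$start_s - sub$start_s %% 60))
  expect_equal(length(unique(starts)), 100)
  expect_true(all(sort(unique(starts)) %% 900 == 0))
  expect_equal(length(sub$labels), 100 * 30)
  expect_true(all(sub$labels == 0L))
})

test_that("short recordings fall back to the 5-min grid", {
  # 6 h: only 24 windows exist at 15-min spacing, so spacing drops to
  # 5 min, giving 72 candidates, all of which are taken (72 < 100)
  pat <- make_patient(6 * 3600)
  sub <- subsample_training_set(pat, "fs", seed = 1)
  expect_equal(length(sub$labels) / 30, 72)
  win_starts <- unique(sub$start_s - sub$start_s %% 60)
  expect_true(all(win_starts %% 300 == 0))
  expect_false(all(win_starts %% 900 == 0))
})

test_that("the subsample is reproducible and includes every seizure segment", {
  ev <- tibble::tibble(onset_s = 1000, end_s = 1060,
                       clear_ictal_start_s = 1010)
  pat <- make_patient(26 * 3600, ev)
  s1 <- subsample_training_set(pat, "fs", seed = 9)
  s2 <- subsample_training_set(pat, "fs", seed = 9)
  expect_identical(s1, s2)
  fs <- derive_labels(ev, pat$duration_s, "fs")
  expect_setequal(s1$start_s[s1$labels == 1L],
                  fs$start_s[fs$label == 1L])
  # no drawn background window overlaps the event
  bg <- s1$start_s[s1$labels == 0L]
  expect_true(all(bg + 2 <= 1000 | bg >= 1060))
})

test_that("a recording with no seizure-free window is rejected", {
  ev <- tibble::tibble(onset_s = 0, end_s = 600, clear_ictal_start_s = 10)
  pat <- make_patient(601, ev)
  expect_error(subsample_training_set(pat, "fs"), "seizure-free")
})

test_that("the projection dimension is capped by the feature dimension", {
  set.seed(2)
  X <- matrix(rnorm(60 * 10), ncol = 10)
  y <- rep(c(0L, 1L), 30)
  tm <- fit_trust_model(X, y, n_components = 20)
  expect_equal(tm$n_components, 10)
  tm3 <- fit_trust_model(matrix(rnorm(18), ncol = 3), rep(c(0L, 1L), 3))
  expect_equal(nrow(tm3$class0), 3)
  expect_equal(nrow(tm3$class1), 3)
  expect_error(fit_trust_model(X, rep(0L, 60)), "both classes")
})

test_that("the projection reproduces an independent eigendecomposition", {
  set.seed(4)
  X <- matrix(rnorm(30 * 5), ncol = 5)
  y <- rep(c(0L, 1L), 15)
  tm <- fit_trust_model(X, y, n_components = 5)
  proj <- seizedefer:::project_points(tm, X)
  # oracle: eigenvectors of the covariance matrix
  Xc <- scale(X, scale = FALSE)
  eig <- eigen(stats::cov(Xc))
  proj_o <- Xc %*% eig$vectors
  expect_equal(as.matrix(dist(proj)), as.matrix(dist(proj_o)),
               tolerance = 1e-8)
})

test_that("the 1-D toy reproduces the distance-ratio arithmetic", {
  tm <- fit_trust_model(matrix(c(0, 10), ncol = 1), c(0L, 1L),
                        n_components = 1)
  expect_equal(trust_score(tm, 2, predicted = 0), 4)     # 8 / 2
  expect_equal(trust_score(tm, 2, predicted = 1), 0.25)  # 2 / 8
  expect_equal(trust_score(tm, 5, predicted = 0), 1)     # equidistant
  # coinciding with a reference point of the predicted class
  expect_equal(trust_score(tm, 0, predicted = 0), Inf)
})

test_that("scores match the all-pairs nearest-neighbour oracle exactly", {
  set.seed(11)
  refs <- matrix(rnorm(50 * 3), ncol = 3)
  y <- rep(c(0L, 1L), 25)
  tm <- fit_trust_model(refs, y, n_components = 3)
  X <- matrix(rnorm(200 * 3), ncol = 3)
  pred <- sample(0:1, 200, replace = TRUE)
  got <- score_series(tm, X, pred, chunk = 64)
  proj <- seizedefer:::project_points(tm, X)
  want <- vapply(seq_len(200), function(i) {
    oracle_trust_score(proj[i, ], tm$class0, tm$class1, pred[i])
  }, numeric(1))
  expect_equal(got, want)
  # flipping the predicted class inverts the score exactly
  flipped <- score_series(tm, X, 1L - pred, chunk = 64)
  expect_equal(flipped, 1 / got)
  # score > 1 iff the projected point is closer to its predicted class
  d0 <- sqrt(seizedefer:::min_dist_sq(proj, tm$class0))
  d1 <- sqrt(seizedefer:::min_dist_sq(proj, tm$class1))
  dp <- ifelse(pred == 1, d1, d0)
  dq <- ifelse(pred == 1, d0, d1)
  expect_equal(got > 1, dp < dq)
})

test_that("score_series validates its alignment", {
  tm <- fit_trust_model(matrix(c(0, 10), ncol = 1), c(0L, 1L))
  expect_error(score_series(tm, matrix(1:4, ncol = 1), c(0L, 1L)),
               "per segment")
})
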