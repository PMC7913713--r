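#' Train a patient-independent margin classifier on 2-s segments
#'
#' Fits a linear, class-weighted, L2-regularized squared-hinge support
#' vector machine by quasi-Newton optimization (no external SVM library
#' is required).  Class weights are balanced by default
#' (`n / (2 n_class)`), which matters under the extreme class imbalance
#' of seizure monitoring.  The fit is fully deterministic: parameters
#' start at zero and the objective is convex, so retraining on the same
#' data yields identical decision distances.
#'
#' The model predicts label 1 exactly when the signed geometric distance
#' `d` to the separating hyperplane is positive.
#'
#' @param features Numeric matrix, one row per 2-s segment.
#' @param labels Integer/numeric 0-1 labels (both classes must be
#'   present).
#' @param regime Optional tag recording which label regime ("ci" or
#'   "fs") produced `labels`; stored on the model for bookkeeping.
#' @param lambda L2 penalty on the weight vector (default `1e-3`).
#' @param balanced Use balanced class weights (default `TRUE`).
#' @param max_iter Maximum L-BFGS iterations.
#' @return An object of class `"decision_model"`.
#' @seealso [decision_distance()], [temperature_scale()],
#'   [svm_confidence()]
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40, -5), 20), matrix(rnorm(40, 5), 20))
#' m <- train_classifier(X, rep(0:1, each = 20))
#' all(predict(m, X) == rep(0:1, each = 20))
train_classifier <- function(features, labels, regime = NA_character_,
                             lambda = 1e-3, balanced = TRUE,
                             max_iter = 500L) {
  X <- as.matrix(features)
  y01 <- as.integer(labels)
  if (length(y01) != nrow(X)) abort("`labels` must match rows of `features`.")
  if (length(unique(y01)) < 2L) {
    abort("training data contains a single class; both classes are required.")
  }
  if (!all(y01 %in% c(0L, 1L))) abort("`labels` must be 0/1.")
  n <- nrow(X)
  p <- ncol(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  y <- ifelse(y01 == 1L, 1, -1)
  wts <- if (balanced) {
    tab <- table(factor(y01, levels = c(0L, 1L)))
    n / (2 * as.numeric(tab[as.character(y01)]))
  } else rep(1, n)

  obj <- function(theta) {
    w <- theta[1:p]; b <- theta[p + 1L]
    h <- pmax(0, 1 - y * (drop(Xs %*% w) + b))
    0.5 * lambda * sum(w^2) + sum(wts * h^2) / n
  }
  grad <- function(theta) {
    w <- theta[1:p]; b <- theta[p + 1L]
    h <- pmax(0, 1 - y * (drop(Xs %*% w) + b))
    g <- -2 * wts * h * y / n
    c(lambda * w + drop(crossprod(Xs, g)), sum(g))
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e4))
  w <- fit$par[1:p]
  b <- fit$par[p + 1L]
  wn <- sqrt(sum(w^2))
  if (wn == 0) abort("degenerate fit: zero weight vector.")
  structure(
    list(w = w, b = b, w_norm = wn, center = center, scale = scale_,
         lambda = lambda, regime = regime, n_train = n,
         class_counts = c(n0 = sum(y01 == 0L), n1 = sum(y01 == 1L)),
         convergence = fit$convergence, feature_names = colnames(X)),
    class = "decision_model"
  )
}

#' Signed distance to the separating hyperplane
#'
#' @param model A `"decision_model"` from [train_classifier()].
#' @param features Numeric matrix of segments to score.
#' @return Numeric vector of signed geometric distances `d`; the
#'   predicted class is 1 iff `d > 0`.
#' @export
decision_distance <- function(model, features) {
  stopifnot(inherits(model, "decision_model"))
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  (drop(Xs %*% model$w) + model$b) / model$w_norm
}

#' @param object A `"decision_model"`.
#' @param newdata Feature matrix.
#' @param type `"class"` (default) for 0/1 predictions or `"distance"`
#'   for signed hyperplane distances.
#' @param ... Unused.
#' @rdname decision_distance
#' @export
predict.decision_model <- function(object, newdata,
                                   type = c("class", "distance"), ...) {
  type <- match.arg(type)
  d <- decision_distance(object, newdata)
  if (type == "distance") d else as.integer(d > 0)
}

#' @export
print.decision_model <- function(x, ...) {
  cat("Linear margin classifier (squared-hinge SVM)\n")
  cat(sprintf("  trained on %d segments (%d non-seizure / %d seizure), regime %s\n",
              x$n_train, x$class_counts[["n0"]], x$class_counts[["n1"]],
              x$regime))
  cat(sprintf("  lambda = %g, |w| = %.4g\n", x$lambda, x$w_norm))
  invisible(x)
}

#' Temperature scaling of decision distances
#'
#' Maps signed hyperplane distances to probabilities with a
#' one-parameter sigmoid, `p_a = 1 / (1 + exp(-a d))`.  The decision
#' threshold sits at `p_a = 0.5` (i.e. `d = 0`) for every temperature
#' `a > 0`, so temperature scaling can never change the predicted class,
#' and the confidence ranking it induces is identical to ranking by
#' `|d|`.
#'
#' @param d Numeric vector of signed decision distances.
#' @param a Positive temperature parameter.
#' @return Probabilities in (0, 1), elementwise.
#' @export
#' @examples
#' temperature_scale(0, a = 17) # 0.5 for any a
temperature_scale <- function(d, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a <= 0) {
    abort("`a` must be a single positive number.")
  }
  plogis(a * d)
}

#' Classifier confidence from calibrated probabilities
#'
#' The confidence of a prediction is its distance from the decision
#' threshold, `c = |p - 0.5|`.  For a fixed temperature the ordering of
#' `c` equals the ordering of `|d|`, so raw distances are an admissible
#' confidence score.
#'
#' @param p Probabilities in `[0, 1]` (the sigmoid is mathematically
#'   strictly inside (0, 1) but saturates in floating point for large
#'   `a * d`).
#' @return Confidences in `[0, 0.5]`.
#' @export
svm_confidence <- function(p) {
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].")
  abs(p - 0.5)
}

#' Persist a fitted model to a single artifact file
#'
#' Works for both `"decision_model"` and `"trust_model"` objects (plain
#' RDS serialization).
#'
#' @param model A fitted model object.
#' @param path Destination file.
#' @return `save_model()` returns `path` invisibly; `load_model()`
#'   returns the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("decision_model", "trust_model")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("decision_model", "trust_model"))) {
    abort("file does not contain a seizedefer model.")
  }
  model
}
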