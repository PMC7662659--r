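# Five classifiers behind one fit/predict contract.
#
# Each fit_*() returns an object inheriting from "classifier_model" whose
# predict() method emits labels from the training label set. The headline
# tuning parameter of each model (hidden nodes, trees, latent variables) is
# stored in $spec for reporting.

new_classifier <- function(kind, parameter, fit, class_labels, extra = list()) {
  structure(
    c(list(spec = list(kind = kind, parameter = parameter),
           class_labels = class_labels, fit = fit), extra),
    class = c(paste0(tolower(kind), "_model"), "classifier_model"))
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<%s classifier: parameter = %s, %d classes>\n",
              x$spec$kind, format(x$spec$parameter),
              length(x$class_labels)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.classifier_model <- function(x, ...) {
  tibble(kind = x$spec$kind, parameter = x$spec$parameter,
         n_classes = length(x$class_labels))
}

#' Extreme learning machine
#'
#' Single hidden layer with seeded random input weights: the hidden
#' activations are `sigmoid(X W' + b)` and the output layer (weights plus
#' bias) solves the one-hot targets by Moore-Penrose pseudoinverse.
#' `n_hidden = "auto"` sweeps
#' the hidden-layer size from 1 to the training-set size and keeps the model
#' with minimum training error (smallest size on ties).
#'
#' @param x training matrix (n x p).
#' @param labels class labels, one per row.
#' @param n_hidden hidden-node count in `[1, n]`, or `"auto"`.
#' @param seed integer seed for the random input layer.
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @return a `classifier_model`.
#' @export
fit_elm <- function(x, labels, n_hidden = "auto", seed = 1L,
                    activation = c("sigmoid", "identity")) {
  x <- as.matrix(x)
  activation <- match.arg(activation)
  act <- if (activation == "sigmoid") logistic else identity
  n <- nrow(x); p <- ncol(x)
  targets <- one_hot(labels)
  fit_one <- function(h) {
    w_in <- matrix(runif(h * p, -1, 1), h, p)
    b <- runif(h, -1, 1)
    hh <- act(sweep(tcrossprod(x, w_in), 2, b, `+`))
    beta <- pinv(cbind(1, hh)) %*% targets
    err <- mean(colnames(targets)[max.col(cbind(1, hh) %*% beta, "first")] !=
                  as.character(labels))
    list(w_in = w_in, b = b, beta = beta, train_error = err, h = h)
  }
  withr::local_seed(as.integer(seed))
  if (identical(n_hidden, "auto")) {
    sweep_fits <- lapply(seq_len(n), fit_one)
    errs <- vapply(sweep_fits, `[[`, numeric(1), "train_error")
    best <- sweep_fits[[which.min(errs)]] # which.min takes the smallest h
  } else {
    if (n_hidden < 1 || n_hidden > n) {
      abort("`n_hidden` must be in [1, n_train] or \"auto\"")
    }
    best <- fit_one(as.integer(n_hidden))
  }
  new_classifier("ELM", best$h, best, colnames(targets),
                 extra = list(activation = activation))
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  newdata <- check_pred_dims(object, newdata, ncol(object$fit$w_in))
  act <- if (object$activation == "sigmoid") logistic else identity
  hh <- act(sweep(tcrossprod(newdata, object$fit$w_in), 2, object$fit$b, `+`))
  scores <- cbind(1, hh) %*% object$fit$beta
  object$class_labels[max.col(scores, "first")]
}

#' Random forest classifier
#'
#' Bagged CART trees with per-split random feature subsets of size
#' `ceiling(sqrt(p))` and majority-vote prediction, via the randomForest
#' package behind the package's uniform contract.
#'
#' @inheritParams fit_elm
#' @param n_trees number of trees.
#' @return a `classifier_model`.
#' @export
fit_rf <- function(x, labels, n_trees = 100, seed = 1L) {
  x <- as.matrix(x)
  if (n_trees < 1) abort("`n_trees` must be >= 1")
  colnames(x) <- paste0("v", seq_len(ncol(x)))
  withr::local_seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x, factor(labels), ntree = as.integer(n_trees),
    mtry = ceiling(sqrt(ncol(x))))
  new_classifier("RF", as.integer(n_trees), fit, levels(factor(labels)))
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  newdata <- check_pred_dims(object, newdata,
                             length(object$fit$forest$xlevels))
  colnames(newdata) <- paste0("v", seq_len(ncol(newdata)))
  as.character(predict(object$fit, newdata))
}

#' Radial basis function network
#'
#' Hidden centers by seeded k-means, Gaussian activations
#' `exp(-||x - c||^2 / (2 spread^2))`, and linear output weights solved by
#' pseudoinverse against one-hot targets; argmax decision. The default
#' spread is the median pairwise distance between centers.
#'
#' @inheritParams fit_elm
#' @param n_centers hidden-node count, at most `n`; `n_centers = n` uses the
#'   training points themselves as centers (interpolation).
#' @param spread Gaussian width; default median inter-center distance.
#' @return a `classifier_model`.
#' @export
fit_rbf <- function(x, labels, n_centers, spread = NULL, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n_centers < 1 || n_centers > n) abort("`n_centers` must be in [1, n]")
  withr::local_seed(as.integer(seed))
  centers <- if (n_centers == n) x else {
    kmeans(x, centers = n_centers, nstart = 3, iter.max = 50)$centers
  }
  if (is.null(spread)) {
    d <- stats::dist(centers)
    spread <- if (length(d)) median(d) else 1
    if (spread <= 0) spread <- 1
  }
  targets <- one_hot(labels)
  phi <- rbf_activations(x, centers, spread)
  beta <- pinv(cbind(1, phi)) %*% targets
  new_classifier("RBF", as.integer(n_centers),
                 list(centers = centers, spread = spread, beta = beta),
                 colnames(targets))
}

rbf_activations <- function(x, centers, spread) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), `+`) -
    2 * tcrossprod(x, centers)
  exp(-pmax(d2, 0) / (2 * spread^2))
}

#' @export
predict.rbf_model <- function(object, newdata, ...) {
  newdata <- check_pred_dims(object, newdata, ncol(object$fit$centers))
  phi <- rbf_activations(newdata, object$fit$centers, object$fit$spread)
  scores <- cbind(1, phi) %*% object$fit$beta
  object$class_labels[max.col(scores, "first")]
}

#' PLS discriminant analysis
#'
#' One-hot class targets regressed on X through the NIPALS PLS engine.
#' Labels are assigned by argmax over the predicted dummy vector; for
#' two-class-style threshold scoring, predictions also carry an `accepted`
#' flag per class column (`|yhat - y| < threshold`, default 0.5).
#'
#' @inheritParams fit_elm
#' @param n_lv number of latent variables.
#' @param threshold acceptance threshold on the dummy scale, in (0, 1).
#' @return a `classifier_model`.
#' @export
fit_plsda <- function(x, labels, n_lv, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0,1)")
  targets <- one_hot(labels)
  fit <- fit_pls(as.matrix(x), targets, n_lv)
  new_classifier("PLSDA", as.integer(n_lv), fit, colnames(targets),
                 extra = list(threshold = threshold))
}

#' @export
predict.plsda_model <- function(object, newdata, type = c("label", "score"),
                                ...) {
  type <- match.arg(type)
  newdata <- check_pred_dims(object, newdata, length(object$fit$x_mean))
  scores <- predict(object$fit, newdata)
  if (type == "score") return(scores)
  object$class_labels[max.col(scores, "first")]
}

#' Threshold acceptance flags for PLS-DA / BPNN predictions
#'
#' For each sample and class column, flags whether the predicted dummy value
#' is within `threshold` of the actual 0/1 target.
#'
#' @param scores predicted dummy matrix (samples x classes).
#' @param labels actual labels.
#' @param threshold acceptance threshold (default 0.5).
#' @return logical matrix of the same shape as `scores`.
#' @export
threshold_accept <- function(scores, labels, threshold = 0.5) {
  targets <- one_hot(labels, levels = colnames(scores))
  abs(scores - targets) < threshold
}

#' Back-propagation neural network
#'
#' One hidden layer, sigmoid activations on both layers, one-hot targets,
#' full-batch gradient descent on the mean squared error at a fixed learning
#' rate. Training stops after `epochs` passes or when the MSE reaches
#' `goal`. Inputs are min-max scaled to [-1, 1] internally; initial weights
#' are seeded uniform(-0.5, 0.5).
#'
#' @inheritParams fit_elm
#' @param n_hidden hidden-neuron count.
#' @param lr learning rate (default 0.6).
#' @param epochs maximum training epochs (default 1000).
#' @param goal MSE stopping target (default 1e-5).
#' @param threshold acceptance threshold for threshold-style scoring.
#' @return a `classifier_model`.
#' @export
fit_bpnn <- function(x, labels, n_hidden, lr = 0.6, epochs = 1000,
                     goal = 1e-5, threshold = 0.5, seed = 1L) {
  x <- as.matrix(x)
  if (n_hidden < 1) abort("`n_hidden` must be >= 1")
  rng <- apply(x, 2, range)
  span <- pmax(rng[2, ] - rng[1, ], 1e-12)
  xs <- sweep(sweep(x, 2, rng[1, ]), 2, span, `/`) * 2 - 1
  targets <- one_hot(labels)
  n <- nrow(xs); p <- ncol(xs); m <- ncol(targets)
  withr::local_seed(as.integer(seed))
  w1 <- matrix(runif(p * n_hidden, -0.5, 0.5), p, n_hidden)
  b1 <- runif(n_hidden, -0.5, 0.5)
  w2 <- matrix(runif(n_hidden * m, -0.5, 0.5), n_hidden, m)
  b2 <- runif(m, -0.5, 0.5)
  mse <- Inf
  for (ep in seq_len(max(epochs, 0))) {
    h <- logistic(sweep(xs %*% w1, 2, b1, `+`))
    o <- logistic(sweep(h %*% w2, 2, b2, `+`))
    err <- o - targets
    mse <- mean(err^2)
    if (mse <= goal) break
    if (!is.finite(mse) || mse > 1e3) {
      abort("BPNN training diverged; lower the learning rate")
    }
    # gradient of the per-sample summed squared error (mean over samples):
    # keeps the learning speed independent of the number of classes
    delta_o <- 2 * err * o * (1 - o) / n
    delta_h <- (delta_o %*% t(w2)) * h * (1 - h)
    w2 <- w2 - lr * crossprod(h, delta_o)
    b2 <- b2 - lr * colSums(delta_o)
    w1 <- w1 - lr * crossprod(xs, delta_h)
    b1 <- b1 - lr * colSums(delta_h)
  }
  new_classifier(
    "BPNN", as.integer(n_hidden),
    list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, rng = rng, span = span,
         mse = mse),
    colnames(targets), extra = list(threshold = threshold))
}

#' @export
predict.bpnn_model <- function(object, newdata, type = c("label", "score"),
                               ...) {
  type <- match.arg(type)
  f <- object$fit
  newdata <- check_pred_dims(object, newdata, nrow(f$w1))
  xs <- sweep(sweep(as.matrix(newdata), 2, f$rng[1, ]), 2, f$span, `/`) *
    2 - 1
  h <- logistic(sweep(xs %*% f$w1, 2, f$b1, `+`))
  o <- logistic(sweep(h %*% f$w2, 2, f$b2, `+`))
  colnames(o) <- object$class_labels
  if (type == "score") return(o)
  object$class_labels[max.col(o, "first")]
}

check_pred_dims <- function(object, newdata, p_expected) {
  newdata <- as.matrix(newdata)
  if (!is.null(p_expected) && !is.na(p_expected) &&
      ncol(newdata) != p_expected) {
    abort(sprintf("newdata has %d columns; model was trained on %d",
                  ncol(newdata), p_expected))
  }
  newdata
}

#' Fit any of the five classifiers by name
#'
#' Dispatcher behind the evaluation task runners: `kind` is one of `"ELM"`,
#' `"RF"`, `"RBF"`, `"PLSDA"`, `"BPNN"`; `parameter` is the classifier's
#' headline parameter (hidden nodes / trees / latent variables).
#'
#' @inheritParams fit_elm
#' @param kind classifier identifier.
#' @param parameter headline parameter; `NULL` picks a default (`"auto"` for
#'   ELM, 100 trees, `min(n, 2 * classes)` RBF centers, `min(12, ...)`
#'   latent variables, 8 hidden neurons).
#' @param ... passed through to the specific `fit_*()`.
#' @return a `classifier_model`.
#' @export
fit_classifier <- function(x, labels, kind, parameter = NULL, seed = 1L,
                           ...) {
  kind <- toupper(kind)
  x <- as.matrix(x)
  n <- nrow(x)
  switch(
    kind,
    ELM = fit_elm(x, labels, n_hidden = parameter %||% "auto", seed = seed,
                  ...),
    RF = fit_rf(x, labels, n_trees = parameter %||% 100, seed = seed, ...),
    RBF = fit_rbf(x, labels,
                  n_centers = parameter %||%
                    min(n, 2L * length(unique(labels)) + 2L),
                  seed = seed, ...),
    PLSDA = fit_plsda(x, labels,
                      n_lv = parameter %||% min(12L, n - 1L, ncol(x)), ...),
    BPNN = fit_bpnn(x, labels, n_hidden = parameter %||% 8, seed = seed,
                    ...),
    abort(paste0("unknown classifier kind: ", kind)))
}
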