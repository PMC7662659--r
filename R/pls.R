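# Latent-variable PLS regression (NIPALS) with cross-validation.
#
# This is the score engine behind UVE stability, SPA/GA-PLS subset fitness
# and PLS-DA. X and Y are mean-centered, never scaled (absorbance units are
# homogeneous across the axis).

#' Fit a PLS regression model (NIPALS)
#'
#' Deflation-based NIPALS: per component the weight vector `w` maximises
#' covariance with the response, `t = Xw`, `q = Y't / t't`, then X is
#' deflated by `t p'` and Y by `t q'`. The NIPALS inner iteration has the
#' fixed point `w = S v / |S v|` with `S = X'Y` and `v` the dominant
#' eigenvector of `S'S`; that fixed point is computed directly (exactly, via
#' the small `m x m` eigenproblem) rather than by power iteration, so fits
#' are deterministic to machine precision. A single-column response reduces
#' to `w = X'y / |X'y|`. Regression coefficients map centered X to centered
#' Y: `B = W (P'W)^-1 Q'`.
#'
#' @param x predictor matrix (n x p).
#' @param y response vector or matrix (n x m); for classification pass the
#'   one-hot dummy matrix.
#' @param ncomp number of latent variables `A`, at most `min(n - 1, p)`.
#' @return an object of class `pls_model` with weights, loadings, scores,
#'   coefficients and centering vectors.
#' @export
fit_pls <- function(x, y, ncomp) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x); m <- ncol(y)
  if (nrow(y) != n) abort("x and y must have the same number of rows")
  a_cap <- min(n - 1L, p)
  if (ncomp < 1 || ncomp > a_cap) {
    abort(sprintf("`ncomp` must be in 1..%d (min(n - 1, p))", a_cap))
  }
  x_mean <- colMeans(x); y_mean <- colMeans(y)
  if (all(abs(sweep(y, 2, y_mean)) < 1e-14)) {
    abort("degenerate response: all values equal after centering")
  }
  xc <- sweep(x, 2, x_mean); yc <- sweep(y, 2, y_mean)
  w_mat <- matrix(0, p, ncomp); p_mat <- matrix(0, p, ncomp)
  q_mat <- matrix(0, m, ncomp); t_mat <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    s <- crossprod(xc, yc) # p x m covariance block
    w <- if (m == 1L) s else {
      v <- eigen(crossprod(s), symmetric = TRUE)$vectors[, 1]
      s %*% v
    }
    wn <- sqrt(sum(w^2))
    if (wn < 1e-14) abort("X deflated to zero; reduce `ncomp`")
    w <- w / wn
    if (w[which.max(abs(w))] < 0) w <- -w # fix eigenvector sign
    tt <- xc %*% w
    q <- crossprod(yc, tt) / sum(tt^2)
    pv <- crossprod(xc, tt) / sum(tt^2)
    w_mat[, a] <- w; p_mat[, a] <- pv; q_mat[, a] <- q; t_mat[, a] <- tt
    xc <- xc - tcrossprod(tt, pv)
    yc <- yc - tcrossprod(tt, q)
  }
  coefs <- w_mat %*% solve(crossprod(p_mat, w_mat), t(q_mat))
  structure(
    list(n_components = ncomp, x_weights = w_mat, x_loadings = p_mat,
         y_loadings = q_mat, x_scores = t_mat, coefficients = coefs,
         x_mean = x_mean, y_mean = y_mean,
         y_names = colnames(y) %||% paste0("y", seq_len(m))),
    class = "pls_model")
}

# Coefficient matrices for every truncation a = 1..A of a fitted model.
pls_coef_path <- function(model) {
  a_all <- model$n_components
  lapply(seq_len(a_all), function(a) {
    w <- model$x_weights[, seq_len(a), drop = FALSE]
    p <- model$x_loadings[, seq_len(a), drop = FALSE]
    q <- model$y_loadings[, seq_len(a), drop = FALSE]
    w %*% solve(crossprod(p, w), t(q))
  })
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata predictor matrix with the training column count.
#' @param ncomp optional truncation to fewer components than fitted.
#' @param ... unused.
#' @return predicted response matrix `(X - x_mean) B + y_mean`.
#' @export
predict.pls_model <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    abort(sprintf("newdata has %d columns; model was trained on %d",
                  ncol(newdata), length(object$x_mean)))
  }
  b <- if (is.null(ncomp)) object$coefficients else {
    if (ncomp < 1 || ncomp > object$n_components) abort("invalid `ncomp`")
    pls_coef_path(object)[[ncomp]]
  }
  out <- sweep(newdata, 2, object$x_mean) %*% b
  sweep(out, 2, object$y_mean, `+`)
}

#' @exportS3Method generics::tidy
tidy.pls_model <- function(x, ...) {
  p <- nrow(x$coefficients)
  var_names <- rownames(x$coefficients) %||% paste0("x", seq_len(p))
  purrr::map_dfr(seq_len(x$n_components), function(a) {
    tibble(component = a, term = var_names,
           weight = x$x_weights[, a], loading = x$x_loadings[, a])
  })
}

#' @exportS3Method generics::glance
glance.pls_model <- function(x, ...) {
  tibble(n_components = x$n_components,
         n_samples = nrow(x$x_scores),
         n_variables = nrow(x$coefficients))
}

#' Cross-validated component selection for PLS
#'
#' Computes `RMSECV(A)` for `A = 1..a_max`: each fold is refit from scratch
#' and held-out predictions are pooled over all samples and response columns,
#' `RMSECV = sqrt(mean((y - yhat)^2))`. `best_a` is the smallest `A` within
#' 1e-12 of the minimum (parsimony tie-break).
#'
#' @inheritParams fit_pls
#' @param a_max largest component count to consider.
#' @param folds `"loo"` (default) or an integer number of venetian-blind
#'   folds; alternatively an integer vector of per-sample fold labels.
#' @return an object of class `cv_pls` with `rmsecv` (length `a_max`),
#'   `best_a` and the fold scheme.
#' @export
cross_validate_pls <- function(x, y, a_max, folds = "loo") {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  fold_id <- if (identical(folds, "loo")) {
    seq_len(n)
  } else if (length(folds) == 1L) {
    if (folds < 2) abort("need at least 2 folds")
    venetian_folds(n, as.integer(folds))
  } else {
    as.integer(folds)
  }
  a_cap <- min(table(fold_id) |> (\(t) n - max(t))() - 1L, ncol(x))
  a_max <- as.integer(a_max)
  if (a_max < 1) abort("`a_max` must be >= 1")
  a_use <- min(a_max, a_cap)
  press <- numeric(a_use)
  n_pooled <- 0
  for (f in unique(fold_id)) {
    hold <- fold_id == f
    if (length(unique(apply(y[!hold, , drop = FALSE], 1, paste,
                            collapse = "\r"))) < 2) {
      warn(sprintf("fold %s leaves a single response pattern; skipped", f))
      next
    }
    fit <- fit_pls(x[!hold, , drop = FALSE], y[!hold, , drop = FALSE], a_use)
    xh <- sweep(x[hold, , drop = FALSE], 2, fit$x_mean)
    # accumulate per-component predictions by score deflation (equivalent to
    # the coefficient form, without per-A solves)
    resid <- sweep(y[hold, , drop = FALSE], 2, fit$y_mean)
    for (a in seq_len(a_use)) {
      tt <- xh %*% fit$x_weights[, a]
      resid <- resid - tt %*% t(fit$y_loadings[, a, drop = FALSE])
      xh <- xh - tt %*% t(fit$x_loadings[, a, drop = FALSE])
      press[a] <- press[a] + sum(resid^2)
    }
    n_pooled <- n_pooled + sum(hold) * ncol(y)
  }
  rmsecv <- sqrt(press / n_pooled)
  rmsecv <- c(rmsecv, rep(NA_real_, a_max - a_use))
  best <- which(rmsecv <= min(rmsecv, na.rm = TRUE) + 1e-12)[1]
  structure(list(rmsecv = rmsecv, best_a = best,
                 fold_scheme = if (identical(folds, "loo")) "loo"
                               else paste0(length(unique(fold_id)), "-fold")),
            class = "cv_pls")
}

#' @exportS3Method generics::tidy
tidy.cv_pls <- function(x, ...) {
  tibble(n_components = seq_along(x$rmsecv), rmsecv = x$rmsecv,
         best = seq_along(x$rmsecv) == x$best_a)
}

#' @exportS3Method generics::glance
glance.cv_pls <- function(x, ...) {
  tibble(best_a = x$best_a, rmsecv_min = x$rmsecv[x$best_a],
         fold_scheme = x$fold_scheme)
}
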