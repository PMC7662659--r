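# Successive projections algorithm (SPA).
#
# Greedy forward selection minimising collinearity: starting from a candidate
# column, each step projects all remaining columns onto the orthogonal
# complement of the span selected so far and picks the one with the largest
# projection norm. Candidate chains from every start are scored by
# leave-one-out RMSE of a multiple linear regression on the subset.

# Build one projection chain of length k_max starting at column `start`.
# Returns the ordered indices (may stop early if the remaining projections
# are numerically zero).
spa_chain <- function(x, start, k_max) {
  p <- ncol(x)
  proj <- x
  norms0 <- colSums(x^2)
  sel <- integer(0)
  cur <- start
  for (k in seq_len(k_max)) {
    sel <- c(sel, cur)
    q <- proj[, cur]
    qq <- sum(q^2)
    if (qq < 1e-12 * max(norms0)) break
    proj <- proj - q %*% (crossprod(q, proj) / qq)
    nrm <- colSums(proj^2)
    nrm[sel] <- -1
    nrm[nrm < 1e-10 * norms0] <- -1 # rank-deficient: skip candidate
    if (k == k_max || all(nrm < 0)) break
    cur <- which.max(nrm)
  }
  sel
}

# Leave-one-out RMSE of intercept + columns `x` regressed on (multi-)response
# y, for every prefix length k_min..k_max of the column order. Uses the hat
# diagonal from an incrementally grown orthonormal basis.
loo_rmse_prefix <- function(x, y, k_min, k_max) {
  n <- nrow(x)
  y <- as.matrix(y)
  q_basis <- matrix(1 / sqrt(n), n, 1) # intercept column, normalised
  res <- y - q_basis %*% crossprod(q_basis, y)
  h <- rowSums(q_basis^2)
  out <- rep(NA_real_, k_max)
  for (k in seq_len(min(k_max, ncol(x)))) {
    v <- x[, k]
    v <- drop(v - q_basis %*% crossprod(q_basis, v))
    v <- drop(v - q_basis %*% crossprod(q_basis, v)) # reorthogonalise
    nv <- sqrt(sum(v^2))
    if (nv > 1e-10) {
      v <- v / nv
      q_basis <- cbind(q_basis, v)
      res <- res - tcrossprod(v, drop(crossprod(res, v)))
      h <- h + v^2
    }
    if (k >= k_min) {
      e_loo <- res / pmax(1 - h, 1e-10)
      out[k] <- sqrt(mean(e_loo^2))
    }
  }
  out
}

#' SPA variable selection
#'
#' Runs a projection chain from every candidate start column, scores each
#' (start, k) prefix with `k_min <= k <= k_max` by leave-one-out RMSE of a
#' linear regression on the subset, and returns the minimiser (ties broken
#' toward fewer variables, then the lower start index).
#'
#' @param x predictor matrix (n x p); columns are used as given (no
#'   centering), as in the classical formulation.
#' @param y response vector or dummy matrix.
#' @param k_min,k_max bounds on the selected subset size (defaults 5 and 30).
#' @param starts candidate start columns; default all columns.
#' @return an object of class `spa_result`: `selected_index` (in selection
#'   order), `rmse_by_k` for the winning start, `k_range`, `start`.
#' @export
spa_select <- function(x, y, k_min = 5, k_max = 30, starts = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  k_max <- min(k_max, n - 1L, p)
  k_min <- min(k_min, k_max)
  starts <- starts %||% seq_len(p)
  best <- list(rmse = Inf, k = NA_integer_, start = NA_integer_,
               chain = integer(0), rmse_by_k = rep(NA_real_, k_max))
  for (s in starts) {
    chain <- spa_chain(x, s, k_max)
    if (length(chain) < k_min) next
    rk <- loo_rmse_prefix(x[, chain, drop = FALSE], y, k_min, k_max)
    k_best <- which(rk <= min(rk, na.rm = TRUE) + 1e-12)[1]
    if (rk[k_best] < best$rmse - 1e-12) {
      best <- list(rmse = rk[k_best], k = k_best, start = s, chain = chain,
                   rmse_by_k = rk)
    }
  }
  if (!is.finite(best$rmse)) abort("no admissible SPA chain found")
  structure(
    list(selected_index = best$chain[seq_len(best$k)],
         rmse_by_k = best$rmse_by_k, k_range = c(k_min, k_max),
         start = best$start, rmse = best$rmse),
    class = "spa_result")
}

#' @exportS3Method generics::tidy
tidy.spa_result <- function(x, ...) {
  tibble(k = seq_along(x$rmse_by_k), rmse = x$rmse_by_k,
         chosen = seq_along(x$rmse_by_k) == length(x$selected_index))
}

#' @exportS3Method generics::glance
glance.spa_result <- function(x, ...) {
  tibble(n_selected = length(x$selected_index), rmse = x$rmse,
         start = x$start, k_min = x$k_range[1], k_max = x$k_range[2])
}

#' RMSE-versus-subset-size plot for an SPA selection
#'
#' @param object a `spa_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spa_result <- function(object, ...) {
  df <- dplyr::filter(tidy(object), !is.na(.data$rmse))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rmse)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$chosen),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "number of selected variables",
                  y = "validation RMSE") +
    ggplot2::theme_minimal()
}

#' Chained UVE-SPA wavelength selection
#'
#' Runs [uve_select()] to discard variables indistinguishable from noise,
#' then [spa_select()] on the retained pool; indices are reported against the
#' original columns of `x`.
#'
#' @inheritParams uve_select
#' @inheritParams spa_select
#' @return an object of class `uve_spa_result`: `selected_index` (original
#'   indexing), plus the underlying `uve` and `spa` results.
#' @export
uve_spa_select <- function(x, y, pls_factor = 12, n_artificial = ncol(x),
                           noise_amplitude = NULL, seed = 1L,
                           k_min = 5, k_max = 30) {
  uve <- uve_select(x, y, pls_factor = pls_factor,
                    n_artificial = n_artificial,
                    noise_amplitude = noise_amplitude, seed = seed)
  pool <- uve$retained_index
  if (length(pool) < k_min) {
    abort(sprintf(
      "UVE retained only %d variable(s), fewer than k_min = %d; widen the cutoff (e.g. more artificial variables or a different pls_factor)",
      length(pool), k_min))
  }
  spa <- spa_select(as.matrix(x)[, pool, drop = FALSE], y,
                    k_min = k_min, k_max = k_max)
  structure(
    list(selected_index = pool[spa$selected_index], uve = uve, spa = spa),
    class = "uve_spa_result")
}

#' @exportS3Method generics::glance
glance.uve_spa_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble(n_selected = length(x$selected_index)),
    dplyr::rename_with(glance(x$uve), ~ paste0("uve_", .x)),
    dplyr::rename_with(glance(x$spa), ~ paste0("spa_", .x)))
}
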