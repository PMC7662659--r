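# Uninformative variable elimination (UVE).
#
# Appends artificial noise variables to X, runs leave-one-out PLS, and scores
# every variable by the stability of its regression coefficient across folds,
# c_j = mean(b_j) / sd(b_j). Real variables whose |stability| does not exceed
# the largest |stability| seen among the noise variables carry no more
# information than noise and are discarded.

#' UVE variable screening
#'
#' @param x predictor matrix (n x p).
#' @param y response vector or dummy matrix. With a multi-column response,
#'   stabilities are screened per response column — each column gets its own
#'   noise cutoff (the largest artificial |stability| in that column) and a
#'   variable is kept if it beats the cutoff in any column. The reported
#'   stability is then cutoff-normalised (band edges at +/- 1), so the usual
#'   stability-versus-cutoff plot stays meaningful.
#' @param pls_factor PLS components used in every fold (default 12, capped at
#'   what the fold size and `p` admit).
#' @param n_artificial number of appended noise variables; default `p`
#'   (at least `p / 2` is recommended for a stable cutoff).
#' @param noise_amplitude scale of the uniform noise columns; stability is
#'   scale-free, the default `0.01 * mean(|x|)` merely keeps the appended
#'   block numerically harmless.
#' @param seed integer seed for the noise draw.
#' @return an object of class `uve_result`: `stability` over real then
#'   artificial variables, `cutoff_lo`/`cutoff_hi`, `retained_index`,
#'   `n_artificial`, `pls_factor`.
#' @export
uve_select <- function(x, y, pls_factor = 12, n_artificial = ncol(x),
                       noise_amplitude = NULL, seed = 1L) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x); p <- ncol(x)
  noise_amplitude <- noise_amplitude %||% (0.01 * mean(abs(x)))
  withr::local_seed(as.integer(seed))
  noise <- matrix(runif(n * n_artificial), n, n_artificial) * noise_amplitude
  z <- cbind(x, noise)
  a <- min(pls_factor, n - 2L, ncol(z))
  m <- ncol(y)
  b_sum <- matrix(0, ncol(z), m)
  b_ssq <- matrix(0, ncol(z), m)
  for (i in seq_len(n)) {
    fit <- fit_pls(z[-i, , drop = FALSE], y[-i, , drop = FALSE], a)
    b <- fit$coefficients
    b_sum <- b_sum + b
    b_ssq <- b_ssq + b^2
  }
  b_mean <- b_sum / n
  b_sd <- sqrt(pmax(b_ssq / n - b_mean^2, 0) * n / (n - 1))
  c_all <- b_mean / b_sd # Inf where sd == 0
  if (m == 1L) {
    stab <- c_all[, 1]
    art <- stab[p + seq_len(n_artificial)]
    cutoff_hi <- max(abs(art)) # Inf artificial stability widens the band
    real <- stab[seq_len(p)]
    retained <- which(abs(real) > cutoff_hi | is.infinite(real))
  } else {
    # per-column screening: each response column carries its own cutoff,
    # the max |stability| of the artificial block in that column; report
    # the cutoff-normalised stability (band edges at +/- 1)
    cutoff_k <- apply(abs(c_all[p + seq_len(n_artificial), , drop = FALSE]),
                      2, max)
    margins <- sweep(abs(c_all), 2, pmax(cutoff_k, 1e-300), `/`)
    margins[is.nan(margins)] <- 1 # Inf/Inf: pinned to the band edge
    pick <- max.col(margins, ties.method = "first")
    sel <- cbind(seq_len(nrow(c_all)), pick)
    stab <- sign(c_all[sel]) * margins[sel]
    cutoff_hi <- 1
    real <- stab[seq_len(p)]
    retained <- which(real > 1 | real < -1 | is.infinite(real))
  }
  cutoff_lo <- -cutoff_hi
  structure(
    list(stability = stab, cutoff_lo = cutoff_lo, cutoff_hi = cutoff_hi,
         retained_index = retained, n_artificial = n_artificial,
         pls_factor = a, n_real = p),
    class = "uve_result")
}

#' @exportS3Method generics::tidy
tidy.uve_result <- function(x, ...) {
  tibble(
    variable = seq_along(x$stability),
    stability = x$stability,
    artificial = seq_along(x$stability) > x$n_real,
    retained = seq_along(x$stability) %in% x$retained_index)
}

#' @exportS3Method generics::glance
glance.uve_result <- function(x, ...) {
  tibble(n_real = x$n_real, n_artificial = x$n_artificial,
         n_retained = length(x$retained_index),
         cutoff = x$cutoff_hi, pls_factor = x$pls_factor)
}

#' Stability plot for a UVE screening
#'
#' Real variables left of the vertical divider, artificial noise variables
#' right of it; horizontal lines mark the noise cutoff band.
#'
#' @param object a `uve_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.uve_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$stability,
                                   colour = .data$artificial)) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = object$n_real + 0.5,
                        colour = "goldenrod") +
    ggplot2::geom_hline(yintercept = c(object$cutoff_lo, object$cutoff_hi),
                        linetype = 2) +
    ggplot2::labs(x = "variable index (real | artificial)",
                  y = "stability c") +
    ggplot2::theme_minimal()
}
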