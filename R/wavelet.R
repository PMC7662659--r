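# Discrete wavelet transform and spectral denoising.
#
# Orthogonal Daubechies DWT with symmetric (half-sample) signal extension.
# Coefficient vectors at each level have length floor((n + F - 1) / 2) for
# filter length F, so the analysis is slightly redundant at the edges and the
# synthesis step reconstructs any signal length exactly (perfect
# reconstruction holds for odd lengths too).

# Standard Daubechies lowpass (scaling) analysis filters, db1-db4.
.db_dec_lo <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(-0.12940952255126037, 0.2241438680420134,
          0.8365163037378079, 0.48296291314453416),
  db3 = c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.8068915093110925, 0.33267055295008263),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
)

db_filters <- function(basis = "db3") {
  basis <- tolower(basis)
  lo <- .db_dec_lo[[basis]]
  if (is.null(lo)) {
    abort(paste0("unsupported wavelet basis '", basis, "'; available: ",
                 paste(names(.db_dec_lo), collapse = ", ")))
  }
  f <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(f) - 1) # quadrature mirror
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       length = f)
}

#' Maximum admissible decomposition level
#'
#' @param n signal length.
#' @param basis Daubechies basis identifier (`"db1"`-`"db4"`).
#' @return the deepest level for which the coarsest band still holds at least
#'   one full filter support, `floor(log2(n / (F - 1)))`.
#' @export
dwt_max_level <- function(n, basis = "db3") {
  f <- db_filters(basis)$length
  if (n < f) return(0L)
  as.integer(floor(log2(n / (f - 1))))
}

# Half-sample symmetric extension by `k` on both sides.
ext_symmetric <- function(x, k) {
  n <- length(x)
  left <- x[pmin(n, pmax(1, k:1))]
  right <- x[pmin(n, pmax(1, n:(n - k + 1)))]
  c(left, x, right)
}

# One analysis step: returns approximation and detail coefficients of length
# floor((n + F - 1) / 2).
dwt_step <- function(x, filt) {
  f <- filt$length
  n <- length(x)
  xe <- ext_symmetric(x, f - 1)
  lc <- floor((n + f - 1) / 2)
  # downsampled convolution: out[k] = sum_j filt[j] * xext[2k + 1 - j]
  # (0-based); xe[m] holds xext[m - f]
  idx <- outer(2 * seq_len(lc), seq_len(f), function(k, j) k - j + f)
  xm <- matrix(xe[idx], lc, f)
  list(a = drop(xm %*% filt$dec_lo),
       d = drop(xm %*% filt$dec_hi))
}

# One synthesis step back to length `n_out`.
idwt_step <- function(a, d, filt, n_out) {
  f <- filt$length
  l <- length(a)
  up <- function(v) { u <- numeric(2 * l - 1); u[seq(1, 2 * l - 1, 2)] <- v; u }
  rec <- function(u, h) stats::convolve(u, rev(h), type = "open")
  y <- rec(up(a), filt$rec_lo) + rec(up(d), filt$rec_hi)
  y <- y[(f - 1):(2 * l)] # drop extension transients; length 2l - f + 2
  if (length(y) < n_out) abort("inconsistent coefficient lengths")
  y[seq_len(n_out)]
}

#' Multilevel wavelet decomposition
#'
#' @param x numeric signal.
#' @inheritParams dwt_max_level
#' @param level decomposition depth (>= 1, <= [dwt_max_level()]).
#' @return list with `a` (coarsest approximation), `d` (list of detail
#'   vectors, level 1 = finest first), `lengths` (per-level input lengths,
#'   used by [waverec()]), `basis`, `level`.
#' @export
wavedec <- function(x, basis = "db3", level = 4) {
  filt <- db_filters(basis)
  n <- length(x)
  maxlev <- dwt_max_level(n, basis)
  if (level < 1) abort("`level` must be >= 1")
  if (level > maxlev) {
    abort(sprintf("level %d too deep for signal length %d (max admissible %d)",
                  level, n, maxlev))
  }
  d <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (j in seq_len(level)) {
    lens[j] <- length(a)
    s <- dwt_step(a, filt)
    d[[j]] <- s$d
    a <- s$a
  }
  list(a = a, d = d, lengths = lens, basis = basis, level = level)
}

#' Multilevel wavelet reconstruction
#'
#' Inverse of [wavedec()]; reconstructs the original signal length exactly.
#'
#' @param dec a decomposition from [wavedec()].
#' @return numeric signal of the original length.
#' @export
waverec <- function(dec) {
  filt <- db_filters(dec$basis)
  a <- dec$a
  for (j in rev(seq_len(dec$level))) {
    a <- idwt_step(a, dec$d[[j]], filt, dec$lengths[j])
  }
  a
}

#' Wavelet denoising configuration
#'
#' Defaults follow common FT-MIR practice: Daubechies db3 basis, depth 4,
#' universal threshold `sigma * sqrt(2 log n)` with soft shrinkage, where
#' `sigma` is the robust noise estimate `median(|finest detail|) / 0.6745`.
#'
#' @param basis Daubechies basis identifier.
#' @param level decomposition depth.
#' @param threshold_rule `"universal_soft"` or `"universal_hard"`.
#' @param threshold optional fixed threshold overriding the universal rule
#'   (0 disables shrinkage entirely).
#' @param boundary signal extension mode; only `"symmetric"` is implemented.
#' @return a `wavelet_config` list.
#' @export
wavelet_config <- function(basis = "db3", level = 4,
                           threshold_rule = c("universal_soft",
                                              "universal_hard"),
                           threshold = NULL, boundary = "symmetric") {
  threshold_rule <- match.arg(threshold_rule)
  if (!identical(boundary, "symmetric")) {
    abort("only symmetric boundary extension is implemented")
  }
  structure(list(basis = basis, level = as.integer(level),
                 threshold_rule = threshold_rule, threshold = threshold,
                 boundary = boundary),
            class = "wavelet_config")
}

#' Denoise one spectrum by wavelet shrinkage
#'
#' Forward transform to `config$level`, shrink all detail coefficients
#' (approximation untouched), inverse transform. Deterministic; output length
#' equals input length.
#'
#' @param x numeric absorbance vector.
#' @param config a [wavelet_config()].
#' @return denoised numeric vector.
#' @export
denoise_spectrum <- function(x, config = wavelet_config()) {
  dec <- wavedec(x, config$basis, config$level)
  thr <- config$threshold
  if (is.null(thr)) {
    sigma <- median(abs(dec$d[[1]])) / 0.6745
    thr <- sigma * sqrt(2 * log(length(x)))
  }
  shrink <- if (config$threshold_rule == "universal_soft") {
    function(d) sign(d) * pmax(abs(d) - thr, 0)
  } else {
    function(d) d * (abs(d) > thr)
  }
  dec$d <- lapply(dec$d, shrink)
  waverec(dec)
}

#' Denoise every spectrum of a dataset
#'
#' Row-wise [denoise_spectrum()]; labels and axis unchanged.
#'
#' @inheritParams spectra_matrix
#' @inheritParams denoise_spectrum
#' @return the denoised dataset tibble.
#' @export
denoise_spectra <- function(data, config = wavelet_config()) {
  m <- spectra_matrix(data)
  out <- t(apply(m, 1, denoise_spectrum, config = config))
  set_spectra_matrix(data, out)
}

#' Per-class mean spectra
#'
#' @inheritParams spectra_matrix
#' @param by grouping label, `"origin"` or `"variety"`.
#' @return tibble with the class column followed by columnwise mean spectra.
#' @export
class_mean_spectra <- function(data, by = c("origin", "variety")) {
  by <- match.arg(by)
  data |>
    dplyr::select(dplyr::all_of(by),
                  !dplyr::any_of(setdiff(.meta_cols, by))) |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                     .groups = "drop")
}
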