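# Internal numerical helpers shared across modules.

#' Moore-Penrose pseudoinverse via SVD
#'
#' @param a numeric matrix.
#' @param tol singular values below `tol * max(d)` are treated as zero.
#' @return the pseudoinverse of `a`.
#' @keywords internal
#' @noRd
pinv <- function(a, tol = 1e-10) {
  s <- svd(a)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) {
    return(matrix(0, ncol(a), nrow(a)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' One-hot (dummy) coding of a label vector
#'
#' @param labels character or factor vector.
#' @param levels label order; defaults to sorted unique labels.
#' @return 0/1 matrix, one column per level, named by level.
#' @keywords internal
#' @noRd
one_hot <- function(labels, levels = NULL) {
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  y[cbind(seq_along(labels), match(labels, levels))] <- 1
  y
}

logistic <- function(x) 1 / (1 + exp(-x))

# Venetian-blind fold assignment: sample i goes to fold ((i - 1) %% k) + 1.
# Deterministic, interleaves classes when samples are grouped by class.
venetian_folds <- function(n, k) ((seq_len(n) - 1L) %% k) + 1L

`%||%` <- function(x, y) if (is.null(x)) y else x
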