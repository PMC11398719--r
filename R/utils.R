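# Edge vectorization helpers. Connectome matrices are symmetric with a zero
# diagonal, so each subject's matrix is stored as its strict upper triangle
# in column-major order; these helpers go back and forth.

#' Upper-triangle edge index table
#'
#' Enumerates the undirected region pairs of an \code{n}-region parcellation
#' in the column-major order used to vectorize connectome matrices.
#'
#' @param n Number of regions.
#' @return A data.frame with integer columns \code{i} and \code{j}
#'   (\code{i < j}), one row per undirected pair.
#' @export
edgeIndex <- function(n) {
  stopifnot(is.numeric(n), n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  data.frame(i = idx[, 1L], j = idx[, 2L])
}

#' @rdname edgeIndex
#' @param m A symmetric matrix.
#' @return For \code{edgeVector}, the strict upper triangle of \code{m} as a
#'   vector.
#' @export
edgeVector <- function(m) {
  m[upper.tri(m)]
}

#' @rdname edgeIndex
#' @param v An edge vector of length \code{n*(n-1)/2}.
#' @return For \code{edgeMatrix}, the symmetric \code{n x n} matrix with zero
#'   diagonal whose upper triangle is \code{v}.
#' @export
edgeMatrix <- function(v, n) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

# z-score a vector; constant input maps to zeros rather than NaN
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# set.seed unless seed is NULL; callers advance derived seeds by small
# offsets so stages are independently reproducible
withSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

checkSymmetricNonneg <- function(m, what = "matrix", upper = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop(what, " contains non-finite values", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop(what, " must be symmetric", call. = FALSE)
  if (min(m) < 0)
    stop(what, " must be nonnegative", call. = FALSE)
  if (!is.null(upper) && max(m) > upper + 1e-12)
    stop(what, " entries must be <= ", upper, call. = FALSE)
  if (any(diag(m) != 0))
    stop(what, " must have a zero diagonal", call. = FALSE)
  invisible(m)
}
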