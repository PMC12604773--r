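#' Sum of the k largest entries of a vector
#'
#' Computes \eqn{s^{(k)}(x) = \sum_{t=1}^{k} x_{\pi(t)}} where \eqn{\pi}
#' sorts the entries of \code{x} in decreasing order.  On the nonnegative
#' cone the difference \eqn{e^T x - s^{(k)}(x)} vanishes exactly when
#' \code{x} has at most \code{k} nonzero entries, which is the identity
#' the sparsity penalty of the tri-factorization objective is built on.
#'
#' @param x numeric vector.
#' @param k integer, \code{1 <= k <= length(x)}.
#' @return scalar, the sum of the \code{k} largest entries.
#' @seealso [largest_k_norm()], [subgrad_sum_top_k()]
#' @export
#' @examples
#' sum_top_k(c(0.5, 3, 1, 2), 2)  # 5
sum_top_k <- function(x, k) {
  check_k(x, k)
  sum(sort(x, decreasing = TRUE)[seq_len(k)])
}

#' Largest-k norm of a vector
#'
#' The sum of the \code{k} largest absolute values of \code{x}.  For
#' \code{k = length(x)} this is the \eqn{\ell_1} norm; on nonnegative
#' vectors it coincides with [sum_top_k()].
#'
#' @inheritParams sum_top_k
#' @return scalar norm value.
#' @export
largest_k_norm <- function(x, k) {
  check_k(x, k)
  sum(sort(abs(x), decreasing = TRUE)[seq_len(k)])
}

#' Subgradient of the sum-of-top-k function
#'
#' Returns a 0/1 indicator vector \code{z} with ones at the \code{k}
#' selected (largest) positions, a member of the subdifferential
#' \eqn{\partial s^{(k)}(x)}: it satisfies \eqn{\sum_t z_t = k},
#' \eqn{0 \le z_t \le 1} and \eqn{\langle x, z\rangle = s^{(k)}(x)}.
#' Ties are broken deterministically: among equal entries the lower
#' index wins (stable sort), so repeated runs select the same support.
#'
#' @inheritParams sum_top_k
#' @return numeric 0/1 vector of \code{length(x)}.
#' @export
#' @examples
#' subgrad_sum_top_k(c(0.5, 3, 1, 2), 2)  # 0 1 0 1
subgrad_sum_top_k <- function(x, k) {
  check_k(x, k)
  ord <- order(x, decreasing = TRUE)          # stable: lower index wins ties
  z <- numeric(length(x))
  z[ord[seq_len(k)]] <- 1
  z
}

#' Proximal operator of the nonnegativity-restricted linear penalty
#'
#' Solves \eqn{\mathrm{argmin}_{Z \ge 0}\; a\, e^T Z e + \tfrac12 \|Z -
#' X\|_F^2}, the proximal map of the convex part of the sparsity penalty
#' (a linear form on the nonnegative cone) scaled by the inverse step
#' size, i.e. \code{a = lambdaG / l2}.  The closed form is the shifted
#' nonnegative soft threshold \code{pmax(X - a, 0)}.
#'
#' @param X numeric matrix (or vector).
#' @param a nonnegative scalar threshold.
#' @return matrix of the same shape as \code{X}, entrywise nonnegative.
#' @export
prox_nonneg_linear <- function(X, a) {
  if (!is.numeric(a) || length(a) != 1L || is.na(a) || a < 0)
    stopf("threshold 'a' must be a single nonnegative number")
  pmax(X - a, 0)
}

check_k <- function(x, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) ||
      k < 1 || k > length(x) || k != floor(k))
    stopf("k must be an integer in [1, %d], got %s", length(x), format(k))
  invisible(TRUE)
}
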