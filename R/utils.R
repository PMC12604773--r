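#' @keywords internal
"_PACKAGE"

## Key used for the coupling-matrix dictionary and relation lookup.
rel_key <- function(i, j) paste(i, j, sep = "_")

## Moore-Penrose pseudoinverse via SVD (rank decided by a relative
## singular-value cutoff, as in the usual numeric convention).
pinv <- function(A, tol = .Machine$double.eps) {
  s <- svd(A)
  keep <- s$d > max(dim(A)) * tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

## Frobenius inner product of two conformable lists of matrices.
list_dot <- function(a, b) {
  sum(vapply(seq_along(a), function(t) sum(a[[t]] * b[[t]]), numeric(1)))
}

## Elementwise difference of two lists of matrices.
list_sub <- function(a, b) {
  out <- a
  for (t in seq_along(a)) out[[t]] <- a[[t]] - b[[t]]
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
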