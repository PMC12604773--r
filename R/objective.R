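#' Solver hyperparameters
#'
#' Collects every tunable of the tri-factorization solver with the
#' package defaults.  \code{lambda} weights the quadratic constraint
#' regularizer \eqn{\mathrm{tr}(G^T\Theta G)}; \code{lambdaG} is the
#' difference-of-convex sparsity penalty weight; \code{k} is the
#' per-factor cardinality budget applied to \code{vec(G_i)} (the same
#' scalar for every type, clamped to the factor size).  \code{delta},
#' \code{tau} and \code{eta} drive the non-monotone Armijo line search:
#' the sufficient-decrease constant, the envelope decay in (0,1), and
#' the step-estimate escalation factor.  \code{l_min}, \code{l_max}
#' bound the Barzilai-Borwein curvature estimates and \code{l_init} is
#' the fallback when the secant information is unusable.
#'
#' @param lambda nonnegative constraint-regularizer weight.
#' @param lambdaG positive sparsity penalty weight.
#' @param k positive integer cardinality budget per factor matrix.
#' @param delta positive Armijo sufficient-decrease constant.
#' @param tau envelope decay factor in (0,1); the limit tau -> 0
#'   recovers a monotone Armijo rule.
#' @param eta step-estimate growth factor, > 1.
#' @param l_min,l_max positive bounds for the curvature estimates.
#' @param l_init fallback curvature estimate.
#' @param ls_max maximum backtracking trials per line search.
#' @param max_iter iteration cap of the outer loop.
#' @param tol relative objective-change stopping tolerance.
#' @param seed integer RNG seed (factor initialization, splits).
#' @param reweight logical; refresh the source weights
#'   \eqn{\omega_{ij} = 1/(2\|R_{ij}-G_iS_{ij}G_j^T\|_F^2)} after every
#'   accepted iteration (and at initialization).  When \code{FALSE} the
#'   weights declared on the network are used throughout.
#' @param eps_res residual floor guarding the weight update against
#'   division by zero on exactly fitted blocks.
#' @param init factor initialization: \code{"random"} (seeded scaled
#'   uniform) or \code{"svd"} (absolute leading singular vectors of the
#'   concatenated incident blocks).
#' @param project_k logical; after fitting, keep only the top-k entries
#'   of each factor (hard projection) before prediction.
#' @return a list of class \code{fit_control}.
#' @export
fit_control <- function(lambda = 1e-4, lambdaG = 1e-2, k = 75,
                        delta = 1e-4, tau = 0.5, eta = 2,
                        l_min = 1e-8, l_max = 1e8, l_init = 1,
                        ls_max = 50, max_iter = 100, tol = 1e-6,
                        seed = 1, reweight = TRUE, eps_res = 1e-12,
                        init = c("random", "svd"), project_k = FALSE) {
  init <- match.arg(init)
  if (lambda < 0) stopf("lambda must be >= 0")
  if (lambdaG <= 0) stopf("lambdaG must be > 0")
  if (k < 1 || k != floor(k)) stopf("k must be a positive integer")
  if (delta <= 0) stopf("delta must be > 0")
  if (tau <= 0 || tau >= 1) stopf("tau must lie in (0,1)")
  if (eta <= 1) stopf("eta must be > 1")
  if (l_min <= 0 || l_max <= l_min) stopf("need 0 < l_min < l_max")
  structure(list(lambda = lambda, lambdaG = lambdaG, k = as.integer(k),
                 delta = delta, tau = tau, eta = eta, l_min = l_min,
                 l_max = l_max, l_init = l_init, ls_max = as.integer(ls_max),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), reweight = isTRUE(reweight),
                 eps_res = eps_res, init = init,
                 project_k = isTRUE(project_k)),
            class = "fit_control")
}

## A factor set holds one nonnegative basis matrix per type and one
## coupling matrix per relation block, keyed "i_j".
factor_set <- function(G, S) {
  structure(list(G = G, S = S), class = "factor_set")
}

check_shapes <- function(net, fs) {
  m <- nrow(net$types)
  if (length(fs$G) != m) stopf("factor set has %d G blocks, network has %d types",
                               length(fs$G), m)
  for (i in seq_len(m)) {
    d <- dim(fs$G[[i]])
    if (d[1] != net$types$n[i] || d[2] != net$types$rank[i])
      stopf("G[[%d]] is %dx%d, expected %dx%d", i, d[1], d[2],
            net$types$n[i], net$types$rank[i])
  }
  for (b in net$relations) {
    S <- fs$S[[rel_key(b$i, b$j)]]
    if (is.null(S)) stopf("missing coupling matrix S[%d,%d]", b$i, b$j)
    if (nrow(S) != net$types$rank[b$i] || ncol(S) != net$types$rank[b$j])
      stopf("S[%d,%d] is %dx%d, expected %dx%d", b$i, b$j, nrow(S), ncol(S),
            net$types$rank[b$i], net$types$rank[b$j])
  }
  invisible(TRUE)
}

#' Smooth part of the objective
#'
#' Evaluates \deqn{f(S,G) = \sum_{(i,j)} \omega_{ij}\,\|R_{ij} - G_i
#' S_{ij} G_j^T\|_F^2 + \lambda \sum_i \sum_r \mathrm{tr}(G_i^T
#' \Theta_i^{(r)} G_i).}
#' The weights \eqn{\omega_{ij}} are taken from the network state at
#' call time; during a fit the optimizer controls when they change.
#'
#' @param net a [hetero_network()].
#' @param fs a factor set (fields \code{G}, \code{S}).
#' @param hp a [fit_control()].
#' @return scalar value of the smooth loss.
#' @export
smooth_value <- function(net, fs, hp) {
  check_shapes(net, fs)
  val <- 0
  for (b in net$relations) {
    E <- b$R - fs$G[[b$i]] %*% fs$S[[rel_key(b$i, b$j)]] %*% t(fs$G[[b$j]])
    val <- val + b$weight * sum(E * E)
  }
  if (hp$lambda != 0)
    for (cn in net$constraints) {
      Gi <- fs$G[[cn$i]]
      val <- val + hp$lambda * sum(Gi * (cn$Theta %*% Gi))
    }
  val
}

#' Nonsmooth sparsity penalty
#'
#' The difference-of-convex cardinality penalty
#' \deqn{g(G) = I_C(G) + \lambda_G \sum_i \left(e^T G_i e -
#' s^{(k)}(\mathrm{vec}(G_i))\right),}
#' where \eqn{I_C} is the indicator of the entrywise-nonnegative cone
#' (returned as \code{Inf} rather than an error so line searches can
#' compare objective values uniformly).  On feasible \eqn{G} the
#' penalty is nonnegative and vanishes exactly when every factor has at
#' most \code{k} nonzero entries.
#'
#' @inheritParams smooth_value
#' @return scalar penalty (possibly \code{Inf}).
#' @export
penalty_value <- function(fs, hp) {
  val <- 0
  for (Gi in fs$G) {
    if (any(Gi < 0)) return(Inf)
    v <- as.vector(Gi)
    kk <- min(hp$k, length(v))
    val <- val + hp$lambdaG * (sum(v) - sum_top_k(v, kk))
  }
  val
}

#' Full objective value
#'
#' \code{smooth_value + penalty_value}; infinite whenever a factor
#' leaves the nonnegative cone.
#'
#' @inheritParams smooth_value
#' @return scalar objective value.
#' @export
total_value <- function(net, fs, hp) {
  p <- penalty_value(fs, hp)
  if (is.infinite(p)) return(p)
  smooth_value(net, fs, hp) + p
}

#' Gradient of the smooth loss in the coupling matrices
#'
#' For each relation block, \eqn{\nabla_{S_{ij}} f = -2\,\omega_{ij}\,
#' G_i^T (R_{ij} - G_i S_{ij} G_j^T)\, G_j}.
#'
#' @inheritParams smooth_value
#' @return named list of gradient blocks keyed like \code{fs$S}.
#' @export
grad_S <- function(net, fs, hp) {
  check_shapes(net, fs)
  out <- list()
  for (b in net$relations) {
    key <- rel_key(b$i, b$j)
    E <- b$R - fs$G[[b$i]] %*% fs$S[[key]] %*% t(fs$G[[b$j]])
    out[[key]] <- -2 * b$weight * (t(fs$G[[b$i]]) %*% E %*% fs$G[[b$j]])
  }
  out
}

#' Gradient of the smooth loss in the basis factors
#'
#' Each type aggregates contributions from blocks where it appears as
#' source, blocks where it appears as destination, and its constraint
#' matrices (stored symmetrized, so the regularizer contributes
#' \eqn{2\lambda\Theta_i G_i}):
#' \deqn{\nabla_{G_i} f = \sum_j -2\omega_{ij} E_{ij} G_j S_{ij}^T +
#'   \sum_j -2\omega_{ji} E_{ji}^T G_j S_{ji} +
#'   2\lambda \sum_r \Theta_i^{(r)} G_i,
#'   \quad E_{ij} = R_{ij} - G_i S_{ij} G_j^T.}
#'
#' @inheritParams smooth_value
#' @return list of gradient matrices, one per type.
#' @export
grad_G <- function(net, fs, hp) {
  check_shapes(net, fs)
  out <- lapply(fs$G, function(g) matrix(0, nrow(g), ncol(g)))
  for (b in net$relations) {
    key <- rel_key(b$i, b$j)
    E <- b$R - fs$G[[b$i]] %*% fs$S[[key]] %*% t(fs$G[[b$j]])
    out[[b$i]] <- out[[b$i]] -
      2 * b$weight * (E %*% fs$G[[b$j]] %*% t(fs$S[[key]]))
    out[[b$j]] <- out[[b$j]] -
      2 * b$weight * (t(E) %*% fs$G[[b$i]] %*% fs$S[[key]])
  }
  if (hp$lambda != 0)
    for (cn in net$constraints)
      out[[cn$i]] <- out[[cn$i]] + 2 * hp$lambda * (cn$Theta %*% fs$G[[cn$i]])
  out
}
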