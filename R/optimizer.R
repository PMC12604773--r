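#' Initialize the nonnegative basis factors
#'
#' Deterministic, seed-driven initialization of one nonnegative
#' \code{n_i x k_i} matrix per type.  The default draws uniform
#' nonnegative entries scaled by \eqn{\sqrt{\bar R_i / k_i}}, where
#' \eqn{\bar R_i} is the mean entry over all relation blocks incident
#' to type \code{i}, so that initial reconstructions start on the scale
#' of the data.  The \code{"svd"} variant uses the absolute values of
#' the leading left singular vectors of the horizontal concatenation of
#' incident blocks.  A type with no incident relations falls back to
#' seeded random nonnegative entries.
#'
#' @inheritParams smooth_value
#' @return list of nonnegative factor matrices, one per type.
#' @export
init_factors <- function(net, hp) {
  m <- nrow(net$types)
  set.seed(hp$seed)
  incident <- lapply(seq_len(m), function(i) {
    blocks <- list()
    for (b in net$relations) {
      if (b$i == i) blocks[[length(blocks) + 1L]] <- b$R
      if (b$j == i && b$i != i) blocks[[length(blocks) + 1L]] <- t(b$R)
    }
    blocks
  })
  G <- vector("list", m)
  for (i in seq_len(m)) {
    n_i <- net$types$n[i]; k_i <- net$types$rank[i]
    if (k_i > n_i) stopf("type %d: rank %d exceeds size %d", i, k_i, n_i)
    if (hp$init == "svd" && length(incident[[i]]) > 0) {
      Cc <- do.call(cbind, incident[[i]])
      sv <- svd(Cc, nu = k_i, nv = 0)
      ## scale by sqrt of the singular values so G and S start on
      ## comparable magnitudes (balances the two curvature estimates)
      d <- sqrt(pmax(sv$d[seq_len(min(k_i, length(sv$d)))], 0))
      U <- abs(sv$u) %*% diag(d, length(d))
      if (ncol(U) < k_i)  # rank-deficient concatenation: pad randomly
        U <- cbind(U, matrix(stats::runif(n_i * (k_i - ncol(U))), n_i))
      G[[i]] <- U
    } else {
      mbar <- if (length(incident[[i]]) > 0)
        mean(vapply(incident[[i]], mean, numeric(1))) else 0
      scale <- sqrt(max(mbar, 1e-2) / k_i)
      G[[i]] <- matrix(stats::runif(n_i * k_i, 0, 2 * scale), n_i, k_i)
    }
  }
  G
}

#' Closed-form least-squares initialization of the coupling matrices
#'
#' For each relation block, the minimizer of
#' \eqn{\|R_{ij} - G_i S_{ij} G_j^T\|_F^2} in \eqn{S_{ij}}:
#' \deqn{S_{ij} = (G_i^T G_i)^\dagger G_i^T R_{ij} G_j (G_j^T
#' G_j)^\dagger,} using pseudoinverses so rank-deficient factors are
#' handled gracefully.
#'
#' @param net a [hetero_network()].
#' @param G list of factor matrices as returned by [init_factors()].
#' @return named list of coupling matrices keyed \code{"i_j"}.
#' @export
init_couplings <- function(net, G) {
  S <- list()
  for (b in net$relations) {
    Gi <- G[[b$i]]; Gj <- G[[b$j]]
    S[[rel_key(b$i, b$j)]] <-
      pinv(crossprod(Gi)) %*% t(Gi) %*% b$R %*% Gj %*% pinv(crossprod(Gj))
  }
  S
}

#' Nesterov extrapolation of the factor iterates
#'
#' \deqn{Y = G^{(\ell)} + \frac{\theta^{(\ell-1)}}{\theta^{(\ell)}}
#' (Z^{(\ell)} - G^{(\ell)}) + \frac{\theta^{(\ell-1)} - 1}
#' {\theta^{(\ell)}} (G^{(\ell)} - G^{(\ell-1)}).}
#' The extrapolated point may leave the nonnegative cone; feasibility
#' is restored by the proximal step that follows.
#'
#' @param G_cur,G_prev,Z_cur lists of factor matrices (current iterate,
#'   previous iterate, current proximal iterate).
#' @param theta_prev,theta_cur extrapolation scalars
#'   \eqn{\theta^{(\ell-1)}, \theta^{(\ell)}}; \code{theta_cur} must be
#'   nonzero.
#' @return list of extrapolated matrices.
#' @export
extrapolate <- function(G_cur, G_prev, Z_cur, theta_prev, theta_cur) {
  if (theta_cur == 0) stopf("theta_cur must be nonzero")
  a <- theta_prev / theta_cur
  b <- (theta_prev - 1) / theta_cur
  lapply(seq_along(G_cur), function(i)
    G_cur[[i]] + a * (Z_cur[[i]] - G_cur[[i]]) +
      b * (G_cur[[i]] - G_prev[[i]]))
}

#' Barzilai-Borwein curvature estimate from a secant pair
#'
#' Given an iterate difference \eqn{\Delta x} and the matching gradient
#' difference \eqn{\Delta g}, returns the curvature estimate
#' \eqn{l = \langle\Delta x, \Delta g\rangle / \langle\Delta x, \Delta
#' x\rangle} clipped to \code{[l_min, l_max]}.  For a quadratic with
#' \eqn{\nabla f = L x} this recovers \eqn{L} exactly.  When the secant
#' information is unusable (zero step, or nonpositive/near-zero inner
#' product, as happens in nonconvex regions) the fallback
#' \code{l_init} is returned, clipped into bounds.
#'
#' @param dx,dg matrices, vectors, or lists of matrices (the blocks of
#'   a stacked iterate).
#' @param hp a [fit_control()] supplying \code{l_min}, \code{l_max},
#'   \code{l_init}.
#' @return positive scalar curvature estimate.
#' @export
curvature_stepsize <- function(dx, dg, hp) {
  if (!is.list(dx)) { dx <- list(as.matrix(dx)); dg <- list(as.matrix(dg)) }
  den <- list_dot(dx, dx)
  num <- list_dot(dx, dg)
  clip <- function(l) min(max(hp$l_min, l), hp$l_max)
  if (den <= .Machine$double.eps || num <= 1e-12 * den)
    return(clip(hp$l_init))
  clip(num / den)
}

## Subgradient W(A) of g2(G) = lambdaG * sum_i s^(k)(vec(G_i)),
## evaluated per type with the budget clamped to the factor size.
penalty_subgrad <- function(A, hp) {
  lapply(A, function(Ai) {
    v <- as.vector(Ai)
    kk <- min(hp$k, length(v))
    matrix(hp$lambdaG * subgrad_sum_top_k(v, kk), nrow(Ai), ncol(Ai))
  })
}

## Shared backtracking line search.  `anchor` is the point the proximal
## G-update is taken from: the extrapolated Y for LS-1, the current
## iterate G for LS-2.  Gradients are evaluated once at
## (S_cur, anchor); backtracking only rescales the steps (the
## escalation rule grows l, shrinking 1/l).
line_search <- function(net, hp, S_cur, S_prev, anchor, G_secant_prev,
                        c_env) {
  fs_anchor <- factor_set(anchor, S_cur)
  gS <- grad_S(net, fs_anchor, hp)
  gS_prev <- grad_S(net, factor_set(anchor, S_prev), hp)
  l1 <- curvature_stepsize(
    lapply(names(S_cur), function(k) S_cur[[k]] - S_prev[[k]]),
    lapply(names(S_cur), function(k) gS[[k]] - gS_prev[[k]]), hp)
  gG <- grad_G(net, fs_anchor, hp)
  gG_prev <- grad_G(net, factor_set(G_secant_prev, S_cur), hp)
  l2 <- curvature_stepsize(list_sub(anchor, G_secant_prev),
                           list_sub(gG, gG_prev), hp)
  W <- penalty_subgrad(anchor, hp)

  S_new <- Z_new <- NULL; F_new <- Inf; gap <- NA_real_
  ok <- FALSE; trials <- 0L
  repeat {
    trials <- trials + 1L
    S_new <- lapply(stats::setNames(names(S_cur), names(S_cur)),
                    function(k) S_cur[[k]] - gS[[k]] / l1)
    Z_new <- lapply(seq_along(anchor), function(i)
      prox_nonneg_linear(anchor[[i]] - gG[[i]] / l2 + W[[i]] / l2,
                         hp$lambdaG / l2))
    gap <- list_dot(lapply(names(S_cur), function(k) S_new[[k]] - S_cur[[k]]),
                    lapply(names(S_cur), function(k) S_new[[k]] - S_cur[[k]])) +
           list_dot(list_sub(Z_new, anchor), list_sub(Z_new, anchor))
    F_new <- total_value(net, factor_set(Z_new, S_new), hp)
    if (is.finite(F_new) && F_new <= c_env - hp$delta * gap) {
      ok <- TRUE
      break
    }
    if (trials >= hp$ls_max) break
    l1 <- min(max(hp$l_min, hp$eta * l1), hp$l_max)
    l2 <- min(max(hp$l_min, hp$eta * l2), hp$l_max)
  }
  list(S = S_new, Z = Z_new, l1 = l1, l2 = l2, ok = ok, F = F_new,
       gap = gap, trials = trials)
}

#' Accelerated proximal step at the extrapolated point (LS-1)
#'
#' Takes the fast-track forward-backward step anchored at the
#' extrapolated point \code{Y}: a gradient step in \eqn{S} with step
#' \eqn{1/l_1} and a proximal step in \eqn{G},
#' \deqn{Z = \mathrm{prox}_{(g_1+I_C)/l_2}\!\left(Y - \tfrac{1}{l_2}
#' \nabla_G f(S, Y) + \tfrac{1}{l_2} W(Y)\right),}
#' where \eqn{W(Y)} is a subgradient of the concave penalty part.  The
#' candidate is accepted when the non-monotone Armijo condition
#' \eqn{F(S^+, Z^+) \le c - \delta(\|\Delta S\|_F^2 + \|Z^+ -
#' Y\|_F^2)} holds; otherwise the step estimates are escalated by
#' \code{eta} (clipped into bounds) and the step retaken, up to
#' \code{ls_max} trials.  Failure is a flagged outcome, not an error.
#'
#' @param net a [hetero_network()] (weights as currently in force).
#' @param state optimizer state list with fields \code{S_cur},
#'   \code{S_prev}, \code{G_cur}, \code{G_prev}, \code{Z_cur},
#'   \code{Y}, \code{c}.
#' @param hp a [fit_control()].
#' @return list with fields \code{S}, \code{Z}, \code{l1}, \code{l2},
#'   \code{ok}, \code{F}, \code{gap}, \code{trials}.
#' @export
ls1_step <- function(net, state, hp) {
  line_search(net, hp, state$S_cur, state$S_prev, state$Y, state$G_prev,
              state$c)
}

#' Proximal step at the current iterate (LS-2)
#'
#' Fallback used when the extrapolated step repeatedly fails the
#' descent test: identical structure to [ls1_step()] but anchored at
#' the non-extrapolated iterate \eqn{G^{(\ell)}}, with secant step
#' estimates taken along \eqn{G^{(\ell)} - G^{(\ell-1)}}.  Because the
#' anchor is feasible, escalating the step estimates makes acceptance
#' increasingly easy; the same \code{ls_max} cap still applies as a
#' safeguard against a moving envelope.
#'
#' @inheritParams ls1_step
#' @return list with fields \code{S}, \code{Z} (the candidate
#'   \eqn{V^{(\ell+1)}}), \code{l1}, \code{l2}, \code{ok}, \code{F},
#'   \code{gap}, \code{trials}.
#' @export
ls2_step <- function(net, state, hp) {
  line_search(net, hp, state$S_cur, state$S_prev, state$G_cur, state$G_prev,
              state$c)
}

#' Momentum scalar recurrence
#'
#' \eqn{\theta' = (\sqrt{4\theta^2 + 1} + 1)/2}, the accelerated-
#' gradient recurrence; the output satisfies
#' \eqn{\theta'^2 - \theta' = \theta^2}.
#'
#' @param theta nonnegative scalar.
#' @return updated scalar, \eqn{\ge 1}.
#' @export
update_theta <- function(theta) {
  (sqrt(4 * theta^2 + 1) + 1) / 2
}

#' Non-monotone envelope update
#'
#' \eqn{q' = \tau q + 1}, \eqn{c' = (\tau q c + F_{new})/q'}: the
#' envelope is a decaying weighted average of past objective values;
#' whenever the accepted \eqn{F_{new} \le c}, the new envelope cannot
#' increase.  As \eqn{\tau \to 0} this degenerates to the monotone
#' Armijo rule \eqn{c' = F_{new}}.
#'
#' @param q envelope weight, \eqn{\ge 1}.
#' @param c current envelope value.
#' @param F_new objective value of the accepted iterate.
#' @param tau decay factor in (0,1).
#' @return list with fields \code{q}, \code{c}.
#' @export
update_envelope <- function(q, c, F_new, tau) {
  q_new <- tau * q + 1
  list(q = q_new, c = (tau * q * c + F_new) / q_new)
}

#' Residual-based source weight update
#'
#' \eqn{\omega_{ij} = 1 / (2\,\max(\|R_{ij} - G_i S_{ij}
#' G_j^T\|_F^2,\ \epsilon))}: poorly reconstructed (unreliable) data
#' sources are down-weighted relative to well-fitted ones.  The floor
#' \eqn{\epsilon} caps the weight of exactly fitted blocks at
#' \eqn{1/(2\epsilon)}.
#'
#' @param net a [hetero_network()].
#' @param fs fitted factor set.
#' @param eps_res residual floor.
#' @return the network with updated relation weights.
#' @export
update_weights <- function(net, fs, eps_res = 1e-12) {
  for (t in seq_along(net$relations)) {
    b <- net$relations[[t]]
    E <- b$R - fs$G[[b$i]] %*% fs$S[[rel_key(b$i, b$j)]] %*% t(fs$G[[b$j]])
    net$relations[[t]]$weight <- 1 / (2 * max(sum(E * E), eps_res))
  }
  net
}

## Unweighted data-fit residuals, one per block plus the total.
data_fit <- function(net, fs) {
  res <- vapply(net$relations, function(b) {
    E <- b$R - fs$G[[b$i]] %*% fs$S[[rel_key(b$i, b$j)]] %*% t(fs$G[[b$j]])
    sum(E * E)
  }, numeric(1))
  names(res) <- vapply(net$relations, function(b) rel_key(b$i, b$j),
                       character(1))
  res
}

#' Fit the sparse tri-factorization by the accelerated proximal DC solver
#'
#' Runs the full solver: seeded factor initialization, closed-form
#' coupling initialization, then per iteration an extrapolated
#' forward-backward step ([ls1_step()]) falling back to a
#' non-extrapolated one ([ls2_step()]) with best-of-two selection,
#' followed by the source-weight, momentum and envelope updates.  The
#' run is deterministic given \code{hp$seed}.
#'
#' When both line searches exhaust their trial caps without satisfying
#' the descent test the run stops with \code{stop_reason =
#' "line_search"}; no non-descending step is ever accepted, so the
#' recorded trace always satisfies \eqn{F^{(\ell+1)} \le c_\ell -
#' \delta \cdot \mathrm{gap}} and \eqn{c} is non-increasing.
#'
#' Source weights: with \code{reweight = TRUE} (default) the weights
#' are refreshed after every accepted iteration, which makes the
#' weighted objective a moving target.  Each refresh injects a jump
#' \eqn{F(x; \omega_{new}) - F(x; \omega_{old})} at the accepted
#' iterate; the envelope and the trace column \code{F} are maintained
#' for the drift-corrected objective (current-weight value minus the
#' accumulated jumps), which is the quantity that genuinely descends.
#' \code{F_raw} records the uncorrected current-weight value.  With
#' \code{reweight = FALSE} the two coincide with the plain objective.
#'
#' @inheritParams smooth_value
#' @param hp a [fit_control()].
#' @return object of class \code{trifuse_fit}: fields \code{factors}
#'   (final factor set), \code{trace} (one row per accepted iteration:
#'   \code{iter, F, F_raw, c, branch, l1, l2, gap, theta, ls_trials,
#'   min_G, resid_total} and one \code{resid_<i>_<j>} column per
#'   block),
#'   \code{stop_reason} (\code{"tolerance"}, \code{"max_iter"} or
#'   \code{"line_search"}), \code{control}, and \code{net} (with the
#'   final source weights).
#' @export
fit_trifactor <- function(net, hp = fit_control()) {
  diags <- validate_network(net)
  hard <- setdiff(diags, net$warnings %||% character(0))
  if (length(hard)) stopf("invalid network:\n%s", paste(hard, collapse = "\n"))

  G0 <- init_factors(net, hp)
  G_prev <- G_cur <- Z_cur <- G0
  S_cur <- init_couplings(net, G0)
  S_prev <- S_cur
  if (hp$reweight)
    net <- update_weights(net, factor_set(G_cur, S_cur), hp$eps_res)
  theta_prev <- 0; theta_cur <- 1
  q <- 1
  ## With per-iteration source reweighting the weighted objective is a
  ## moving target: each weight refresh injects a jump
  ## F(x; w_new) - F(x; w_old) at the current iterate.  The quantity
  ## that genuinely descends is the drift-corrected objective
  ## F(x; w_cur) - sum(jumps so far); the envelope c is maintained in
  ## that corrected frame (c_tilde), and line searches compare raw
  ## candidate values against c_tilde + jump_cum.  With reweighting
  ## off, jump_cum stays 0 and this reduces to the plain scheme.
  jump_cum <- 0
  c_tilde <- total_value(net, factor_set(G_cur, S_cur), hp)
  F_prev <- c_tilde
  stop_reason <- "max_iter"
  rows <- vector("list", hp$max_iter)

  for (iter in seq_len(hp$max_iter)) {
    Y <- extrapolate(G_cur, G_prev, Z_cur, theta_prev, theta_cur)
    state <- list(S_cur = S_cur, S_prev = S_prev, G_cur = G_cur,
                  G_prev = G_prev, Z_cur = Z_cur, Y = Y,
                  c = c_tilde + jump_cum)
    r1 <- ls1_step(net, state, hp)
    if (r1$ok) {
      S_new <- r1$S; G_new <- r1$Z; Z_next <- r1$Z
      F_acc <- r1$F; gap <- r1$gap; branch <- "LS1"
      l1 <- r1$l1; l2 <- r1$l2; trials <- r1$trials
    } else {
      r2 <- ls2_step(net, state, hp)
      if (!r2$ok) { stop_reason <- "line_search"; break }
      ## Best-of-two (Algorithm step 4): reuse the extrapolated Z
      ## candidate when it is at least as good as V *and* itself
      ## passes the envelope test, otherwise take V.
      F_z <- total_value(net, factor_set(r1$Z, r2$S), hp)
      gap_z <- list_dot(lapply(names(S_cur), function(k) r2$S[[k]] - S_cur[[k]]),
                        lapply(names(S_cur), function(k) r2$S[[k]] - S_cur[[k]])) +
               list_dot(list_sub(r1$Z, Y), list_sub(r1$Z, Y))
      if (is.finite(F_z) && F_z <= r2$F &&
          F_z <= c_tilde + jump_cum - hp$delta * gap_z) {
        S_new <- r2$S; G_new <- r1$Z; F_acc <- F_z; gap <- gap_z
        branch <- "LS2-Z"
      } else {
        S_new <- r2$S; G_new <- r2$Z; F_acc <- r2$F; gap <- r2$gap
        branch <- "LS2-V"
      }
      Z_next <- G_new   # the selected iterate seeds the next extrapolation
      l1 <- r2$l1; l2 <- r2$l2; trials <- r1$trials + r2$trials
    }

    fs_new <- factor_set(G_new, S_new)
    res <- data_fit(net, fs_new)
    F_rec <- F_acc - jump_cum
    row <- data.frame(iter = iter, F = F_rec, F_raw = F_acc, c = c_tilde,
                      branch = branch, l1 = l1, l2 = l2, gap = gap,
                      theta = theta_cur, ls_trials = trials,
                      min_G = min(vapply(G_new, min, numeric(1))),
                      resid_total = sum(res), stringsAsFactors = FALSE)
    for (nm in names(res)) row[[paste0("resid_", nm)]] <- res[[nm]]
    rows[[iter]] <- row

    S_prev <- S_cur; S_cur <- S_new
    G_prev <- G_cur; G_cur <- G_new
    Z_cur <- Z_next
    if (hp$reweight) {
      net <- update_weights(net, fs_new, hp$eps_res)
      jump_cum <- jump_cum + total_value(net, fs_new, hp) - F_acc
    }
    theta_prev <- theta_cur; theta_cur <- update_theta(theta_cur)
    env <- update_envelope(q, c_tilde, F_rec, hp$tau)
    q <- env$q; c_tilde <- env$c
    if (abs(F_rec - F_prev) / max(1, abs(F_prev)) < hp$tol) {
      stop_reason <- "tolerance"
      F_prev <- F_rec
      break
    }
    F_prev <- F_rec
  }

  fs <- factor_set(G_cur, S_cur)
  if (hp$project_k) fs$G <- lapply(fs$G, project_top_k, k = hp$k)
  structure(list(factors = fs,
                 trace = do.call(rbind, rows[!vapply(rows, is.null, logical(1))]),
                 stop_reason = stop_reason, control = hp, net = net),
            class = "trifuse_fit")
}

## Hard top-k projection of a factor matrix (used by project_k).
project_top_k <- function(Gi, k) {
  v <- as.vector(Gi)
  kk <- min(k, length(v))
  keep <- order(v, decreasing = TRUE)[seq_len(kk)]
  out <- numeric(length(v))
  out[keep] <- v[keep]
  matrix(out, nrow(Gi), ncol(Gi))
}

#' @export
print.trifuse_fit <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("trifuse_fit: %d iterations, stop reason '%s'\n",
              if (is.null(tr)) 0L else nrow(tr), x$stop_reason))
  if (!is.null(tr) && nrow(tr))
    cat(sprintf("  final F = %.6g, data-fit residual = %.6g\n",
                tr$F[nrow(tr)], tr$resid_total[nrow(tr)]))
  invisible(x)
}
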