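test_that("init_factors is deterministic, nonnegative, shape-correct", {
  net <- tiny_network(1)
  hp <- fit_control(seed = 5)
  G1 <- init_factors(net, hp)
  G2 <- init_factors(net, hp)
  expect_identical(G1, G2)
  for (i in seq_along(G1)) {
    expect_true(all(G1[[i]] >= 0))
    expect_equal(dim(G1[[i]]), c(net$types$n[i], net$types$rank[i]))
  }
  # a type with no incident relations still gets a seeded random factor
  net_iso <- hetero_network(
    data.frame(name = c("A", "B", "C"), n = c(3, 3, 4), rank = c(2, 2, 2)),
    relations = list(list(i = 1, j = 2, R = matrix(1, 3, 3))),
    target = c(1, 2))
  G <- init_factors(net_iso, hp)
  expect_equal(dim(G[[3]]), c(4, 2))
  expect_true(all(G[[3]] >= 0) && any(G[[3]] > 0))
  # svd variant is deterministic and nonnegative too
  hps <- fit_control(seed = 5, init = "svd")
  expect_identical(init_factors(net, hps), init_factors(net, hps))
  expect_true(all(unlist(init_factors(net, hps)) >= 0))
})

test_that("init_couplings solves the per-block least squares", {
  net <- tiny_network(2, with_constraints = FALSE)
  # orthonormal columns: pseudoinverse of G'G is the identity
  Gq <- lapply(seq_len(3), function(i)
    qr.Q(qr(matrix(rnorm(net$types$n[i] * 2), ncol = 2))))
  S <- init_couplings(net, Gq)
  for (b in net$relations) {
    key <- paste(b$i, b$j, sep = "_")
    expect_equal(S[[key]], t(Gq[[b$i]]) %*% b$R %*% Gq[[b$j]],
                 tolerance = 1e-10)
  }
  # planted recovery with full-column-rank factors
  set.seed(10)
  G <- lapply(c(4, 5, 3), function(n) matrix(runif(n * 2), n, 2))
  S0 <- matrix(rnorm(4), 2, 2)
  net$relations[[1]]$R <- G[[1]] %*% S0 %*% t(G[[2]])
  expect_lt(max(abs(init_couplings(net, G)[["1_2"]] - S0)), 1e-8)
  # zero block -> zero coupling
  net$relations[[3]]$R[] <- 0
  expect_equal(init_couplings(net, G)[["2_3"]], matrix(0, 2, 2))
})

test_that("extrapolate implements the momentum formula", {
  G <- list(matrix(1:4, 2), matrix(5:8, 2))
  # first iteration (theta_prev = 0, theta_cur = 1, Z = G = G_prev): Y = G
  expect_equal(extrapolate(G, G, G, 0, 1), G)
  # Z = G and G = G_prev: fixed point for any theta
  expect_equal(extrapolate(G, G, G, 2.3, 3.1), G)
  # random transcription check against direct arithmetic
  set.seed(3)
  Gp <- lapply(G, function(m) m + matrix(rnorm(4), 2))
  Z <- lapply(G, function(m) m + matrix(rnorm(4), 2))
  tp <- 1.7; tc <- 2.2
  Y <- extrapolate(G, Gp, Z, tp, tc)
  for (i in 1:2)
    expect_equal(Y[[i]], G[[i]] + (tp / tc) * (Z[[i]] - G[[i]]) +
                   ((tp - 1) / tc) * (G[[i]] - Gp[[i]]))
  expect_error(extrapolate(G, Gp, Z, 1, 0), "nonzero")
})

test_that("curvature_stepsize recovers quadratic curvature with guards", {
  hp <- fit_control()
  set.seed(4)
  dx <- matrix(rnorm(12), 3)
  expect_equal(curvature_stepsize(dx, 7.5 * dx, hp), 7.5)  # grad = L x
  expect_equal(curvature_stepsize(0 * dx, dx, hp), hp$l_init)   # zero step
  expect_equal(curvature_stepsize(dx, -2 * dx, hp), hp$l_init)  # concave
  # clipping into [l_min, l_max]
  expect_equal(curvature_stepsize(dx, 1e12 * dx, hp), hp$l_max)
})

test_that("update_theta satisfies the accelerated-gradient recurrence", {
  expect_equal(update_theta(0), 1)
  expect_equal(update_theta(1), (sqrt(5) + 1) / 2)
  th <- 0.3
  for (i in 1:50) {
    th2 <- update_theta(th)
    expect_lt(abs(th2^2 - th2 - th^2), 1e-12)
    th <- th2
  }
})

test_that("update_envelope is the decaying objective average", {
  env <- update_envelope(1, 10, 8, 0.5)
  expect_equal(env$q, 1.5)
  expect_equal(env$c, 13 / 1.5)
  # tau -> 0 limit: monotone Armijo (c = F_new)
  env0 <- update_envelope(1, 10, 8, 1e-12)
  expect_equal(env0$c, 8, tolerance = 1e-10)
  # convex-combination bound: F_new <= c implies c_new <= c
  set.seed(6)
  for (rep in 1:25) {
    q <- runif(1, 1, 2); c <- rnorm(1); tau <- runif(1)
    Fn <- c - runif(1)
    expect_lte(update_envelope(q, c, Fn, tau)$c, c)
  }
})

test_that("update_weights inverts twice the squared residual", {
  net <- hetero_network(data.frame(name = c("A", "B"), n = c(1, 1),
                                   rank = c(1, 1)),
                        relations = list(list(i = 1, j = 2,
                                              R = matrix(2, 1, 1))),
                        target = c(1, 2))
  fs <- list(G = list(matrix(1), matrix(1)), S = list("1_2" = matrix(2)))
  # residual 0: weight capped at 1/(2 eps)
  expect_equal(update_weights(net, fs, 1e-12)$relations[[1]]$weight,
               1 / (2e-12))
  fs$S[["1_2"]] <- matrix(2 - sqrt(0.5))     # residual^2 = 0.5 -> w = 1
  expect_equal(update_weights(net, fs)$relations[[1]]$weight, 1)
  fs$S[["1_2"]] <- matrix(2 - sqrt(2))       # residual^2 = 2 -> w = 0.25
  expect_equal(update_weights(net, fs)$relations[[1]]$weight, 0.25)
})

test_that("line searches keep iterates feasible and flag failure", {
  net <- tiny_network(9)
  hp <- fit_control(seed = 9, lambda = 0.01, lambdaG = 0.01, k = 6)
  G0 <- init_factors(net, hp)
  S0 <- init_couplings(net, G0)
  state <- list(S_cur = S0, S_prev = S0, G_cur = G0, G_prev = G0,
                Z_cur = G0, Y = G0,
                c = total_value(net, list(G = G0, S = S0), hp))
  r1 <- ls1_step(net, state, hp)
  expect_true(r1$ok)
  for (Zi in r1$Z) expect_true(all(Zi >= 0))
  # first accepted pair decreases F below the envelope
  expect_lt(r1$F, state$c - hp$delta * r1$gap + 1e-12)
  r2 <- ls2_step(net, state, hp)
  expect_true(r2$ok)
  for (Vi in r2$Z) expect_true(all(Vi >= 0))
  # accepted V satisfies the descent inequality with nonneg margin
  expect_gte(state$c - hp$delta * r2$gap - r2$F, 0)
  # absurd delta: flagged failure after ls_max trials
  hp_bad <- hp; hp_bad$delta <- 1e12
  rbad <- ls1_step(net, state, hp_bad)
  expect_false(rbad$ok)
  expect_equal(rbad$trials, hp$ls_max)
})

test_that("fit drives a noise-free planted network to near-exact fit", {
  pn <- generate_planted_network(n = c(12, 9, 14, 12, 6, 6), rank = 3,
                                 seed = 21, binarize = FALSE, noise = 0)
  hp <- fit_control(lambda = 0, lambdaG = 1e-4, k = 100000, seed = 21,
                    reweight = FALSE, init = "svd", max_iter = 100)
  fit <- fit_trifactor(pn$net, hp)
  G0 <- init_factors(pn$net, hp)
  init_res <- sum(trifuse:::data_fit(pn$net,
                                     list(G = G0, S = init_couplings(pn$net, G0))))
  expect_lt(fit$trace$resid_total[nrow(fit$trace)], 1e-3 * init_res)
})

test_that("fit traces satisfy the descent invariants and determinism", {
  pn <- generate_planted_network(n = c(10, 8, 12, 10, 6, 6), rank = 3,
                                 seed = 2, density = 0.15)
  hp <- fit_control(seed = 2, max_iter = 40)
  fit <- fit_trifactor(pn$net, hp)
  tr <- fit$trace
  expect_true(all(tr$F <= tr$c - hp$delta * tr$gap + 1e-10))
  expect_true(all(diff(tr$c) <= 1e-10))
  expect_true(all(tr$min_G >= 0))
  expect_true(all(tr$branch %in% c("LS1", "LS2-Z", "LS2-V")))
  # theta recurrence along the trace
  th <- tr$theta
  expect_true(all(abs(th[-1]^2 - th[-1] - th[-length(th)]^2) < 1e-10))
  fit2 <- fit_trifactor(pn$net, hp)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$factors, fit2$factors)
})

test_that("stationary point of a single-block problem solves the S normal equations", {
  set.seed(31)
  G1 <- matrix(runif(10), 5, 2); G2 <- matrix(runif(8), 4, 2)
  R <- G1 %*% matrix(c(1, 0.2, 0.1, 0.8), 2) %*% t(G2)
  net <- hetero_network(data.frame(name = c("A", "B"), n = c(5, 4),
                                   rank = c(2, 2)),
                        relations = list(list(i = 1, j = 2, R = R)),
                        target = c(1, 2))
  # k covers every entry, so the DC penalty cancels exactly
  hp <- fit_control(lambda = 0, lambdaG = 1e-3, k = 1000, seed = 31,
                    reweight = FALSE, init = "svd", max_iter = 500,
                    tol = 1e-14)
  fit <- fit_trifactor(net, hp)
  S_ls <- init_couplings(net, fit$factors$G)[["1_2"]]
  expect_lt(max(abs(fit$factors$S[["1_2"]] - S_ls)), 1e-6)
})

test_that("project_k leaves at most k nonzeros per factor", {
  pn <- generate_planted_network(n = c(8, 6, 9, 8, 5, 5), rank = 2,
                                 seed = 3, density = 0.2)
  hp <- fit_control(seed = 3, k = 10, max_iter = 10, project_k = TRUE)
  fit <- fit_trifactor(pn$net, hp)
  for (Gi in fit$factors$G)
    expect_lte(sum(Gi != 0), 10)
})
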