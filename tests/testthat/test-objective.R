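hp0 <- fit_control(lambda = 1, lambdaG = 1, k = 2)

test_that("smooth_value matches direct evaluation", {
  # planted exact fit, lambda = 0 -> zero loss
  net <- tiny_network(3, with_constraints = FALSE)
  fs <- random_factor_set(net, 3)
  for (b in seq_along(net$relations)) {
    bl <- net$relations[[b]]
    net$relations[[b]]$R <-
      fs$G[[bl$i]] %*% fs$S[[paste(bl$i, bl$j, sep = "_")]] %*% t(fs$G[[bl$j]])
  }
  hp <- fit_control(lambda = 0, lambdaG = 1, k = 1000)  # k covers all entries
  expect_equal(smooth_value(net, fs, hp), 0)
  expect_equal(total_value(net, fs, hp), 0)     # feasible + exact fit

  # single type, Theta = I, lambda = 1, no relations: tr(G'G) = ||G||_F^2
  G <- matrix(c(1, 2), 2, 1)
  net1 <- hetero_network(data.frame(name = "A", n = 2, rank = 1),
                         relations = list(list(i = 1, j = 1,
                                               R = matrix(0, 2, 2))),
                         constraints = list(list(i = 1, Theta = diag(2))),
                         target = c(1, 1))
  fs1 <- list(G = list(G), S = list("1_1" = matrix(0, 1, 1)))
  expect_equal(smooth_value(net1, fs1, hp0), sum(G^2))

  # random instance vs naive per-entry double loop
  net <- tiny_network(5)
  fs <- random_factor_set(net, 5)
  naive <- 0
  for (b in net$relations) {
    Rhat <- fs$G[[b$i]] %*% fs$S[[paste(b$i, b$j, sep = "_")]] %*%
      t(fs$G[[b$j]])
    for (u in seq_len(nrow(b$R))) for (v in seq_len(ncol(b$R)))
      naive <- naive + b$weight * (b$R[u, v] - Rhat[u, v])^2
  }
  for (cn in net$constraints)
    naive <- naive + hp0$lambda * sum(diag(t(fs$G[[cn$i]]) %*% cn$Theta %*%
                                             fs$G[[cn$i]]))
  expect_equal(smooth_value(net, fs, hp0), naive)
  expect_error(smooth_value(net, random_factor_set(tiny_network(1, n = c(5, 5, 5)), 1), hp0),
               "expected")
})

test_that("penalty_value implements the DC cardinality penalty", {
  hp <- fit_control(lambda = 0, lambdaG = 1, k = 2)
  # at most k nonzeros -> 0
  fs <- list(G = list(matrix(c(3, 0, 0, 2), 2, 2)), S = list())
  expect_equal(penalty_value(fs, hp), 0)
  # negative entry -> infinite sentinel
  fs$G[[1]][1, 2] <- -0.1
  expect_equal(penalty_value(fs, hp), Inf)
  # vec (1,2,3,4), k = 2: (10 - 7) = 3
  fs <- list(G = list(matrix(1:4, 2, 2)), S = list())
  expect_equal(penalty_value(fs, hp), 3)
  # total = smooth + penalty, and Inf propagates
  net <- tiny_network(2)
  fsr <- random_factor_set(net, 2)
  expect_equal(total_value(net, fsr, hp0),
               smooth_value(net, fsr, hp0) + penalty_value(fsr, hp0))
  fsr$G[[1]][1] <- -1
  expect_equal(total_value(net, fsr, hp0), Inf)
})

test_that("penalty vanishes exactly on k-sparse feasible factors", {
  hp <- fit_control(lambda = 0, lambdaG = 1, k = 2)
  grid <- expand.grid(rep(list(0:2), 4))
  for (r in seq_len(nrow(grid))) {
    G <- matrix(as.numeric(grid[r, ]), 2, 2)
    p <- penalty_value(list(G = list(G), S = list()), hp)
    expect_gte(p, 0)
    expect_identical(p == 0, sum(G != 0) <= hp$k)
  }
})

test_that("grad_S is exact", {
  # G = I: dS = -2 w (R - S); zero at the exact fit S = R
  net1 <- hetero_network(data.frame(name = c("A", "B"), n = c(2, 2),
                                    rank = c(2, 2)),
                         relations = list(list(i = 1, j = 2,
                                               R = matrix(1:4, 2), weight = 1)),
                         target = c(1, 2))
  fs <- list(G = list(diag(2), diag(2)), S = list("1_2" = matrix(1:4, 2)))
  expect_equal(grad_S(net1, fs, hp0)[["1_2"]], matrix(0, 2, 2))
  fs$S[["1_2"]] <- matrix(0, 2, 2)
  expect_equal(grad_S(net1, fs, hp0)[["1_2"]], -2 * matrix(1:4, 2))
  # R = 0, S = I: dS = 2 I
  net1$relations[[1]]$R <- matrix(0, 2, 2)
  fs$S[["1_2"]] <- diag(2)
  expect_equal(grad_S(net1, fs, hp0)[["1_2"]], 2 * diag(2))
  # finite differences on a random instance
  net <- tiny_network(6)
  fs <- random_factor_set(net, 6)
  expect_lt(rel_err(grad_S(net, fs, hp0), fd_grad(net, fs, hp0, "S")), 1e-6)
})

test_that("grad_G is exact, including asymmetric block pairs", {
  # exact fit, lambda = 0 -> zero gradient
  net <- tiny_network(4, with_constraints = FALSE)
  fs <- random_factor_set(net, 4)
  for (b in seq_along(net$relations)) {
    bl <- net$relations[[b]]
    net$relations[[b]]$R <-
      fs$G[[bl$i]] %*% fs$S[[paste(bl$i, bl$j, sep = "_")]] %*% t(fs$G[[bl$j]])
  }
  hp <- fit_control(lambda = 0, lambdaG = 1, k = 2)
  for (g in grad_G(net, fs, hp))
    expect_lt(max(abs(g)), 1e-10)
  # no relations, Theta = I, lambda = 1: dG = 2 G
  netI <- hetero_network(data.frame(name = "A", n = 3, rank = 2),
                         relations = list(list(i = 1, j = 1,
                                               R = matrix(0, 3, 3),
                                               weight = 1e-30)),
                         constraints = list(list(i = 1, Theta = diag(3))),
                         target = c(1, 1))
  G <- matrix(runif(6), 3, 2)
  fsI <- list(G = list(G), S = list("1_1" = matrix(0, 2, 2)))
  expect_equal(grad_G(netI, fsI, hp0)[[1]], 2 * G, tolerance = 1e-12)
  # finite differences, network has both (1,2) and (2,1) blocks
  net <- tiny_network(7)
  fs <- random_factor_set(net, 7)
  expect_lt(rel_err(grad_G(net, fs, hp0), fd_grad(net, fs, hp0, "G")), 1e-6)
})

test_that("objective is invariant to latent-dimension permutation", {
  net <- tiny_network(8)
  fs <- random_factor_set(net, 8)
  base <- total_value(net, fs, hp0)
  perm <- c(2, 1)                       # swap type 2's latent dims
  fs2 <- fs
  fs2$G[[2]] <- fs$G[[2]][, perm]
  for (b in net$relations) {
    key <- paste(b$i, b$j, sep = "_")
    if (b$i == 2) fs2$S[[key]] <- fs2$S[[key]][perm, , drop = FALSE]
    if (b$j == 2) fs2$S[[key]] <- fs2$S[[key]][, perm, drop = FALSE]
  }
  expect_equal(total_value(net, fs2, hp0), base)
})
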