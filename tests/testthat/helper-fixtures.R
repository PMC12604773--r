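# Fixtures are built in code; no data files.

# Small random network with an asymmetric block pattern: types A-B-C,
# blocks (1,2), (2,1) [asymmetric pair], (2,3), and two constraint
# matrices on type 1 plus one on type 3.
tiny_network <- function(seed = 1, n = c(4, 5, 3), rank = c(2, 2, 2),
                         with_constraints = TRUE) {
  set.seed(seed)
  rel <- list(
    list(i = 1, j = 2, R = matrix(runif(n[1] * n[2]), n[1], n[2]),
         weight = runif(1, 0.5, 2)),
    list(i = 2, j = 1, R = matrix(runif(n[2] * n[1]), n[2], n[1]),
         weight = runif(1, 0.5, 2)),
    list(i = 2, j = 3, R = matrix(runif(n[2] * n[3]), n[2], n[3]),
         weight = runif(1, 0.5, 2)))
  cons <- if (with_constraints) {
    sym <- function(m) (m + t(m)) / 2
    list(list(i = 1, Theta = sym(matrix(rnorm(n[1]^2), n[1]))),
         list(i = 1, Theta = sym(matrix(rnorm(n[1]^2), n[1]))),
         list(i = 3, Theta = sym(matrix(rnorm(n[3]^2), n[3]))))
  } else list()
  hetero_network(
    types = data.frame(name = c("A", "B", "C"), n = n, rank = rank),
    relations = rel, constraints = cons, target = c(1, 2))
}

random_factor_set <- function(net, seed = 1, nonneg = TRUE) {
  set.seed(seed)
  G <- lapply(seq_len(nrow(net$types)), function(i) {
    v <- runif(net$types$n[i] * net$types$rank[i])
    if (!nonneg) v <- v - 0.5
    matrix(v, net$types$n[i], net$types$rank[i])
  })
  S <- list()
  for (b in net$relations)
    S[[paste(b$i, b$j, sep = "_")]] <-
      matrix(rnorm(net$types$rank[b$i] * net$types$rank[b$j]),
             net$types$rank[b$i], net$types$rank[b$j])
  list(G = G, S = S)
}

# Central finite-difference gradient of smooth_value w.r.t. every entry
# of every S block / G block (independent oracle).
fd_grad <- function(net, fs, hp, what = c("S", "G"), h = 1e-5) {
  what <- match.arg(what)
  blocks <- if (what == "S") fs$S else fs$G
  lapply(seq_along(blocks), function(t) {
    B <- blocks[[t]]
    g <- B
    for (u in seq_along(B)) {
      fp <- fs; fm <- fs
      if (what == "S") { fp$S[[t]][u] <- B[u] + h; fm$S[[t]][u] <- B[u] - h }
      else { fp$G[[t]][u] <- B[u] + h; fm$G[[t]][u] <- B[u] - h }
      g[u] <- (smooth_value(net, fp, hp) - smooth_value(net, fm, hp)) / (2 * h)
    }
    g
  })
}

rel_err <- function(a, b) {
  na <- sqrt(sum(unlist(Map(function(x, y) sum((x - y)^2), a, b))))
  nb <- sqrt(sum(unlist(lapply(b, function(x) sum(x^2)))))
  na / max(1, nb)
}

# Slow numeric prox oracle: box-constrained quasi-Newton minimization of
# (1/l2)(lambdaG * sum(Z)) + 0.5 * ||Z - X||_F^2 over Z >= 0.
prox_oracle <- function(X, a) {
  obj <- function(z) a * sum(z) + 0.5 * sum((z - as.vector(X))^2)
  gr <- function(z) a + (z - as.vector(X))
  z0 <- pmax(as.vector(X), 0)
  res <- stats::optim(z0, obj, gr, method = "L-BFGS-B", lower = 0,
                      control = list(factr = 1e1, maxit = 500))
  matrix(res$par, nrow(X), ncol(X))
}

# O(n^2) pairwise AUC oracle (midrank convention) and direct AUPR oracle.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

aupr_oracle <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  npos <- sum(labels == 1)
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}
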