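## Default six-type topology: RBPs, miRNAs, genes, AS events, diseases,
## drugs; seven inter-relations and constraint matrices on genes and
## drugs.  Type indices: 1 RBP, 2 miRNA, 3 gene, 4 AS, 5 disease, 6 drug.
default_type_names <- c("RBP", "miRNA", "gene", "AS", "disease", "drug")
default_relations <- list(c(1, 3), c(1, 4), c(3, 4), c(2, 3), c(2, 5),
                          c(3, 5), c(3, 6))

#' Generate a planted-structure heterogeneous network
#'
#' Draws sparse nonnegative ground-truth factors \eqn{G^*_i} (each
#' entity carries a dominant latent cluster) and diagonally boosted
#' couplings \eqn{S^*_{ij}}, forms the planted score matrices
#' \eqn{P_{ij} = G^*_i S^*_{ij} G^{*T}_j}, and emits observed relation
#' blocks.  In the default binary mode each block keeps the top
#' \code{density} quantile of \eqn{P_{ij}} as positives (so density is
#' controlled exactly) and then flips each entry independently with
#' probability \code{noise}.  With \code{binarize = FALSE} the blocks
#' are the real-valued \eqn{P_{ij}} themselves plus (for
#' \code{noise > 0}) Gaussian noise of relative scale \code{noise} --
#' the exact-fit regime used to verify the solver.
#'
#' The default emulates a six-entity-type molecular network (RBPs,
#' miRNAs, genes, AS events, diseases, drugs) with seven inter-relations
#' (RBP-gene, RBP-AS, gene-AS, miRNA-gene, miRNA-disease, gene-disease,
#' gene-drug) and two constraint matrices: graph Laplacians of mutual
#' k-nearest-neighbour cosine-similarity graphs over the ground-truth
#' gene and drug factors (positive semidefinite, so the quadratic
#' regularizer is bounded below).  The target block is RBP-AS.
#'
#' @param n integer vector of entity counts per type.
#' @param rank latent ranks (recycled to \code{length(n)}).
#' @param density fraction of entries kept positive per block, in (0,1).
#' @param noise entrywise flip probability (binary mode) or relative
#'   Gaussian noise scale (real-valued mode), in [0,1).
#' @param seed integer RNG seed; the network is deterministic given it.
#' @param binarize logical; see above.
#' @param relations list of type-index pairs; defaults to the
#'   seven-block topology when \code{length(n) == 6}.
#' @param constraint_types types carrying a constraint matrix; default
#'   genes and drugs when \code{length(n) == 6}, none otherwise.
#' @param target the block to predict, default \code{c(1, 4)} (RBP-AS).
#' @param type_names optional character names per type.
#' @return object of class \code{planted_network}: fields \code{net}
#'   (a [hetero_network()]), \code{truth} (list \code{G}, \code{S},
#'   \code{P_target}), and the generator settings.
#' @export
generate_planted_network <- function(n = c(40, 30, 50, 40, 20, 20),
                                     rank = 5, density = 0.1,
                                     noise = 0.01, seed = 1,
                                     binarize = TRUE,
                                     relations = NULL,
                                     constraint_types = NULL,
                                     target = c(1, 4),
                                     type_names = NULL) {
  m <- length(n)
  rank <- rep_len(rank, m)
  if (density <= 0 || density >= 1) stopf("density must lie in (0,1)")
  if (noise < 0 || noise >= 1) stopf("noise must lie in [0,1)")
  if (is.null(relations)) {
    if (m != 6) stopf("for m != 6 types, 'relations' must be given")
    relations <- default_relations
  }
  if (is.null(constraint_types)) constraint_types <- if (m == 6) c(3, 6)
  if (is.null(type_names))
    type_names <- if (m == 6) default_type_names else
      paste0("type", seq_len(m))

  set.seed(seed)
  ## Ground-truth factors: one dominant cluster per entity plus sparse
  ## background, so the planted signal is genuinely low-rank and sparse.
  Gs <- lapply(seq_len(m), function(i) {
    k <- rank[i]
    cl <- sample(k, n[i], replace = TRUE)
    G <- matrix(stats::runif(n[i] * k, 0, 0.3) *
                  (stats::runif(n[i] * k) < 0.25), n[i], k)
    G[cbind(seq_len(n[i]), cl)] <- stats::runif(n[i], 0.8, 1.2)
    G
  })
  Ss <- list()
  for (p in relations) {
    ki <- rank[p[1]]; kj <- rank[p[2]]
    S <- matrix(stats::runif(ki * kj, 0, 0.2), ki, kj)
    d <- min(ki, kj)
    S[cbind(seq_len(d), seq_len(d))] <- S[cbind(seq_len(d), seq_len(d))] + 1
    Ss[[rel_key(p[1], p[2])]] <- S
  }

  blocks <- list(); P_target <- NULL
  for (p in relations) {
    P <- Gs[[p[1]]] %*% Ss[[rel_key(p[1], p[2])]] %*% t(Gs[[p[2]]])
    if (all(p == target)) P_target <- P
    if (binarize) {
      thr <- stats::quantile(P, 1 - density, names = FALSE)
      R <- (P > thr) * 1
      if (sum(R) == 0)
        stopf("density %g yields zero positives in block (%d,%d)",
              density, p[1], p[2])
      if (noise > 0) {
        flip <- stats::runif(length(R)) < noise
        R[flip] <- 1 - R[flip]
      }
    } else {
      R <- P
      if (noise > 0)
        R <- pmax(R + stats::rnorm(length(P), 0, noise * stats::sd(P)), 0)
    }
    blocks[[length(blocks) + 1L]] <- list(i = p[1], j = p[2], R = R,
                                          weight = 1)
  }

  constraints <- lapply(constraint_types, function(i)
    list(i = i, Theta = knn_laplacian(Gs[[i]])))

  net <- hetero_network(
    types = data.frame(name = type_names, n = n, rank = rank,
                       stringsAsFactors = FALSE),
    relations = blocks, constraints = constraints, target = target)
  structure(list(net = net, truth = list(G = Gs, S = Ss,
                                         P_target = P_target),
                 density = density, noise = noise, seed = seed,
                 binarize = binarize),
            class = "planted_network")
}

## Unnormalized Laplacian of the mutual k-nearest-neighbour graph under
## cosine similarity of the rows of G; positive semidefinite.
knn_laplacian <- function(G, k = 5) {
  n <- nrow(G)
  k <- min(k, n - 1)
  nrm <- sqrt(rowSums(G^2))
  nrm[nrm == 0] <- 1
  Gn <- G / nrm
  Csim <- Gn %*% t(Gn)
  diag(Csim) <- -Inf
  A <- matrix(0, n, n)
  for (u in seq_len(n)) {
    nb <- order(Csim[u, ], decreasing = TRUE)[seq_len(k)]
    A[u, nb] <- 1
  }
  A <- A * t(A)                      # mutual neighbours only
  diag(rowSums(A)) - A
}

#' Hold out the positives of a share of target rows
#'
#' Samples \code{fraction} of the target-block rows (at least one) and
#' removes all their positive entries from the training copy of the
#' network, returning the removed entries as the evaluation positives.
#' Held-out and remaining positives partition the original positives.
#'
#' @param pn a \code{planted_network} (or any list with a \code{net}
#'   field, or a bare [hetero_network()]).
#' @param fraction share of rows to hold out, in (0,1).
#' @param seed RNG seed for the row sample.
#' @return list with fields \code{train} (the modified network),
#'   \code{holdout} (data.frame \code{row}, \code{col} of removed
#'   positives) and \code{rows} (held-out row indices).
#' @export
mask_holdout <- function(pn, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0,1)")
  net <- if (inherits(pn, "hetero_network")) pn else pn$net
  ti <- relation_index(net, net$target[1], net$target[2])
  R <- net$relations[[ti]]$R
  set.seed(seed)
  nr <- nrow(R)
  rows <- sort(sample(nr, max(1L, round(fraction * nr))))
  pos <- which(R[rows, , drop = FALSE] != 0, arr.ind = TRUE)
  if (nrow(pos) == 0) stopf("held-out rows contain no positives")
  holdout <- data.frame(row = rows[pos[, 1]], col = pos[, 2])
  holdout <- holdout[order(holdout$row, holdout$col), , drop = FALSE]
  rownames(holdout) <- NULL
  net$relations[[ti]]$R[rows, ] <- 0
  list(train = net, holdout = holdout, rows = rows)
}
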