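#' Reconstruct the score matrix of a relation block
#'
#' \eqn{\hat R_{ij} = G_i S_{ij} G_j^T}: the dense association scores
#' used for ranking unobserved pairs of the target relation.
#'
#' @param fs a factor set (e.g. \code{fit$factors}) or a
#'   \code{trifuse_fit}.
#' @param target length-2 integer pair \code{c(i, j)}; defaults to the
#'   fitted network's target when \code{fs} is a \code{trifuse_fit}.
#' @return numeric \code{n_i x n_j} score matrix.
#' @export
reconstruct_scores <- function(fs, target = NULL) {
  if (inherits(fs, "trifuse_fit")) {
    if (is.null(target)) target <- fs$net$target
    fs <- fs$factors
  }
  if (is.null(target)) stopf("'target' pair required for a bare factor set")
  key <- rel_key(target[1], target[2])
  if (is.null(fs$S[[key]]))
    stopf("target (%s) is not a relation in the factor set",
          paste(target, collapse = ","))
  fs$G[[target[1]]] %*% fs$S[[key]] %*% t(fs$G[[target[2]]])
}

#' Assign target rows to cross-validation folds
#'
#' Shuffles the row indices with the given seed and deals them into
#' \code{folds} groups of near-equal size.  Errors if any fold would
#' receive no positive entry, since AUC/AUPR are undefined there.
#'
#' @param R the target relation matrix (nonzero = known association).
#' @param folds number of folds, \code{>= 2}.
#' @param seed RNG seed.
#' @return integer vector of fold ids (1..folds), one per row.
#' @export
kfold_row_split <- function(R, folds = 5, seed = 1) {
  if (folds < 2) stopf("folds must be >= 2")
  set.seed(seed)
  nr <- nrow(R)
  assign <- integer(nr)
  assign[sample(nr)] <- rep_len(seq_len(folds), nr)
  for (f in seq_len(folds))
    if (sum(R[assign == f, , drop = FALSE] != 0) == 0)
      stopf("fold %d receives no positive entries", f)
  assign
}

#' Ranking metrics: AUC and AUPR
#'
#' AUC by the rank statistic with midranks for ties (the probability a
#' random positive outranks a random negative, ties counted half) and
#' AUPR by step interpolation over the distinct score thresholds
#' (precision at each achievable recall level, tied scores handled as
#' one threshold group).
#'
#' @param scores numeric vector of predicted scores.
#' @param labels 0/1 vector of the same length; both classes present.
#' @return named numeric vector \code{c(auc =, aupr =)}.
#' @export
auc_aupr <- function(scores, labels) {
  labels <- as.numeric(labels != 0)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("both classes must be present (got %d positives, %d negatives)",
          n_pos, n_neg)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ## Threshold sweep from the highest score down; tied scores form a
  ## single cut so precision/recall are well-defined under ties.
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  grp_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[grp_end]
  fp <- cumsum(1 - lab)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  aupr <- sum(diff(c(0, rec)) * prec)
  c(auc = auc, aupr = aupr)
}

#' Row-wise k-fold cross-validation of the target block
#'
#' For each fold the known associations of the fold's test rows are
#' removed from the training copy of the target matrix (every other
#' block is left untouched), the factorization is refitted, and the
#' reconstructed scores of all test-row entries are evaluated against
#' the original labels: the removed positives versus all zero entries
#' of the test rows (no negative sampling).  Metrics are reported per
#' fold and pooled over the concatenated fold predictions; the pooled
#' value is the headline number.
#'
#' The alternative \code{split = "entry"} deals the positive entries
#' (not the rows) into folds; each fold is then scored on its held-out
#' positives against all never-positive entries of the matrix.
#'
#' @param net a [hetero_network()] (or \code{planted_network}).
#' @param hp a [fit_control()]; fold fits use seeds
#'   \code{seed + fold}.
#' @param folds number of folds (default 5).
#' @param seed split seed; defaults to \code{hp$seed}.
#' @param split \code{"row"} (default) or \code{"entry"}.
#' @return object of class \code{trifuse_cv}: \code{per_fold}
#'   (data.frame fold/auc/aupr/n_pos/n_neg), \code{pooled_auc},
#'   \code{pooled_aupr}, \code{mean_auc}, \code{mean_aupr},
#'   \code{fold_assign}, \code{seed}, \code{split}.
#' @export
cross_validate <- function(net, hp = fit_control(), folds = 5,
                           seed = hp$seed, split = c("row", "entry")) {
  split <- match.arg(split)
  if (inherits(net, "planted_network")) net <- net$net
  ti <- relation_index(net, net$target[1], net$target[2])
  R <- net$relations[[ti]]$R

  if (split == "row") {
    assign <- kfold_row_split(R, folds, seed)
  } else {
    pos <- which(R != 0)
    if (length(pos) < folds) stopf("fewer positives than folds")
    set.seed(seed)
    assign_pos <- integer(length(pos))
    assign_pos[sample(length(pos))] <- rep_len(seq_len(folds), length(pos))
  }

  all_scores <- numeric(0); all_labels <- numeric(0)
  per <- vector("list", folds)
  for (f in seq_len(folds)) {
    net_f <- net
    hp_f <- hp
    hp_f$seed <- hp$seed + f
    if (split == "row") {
      test_rows <- which(assign == f)
      net_f$relations[[ti]]$R[test_rows, ] <- 0
      fit <- fit_trifactor(net_f, hp_f)
      sc <- reconstruct_scores(fit$factors, net$target)
      scores <- as.vector(sc[test_rows, , drop = FALSE])
      labels <- as.numeric(R[test_rows, , drop = FALSE] != 0)
    } else {
      test_pos <- pos[assign_pos == f]
      net_f$relations[[ti]]$R[test_pos] <- 0
      fit <- fit_trifactor(net_f, hp_f)
      sc <- reconstruct_scores(fit$factors, net$target)
      neg <- which(R == 0)
      idx <- c(test_pos, neg)
      scores <- sc[idx]
      labels <- c(rep(1, length(test_pos)), rep(0, length(neg)))
    }
    met <- auc_aupr(scores, labels)
    per[[f]] <- data.frame(fold = f, auc = met["auc"], aupr = met["aupr"],
                           n_pos = sum(labels == 1),
                           n_neg = sum(labels == 0))
    all_scores <- c(all_scores, scores)
    all_labels <- c(all_labels, labels)
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  pooled <- auc_aupr(all_scores, all_labels)
  structure(list(per_fold = per,
                 pooled_auc = unname(pooled["auc"]),
                 pooled_aupr = unname(pooled["aupr"]),
                 mean_auc = mean(per$auc), mean_aupr = mean(per$aupr),
                 fold_assign = if (split == "row") assign else assign_pos,
                 seed = seed, split = split),
            class = "trifuse_cv")
}

#' @export
print.trifuse_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s split): pooled AUC %.4f, pooled AUPR %.4f\n",
              nrow(x$per_fold), x$split, x$pooled_auc, x$pooled_aupr))
  cat(sprintf("  per-fold AUC: %s\n",
              paste(sprintf("%.4f", x$per_fold$auc), collapse = " ")))
  invisible(x)
}

#' Rank candidate associations
#'
#' Returns the \code{top_n} highest-scoring pairs of the target block,
#' excluding known training positives, with a deterministic tie order
#' (score descending, then row index, then column index).  Restricting
#' to a single \code{row} entity gives the per-query ranking used for
#' case-study style output.
#'
#' @param sm score matrix from [reconstruct_scores()].
#' @param training_positives matrix/data.frame with two columns (row,
#'   col indices) of known positives to exclude, or a 0/1 matrix the
#'   same shape as \code{sm}.
#' @param top_n number of pairs to return (fewer if fewer remain).
#' @param row optional single row index to restrict the ranking to.
#' @param row_ids,col_ids optional identifier vectors used to label the
#'   output (defaults to indices).
#' @return data.frame \code{row_id, col_id, score, rank}.
#' @export
rank_pairs <- function(sm, training_positives = NULL, top_n = 100,
                       row = NULL, row_ids = NULL, col_ids = NULL) {
  if (top_n < 1) stopf("top_n must be >= 1")
  excl <- matrix(FALSE, nrow(sm), ncol(sm))
  if (!is.null(training_positives)) {
    tp <- training_positives
    if (is.matrix(tp) && all(dim(tp) == dim(sm))) {
      excl <- tp != 0
    } else {
      tp <- as.matrix(as.data.frame(tp))
      if (nrow(tp)) excl[tp[, 1:2, drop = FALSE]] <- TRUE
    }
  }
  idx <- which(!excl, arr.ind = TRUE)
  if (!is.null(row)) idx <- idx[idx[, 1] == row, , drop = FALSE]
  sc <- sm[idx]
  ord <- order(-sc, idx[, 1], idx[, 2])
  ord <- ord[seq_len(min(top_n, length(ord)))]
  if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(sm)))
  if (is.null(col_ids)) col_ids <- as.character(seq_len(ncol(sm)))
  data.frame(row_id = row_ids[idx[ord, 1]], col_id = col_ids[idx[ord, 2]],
             score = sc[ord], rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Grid sweep of the regularization and sparsity parameters
#'
#' Runs [cross_validate()] for every combination of the supplied
#' \code{lambda}, \code{lambdaG} and \code{k} values and tabulates the
#' pooled metrics, mirroring the usual sensitivity analysis over
#' \eqn{\lambda, \lambda_G \in \{1, 10^{-1}, \dots, 10^{-5}\}} and a
#' range of cardinality budgets.
#'
#' @inheritParams cross_validate
#' @param lambda,lambdaG,k vectors of values to sweep.
#' @return data.frame with one row per grid cell: the three parameter
#'   values plus \code{pooled_auc}, \code{pooled_aupr}.
#' @export
cv_grid <- function(net, hp = fit_control(), lambda = hp$lambda,
                    lambdaG = hp$lambdaG, k = hp$k, folds = 5,
                    seed = hp$seed) {
  grid <- expand.grid(lambda = lambda, lambdaG = lambdaG, k = k,
                      KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    hp_g <- hp
    hp_g$lambda <- grid$lambda[g]
    hp_g$lambdaG <- grid$lambdaG[g]
    hp_g$k <- as.integer(grid$k[g])
    cv <- cross_validate(net, hp_g, folds = folds, seed = seed)
    cbind(grid[g, , drop = FALSE],
          data.frame(pooled_auc = cv$pooled_auc,
                     pooled_aupr = cv$pooled_aupr))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
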