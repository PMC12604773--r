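#' Construct a heterogeneous multi-type network
#'
#' A \code{hetero_network} bundles the relational data the solver
#' factorizes: \code{m} entity types (each with an entity count
#' \code{n_i} and a latent rank \code{k_i}), a set of inter-relation
#' blocks \eqn{R_{ij}} with positive source weights \eqn{\omega_{ij}},
#' optional intra-relation constraint matrices \eqn{\Theta_i^{(r)}}
#' (one type may carry several), and one ordered type pair designated
#' as the prediction target.
#'
#' Constraint matrices are symmetrized on construction,
#' \eqn{(\Theta + \Theta^T)/2}, because the quadratic regularizer
#' \eqn{\mathrm{tr}(G^T \Theta G)} depends only on the symmetric part
#' and the symmetric form gives the gradient \eqn{2\lambda\Theta G}.
#'
#' @param types data.frame with columns \code{name}, \code{n},
#'   \code{rank}; row order defines the type indices \code{1..m}.
#' @param relations list of entries \code{list(i =, j =, R =, weight =)}
#'   where \code{R} is an \code{n_i x n_j} matrix and \code{weight > 0}.
#' @param constraints list of entries \code{list(i =, Theta =)} with
#'   \code{Theta} a square \code{n_i x n_i} matrix.
#' @param target length-2 integer vector \code{c(i, j)} naming the
#'   relation block whose unobserved entries are to be predicted.
#' @param ids optional list (one character vector per type) of entity
#'   identifiers; defaults to \code{"<name>_<row>"}.
#' @return an object of class \code{hetero_network}.
#' @seealso [load_network()], [validate_network()]
#' @export
hetero_network <- function(types, relations, constraints = list(),
                           target, ids = NULL) {
  types <- as.data.frame(types, stringsAsFactors = FALSE)
  if (!all(c("name", "n", "rank") %in% names(types)))
    stopf("'types' needs columns name, n, rank")
  m <- nrow(types)
  if (anyDuplicated(types$name)) stopf("type names must be unique")
  if (any(types$n < 1)) stopf("every type needs n >= 1")
  if (any(types$rank < 1 | types$rank > types$n))
    stopf("latent ranks must satisfy 1 <= k_i <= n_i")
  if (is.null(ids))
    ids <- lapply(seq_len(m), function(i)
      paste(types$name[i], seq_len(types$n[i]), sep = "_"))
  rel <- lapply(relations, function(b) {
    i <- as.integer(b$i); j <- as.integer(b$j)
    if (i < 1 || i > m || j < 1 || j > m)
      stopf("relation references undeclared type (%d,%d)", i, j)
    R <- as.matrix(b$R)
    if (nrow(R) != types$n[i] || ncol(R) != types$n[j])
      stopf("relation (%d,%d): matrix is %dx%d, declared types are %dx%d",
            i, j, nrow(R), ncol(R), types$n[i], types$n[j])
    w <- if (is.null(b$weight)) 1 else as.numeric(b$weight)
    if (w <= 0) stopf("relation (%d,%d): weight must be positive", i, j)
    list(i = i, j = j, R = R, weight = w)
  })
  keys <- vapply(rel, function(b) rel_key(b$i, b$j), character(1))
  if (anyDuplicated(keys)) stopf("duplicate relation block declared")
  con <- lapply(constraints, function(cn) {
    i <- as.integer(cn$i)
    if (i < 1 || i > m) stopf("constraint references undeclared type %d", i)
    Th <- as.matrix(cn$Theta)
    if (nrow(Th) != ncol(Th) || nrow(Th) != types$n[i])
      stopf("constraint for type %d ('%s'): matrix side %dx%d, expected %d",
            i, types$name[i], nrow(Th), ncol(Th), types$n[i])
    list(i = i, Theta = (Th + t(Th)) / 2)
  })
  target <- as.integer(target)
  if (length(target) != 2L || !(rel_key(target[1], target[2]) %in% keys))
    stopf("target pair (%s) does not name a declared relation block",
          paste(target, collapse = ","))
  structure(list(types = types, ids = ids, relations = rel,
                 constraints = con, target = target),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("hetero_network: %d types, %d relation blocks, %d constraints\n",
              nrow(x$types), length(x$relations), length(x$constraints)))
  for (t in seq_len(nrow(x$types)))
    cat(sprintf("  type %d %-10s n=%4d rank=%d\n", t, x$types$name[t],
                x$types$n[t], x$types$rank[t]))
  for (b in x$relations)
    cat(sprintf("  R[%d,%d] %s-%s  %d nonzeros  weight=%g%s\n", b$i, b$j,
                x$types$name[b$i], x$types$name[b$j], sum(b$R != 0),
                b$weight,
                if (all(c(b$i, b$j) == x$target)) "  <- target" else ""))
  invisible(x)
}

## Index of the (i,j) relation block inside net$relations, or NA.
relation_index <- function(net, i, j) {
  keys <- vapply(net$relations, function(b) rel_key(b$i, b$j), character(1))
  match(rel_key(i, j), keys)
}

target_block <- function(net) {
  net$relations[[relation_index(net, net$target[1], net$target[2])]]
}

#' Load a heterogeneous network from a YAML config
#'
#' The config declares \code{types} (name, n, rank, optional \code{ids}
#' file with one identifier per line), \code{relations} (src, dst, path,
#' optional weight), optional \code{constraints} (type, path) and
#' \code{target} (src, dst).  Relation files are either two/three-column
#' TSV edge lists (\code{src_id<TAB>dst_id[<TAB>weight]}) or MatrixMarket
#' coordinate files (\code{.mtx}); constraint files likewise.  Paths are
#' resolved relative to the config file.  String entity identifiers are
#' mapped to internal 1-based indices per type; the mapping is kept in
#' the returned object (\code{$ids}) for use when writing predictions.
#'
#' Duplicate edges collapse to a single entry (last weight wins for
#' weighted TSV input); an edge naming an identifier outside the
#' declared roster is an error that reports the offending line.
#'
#' @param config_path path to the YAML network description.
#' @return a validated [hetero_network()].
#' @export
load_network <- function(config_path) {
  if (!file.exists(config_path)) stopf("config file not found: %s", config_path)
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  for (key in c("types", "relations", "target"))
    if (is.null(cfg[[key]])) stopf("config is missing '%s'", key)

  types <- data.frame(
    name = vapply(cfg$types, function(t) as.character(t$name), character(1)),
    n    = vapply(cfg$types, function(t) as.integer(t$n), integer(1)),
    rank = vapply(cfg$types, function(t) as.integer(t$rank), integer(1)),
    stringsAsFactors = FALSE)
  ids <- lapply(seq_along(cfg$types), function(t) {
    spec <- cfg$types[[t]]
    if (!is.null(spec$ids)) {
      p <- resolve_path(spec$ids, base)
      v <- readLines(p)
      v <- v[nzchar(v)]
      if (length(v) != spec$n)
        stopf("type '%s': ids file has %d entries, declared n=%d",
              spec$name, length(v), spec$n)
      v
    } else paste(spec$name, seq_len(spec$n), sep = "_")
  })
  name2idx <- stats::setNames(seq_len(nrow(types)), types$name)
  type_idx <- function(nm) {
    i <- name2idx[[as.character(nm)]]
    if (is.null(i)) stopf("relation references undeclared type '%s'", nm)
    i
  }

  relations <- lapply(cfg$relations, function(r) {
    i <- type_idx(r$src); j <- type_idx(r$dst)
    R <- read_relation_file(resolve_path(r$path, base),
                            ids[[i]], ids[[j]], types$name[i], types$name[j])
    list(i = i, j = j, R = R,
         weight = if (is.null(r$weight)) 1 else as.numeric(r$weight))
  })
  constraints <- lapply(cfg$constraints %||% list(), function(cn) {
    i <- type_idx(cn$type)
    Th <- read_relation_file(resolve_path(cn$path, base),
                             ids[[i]], ids[[i]], types$name[i], types$name[i])
    list(i = i, Theta = Th)
  })
  target <- c(type_idx(cfg$target$src), type_idx(cfg$target$dst))
  warn <- unlist(c(
    lapply(relations, function(r) attr(r$R, "warnings")),
    lapply(constraints, function(cn) attr(cn$Theta, "warnings"))))
  net <- hetero_network(types, relations, constraints, target, ids = ids)
  net$warnings <- as.character(warn %||% character(0))
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_path <- function(p, base) {
  if (file.exists(p)) p else file.path(base, p)
}

## Reads an edge-list TSV or a MatrixMarket file into a dense matrix
## indexed by the declared rosters.
read_relation_file <- function(path, row_ids, col_ids, src_name, dst_name) {
  if (!file.exists(path)) stopf("relation file not found: %s", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    M <- as.matrix(Matrix::readMM(path))
    if (nrow(M) != length(row_ids) || ncol(M) != length(col_ids))
      stopf("%s: MatrixMarket size %dx%d does not match types %s (%d) x %s (%d)",
            path, nrow(M), ncol(M), src_name, length(row_ids),
            dst_name, length(col_ids))
    storage.mode(M) <- "double"
    return(M)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  dups <- 0L
  R <- matrix(0, length(row_ids), length(col_ids))
  rmap <- stats::setNames(seq_along(row_ids), row_ids)
  cmap <- stats::setNames(seq_along(col_ids), col_ids)
  for (ln in seq_along(lines)) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L)
      stopf("%s line %d: expected at least 2 tab-separated fields", path, ln)
    ri <- rmap[f[1]]; ci <- cmap[f[2]]
    if (is.na(ri))
      stopf("%s line %d: entity '%s' is not in the declared %s roster",
            path, ln, f[1], src_name)
    if (is.na(ci))
      stopf("%s line %d: entity '%s' is not in the declared %s roster",
            path, ln, f[2], dst_name)
    if (R[ri, ci] != 0) dups <- dups + 1L
    R[ri, ci] <- if (length(f) >= 3L) as.numeric(f[3]) else 1
  }
  if (dups > 0L)
    attr(R, "warnings") <- sprintf(
      "%s: %d duplicate edge(s) collapsed to single entries", path, dups)
  R
}

#' Diagnose structural problems in a network
#'
#' Re-checks the invariants of an assembled [hetero_network()] and
#' returns human-readable diagnostics instead of raising errors, so a
#' caller can report everything wrong at once.  An empty character
#' vector means the network is well-formed.
#'
#' @param net a [hetero_network()] (or a bare list with the same shape,
#'   e.g. one being assembled by hand).
#' @return character vector of diagnostics (length 0 when clean).
#' @export
validate_network <- function(net) {
  out <- character(0)
  m <- nrow(net$types)
  if (any(net$types$n < 1))
    out <- c(out, "some type has entity count n < 1")
  bad <- which(net$types$rank < 1 | net$types$rank > net$types$n)
  for (i in bad)
    out <- c(out, sprintf("type %d ('%s'): rank %d outside [1, %d]",
                          i, net$types$name[i], net$types$rank[i],
                          net$types$n[i]))
  for (b in net$relations) {
    if (b$i < 1 || b$i > m || b$j < 1 || b$j > m) {
      out <- c(out, sprintf("relation (%d,%d) references undeclared types",
                            b$i, b$j))
      next
    }
    if (nrow(b$R) != net$types$n[b$i] || ncol(b$R) != net$types$n[b$j])
      out <- c(out, sprintf(
        "relation (%d,%d): matrix %dx%d but declared sizes are %d and %d",
        b$i, b$j, nrow(b$R), ncol(b$R), net$types$n[b$i], net$types$n[b$j]))
    if (b$weight <= 0)
      out <- c(out, sprintf("relation (%d,%d): nonpositive weight %g",
                            b$i, b$j, b$weight))
  }
  for (cn in net$constraints) {
    side <- net$types$n[cn$i]
    if (nrow(cn$Theta) != side || ncol(cn$Theta) != side)
      out <- c(out, sprintf(
        "constraint for type %d ('%s'): matrix is %dx%d, expected %dx%d",
        cn$i, net$types$name[cn$i], nrow(cn$Theta), ncol(cn$Theta),
        side, side))
  }
  if (is.na(relation_index(net, net$target[1], net$target[2])))
    out <- c(out, sprintf("target pair (%d,%d) has no relation block",
                          net$target[1], net$target[2]))
  c(out, net$warnings %||% character(0))
}

#' Write a network to disk in the loader's layout
#'
#' Emits one TSV edge list per relation, one MatrixMarket file per
#' constraint matrix, and a \code{network.yaml} config that
#' [load_network()] reads back verbatim (round trip preserved).
#'
#' @param net a [hetero_network()].
#' @param dir output directory (created if needed).
#' @return invisibly, the path of the written config file.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rel_cfg <- list()
  for (b in net$relations) {
    fname <- sprintf("rel_%s_%s.tsv", net$types$name[b$i], net$types$name[b$j])
    nz <- which(b$R != 0, arr.ind = TRUE)
    nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
    lines <- sprintf("%s\t%s\t%.10g", net$ids[[b$i]][nz[, 1]],
                     net$ids[[b$j]][nz[, 2]], b$R[nz])
    writeLines(lines, file.path(dir, fname))
    rel_cfg[[length(rel_cfg) + 1L]] <-
      list(src = net$types$name[b$i], dst = net$types$name[b$j],
           path = fname, weight = b$weight)
  }
  con_cfg <- list()
  cnt <- integer(nrow(net$types))
  for (cn in net$constraints) {
    cnt[cn$i] <- cnt[cn$i] + 1L
    fname <- sprintf("theta_%s_%d.mtx", net$types$name[cn$i], cnt[cn$i])
    Matrix::writeMM(Matrix::Matrix(cn$Theta, sparse = TRUE),
                    file.path(dir, fname))
    con_cfg[[length(con_cfg) + 1L]] <-
      list(type = net$types$name[cn$i], path = fname)
  }
  cfg <- list(
    types = lapply(seq_len(nrow(net$types)), function(t)
      list(name = net$types$name[t], n = net$types$n[t],
           rank = net$types$rank[t])),
    relations = rel_cfg,
    constraints = con_cfg,
    target = list(src = net$types$name[net$target[1]],
                  dst = net$types$name[net$target[2]]))
  cfg_path <- file.path(dir, "network.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
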