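Package: trifuse
Title: Sparse Low-Rank Collective Matrix Tri-Factorization for
    Heterogeneous Biological Networks
Version: 0.1.0
Authors@R:
    person("trifuse", "developers", email = "trifuse@example.org",
           role = c("aut", "cre"))
Description: Predicts unobserved associations in a designated target
    relation of a multi-type molecular network (for example RNA-binding
    proteins versus alternative-splicing events) by collective matrix
    tri-factorization R_ij ~ G_i S_ij G_j' with entrywise nonnegative,
    cardinality-penalized basis factors.  The cardinality constraint is
    handled as a difference-of-convex penalty (total entry sum minus the
    sum of the k largest entries) and the objective is minimized by an
    accelerated proximal difference-of-convex solver with Nesterov
    extrapolation, Barzilai-Borwein curvature step estimates and a
    non-monotone Armijo line search.  Includes a planted-structure
    network simulator, row-wise k-fold cross-validation with AUC/AUPR,
    prediction ranking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
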