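#' Specification for a synthetic benchmark dataset
#'
#' Describes a dataset with the structure the factorization model assumes:
#' miRNAs and diseases fall into `k_true` latent groups; associations arise
#' from the product of cluster-structured nonnegative factors; the fabricated
#' functional-similarity matrix and the synthetic MeSH tree both reflect the
#' same groups, so the graph-regularization terms have real signal to
#' exploit.
#'
#' @param n_m,n_d Numbers of miRNAs and diseases.
#' @param k_true Planted latent rank (number of groups).
#' @param density Fraction of pairs set to 1 before noise, in (0, 1).
#' @param noise Per-entry label-flip probability in \[0, 0.5).
#' @param dag_depth Depth of the synthetic MeSH subtrees (number of
#'   dot-separated levels below the category root); default 3.
#' @param fs_noise Standard deviation of the perturbation added to the
#'   fabricated functional-similarity matrix; default 0.1.
#' @param frac_no_dag Fraction of diseases omitted from the MeSH table to
#'   exercise the Gaussian-kernel fallback; default 0.1.
#' @param seed Integer seed.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_m = 200, n_d = 100, k_true = 10, density = 0.05,
                       noise = 0.02, dag_depth = 3, fs_noise = 0.1,
                       frac_no_dag = 0.1, seed = 1) {
  stopifnot(n_m >= 2, n_d >= 2, k_true >= 1, density > 0, density < 1,
            noise >= 0, noise < 0.5, dag_depth >= 1,
            fs_noise >= 0, frac_no_dag >= 0, frac_no_dag < 1)
  if (round(density * n_m * n_d) < 1) stop("density too low for matrix size")
  structure(list(n_m = n_m, n_d = n_d, k_true = k_true, density = density,
                 noise = noise, dag_depth = dag_depth, fs_noise = fs_noise,
                 frac_no_dag = frac_no_dag, seed = seed),
            class = "synth_spec")
}

#' Named synthetic presets
#'
#' `"small"` (200 miRNAs x 100 diseases, 10 groups, density 0.05, flip
#' probability 0.02) is the standard benchmark used throughout the test
#' suite; `"medium"` mirrors the scale and ~2.9% density of an HMDD v2.0
#' export (495 x 383).
#'
#' @param name `"small"` or `"medium"`.
#' @param seed Integer seed.
#' @return A `synth_spec`.
#' @export
synth_preset <- function(name = c("small", "medium"), seed = 1) {
  name <- match.arg(name)
  switch(name,
         small = synth_spec(n_m = 200, n_d = 100, k_true = 10,
                            density = 0.05, noise = 0.02, seed = seed),
         medium = synth_spec(n_m = 495, n_d = 383, k_true = 15,
                             density = 0.029, noise = 0.02, seed = seed))
}

#' Generate a synthetic miRNA-disease benchmark
#'
#' Nonnegative planted factors with cluster structure are sampled (each
#' entity has one dominant group loading over a small uniform background);
#' the row-normalised product `P = W* H*'` defines the ground-truth
#' association propensity. The top `density` fraction of `P` entries become
#' the known positives, after which each entry is flipped independently with
#' probability `noise`. The functional-similarity matrix is the cosine
#' similarity of the planted miRNA factors, perturbed by Gaussian noise of sd
#' `fs_noise`, symmetrized and clipped to `[0, 1]`. The MeSH table embeds
#' each disease group as a subtree of a synthetic tree (same-group diseases
#' share a long tree-number prefix), with a `frac_no_dag` fraction of
#' diseases left out of the table.
#'
#' @param spec A `synth_spec`.
#' @return List with elements `dataset` (an `association_dataset`), `mesh`
#'   (a `mesh_table`-shaped data frame), `fs` (miRNA functional-similarity
#'   matrix), `truth` (ground-truth propensity matrix `P`), and `groups`
#'   (list of miRNA and disease group assignments).
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n_m <- spec$n_m; n_d <- spec$n_d; k <- spec$k_true
  mirna_names <- sprintf("mir-%03d", seq_len(n_m))
  disease_names <- sprintf("disease-%03d", seq_len(n_d))
  g_m <- sample(rep_len(seq_len(k), n_m))
  g_d <- sample(rep_len(seq_len(k), n_d))
  Wt <- matrix(stats::runif(n_m * k, 0, 0.2), n_m, k)
  Wt[cbind(seq_len(n_m), g_m)] <- Wt[cbind(seq_len(n_m), g_m)] +
    stats::runif(n_m, 0.8, 1.2)
  Ht <- matrix(stats::runif(n_d * k, 0, 0.2), n_d, k)
  Ht[cbind(seq_len(n_d), g_d)] <- Ht[cbind(seq_len(n_d), g_d)] +
    stats::runif(n_d, 0.8, 1.2)
  P <- tcrossprod(Wt, Ht)
  P <- P / rowSums(P)
  dimnames(P) <- list(mirna_names, disease_names)

  n_pos <- round(spec$density * n_m * n_d)
  Y <- matrix(0L, n_m, n_d, dimnames = dimnames(P))
  Y[order(P, decreasing = TRUE)[seq_len(n_pos)]] <- 1L
  if (spec$noise > 0) {
    flip <- stats::runif(n_m * n_d) < spec$noise
    Y[flip] <- 1L - Y[flip]
  }

  # fabricated functional similarity: cosine of planted miRNA factors
  nrm <- sqrt(rowSums(Wt^2))
  FS <- tcrossprod(Wt / nrm)
  if (spec$fs_noise > 0) {
    E <- matrix(stats::rnorm(n_m * n_m, 0, spec$fs_noise), n_m, n_m)
    FS <- FS + (E + t(E)) / 2
  }
  FS[FS < 0] <- 0
  FS[FS > 1] <- 1
  diag(FS) <- 1
  dimnames(FS) <- list(mirna_names, mirna_names)

  # synthetic MeSH tree: one category root per disease group, a shared chain
  # of (dag_depth - 1) levels, then one leaf segment per disease
  chains <- vapply(seq_len(k), function(g) {
    segs <- sprintf("%03d", sample(100:999, max(spec$dag_depth - 1L, 0L)))
    paste(c(sprintf("C%02d", g), segs), collapse = ".")
  }, "")
  leaf <- sprintf("%03d", sample(100:999, n_d, replace = TRUE))
  tree_number <- paste(chains[g_d], leaf, sep = ".")
  keep <- rep(TRUE, n_d)
  n_drop <- round(spec$frac_no_dag * n_d)
  if (n_drop > 0) keep[sample.int(n_d, n_drop)] <- FALSE
  mesh <- data.frame(disease = disease_names[keep],
                     tree_number = tree_number[keep],
                     stringsAsFactors = FALSE)
  class(mesh) <- c("mesh_table", "data.frame")

  # built directly (not via the edge-list constructor) so that entities with
  # no association are kept with all-zero profiles
  dataset <- list(mirna_names = mirna_names, disease_names = disease_names,
                  Y = Y)
  attr(dataset, "n_edges") <- sum(Y)
  class(dataset) <- "association_dataset"

  list(dataset = dataset, mesh = mesh, fs = FS, truth = P,
       groups = list(mirna = g_m, disease = g_d))
}

#' Hand-checkable micro fixtures
#'
#' The small cases whose expected values can be derived by hand and that
#' recur across the test suite: the sibling-disease MeSH DAG pair (semantic
#' similarity 1/3 at decay 0.5), the 2x2 identity association matrix whose
#' GIP off-diagonal is `exp(-2)` at unit bandwidth, and a tiny 3x2
#' factorization instance.
#'
#' @return A list with elements `sibling_mesh` (mesh table for diseases
#'   `d1`, `d2` under a shared root), `identity_dataset` (2 miRNAs x 2
#'   diseases, `Y = I`), and `tiny` (a 3x2 binary `Y` with planted rank-1
#'   structure).
#' @export
toy_fixture <- function() {
  sibling_mesh <- data.frame(
    disease = c("d1", "d2"),
    tree_number = c("C01.111", "C01.222"),
    stringsAsFactors = FALSE)
  class(sibling_mesh) <- c("mesh_table", "data.frame")
  identity_dataset <- association_dataset(c("m1", "m2"), c("dA", "dB"))
  identity_dataset$Y <- diag(2L)
  dimnames(identity_dataset$Y) <- list(c("m1", "m2"), c("dA", "dB"))
  tiny <- list(Y = matrix(c(1, 1, 0, 1, 1, 0), 3, 2,
                          dimnames = list(c("m1", "m2", "m3"),
                                          c("d1", "d2"))),
               W = matrix(c(1, 1, 0), 3, 1),
               H = matrix(c(1, 1), 2, 1))
  list(sibling_mesh = sibling_mesh, identity_dataset = identity_dataset,
       tiny = tiny)
}
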