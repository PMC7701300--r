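#' Partition the known associations into cross-validation folds
#'
#' Uniformly random, seeded partition of the 1-entries of the association
#' matrix; fold sizes differ by at most one.
#'
#' @param dataset An `association_dataset`.
#' @param n_folds Number of folds; default 5.
#' @param seed Integer seed.
#' @return A data frame of class `fold_plan` with columns `index` (linear
#'   index into `Y` of each positive) and `fold`.
#' @export
make_folds <- function(dataset, n_folds = 5, seed = 1) {
  stopifnot(n_folds >= 2)
  pos <- which(dataset$Y == 1)
  n_pos <- length(pos)
  if (n_folds > n_pos) stop("more folds than known associations")
  set.seed(seed)
  fold <- integer(n_pos)
  fold[sample.int(n_pos)] <- rep_len(seq_len(n_folds), n_pos)
  out <- data.frame(index = pos, fold = fold)
  attr(out, "seed") <- seed
  attr(out, "n_folds") <- n_folds
  class(out) <- c("fold_plan", "data.frame")
  out
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps thresholds over the unique score values (equal scores grouped into
#' one step), accumulates TPR = TP/(TP+FN) and FPR = FP/(TN+FP), and
#' integrates by the trapezoid rule. With tied scores grouped this equals the
#' normalised Mann-Whitney statistic with ties counted 1/2.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 (or logical) truth labels, parallel to `scores`.
#' @return List with elements `auc` and `points` (data frame of `fpr`,
#'   `tpr`, starting at the origin).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels); N <- length(labels) - P
  if (P == 0 || N == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- c(which(diff(s) != 0), length(s))
  tpr <- c(0, cumsum(l)[last] / P)
  fpr <- c(0, cumsum(1 - l)[last] / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(auc = auc, points = data.frame(fpr = fpr, tpr = tpr))
}

#' Precision-recall curve and AUPR
#'
#' Precision = TP/(TP+FP) and recall = TP/(TP+FN) at each unique-score
#' threshold; area by the trapezoid rule over recall, with the curve anchored
#' at recall 0 at the first threshold's precision.
#'
#' @inheritParams roc_auc
#' @return List with elements `aupr` and `points` (data frame of `recall`,
#'   `precision`).
#' @export
pr_aupr <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  P <- sum(labels)
  if (P == 0 || P == length(labels)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  l <- labels[ord]; s <- scores[ord]
  last <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(l)[last]
  prec <- tp / last
  rec <- tp / P
  rec <- c(0, rec); prec <- c(prec[1L], prec)
  aupr <- sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
  list(aupr = aupr, points = data.frame(recall = rec, precision = prec))
}

# Integrated similarities recomputed from a training association matrix only,
# so held-out positives cannot leak through the interaction profiles.
training_similarities <- function(Y_train, semantic = NULL, fs = NULL,
                                  gamma_prime = 1) {
  km <- gip_kernel(Y_train, "mirna", gamma_prime)
  kd <- gip_kernel(Y_train, "disease", gamma_prime)
  has_fs <- if (is.null(fs)) NULL else rep(TRUE, nrow(fs))
  sim_m <- integrate_similarity(fs, km, has_primary = has_fs)
  sim_d <- integrate_similarity(semantic, kd)
  list(sim_mirna = sim_m, sim_disease = sim_d)
}

#' Global fivefold cross-validation of association prediction
#'
#' The known positives are split into `n_folds` folds. For each fold the
#' held-out positives are zeroed in the training matrix, the Gaussian
#' interaction-profile kernels and integrated similarities are recomputed
#' from the training matrix alone, the model is refit, and the held-out
#' positives (label 1) are scored against every pair never known in the full
#' dataset (label 0). AUC/AUPR are reported per fold, as the per-fold mean,
#' and pooled over the concatenated fold score sets.
#'
#' @param dataset An `association_dataset`.
#' @param mesh Optional `mesh_table` for disease semantic similarity; when
#'   absent the disease similarity is purely the Gaussian kernel.
#' @param fs Optional precomputed miRNA functional-similarity matrix in
#'   dataset row order; when absent the miRNA similarity is purely Gaussian.
#' @param n_folds Number of folds; default 5.
#' @param seed Integer seed driving the fold plan and the fits.
#' @param folds Optional precomputed `fold_plan` (shared across sweep runs).
#' @param delta Semantic decay factor; default 0.5.
#' @param gamma_prime GIP bandwidth parameter; default 1.
#' @param ... Hyperparameters passed on to [mfmda()] (`k`, `lambda_l`,
#'   `lambda_m`, `lambda_d`, `max_iter`, `tol`, `eps`).
#' @return An object of class `mfmda_cv`: per-fold table, pooled and mean
#'   AUC/AUPR, and pooled ROC/PR points.
#' @export
run_fivefold <- function(dataset, mesh = NULL, fs = NULL, n_folds = 5,
                         seed = 1, folds = NULL, delta = 0.5,
                         gamma_prime = 1, ...) {
  Y <- dataset$Y
  if (is.null(folds)) folds <- make_folds(dataset, n_folds, seed)
  n_folds <- attr(folds, "n_folds")
  semantic <- if (is.null(mesh)) NULL else
    semantic_similarity_matrix(dataset$disease_names, mesh, delta)
  neg <- which(Y == 0)
  pooled_scores <- numeric(0); pooled_labels <- numeric(0)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test_pos <- folds$index[folds$fold == f]
    Y_train <- Y
    Y_train[test_pos] <- 0
    sims <- training_similarities(Y_train, semantic, fs, gamma_prime)
    fit <- mfmda(Y_train, sims$sim_mirna, sims$sim_disease,
                 seed = seed * 1000L + f, ...)
    Ystar <- predict(fit)
    sc <- c(Ystar[test_pos], Ystar[neg])
    lb <- c(rep(1, length(test_pos)), rep(0, length(neg)))
    roc <- roc_auc(sc, lb)
    pr <- pr_aupr(sc, lb)
    per_fold[[f]] <- data.frame(fold = f, n_test_pos = length(test_pos),
                                auc = roc$auc, aupr = pr$aupr)
    pooled_scores <- c(pooled_scores, sc)
    pooled_labels <- c(pooled_labels, lb)
  }
  per_fold <- do.call(rbind, per_fold)
  roc_pool <- roc_auc(pooled_scores, pooled_labels)
  pr_pool <- pr_aupr(pooled_scores, pooled_labels)
  structure(list(protocol = "fivefold",
                 per_fold = per_fold,
                 auc_pooled = roc_pool$auc, aupr_pooled = pr_pool$aupr,
                 auc_mean = mean(per_fold$auc), aupr_mean = mean(per_fold$aupr),
                 roc_points = roc_pool$points, pr_points = pr_pool$points,
                 seed = seed, folds = folds),
            class = "mfmda_cv")
}

#' Leave-one-disease-out cross-validation (new-disease protocol)
#'
#' For each test disease the whole column of known associations is zeroed in
#' the training matrix, the interaction-profile kernels are recomputed, the
#' model is refit, and the removed positives are scored against that
#' disease's never-known miRNAs. Reports one AUC per disease and their mean.
#' Diseases whose column has no positive, or no negative, are skipped with a
#' warning.
#'
#' @inheritParams run_fivefold
#' @param diseases Disease names or column indices to hold out; default all.
#' @return An object of class `mfmda_cv` with per-disease AUCs and
#'   `auc_mean`.
#' @export
run_cv_d <- function(dataset, mesh = NULL, fs = NULL, diseases = NULL,
                     seed = 1, delta = 0.5, gamma_prime = 1, ...) {
  Y <- dataset$Y
  if (is.null(diseases)) diseases <- seq_len(ncol(Y))
  if (is.character(diseases)) {
    diseases <- match(tolower(diseases), tolower(dataset$disease_names))
    if (anyNA(diseases)) stop("unknown disease name in `diseases`")
  }
  semantic <- if (is.null(mesh)) NULL else
    semantic_similarity_matrix(dataset$disease_names, mesh, delta)
  res <- vector("list", length(diseases))
  for (a in seq_along(diseases)) {
    j <- diseases[a]
    pos <- which(Y[, j] == 1)
    negs <- which(Y[, j] == 0)
    if (length(pos) == 0L || length(negs) == 0L) {
      warning("disease ", dataset$disease_names[j],
              " skipped: needs both known and unknown miRNAs")
      next
    }
    Y_train <- Y
    Y_train[, j] <- 0
    sims <- training_similarities(Y_train, semantic, fs, gamma_prime)
    fit <- mfmda(Y_train, sims$sim_mirna, sims$sim_disease,
                 seed = seed * 1000L + a, ...)
    col_scores <- predict(fit)[, j]
    roc <- roc_auc(c(col_scores[pos], col_scores[negs]),
                   c(rep(1, length(pos)), rep(0, length(negs))))
    res[[a]] <- data.frame(disease = dataset$disease_names[j],
                           n_pos = length(pos), auc = roc$auc)
  }
  per_disease <- do.call(rbind, res)
  if (is.null(per_disease)) stop("no evaluable disease in `diseases`")
  structure(list(protocol = "cv_d",
                 per_disease = per_disease,
                 auc_mean = mean(per_disease$auc),
                 seed = seed),
            class = "mfmda_cv")
}

#' @export
print.mfmda_cv <- function(x, ...) {
  if (x$protocol == "fivefold") {
    cat(sprintf("Global %d-fold cross-validation\n", nrow(x$per_fold)))
    cat(sprintf("  pooled AUC = %.4f, pooled AUPR = %.4f\n",
                x$auc_pooled, x$aupr_pooled))
    cat(sprintf("  per-fold mean AUC = %.4f, mean AUPR = %.4f\n",
                x$auc_mean, x$aupr_mean))
  } else {
    cat("New-disease cross-validation (per-disease column removal)\n")
    cat(sprintf("  %d diseases evaluated, mean AUC = %.4f\n",
                nrow(x$per_disease), x$auc_mean))
  }
  invisible(x)
}

#' Fivefold AUC across graph-regularization weights
#'
#' Reruns [run_fivefold()] once per `(lambda_m, lambda_d)` grid point with a
#' shared fold plan, so differences across rows are attributable to the
#' regularization weights alone.
#'
#' @inheritParams run_fivefold
#' @param lambda_grid Numeric vector (used for both weights) or a two-column
#'   matrix/data frame of `(lambda_m, lambda_d)` pairs.
#' @param ... Remaining hyperparameters passed to [mfmda()].
#' @return Data frame with columns `lambda_m`, `lambda_d`, `auc_pooled`,
#'   `aupr_pooled`, `auc_mean`.
#' @export
sweep_lambda <- function(dataset, mesh = NULL, fs = NULL,
                         lambda_grid = seq(0.2, 1, by = 0.2),
                         n_folds = 5, seed = 1, delta = 0.5,
                         gamma_prime = 1, ...) {
  if (is.null(dim(lambda_grid))) {
    lambda_grid <- cbind(lambda_m = lambda_grid, lambda_d = lambda_grid)
  }
  folds <- make_folds(dataset, n_folds, seed)
  rows <- lapply(seq_len(nrow(lambda_grid)), function(g) {
    cv <- run_fivefold(dataset, mesh, fs, seed = seed, folds = folds,
                       delta = delta, gamma_prime = gamma_prime,
                       lambda_m = lambda_grid[g, 1L],
                       lambda_d = lambda_grid[g, 2L], ...)
    data.frame(lambda_m = lambda_grid[g, 1L], lambda_d = lambda_grid[g, 2L],
               auc_pooled = cv$auc_pooled, aupr_pooled = cv$aupr_pooled,
               auc_mean = cv$auc_mean)
  })
  do.call(rbind, rows)
}

#' Rank unverified candidate miRNAs for one disease
#'
#' miRNAs already known to be associated with the disease are excluded; the
#' remaining candidates are ordered by predicted score, descending, with ties
#' broken by miRNA index (dataset row order).
#'
#' @param model A fitted `mfmda` model, or a score matrix `Y*`.
#' @param dataset The `association_dataset` the model was fit to.
#' @param disease Disease name or column index.
#' @param top_k Number of candidates to keep; default 10. Truncated when
#'   fewer candidates exist.
#' @return Data frame with columns `rank`, `mirna`, `score`.
#' @export
rank_candidates <- function(model, dataset, disease, top_k = 10) {
  Ystar <- if (inherits(model, "mfmda")) predict(model) else as.matrix(model)
  j <- if (is.character(disease)) {
    match(tolower(trimws(disease)), tolower(dataset$disease_names))
  } else disease
  if (is.na(j) || j < 1 || j > ncol(Ystar)) stop("unknown disease: ", disease)
  cand <- which(dataset$Y[, j] == 0)
  ord <- cand[order(-Ystar[cand, j], cand)]
  ord <- utils::head(ord, top_k)
  data.frame(rank = seq_along(ord),
             mirna = dataset$mirna_names[ord],
             score = as.numeric(Ystar[, j][ord]),
             stringsAsFactors = FALSE)
}
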