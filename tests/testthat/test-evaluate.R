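make_toy_dataset <- function(Y) {
  d <- list(mirna_names = sprintf("m%d", seq_len(nrow(Y))),
            disease_names = sprintf("d%d", seq_len(ncol(Y))),
            Y = Y)
  class(d) <- "association_dataset"
  d
}

test_that("folds partition the positives into near-equal seeded groups", {
  Y <- matrix(0L, 5, 4); Y[1:10] <- 1L
  ds <- make_toy_dataset(Y)
  f <- make_folds(ds, 5, seed = 3)
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  expect_setequal(f$index, which(Y == 1))
  # 11 positives: sizes differ by at most one
  Y2 <- matrix(0L, 5, 4); Y2[1:11] <- 1L
  f2 <- make_folds(make_toy_dataset(Y2), 5, seed = 3)
  expect_equal(sort(as.integer(table(f2$fold))), c(2L, 2L, 2L, 2L, 3L))
  # reproducible
  expect_identical(make_folds(ds, 5, seed = 3), f)
  expect_error(make_folds(ds, 11, seed = 1), "more folds")
})

test_that("ROC/AUC agrees with the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 0, 0))$auc, 1)
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), sample(c(1, 8), 1)))  # some ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC is permutation invariant and complements under reversal", {
  set.seed(32)
  scores <- rnorm(100)  # tie-free
  labels <- rbinom(100, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  p <- sample(100)
  expect_equal(roc_auc(scores[p], labels[p])$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a, tolerance = 1e-12)
  # random scores on many points sit near 0.5
  big <- roc_auc(rnorm(20000), rbinom(20000, 1, 0.3))$auc
  expect_gt(big, 0.47); expect_lt(big, 0.53)
})

test_that("PR/AUPR matches the exhaustive-threshold oracle", {
  # perfect ranking has unit area; uniform scores give prevalence
  expect_equal(pr_aupr(c(4, 3, 2, 1), c(1, 1, 0, 0))$aupr, 1)
  flat <- pr_aupr(rep(1, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(flat$points$precision[nrow(flat$points)], 0.3)
  set.seed(33)
  for (rep in 1:40) {
    n <- sample(5:80, 1)
    scores <- sample(round(rnorm(n), 1))
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(pr_aupr(scores, labels)$aupr, oracle_aupr(scores, labels),
                 tolerance = 1e-12)
    p <- sample(n)
    expect_equal(pr_aupr(scores[p], labels[p])$aupr,
                 pr_aupr(scores, labels)$aupr, tolerance = 1e-12)
  }
})

test_that("fivefold protocol holds out each positive exactly once without leakage", {
  syn <- synth_generate(synth_spec(n_m = 60, n_d = 30, k_true = 4,
                                   density = 0.08, noise = 0, seed = 7))
  ds <- syn$dataset
  folds <- make_folds(ds, 5, seed = 7)
  expect_setequal(folds$index, which(ds$Y == 1))
  expect_equal(anyDuplicated(folds$index), 0L)
  # training matrices per fold: held-out positives absent, similarities
  # reproducible from the training matrix alone
  for (f in 1:5) {
    Y_train <- ds$Y
    Y_train[folds$index[folds$fold == f]] <- 0L
    expect_equal(sum(Y_train[folds$index[folds$fold == f]]), 0)
    K1 <- gip_kernel(Y_train, "disease")
    K2 <- gip_kernel(Y_train, "disease")
    expect_identical(K1, K2)
  }
  cv <- run_fivefold(ds, syn$mesh, syn$fs, seed = 7, k = 10)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_equal(sum(cv$per_fold$n_test_pos), sum(ds$Y))
  expect_s3_class(cv, "mfmda_cv")
  expect_output(print(cv), "pooled AUC")
})

test_that("column-removal protocol evaluates and skips diseases sensibly", {
  syn <- synth_generate(synth_spec(n_m = 60, n_d = 30, k_true = 4,
                                   density = 0.08, noise = 0, seed = 8))
  ds <- syn$dataset
  evaluable <- which(colSums(ds$Y) > 0 & colSums(ds$Y) < nrow(ds$Y))[1:4]
  cv <- run_cv_d(ds, syn$mesh, syn$fs, diseases = evaluable, seed = 8, k = 10)
  expect_equal(nrow(cv$per_disease), 4L)
  expect_true(all(cv$per_disease$auc >= 0 & cv$per_disease$auc <= 1))
  # a disease with every miRNA known has no negatives: skipped with warning
  ds2 <- ds
  ds2$Y[, 2] <- 1L
  expect_warning(run_cv_d(ds2, syn$mesh, syn$fs, diseases = c(1, 2),
                          seed = 8, k = 10), "skipped")
})

test_that("the lambda sweep shares folds so differences come from lambda", {
  syn <- synth_generate(synth_spec(n_m = 50, n_d = 25, k_true = 4,
                                   density = 0.1, noise = 0, seed = 9))
  sw <- sweep_lambda(syn$dataset, syn$mesh, syn$fs, lambda_grid = 0.2,
                     seed = 9, k = 10)
  expect_equal(nrow(sw), 1L)
  # same grid point twice: identical results under the shared plan
  sw2 <- sweep_lambda(syn$dataset, syn$mesh, syn$fs,
                      lambda_grid = c(0.2, 0.2), seed = 9, k = 10)
  expect_equal(sw2$auc_pooled[1], sw2$auc_pooled[2], tolerance = 1e-12)
})

test_that("candidate ranking excludes known pairs and breaks ties by index", {
  Y <- matrix(0L, 4, 2); Y[1, 1] <- 1L
  ds <- make_toy_dataset(Y)
  Ystar <- matrix(c(9, 3, 5, 5, 1, 1, 1, 1), 4, 2)
  r <- rank_candidates(Ystar, ds, 1, top_k = 10)
  expect_identical(r$mirna, c("m3", "m4", "m2"))  # m1 known, tie m3<m4 by index
  expect_equal(r$rank, 1:3)
  # top_k larger than candidate pool truncates; all-known yields empty
  expect_equal(nrow(rank_candidates(Ystar, ds, "d1", top_k = 2)), 2L)
  ds$Y[, 2] <- 1L
  expect_equal(nrow(rank_candidates(Ystar, ds, "d2")), 0L)
  expect_error(rank_candidates(Ystar, ds, "nope"), "unknown disease")
})
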