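# Independent oracles used to cross-check the implementation. These are
# deliberately naive (brute force / direct recursion) and share no code with
# the package internals.

# normalised Mann-Whitney statistic, ties counted 1/2
oracle_auc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  d <- outer(sp, sn, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(sp) * length(sn))
}

# exhaustive threshold sweep for the PR curve, trapezoid over recall,
# anchored at recall 0 with the first threshold's precision
oracle_aupr <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prec <- rec <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    prec[i] <- sum(pred & labels == 1) / sum(pred)
    rec[i] <- sum(pred & labels == 1) / P
  }
  rec <- c(0, rec)
  prec <- c(prec[1L], prec)
  sum(diff(rec) * (prec[-1] + prec[-length(prec)]) / 2)
}

# direct recursive evaluation of the semantic-contribution recurrence
oracle_contributions <- function(dag, delta) {
  children_of <- function(t) dag$edges$child[dag$edges$parent == t]
  rec <- function(t) {
    if (t %in% dag$disease_nodes) return(1)
    max(vapply(children_of(t), function(ch) delta * rec(ch), numeric(1)))
  }
  stats::setNames(vapply(dag$nodes, rec, numeric(1)), dag$nodes)
}

# plain multiplicative NMF step (Lee-Seung, alternating, same eps guard)
oracle_nmf_step <- function(Y, W, H, eps = 1e-10) {
  W2 <- W * (Y %*% H) / (W %*% t(H) %*% H + eps)
  H2 <- H * (t(Y) %*% W2) / (H %*% t(W2) %*% W2 + eps)
  list(W = W2, H = H2)
}

# random disease with 1-3 tree numbers over a tiny segment alphabet, so DAGs
# stay small (<= 8 nodes) and overlap across diseases is common
random_mesh_rows <- function(disease, n_trees = sample(1:3, 1)) {
  trees <- replicate(n_trees, {
    root <- sample(c("A01", "B02"), 1)
    depth <- sample(0:2, 1)
    segs <- sample(c("100", "200", "300"), depth, replace = TRUE)
    paste(c(root, segs), collapse = ".")
  })
  data.frame(disease = disease, tree_number = unique(trees),
             stringsAsFactors = FALSE)
}

# small random factorization instance with strictly positive factors
random_instance <- function(n_m = 20, n_d = 15, k = 4, density = 0.2) {
  Y <- matrix(as.numeric(runif(n_m * n_d) < density), n_m, n_d)
  Sm <- matrix(runif(n_m * n_m), n_m, n_m)
  Sm <- (Sm + t(Sm)) / 2
  diag(Sm) <- 1
  Sd <- matrix(runif(n_d * n_d), n_d, n_d)
  Sd <- (Sd + t(Sd)) / 2
  diag(Sd) <- 1
  list(Y = Y, Sm = Sm, Sd = Sd,
       W = matrix(runif(n_m * k, 0.05, 1), n_m, k),
       H = matrix(runif(n_d * k, 0.05, 1), n_d, k))
}
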