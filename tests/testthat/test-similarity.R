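test_that("tree numbers expand to prefix DAGs", {
  mesh <- data.frame(disease = "d", tree_number = "C04.588")
  dag <- build_disease_dag("d", mesh)
  expect_setequal(dag$nodes, c("C04", "C04.588"))
  expect_equal(dag$edges, data.frame(parent = "C04", child = "C04.588"))
  # shared root across two tree numbers is deduplicated
  mesh2 <- data.frame(disease = c("d", "d"),
                      tree_number = c("C04.111", "C04.222"))
  dag2 <- build_disease_dag("d", mesh2)
  expect_equal(sum(dag2$nodes == "C04"), 1L)
  expect_setequal(dag2$disease_nodes, c("C04.111", "C04.222"))
  # absent disease signals "no DAG"
  expect_null(build_disease_dag("unknown", mesh))
})

test_that("semantic contributions follow the decaying-max recurrence", {
  # single node: base case
  mesh <- data.frame(disease = "d", tree_number = "C04")
  expect_equal(semantic_contributions(build_disease_dag("d", mesh)),
               c(C04 = 1))
  # chain root -> child
  mesh <- data.frame(disease = "c", tree_number = "C04.588")
  D <- semantic_contributions(build_disease_dag("c", mesh), delta = 0.5)
  expect_equal(D[["C04.588"]], 1)
  expect_equal(D[["C04"]], 0.5)
  # diamond: max over two paths of different length
  dag <- structure(list(
    disease = "d", nodes = c("a", "b", "d"),
    edges = data.frame(parent = c("a", "a", "b"), child = c("d", "b", "d")),
    disease_nodes = "d"), class = "disease_dag")
  D <- semantic_contributions(dag, delta = 0.5)
  expect_equal(D[["a"]], 0.5)  # max(0.5 * 1, 0.5 * 0.5)
  expect_equal(D[["b"]], 0.5)
  # cycles are rejected
  bad <- structure(list(
    disease = "d", nodes = c("a", "b", "d"),
    edges = data.frame(parent = c("a", "b", "b"), child = c("b", "a", "d")),
    disease_nodes = "d"), class = "disease_dag")
  expect_error(semantic_contributions(bad), "cycle")
})

test_that("semantic contributions match the recursive oracle on random DAGs", {
  set.seed(11)
  for (delta in c(0.3, 0.5, 0.8)) {
    for (rep in 1:40) {
      mesh <- random_mesh_rows("d")
      dag <- build_disease_dag("d", mesh)
      expect_lte(length(dag$nodes), 8L)
      expect_identical(semantic_contributions(dag, delta),
                       oracle_contributions(dag, delta))
    }
  }
})

test_that("ancestor contributions weakly increase with the decay factor", {
  set.seed(12)
  for (rep in 1:25) {
    dag <- build_disease_dag("d", random_mesh_rows("d"))
    lo <- semantic_contributions(dag, 0.3)
    hi <- semantic_contributions(dag, 0.6)
    expect_true(all(hi >= lo - 1e-15))
  }
})

test_that("semantic similarity is the normalised shared-contribution ratio", {
  toy <- toy_fixture()
  d1 <- build_disease_dag("d1", toy$sibling_mesh)
  d2 <- build_disease_dag("d2", toy$sibling_mesh)
  expect_equal(semantic_similarity(d1, d2, 0.5), 1 / 3)
  expect_equal(semantic_similarity(d1, d1), 1)
  # disjoint DAGs share nothing
  mesh <- data.frame(disease = c("x", "y"),
                     tree_number = c("C04.111", "D05.222"))
  expect_equal(semantic_similarity(build_disease_dag("x", mesh),
                                   build_disease_dag("y", mesh)), 0)
})

test_that("the pairwise semantic matrix is symmetric with unit diagonal", {
  set.seed(13)
  mesh <- do.call(rbind, lapply(sprintf("d%d", 1:8), random_mesh_rows))
  S <- semantic_similarity_matrix(c(sprintf("d%d", 1:8), "nodag"), mesh)
  has <- attr(S, "has_dag")
  expect_identical(unname(has), c(rep(TRUE, 8), FALSE))
  sub <- S[1:8, 1:8]
  expect_equal(sub, t(sub), tolerance = 1e-12)
  expect_equal(unname(diag(sub)), rep(1, 8))
  expect_true(all(sub >= 0 & sub <= 1))
  expect_true(all(is.na(S[9, ])))
})

test_that("the GIP kernel matches its closed form and kernel axioms", {
  K <- gip_kernel(diag(2), "mirna", gamma_prime = 1)
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(unname(diag(K)), c(1, 1))
  set.seed(14)
  Y <- matrix(rbinom(60, 1, 0.3), 10, 6)
  Y[1, ] <- Y[2, ]  # identical profiles
  for (axis in c("mirna", "disease")) {
    K <- gip_kernel(Y, axis)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(unname(diag(K)), rep(1, nrow(K)))
    expect_true(all(K > 0 & K <= 1))
  }
  expect_equal(gip_kernel(Y, "mirna")[1, 2], 1)
  expect_error(gip_kernel(matrix(0, 3, 3), "mirna"), "all-zero")
})

test_that("the GIP kernel commutes with entity permutations", {
  set.seed(15)
  Y <- matrix(rbinom(80, 1, 0.25), 10, 8)
  Y[1, 1] <- 1  # ensure nonzero
  p <- sample(10)
  expect_equal(gip_kernel(Y[p, ], "mirna"),
               gip_kernel(Y, "mirna")[p, p],
               ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("integration uses the primary similarity only when both sides have one", {
  set.seed(16)
  Yg <- matrix(rbinom(12, 1, 0.5), 4, 3)
  Yg[1, 1] <- 1
  gauss <- gip_kernel(Yg, "mirna")
  prim <- matrix(NA_real_, 4, 4)
  prim[1:3, 1:3] <- 0.7
  diag(prim)[1:3] <- 1
  has <- c(TRUE, TRUE, TRUE, FALSE)
  S <- integrate_similarity(prim, gauss, has_primary = has)
  mask <- attr(S, "source_mask")
  expect_equal(S[1, 2], 0.7)
  expect_identical(mask[1, 2], "primary")
  expect_equal(S[1, 4], gauss[1, 4])  # fallback row/column
  expect_identical(mask[, 4], rep("gaussian", 4))
  expect_equal(unname(diag(S)), rep(1, 4))
  # all primaries defined: output equals primary except diagonal
  prim2 <- matrix(0.4, 4, 4)
  S2 <- integrate_similarity(prim2, gauss, has_primary = rep(TRUE, 4))
  expect_equal(unname(S2[1, 2]), 0.4)
  expect_equal(unname(diag(S2)), rep(1, 4))
  expect_error(integrate_similarity(prim[1:3, 1:3], gauss), "mismatch")
})
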