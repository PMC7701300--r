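#' Build the MeSH ancestor DAG for one disease
#'
#' Every dot-prefix of each of the disease's MeSH tree numbers is an ancestor
#' heading; edges connect each prefix to its immediate extension. The full
#' tree numbers themselves are the nodes identified with the disease (a
#' disease with several tree numbers has several such leaves, all carrying
#' semantic contribution 1).
#'
#' @param disease Disease name (matched against the table after trimming,
#'   case-insensitively).
#' @param mesh_table A `mesh_table` from [read_mesh_table()], or any data
#'   frame with columns `disease` and `tree_number`.
#' @return An object of class `disease_dag` (list with `disease`, `nodes`,
#'   `edges` data frame of parent/child codes, and `disease_nodes`), or
#'   `NULL` when the disease has no tree number — the caller then falls back
#'   to the Gaussian interaction-profile similarity.
#' @export
build_disease_dag <- function(disease, mesh_table) {
  hit <- tolower(trimws(mesh_table$disease)) == tolower(trimws(disease))
  trees <- unique(mesh_table$tree_number[hit])
  if (length(trees) == 0L) return(NULL)
  nodes <- character(0)
  parent <- character(0)
  child <- character(0)
  for (tn in trees) {
    segs <- strsplit(tn, ".", fixed = TRUE)[[1L]]
    prefixes <- vapply(seq_along(segs),
                       function(k) paste(segs[seq_len(k)], collapse = "."), "")
    nodes <- c(nodes, prefixes)
    if (length(prefixes) > 1L) {
      parent <- c(parent, prefixes[-length(prefixes)])
      child <- c(child, prefixes[-1L])
    }
  }
  nodes <- unique(nodes)
  edges <- unique(data.frame(parent = parent, child = child,
                             stringsAsFactors = FALSE))
  structure(list(disease = disease, nodes = nodes, edges = edges,
                 disease_nodes = trees),
            class = "disease_dag")
}

#' Semantic contribution of each DAG node to its disease
#'
#' The disease's own node(s) contribute 1; every other ancestor `t`
#' contributes `max(delta * D(t'))` over its children `t'` in the DAG, so
#' contributions decay geometrically with distance from the disease. Computed
#' by a reverse-topological sweep; a cycle in the edge set is an error.
#'
#' @param dag A `disease_dag`.
#' @param delta Semantic decay factor in (0, 1); default 0.5.
#' @return Named numeric vector of contributions, one per DAG node, each in
#'   (0, 1].
#' @export
semantic_contributions <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  nodes <- dag$nodes
  n <- length(nodes)
  kids <- split(match(dag$edges$child, nodes), match(dag$edges$parent, nodes))
  n_kids <- integer(n)
  n_kids[as.integer(names(kids))] <- lengths(kids)
  # Kahn topological order on parent -> child edges
  outdeg <- n_kids
  parents_of <- split(match(dag$edges$parent, nodes), match(dag$edges$child, nodes))
  queue <- which(outdeg == 0L)  # sinks first (reverse-topological)
  order_rev <- integer(0)
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    order_rev <- c(order_rev, v)
    for (p in parents_of[[as.character(v)]]) {
      outdeg[p] <- outdeg[p] - 1L
      if (outdeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order_rev) < n) stop("cycle detected in disease DAG")
  D <- numeric(n)
  names(D) <- nodes
  is_disease <- nodes %in% dag$disease_nodes
  for (v in order_rev) {
    if (is_disease[v]) {
      D[v] <- 1
    } else {
      ch <- kids[[as.character(v)]]
      if (length(ch) == 0L) stop("non-disease leaf node in DAG: ", nodes[v])
      D[v] <- max(delta * D[ch])
    }
  }
  D
}

#' Semantic similarity between two diseases from their MeSH DAGs
#'
#' The sum of both diseases' contributions over the shared ancestor headings,
#' normalised by the two total contribution sums:
#' `sum_{t in T_i & T_j} (D_i(t) + D_j(t)) / (sum_t D_i(t) + sum_t D_j(t))`.
#' Symmetric, in `[0, 1]`, and exactly 1 for identical DAGs.
#'
#' @param dag_i,dag_j `disease_dag` objects.
#' @param delta Semantic decay factor; default 0.5.
#' @return A single similarity value.
#' @export
semantic_similarity <- function(dag_i, dag_j, delta = 0.5) {
  Di <- semantic_contributions(dag_i, delta)
  Dj <- semantic_contributions(dag_j, delta)
  shared <- intersect(names(Di), names(Dj))
  (sum(Di[shared]) + sum(Dj[shared])) / (sum(Di) + sum(Dj))
}

#' Pairwise disease semantic-similarity matrix
#'
#' Builds one DAG per disease and evaluates [semantic_similarity()] for every
#' pair of diseases that have DAGs. Diseases absent from the MeSH table get
#' `NA` rows/columns and a `FALSE` entry in the `has_dag` attribute; the
#' integrated similarity fills those from the Gaussian kernel.
#'
#' @param diseases Character vector of disease names (matrix order).
#' @param mesh_table A `mesh_table`.
#' @param delta Semantic decay factor; default 0.5.
#' @return A symmetric matrix with `NA` where either disease lacks a DAG,
#'   and attribute `has_dag` (named logical vector).
#' @export
semantic_similarity_matrix <- function(diseases, mesh_table, delta = 0.5) {
  n <- length(diseases)
  dags <- lapply(diseases, build_disease_dag, mesh_table = mesh_table)
  has_dag <- !vapply(dags, is.null, TRUE)
  contrib <- vector("list", n)
  totals <- rep(NA_real_, n)
  for (i in which(has_dag)) {
    contrib[[i]] <- semantic_contributions(dags[[i]], delta)
    totals[i] <- sum(contrib[[i]])
  }
  S <- matrix(NA_real_, n, n, dimnames = list(diseases, diseases))
  idx <- which(has_dag)
  for (a in seq_along(idx)) {
    i <- idx[a]
    S[i, i] <- 1
    if (a < length(idx)) {
      for (j in idx[(a + 1L):length(idx)]) {
        shared <- intersect(names(contrib[[i]]), names(contrib[[j]]))
        s <- (sum(contrib[[i]][shared]) + sum(contrib[[j]][shared])) /
          (totals[i] + totals[j])
        S[i, j] <- s
        S[j, i] <- s
      }
    }
  }
  names(has_dag) <- diseases
  attr(S, "has_dag") <- has_dag
  S
}

#' Gaussian interaction-profile (GIP) kernel similarity
#'
#' The interaction profile of a miRNA (disease) is its row (column) of the
#' binary association matrix `Y`. The kernel between two entities is
#' `exp(-gamma * ||p_i - p_j||^2)`, with the bandwidth normalised by the mean
#' squared profile norm: `gamma = gamma_prime / mean(||p_i||^2)`.
#'
#' @param Y Binary association matrix (miRNA rows x disease columns).
#' @param axis `"mirna"` (row profiles) or `"disease"` (column profiles).
#' @param gamma_prime Raw bandwidth parameter; default 1.
#' @return Symmetric kernel matrix with unit diagonal, entries in (0, 1].
#' @export
gip_kernel <- function(Y, axis = c("mirna", "disease"), gamma_prime = 1) {
  axis <- match.arg(axis)
  stopifnot(gamma_prime > 0)
  P <- if (axis == "mirna") Y else t(Y)
  sq <- rowSums(P^2)
  msq <- mean(sq)
  if (msq == 0) stop("all-zero association matrix: GIP bandwidth undefined")
  gamma <- gamma_prime / msq
  G <- tcrossprod(P)
  d2 <- outer(sq, sq, "+") - 2 * G
  d2[d2 < 0] <- 0
  K <- exp(-gamma * d2)
  diag(K) <- 1
  nm <- if (axis == "mirna") rownames(Y) else colnames(Y)
  dimnames(K) <- list(nm, nm)
  attr(K, "gamma") <- gamma
  attr(K, "gamma_prime") <- gamma_prime
  K
}

#' Integrate a primary similarity with the GIP kernel fallback
#'
#' Entry (i, j) takes the primary (semantic or functional) similarity when
#' both entities have one defined — a disease has a MeSH DAG, a miRNA appears
#' in the functional-similarity matrix — and the Gaussian kernel value
#' otherwise. The diagonal is forced to 1. The choice per entry is recorded
#' in the `source_mask` attribute (`"primary"` / `"gaussian"`).
#'
#' @param primary Square matrix of primary similarities, `NA` (or missing
#'   rows per `has_primary`) where undefined; `NULL` for none.
#' @param gaussian GIP kernel matrix, same labels and order.
#' @param has_primary Logical vector marking entities with a defined primary
#'   similarity; defaults to the `has_dag` attribute of `primary`, else to
#'   rows of `primary` free of `NA`.
#' @return Symmetric similarity matrix in `[0, 1]` with `source_mask`
#'   attribute.
#' @export
integrate_similarity <- function(primary, gaussian, has_primary = NULL) {
  n <- nrow(gaussian)
  if (is.null(primary)) {
    has_primary <- rep(FALSE, n)
    primary <- matrix(NA_real_, n, n, dimnames = dimnames(gaussian))
  }
  if (!all(dim(primary) == dim(gaussian))) stop("matrix shape mismatch")
  if (!is.null(rownames(primary)) && !is.null(rownames(gaussian)) &&
      !identical(rownames(primary), rownames(gaussian))) {
    stop("similarity matrix labels do not match")
  }
  if (is.null(has_primary)) {
    has_primary <- attr(primary, "has_dag")
    if (is.null(has_primary)) has_primary <- rowSums(is.na(primary)) == 0L
  }
  use_primary <- outer(has_primary, has_primary, "&")
  S <- ifelse(use_primary, primary, gaussian)
  if (anyNA(S)) stop("primary similarity undefined where required")
  diag(S) <- 1
  dimnames(S) <- dimnames(gaussian)
  mask <- matrix(ifelse(use_primary, "primary", "gaussian"), n, n,
                 dimnames = dimnames(gaussian))
  attr(S, "source_mask") <- mask
  S
}
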