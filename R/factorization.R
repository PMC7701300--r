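#' Graph Laplacian of a similarity matrix
#'
#' `L = D - S` with `D` the diagonal of row sums of `S`. For a symmetric
#' nonnegative `S`, `L` is symmetric positive semidefinite and satisfies the
#' quadratic-form identity
#' `x' L x = (1/2) * sum_{ij} S_ij (x_i - x_j)^2`.
#'
#' @param S Symmetric nonnegative similarity matrix.
#' @param tol Symmetry tolerance; default `1e-8`.
#' @return A list of class `graph_laplacian` with elements `L` and `degrees`
#'   (the row sums of `S`).
#' @export
graph_laplacian <- function(S, tol = 1e-8) {
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > tol) stop("similarity matrix must be symmetric")
  d <- rowSums(S)
  L <- diag(d, nrow(S)) - S
  dimnames(L) <- dimnames(S)
  structure(list(L = L, degrees = d), class = "graph_laplacian")
}

#' Regularized factorization objective
#'
#' The fitted criterion: squared Frobenius reconstruction error on the
#' weighted entries, plus Tikhonov penalties on both factors, plus the two
#' graph-smoothness terms
#' `lambda_m * tr(W' L_m W) + lambda_d * tr(H' L_d H)`, where each trace
#' equals half the pairwise sum `sum_{i,p} ||w_i - w_p||^2 S_ip`. This is the
#' weighting under which the multiplicative updates are guaranteed to
#' descend; see the methods vignette.
#'
#' @param Y Binary association matrix.
#' @param W,H Nonnegative factor matrices (`nrow(Y) x k`, `ncol(Y) x k`).
#' @param sim_mirna,sim_disease Integrated similarity matrices for the miRNA
#'   and disease sides.
#' @param lambda_l,lambda_m,lambda_d Nonnegative regularization weights.
#' @param I Optional 0/1 weight matrix over entries of `Y`; default all ones.
#' @return The scalar objective value.
#' @export
mfmda_objective <- function(Y, W, H, sim_mirna, sim_disease,
                            lambda_l = 1, lambda_m = 0.2, lambda_d = 0.2,
                            I = NULL) {
  if (any(W < 0) || any(H < 0)) stop("factor matrices must be nonnegative")
  R <- Y - tcrossprod(W, H)
  if (!is.null(I)) R <- I * R
  obj <- sum(R^2) + lambda_l * (sum(W^2) + sum(H^2))
  if (lambda_m > 0) {
    Lm <- graph_laplacian(sim_mirna)$L
    obj <- obj + lambda_m * sum(W * (Lm %*% W))
  }
  if (lambda_d > 0) {
    Ld <- graph_laplacian(sim_disease)$L
    obj <- obj + lambda_d * sum(H * (Ld %*% H))
  }
  obj
}

#' One multiplicative update step
#'
#' The KKT-derived elementwise updates: `W` first, then `H` using the updated
#' `W` (alternating descent):
#' \deqn{w_{ik} \leftarrow w_{ik}\,\frac{(YH + \lambda_m S_m W)_{ik}}
#'   {(W H^T H + \lambda_l W + \lambda_m D_m W)_{ik} + \epsilon}}
#' and symmetrically for `H` with `Y'`, `S_d`, `D_d`. Nonnegativity is
#' preserved; `eps` guards the denominators against 0/0.
#'
#' @inheritParams mfmda_objective
#' @param degrees_m,degrees_d Row-sum degree vectors of the similarity
#'   matrices (computed if `NULL`).
#' @param eps Denominator guard; default `1e-10`.
#' @return List with updated `W` and `H`.
#' @export
mfmda_update <- function(Y, W, H, sim_mirna, sim_disease,
                         lambda_l = 1, lambda_m = 0.2, lambda_d = 0.2,
                         degrees_m = NULL, degrees_d = NULL, eps = 1e-10) {
  if (is.null(degrees_m) && lambda_m > 0) degrees_m <- rowSums(sim_mirna)
  if (is.null(degrees_d) && lambda_d > 0) degrees_d <- rowSums(sim_disease)
  num_w <- Y %*% H
  if (lambda_m > 0) num_w <- num_w + lambda_m * (sim_mirna %*% W)
  den_w <- W %*% crossprod(H) + lambda_l * W
  if (lambda_m > 0) den_w <- den_w + lambda_m * (degrees_m * W)
  W <- W * num_w / (den_w + eps)
  num_h <- crossprod(Y, W)
  if (lambda_d > 0) num_h <- num_h + lambda_d * (sim_disease %*% H)
  den_h <- H %*% crossprod(W) + lambda_l * H
  if (lambda_d > 0) den_h <- den_h + lambda_d * (degrees_d * H)
  H <- H * num_h / (den_h + eps)
  list(W = W, H = H)
}

#' Fit a graph-regularized nonnegative matrix factorization
#'
#' Factorizes the binary miRNA-disease association matrix `Y` as
#' `Y ~ W H'` with nonnegative factors, penalising factor norms
#' (`lambda_l`) and pulling the latent vectors of similar miRNAs
#' (`lambda_m`, via `sim_mirna`) and similar diseases (`lambda_d`, via
#' `sim_disease`) towards each other. Solved by alternating multiplicative
#' updates from a strictly positive seeded random start, iterated until the
#' relative objective change falls below `tol` or `max_iter` is reached.
#' Predicted association scores are `Y* = W H'` (see [predict.mfmda()]).
#'
#' @param Y Binary association matrix (miRNA rows x disease columns), e.g.
#'   the `Y` element of an [association_dataset()].
#' @param sim_mirna,sim_disease Integrated similarity matrices (symmetric,
#'   unit diagonal, values in `[0, 1]`) for miRNAs and diseases, e.g. from
#'   [integrate_similarity()]. May be `NULL` when the matching lambda is 0.
#' @param k Latent dimension; default 50.
#' @param lambda_l Tikhonov weight on both factors; default 1.
#' @param lambda_m,lambda_d Graph-regularization weights; default 0.2 each.
#' @param max_iter Maximum iterations; default 500.
#' @param tol Relative objective-change convergence tolerance; default
#'   `1e-6`.
#' @param seed Optional integer seed for the random initialization; the fit
#'   is bitwise reproducible given the same seed.
#' @param eps Denominator guard in the updates; default `1e-10`.
#' @return An object of class `mfmda`: list with factors `W`, `H`, the
#'   `objective_trace` (initial value plus one per iteration), `converged`,
#'   `iterations`, and the hyperparameters in `hyper`.
#' @examples
#' syn <- synth_generate(synth_spec(n_m = 40, n_d = 25, k_true = 4, seed = 1))
#' fit <- mfmda(syn$dataset$Y, sim_mirna = syn$fs, lambda_d = 0,
#'              k = 8, seed = 1)
#' fit
#' @export
mfmda <- function(Y, sim_mirna = NULL, sim_disease = NULL,
                  k = 50, lambda_l = 1, lambda_m = 0.2, lambda_d = 0.2,
                  max_iter = 500, tol = 1e-6, seed = NULL, eps = 1e-10) {
  stopifnot(k >= 1, lambda_l >= 0, lambda_m >= 0, lambda_d >= 0,
            max_iter >= 1, tol > 0, eps > 0)
  Y <- as.matrix(Y)
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  n_m <- nrow(Y); n_d <- ncol(Y)
  if (lambda_m > 0) {
    stopifnot(!is.null(sim_mirna), nrow(sim_mirna) == n_m)
  } else sim_mirna <- matrix(0, n_m, n_m)
  if (lambda_d > 0) {
    stopifnot(!is.null(sim_disease), nrow(sim_disease) == n_d)
  } else sim_disease <- matrix(0, n_d, n_d)

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
  }
  scale0 <- sqrt(max(mean(Y), eps) / k)
  W <- matrix(stats::runif(n_m * k, 0.01, 1.01), n_m, k) * scale0
  H <- matrix(stats::runif(n_d * k, 0.01, 1.01), n_d, k) * scale0

  dm <- rowSums(sim_mirna)
  dd <- rowSums(sim_disease)
  obj <- mfmda_objective(Y, W, H, sim_mirna, sim_disease,
                         lambda_l, lambda_m, lambda_d)
  trace <- numeric(max_iter + 1L)
  trace[1L] <- obj
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    step <- mfmda_update(Y, W, H, sim_mirna, sim_disease,
                         lambda_l, lambda_m, lambda_d,
                         degrees_m = dm, degrees_d = dd, eps = eps)
    W <- step$W; H <- step$H
    if (!all(is.finite(W)) || !all(is.finite(H))) {
      stop("non-finite factor entries at iteration ", it)
    }
    obj_new <- mfmda_objective(Y, W, H, sim_mirna, sim_disease,
                               lambda_l, lambda_m, lambda_d)
    iter <- it
    trace[it + 1L] <- obj_new
    if (abs(obj - obj_new) < tol * max(abs(obj), eps)) {
      converged <- TRUE
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  rownames(W) <- rownames(Y)
  rownames(H) <- colnames(Y)
  structure(list(W = W, H = H,
                 objective_trace = trace[seq_len(iter + 1L)],
                 converged = converged, iterations = iter,
                 hyper = list(k = k, lambda_l = lambda_l, lambda_m = lambda_m,
                              lambda_d = lambda_d, max_iter = max_iter,
                              tol = tol, seed = seed, eps = eps),
                 dims = c(n_m = n_m, n_d = n_d),
                 Y = Y),
            class = "mfmda")
}

#' @export
print.mfmda <- function(x, ...) {
  h <- x$hyper
  cat("Graph-regularized NMF association model\n")
  cat(sprintf("  %d miRNAs x %d diseases, latent dimension k = %d\n",
              x$dims["n_m"], x$dims["n_d"], h$k))
  cat(sprintf("  lambda_l = %g, lambda_m = %g, lambda_d = %g\n",
              h$lambda_l, h$lambda_m, h$lambda_d))
  cat(sprintf("  %s after %d iterations, objective %.6g\n",
              if (x$converged) "converged" else "stopped (max_iter)",
              x$iterations, utils::tail(x$objective_trace, 1L)))
  invisible(x)
}

#' @export
summary.mfmda <- function(object, ...) {
  res <- object$Y - tcrossprod(object$W, object$H)
  out <- list(model = object,
              rel_residual = sum(res^2) / max(sum(object$Y^2), 1),
              frob_W = sqrt(sum(object$W^2)),
              frob_H = sqrt(sum(object$H^2)))
  class(out) <- "summary.mfmda"
  out
}

#' @export
print.summary.mfmda <- function(x, ...) {
  print(x$model)
  cat(sprintf("  relative reconstruction error ||Y - WH'||^2 / ||Y||^2 = %.4f\n",
              x$rel_residual))
  cat(sprintf("  ||W||_F = %.4f, ||H||_F = %.4f\n", x$frob_W, x$frob_H))
  invisible(x)
}

#' Extract the factor matrices
#' @param object A fitted `mfmda` model.
#' @param ... Unused.
#' @return List with components `W` and `H`.
#' @export
coef.mfmda <- function(object, ...) list(W = object$W, H = object$H)

#' Predicted association score matrix
#'
#' `Y* = W H'`; higher scores mark pairs more likely to be associated.
#'
#' @param object A fitted `mfmda` model.
#' @param ... Unused.
#' @return Nonnegative score matrix, same shape and dimnames as `Y`.
#' @export
predict.mfmda <- function(object, ...) tcrossprod(object$W, object$H)

#' @export
fitted.mfmda <- function(object, ...) predict(object)

#' @export
residuals.mfmda <- function(object, ...) object$Y - predict(object)

#' Plot the objective trace of a fit
#' @param x A fitted `mfmda` model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mfmda <- function(x, ...) {
  graphics::plot(seq_along(x$objective_trace) - 1L, x$objective_trace,
                 type = "l", xlab = "iteration", ylab = "objective",
                 main = "Multiplicative-update objective trace", ...)
  invisible(x)
}
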