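#' Configuration for topographic sparse coding
#'
#' Bundles the objective and optimizer settings used by [encode()] and
#' [tsc_learn()]. The objective over a dictionary `A` (d x k, unit-norm
#' columns) and codes `s` (k x N) for samples `x` (d x N) is
#'
#'   J(A, s) = ||A s - x||_F^2
#'             + lambda * sum_{g,n} sqrt( (V (s*s))_{g,n} + epsilon )
#'             + gamma * ||A||_F^2,     subject to ||s_col||_2^2 <= C
#'
#' where `V` is the binary grouping matrix of [build_grouping_matrix()] and
#' `s*s` is the elementwise square. `epsilon > 0` smooths the grouped L1
#' term so plain gradient methods apply everywhere (at `epsilon = 0` the
#' penalty is the non-differentiable group-L2 norm, and equals the entrywise
#' L1 norm when groups are singletons). The squared-norm bound `C` is
#' enforced per code column by projection.
#'
#' @param lambda Sparsity weight (default 0.1).
#' @param gamma Dictionary weight-decay coefficient (default 0.1).
#' @param epsilon Smoothing constant of the grouped penalty (default 1e-2;
#'   must be > 0 for gradient-based encoding).
#' @param C Per-column squared-norm bound on the codes (default 1).
#' @param grid_rows,grid_cols Atom-grid dimensions; `k = grid_rows *
#'   grid_cols` atoms.
#' @param group_size Topographic neighbourhood side (default 3).
#' @param wraparound Toroidal grid (default `TRUE`).
#' @param batch_size Mini-batch size for [tsc_learn()] (default 256; capped
#'   at `N`).
#' @param max_outer_iters,max_inner_iters Iteration caps for the outer
#'   alternation and the inner code descent.
#' @param tol_rel Relative objective-change stopping tolerance.
#' @param step_init Initial step size of the backtracking line searches.
#' @param seed Integer seed controlling dictionary initialization and
#'   mini-batch sampling.
#' @return A list of class `tsc_config`.
#' @export
tsc_config <- function(lambda = 0.1, gamma = 0.1, epsilon = 1e-2, C = 1,
                       grid_rows = 11, grid_cols = 11, group_size = 3,
                       wraparound = TRUE, batch_size = 256,
                       max_outer_iters = 50, max_inner_iters = 100,
                       tol_rel = 1e-6, step_init = 1.0, seed = 1L) {
  cfg <- list(
    lambda = stopifnot_positive(lambda, "lambda", strict = FALSE),
    gamma = stopifnot_positive(gamma, "gamma", strict = FALSE),
    epsilon = stopifnot_positive(epsilon, "epsilon", strict = FALSE),
    C = stopifnot_positive(C, "C"),
    grid_rows = stopifnot_scalar_count(grid_rows, "grid_rows"),
    grid_cols = stopifnot_scalar_count(grid_cols, "grid_cols"),
    group_size = stopifnot_scalar_count(group_size, "group_size"),
    wraparound = isTRUE(wraparound),
    batch_size = stopifnot_scalar_count(batch_size, "batch_size"),
    max_outer_iters = stopifnot_scalar_count(max_outer_iters, "max_outer_iters"),
    max_inner_iters = stopifnot_scalar_count(max_inner_iters, "max_inner_iters"),
    tol_rel = stopifnot_positive(tol_rel, "tol_rel"),
    step_init = stopifnot_positive(step_init, "step_init"),
    seed = as.integer(seed)
  )
  cfg$k <- cfg$grid_rows * cfg$grid_cols
  structure(cfg, class = "tsc_config")
}

check_conformable <- function(A, s, x, V = NULL) {
  if (!is.matrix(A) || !is.matrix(s) || !is.matrix(x)) {
    abort("A, s and x must be matrices")
  }
  if (ncol(A) != nrow(s)) abort("ncol(A) must equal nrow(s)")
  if (nrow(A) != nrow(x)) abort("nrow(A) must equal nrow(x)")
  if (ncol(s) != ncol(x)) abort("ncol(s) must equal ncol(x)")
  if (!is.null(V) && ncol(V) != nrow(s)) {
    abort("grouping matrix column count must equal the number of code rows")
  }
  invisible(TRUE)
}

#' Smoothed grouped-L1 sparsity penalty
#'
#' Computes `sum_{g,n} sqrt( sum_{j in group g} s[j,n]^2 + epsilon )`: the
#' group-L2 magnitudes of each code column, smoothed by `epsilon` and summed
#' over all groups and samples. With singleton groups (`V` the identity) and
#' `epsilon = 0` this is exactly the entrywise L1 norm of `s`.
#'
#' @param codes k x N code matrix.
#' @param V Binary grouping matrix (groups x k), see
#'   [build_grouping_matrix()].
#' @param epsilon Non-negative smoothing constant.
#' @return The scalar penalty value.
#' @export
smoothed_group_penalty <- function(codes, V, epsilon) {
  if (!is.matrix(codes)) codes <- as.matrix(codes)
  if (ncol(V) != nrow(codes)) {
    abort("grouping matrix column count must equal the number of code rows")
  }
  epsilon <- stopifnot_positive(epsilon, "epsilon", strict = FALSE)
  energy <- unclass(V) %*% (codes^2)   # groups x N group energies
  sum(sqrt(energy + epsilon))
}

#' Topographic sparse-coding objective
#'
#' Evaluates `J(A, s)` (see [tsc_config()]) and its additive decomposition.
#'
#' @param A d x k dictionary.
#' @param s k x N codes.
#' @param x d x N samples.
#' @param V Grouping matrix.
#' @param cfg A [tsc_config()].
#' @return A list with `J`, the decomposition `terms` (named numeric:
#'   `reconstruction` = squared Frobenius residual, `penalty` = lambda-scaled
#'   smoothed group penalty, `decay` = gamma-scaled squared dictionary norm;
#'   the three sum to `J`), the `residual` matrix `x - A s` and its `sse`.
#' @export
tsc_objective <- function(A, s, x, V, cfg) {
  check_conformable(A, s, x, V)
  resid <- x - A %*% s
  sse <- sum(resid^2)
  pen <- cfg$lambda * smoothed_group_penalty(s, V, cfg$epsilon)
  dec <- cfg$gamma * sum(A^2)
  list(J = sse + pen + dec,
       terms = c(reconstruction = sse, penalty = pen, decay = dec),
       residual = resid, sse = sse)
}

#' Gradient of the objective with respect to the codes
#'
#' Analytic gradient `dJ/ds = 2 A^T (A s - x) + lambda * (V^T w) * s`, where
#' `w[g,n] = 1 / sqrt( (V (s*s))_{g,n} + epsilon )` are reciprocal smoothed
#' group magnitudes; each coefficient is weighted by the sum over the groups
#' it belongs to. Requires `epsilon > 0` (the unsmoothed penalty is not
#' differentiable at zero).
#'
#' @inheritParams tsc_objective
#' @return The k x N gradient matrix.
#' @export
grad_codes <- function(A, s, x, V, cfg) {
  check_conformable(A, s, x, V)
  if (cfg$epsilon <= 0) {
    abort("grad_codes requires epsilon > 0: the unsmoothed penalty is not differentiable at zero")
  }
  Vm <- unclass(V)
  w <- 1 / sqrt(Vm %*% (s^2) + cfg$epsilon)          # groups x N
  2 * crossprod(A, A %*% s - x) + cfg$lambda * (crossprod(Vm, w) * s)
}

#' Gradient of the objective with respect to the dictionary
#'
#' `dJ/dA = 2 (A s - x) s^T + 2 gamma A`. The grouped penalty does not
#' involve `A`, so only the reconstruction and weight-decay terms contribute.
#'
#' @inheritParams tsc_objective
#' @return The d x k gradient matrix.
#' @export
grad_dictionary <- function(A, s, x, cfg) {
  check_conformable(A, s, x)
  2 * tcrossprod(A %*% s - x, s) + 2 * cfg$gamma * A
}
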