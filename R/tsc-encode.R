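#' Initialize codes from the dictionary
#'
#' The analytic warm start used before gradient descent on the codes:
#' `s = A^T x`, with row `r` divided by the norm of the r-th dictionary
#' atom. For a unit-norm dictionary this is just the correlation of every
#' atom with every sample.
#'
#' @param A d x k dictionary; columns must have nonzero norm.
#' @param x d x N sample matrix.
#' @return The k x N initial code matrix.
#' @export
init_codes <- function(A, x) {
  if (nrow(A) != nrow(x)) abort("nrow(A) must equal nrow(x)")
  nrm <- col_norms(A)
  if (any(nrm == 0)) abort("dictionary has a zero-norm atom")
  sweep(crossprod(A, x), 1, nrm, "/")
}

# Project each code column onto the ball { v : ||v||^2 <= C }.
project_codes <- function(s, C) {
  nsq <- colSums(s^2)
  over <- nsq > C
  if (any(over)) {
    s[, over] <- sweep(s[, over, drop = FALSE], 2, sqrt(nsq[over] / C), "/")
  }
  s
}

#' Encode samples against a fixed dictionary
#'
#' Minimizes the objective of [tsc_config()] over the codes `s` with the
#' dictionary held fixed: projected gradient descent with a backtracking
#' (halving) line search under an Armijo sufficient-decrease condition,
#' starting from [init_codes()]. After every accepted step each code column is projected
#' onto the `C`-ball, so the returned codes always satisfy the constraint.
#' With the dictionary fixed the problem is convex, so the final objective
#' does not depend on the starting point.
#'
#' @param A d x k dictionary (held fixed).
#' @param x d x N samples.
#' @param V Grouping matrix; defaults to the grid implied by `cfg`.
#' @param cfg A [tsc_config()]; `epsilon` must be > 0.
#' @param warm_start Optional k x N starting codes; used instead of
#'   [init_codes()] when supplied (both are projected onto the `C`-ball
#'   first).
#' @param max_iters Override of `cfg$max_inner_iters`.
#' @return A list with `codes` (k x N) and `trace`, a tibble with one row
#'   per accepted iteration (`iter`, `J`, `reconstruction`, `penalty`,
#'   `decay`, `step`); the three term columns sum to `J` and the `J` column
#'   is non-increasing.
#' @export
encode <- function(A, x, V = NULL, cfg = tsc_config(), warm_start = NULL,
                   max_iters = NULL) {
  if (cfg$epsilon <= 0) {
    abort("encode requires epsilon > 0 (smoothed penalty)")
  }
  if (is.null(V)) {
    V <- build_grouping_matrix(cfg$grid_rows, cfg$grid_cols,
                               cfg$group_size, cfg$wraparound)
  }
  if (ncol(V) != ncol(A)) abort("grouping matrix does not match dictionary size")
  max_iters <- max_iters %||% cfg$max_inner_iters

  s <- if (is.null(warm_start)) init_codes(A, x) else warm_start
  s <- project_codes(s, cfg$C)
  ob <- tsc_objective(A, s, x, V, cfg)

  rows <- vector("list", max_iters + 1L)
  rows[[1]] <- c(iter = 0, J = ob$J, ob$terms, step = NA_real_)
  n_rec <- 1L
  for (it in seq_len(max_iters)) {
    g <- grad_codes(A, s, x, V, cfg)
    step <- cfg$step_init
    accepted <- FALSE
    while (step > 1e-14) {
      s_new <- project_codes(s - step * g, cfg$C)
      ob_new <- tsc_objective(A, s_new, x, V, cfg)
      if (!is.finite(ob_new$J)) {
        abort(sprintf("encode diverged (non-finite objective at iteration %d)", it))
      }
      # Armijo condition generalized to the projected step
      decrease_needed <- 1e-4 * sum(g * (s - s_new))
      if (ob_new$J <= ob$J - max(decrease_needed, 0)) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel_change <- (ob$J - ob_new$J) / max(1, abs(ob$J))
    s <- s_new
    ob <- ob_new
    n_rec <- n_rec + 1L
    rows[[n_rec]] <- c(iter = it, J = ob$J, ob$terms, step = step)
    if (rel_change < cfg$tol_rel) break
  }
  trace <- dplyr::bind_rows(lapply(rows[seq_len(n_rec)], function(r) {
    tibble::tibble(iter = r[["iter"]], J = r[["J"]],
                   reconstruction = r[["reconstruction"]],
                   penalty = r[["penalty"]], decay = r[["decay"]],
                   step = r[["step"]])
  }))
  list(codes = s, trace = trace)
}
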