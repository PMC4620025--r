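#' Learn a topographic dictionary by alternating mini-batch descent
#'
#' Alternates, until the full-data objective stalls or `max_outer_iters` is
#' reached:
#' 1. draw a mini-batch of sample columns with the seeded RNG;
#' 2. encode the batch with the dictionary fixed ([encode()], starting from
#'    the better of the `A^T x` initialization and the warm codes kept from
#'    the previous pass over those columns);
#' 3. take a gradient step on the dictionary with the batch codes'
#'    background fixed: a candidate `normalize(A - t * dJ/dA)` is accepted
#'    only if the re-encoded batch objective decreases, backtracking on `t`
#'    otherwise;
#' 4. dictionary columns are therefore unit-norm after every update.
#'
#' Accepting a dictionary step on the *re-encoded* batch objective (rather
#' than on the stale codes) makes the monitored objective non-increasing by
#' construction, which in full-batch mode (`batch_size = N`) gives a
#' monotone alternating-descent trace.
#'
#' @param x d x N sample matrix (columns are samples).
#' @param cfg A [tsc_config()]; `k = grid_rows * grid_cols` atoms are
#'   learned and `batch_size` is capped at `N`.
#' @return An object of class `tsc_fit`: a list with `dictionary` (d x k,
#'   unit-norm columns), `codes` (k x N, encoded against the final
#'   dictionary), `trace` (a tibble with one row per outer iteration:
#'   `outer`, `J_full`, `reconstruction`, `penalty`, `decay`, `J_batch`,
#'   `step`, `batch` as a list-column of column indices), the grouping
#'   matrix `V` and `config`.
#' @seealso [encode()], [generate_tsc_instance()], [match_atoms()]
#' @export
tsc_learn <- function(x, cfg = tsc_config()) {
  if (!is.matrix(x)) x <- as.matrix(x)
  N <- ncol(x)
  d <- nrow(x)
  k <- cfg$k
  if (cfg$batch_size > N) abort("batch_size exceeds the number of samples")
  V <- build_grouping_matrix(cfg$grid_rows, cfg$grid_cols,
                             cfg$group_size, cfg$wraparound)

  with_seed(cfg$seed, {
    A <- normalize_columns(matrix(rnorm(d * k), d, k))
    s_full <- project_codes(init_codes(A, x), cfg$C)

    encode_best <- function(A, xb, warm) {
      fresh <- encode(A, xb, V, cfg)
      if (is.null(warm)) return(fresh)
      warmed <- encode(A, xb, V, cfg, warm_start = warm)
      if (warmed$trace$J[nrow(warmed$trace)] < fresh$trace$J[nrow(fresh$trace)]) {
        warmed
      } else {
        fresh
      }
    }

    J_full_prev <- tsc_objective(A, s_full, x, V, cfg)$J
    rows <- vector("list", cfg$max_outer_iters)
    n_rec <- 0L
    full_batch <- cfg$batch_size == N
    n_stalled <- 0L
    for (outer in seq_len(cfg$max_outer_iters)) {
      idx <- sort(sample.int(N, cfg$batch_size))
      xb <- x[, idx, drop = FALSE]

      enc <- encode_best(A, xb, s_full[, idx, drop = FALSE])
      sb <- enc$codes
      f_curr <- tsc_objective(A, sb, xb, V, cfg)$J

      g <- grad_dictionary(A, sb, xb, cfg)
      step <- cfg$step_init
      moved <- FALSE
      while (step > 1e-12) {
        A_cand <- A - step * g
        nrm <- col_norms(A_cand)
        if (any(nrm == 0)) {
          step <- step / 2
          next
        }
        A_cand <- sweep(A_cand, 2, nrm, "/")
        # warm codes rescaled so A_cand %*% warm reproduces A_cand-scale fits
        warm <- sweep(sb, 1, nrm, "*")
        enc_cand <- encode(A_cand, xb, V, cfg, warm_start = warm,
                           max_iters = min(cfg$max_inner_iters, 50L))
        f_cand <- enc_cand$trace$J[nrow(enc_cand$trace)]
        if (is.finite(f_cand) && f_cand < f_curr) {
          A <- A_cand
          sb <- enc_cand$codes
          f_curr <- f_cand
          moved <- TRUE
          break
        }
        step <- step / 2
      }

      s_full[, idx] <- sb
      # refresh codes of all columns against the updated dictionary
      s_full <- encode_best(A, x, s_full)$codes
      ob_full <- tsc_objective(A, s_full, x, V, cfg)
      n_rec <- n_rec + 1L
      rows[[n_rec]] <- tibble::tibble(
        outer = outer, J_full = ob_full$J,
        reconstruction = ob_full$terms[["reconstruction"]],
        penalty = ob_full$terms[["penalty"]],
        decay = ob_full$terms[["decay"]],
        J_batch = f_curr, step = if (moved) step else NA_real_,
        batch = list(idx))
      rel <- (J_full_prev - ob_full$J) / max(1, abs(J_full_prev))
      J_full_prev <- ob_full$J
      n_stalled <- if (moved && !(rel >= 0 && rel < cfg$tol_rel)) 0L else n_stalled + 1L
      if (full_batch && n_stalled > 0L) break
      if (n_stalled >= 5L) break
    }

    structure(list(dictionary = A, codes = s_full,
                   trace = dplyr::bind_rows(rows[seq_len(n_rec)]),
                   V = V, config = cfg),
              class = "tsc_fit")
  })
}

#' @export
print.tsc_fit <- function(x, ...) {
  cat(sprintf("Topographic sparse coding fit: %d x %d dictionary (%dx%d atom grid), %d samples\n",
              nrow(x$dictionary), ncol(x$dictionary),
              x$config$grid_rows, x$config$grid_cols, ncol(x$codes)))
  last <- x$trace[nrow(x$trace), ]
  cat(sprintf("  %d outer iterations, final objective %.6g (reconstruction %.4g, penalty %.4g, decay %.4g)\n",
              nrow(x$trace), last$J_full, last$reconstruction, last$penalty, last$decay))
  invisible(x)
}

#' Match learned atoms to reference atoms
#'
#' Greedy sign- and permutation-invariant matching: the absolute cosine
#' similarity between every learned and reference atom is computed, and
#' pairs are matched greedily by decreasing similarity, each atom used at
#' most once. Used to score dictionary recovery on synthetic instances where
#' the generating dictionary is known.
#'
#' @param learned,reference d x k matrices of atoms (columns).
#' @return A tibble with `learned`, `reference` (column indices) and
#'   `abs_cosine`, one row per matched pair, plus a `mean_abs_cosine`
#'   attribute.
#' @export
match_atoms <- function(learned, reference) {
  if (nrow(learned) != nrow(reference)) abort("atom dimensions differ")
  L <- normalize_columns(learned)
  R <- normalize_columns(reference)
  sim <- abs(crossprod(L, R))
  n <- min(ncol(L), ncol(R))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    best <- arrayInd(which.max(sim), dim(sim))
    out[[i]] <- tibble::tibble(learned = best[1], reference = best[2],
                               abs_cosine = sim[best])
    sim[best[1], ] <- -Inf
    sim[, best[2]] <- -Inf
  }
  res <- dplyr::bind_rows(out)
  attr(res, "mean_abs_cosine") <- mean(res$abs_cosine)
  res
}
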