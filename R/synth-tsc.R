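#' Configuration for synthetic sparse-coding instances
#'
#' Describes a ground-truth generative model `x = A s + r`: a random
#' unit-norm dictionary `A` (d x k), sparse codes `s` (k x N) with a fixed
#' number of active atoms per sample, and Gaussian noise `r`. When
#' `topographic = TRUE` the atoms are viewed on a (near-)square grid and the
#' active atoms of each sample are drawn from one 3 x 3 toroidal grid
#' neighbourhood, mimicking the topographic structure the learner is meant
#' to exploit; otherwise active atoms are drawn independently.
#'
#' `code_scale` sets the standard deviation of the nonzero code values; the
#' default 0.5 keeps typical column energies (`atoms_active_per_sample *
#' code_scale^2`) inside the unit code-norm bound used downstream, so the
#' constraint does not distort recovery experiments.
#'
#' @param d Feature dimension.
#' @param k Number of dictionary atoms.
#' @param N Number of samples.
#' @param atoms_active_per_sample Nonzeros per code column (default 3).
#' @param code_scale Standard deviation of nonzero code values (default 0.5).
#' @param noise_sd Standard deviation of the additive residual (default 0.01).
#' @param topographic Draw active atoms as grid neighbourhoods (default `TRUE`).
#' @param seed Integer seed.
#' @return A list of class `synth_tsc_config`.
#' @export
synth_tsc_config <- function(d = 16, k = 16, N = 1000,
                             atoms_active_per_sample = 3, code_scale = 0.5,
                             noise_sd = 0.01, topographic = TRUE, seed = 1L) {
  cfg <- list(
    d = stopifnot_scalar_count(d, "d"),
    k = stopifnot_scalar_count(k, "k"),
    N = stopifnot_scalar_count(N, "N"),
    atoms_active_per_sample = stopifnot_scalar_count(atoms_active_per_sample,
                                                     "atoms_active_per_sample"),
    code_scale = stopifnot_positive(code_scale, "code_scale"),
    noise_sd = stopifnot_positive(noise_sd, "noise_sd", strict = FALSE),
    topographic = isTRUE(topographic),
    seed = as.integer(seed)
  )
  if (cfg$atoms_active_per_sample > cfg$k) {
    abort("atoms_active_per_sample must not exceed k")
  }
  structure(cfg, class = "synth_tsc_config")
}

# Choose a near-square grid for k atoms (exact square when k is a square).
atom_grid_dims <- function(k) {
  r <- floor(sqrt(k))
  while (k %% r != 0) r <- r - 1
  c(rows = r, cols = k / r)
}

#' Generate a synthetic sparse-coding instance with known ground truth
#'
#' Draws `A` with unit-norm standard-normal columns, codes with exactly
#' `atoms_active_per_sample` nonzeros per column (values `N(0,
#' code_scale^2)`, magnitudes bounded away from zero at `0.2 * code_scale`
#' so "active" is unambiguous), and returns `x = A s + r` with
#' `r ~ N(0, noise_sd^2)`. Deterministic given the config seed.
#'
#' @param config A [synth_tsc_config()].
#' @return A list with `dictionary` (d x k), `codes` (k x N), `samples`
#'   (d x N), the generating `config` and, when `topographic = TRUE`, the
#'   grid dimensions used (`grid`).
#' @export
generate_tsc_instance <- function(config = synth_tsc_config()) {
  cfg <- config
  with_seed(cfg$seed, {
    A <- normalize_columns(matrix(rnorm(cfg$d * cfg$k), cfg$d, cfg$k))
    s <- matrix(0, cfg$k, cfg$N)
    grid <- atom_grid_dims(cfg$k)
    for (n in seq_len(cfg$N)) {
      active <- if (cfg$topographic) {
        # one 3x3 toroidal neighbourhood around a random grid centre
        ctr <- c(sample.int(grid[1], 1), sample.int(grid[2], 1))
        rr <- (ctr[1] + (-1:1) - 1) %% grid[1] + 1
        cc <- (ctr[2] + (-1:1) - 1) %% grid[2] + 1
        hood <- unique(as.vector(outer(rr, cc, function(r, c) (r - 1) * grid[2] + c)))
        if (length(hood) < cfg$atoms_active_per_sample) {
          abort("atoms_active_per_sample exceeds the atoms available in a 3x3 grid neighbourhood")
        }
        sample(hood, cfg$atoms_active_per_sample)
      } else {
        sample.int(cfg$k, cfg$atoms_active_per_sample)
      }
      vals <- rnorm(length(active), sd = cfg$code_scale)
      vals <- sign(vals) * pmax(abs(vals), 0.2 * cfg$code_scale)
      s[active, n] <- vals
    }
    x <- A %*% s
    if (cfg$noise_sd > 0) {
      x <- x + matrix(rnorm(length(x), sd = cfg$noise_sd), nrow(x), ncol(x))
    }
    list(dictionary = A, codes = s, samples = x, config = cfg,
         grid = if (cfg$topographic) grid else NULL)
  })
}
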