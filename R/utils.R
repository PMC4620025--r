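#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif predict median
#' @importFrom utils modifyList
NULL

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stopifnot_scalar_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

stopifnot_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && (if (strict) x > 0 else x >= 0)
  if (!ok) abort(sprintf("`%s` must be a single %s number", name,
                         if (strict) "positive" else "non-negative"))
  as.numeric(x)
}

col_norms <- function(m) sqrt(colSums(m^2))

normalize_columns <- function(m) {
  nrm <- col_norms(m)
  if (any(nrm == 0)) abort("cannot normalize a zero-norm column")
  sweep(m, 2, nrm, "/")
}
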