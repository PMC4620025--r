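#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a topographic sparse-coding fit
#'
#' One row per dictionary atom with its grid position and summary
#' statistics of its codes across samples.
#'
#' @param x A `tsc_fit` from [tsc_learn()].
#' @param ... Unused.
#' @return A tibble with `atom`, `grid_row`, `grid_col`, `atom_norm`,
#'   `mean_abs_code`, `activation_rate` (share of samples where the atom's
#'   coefficient magnitude exceeds 1% of the largest).
#' @method tidy tsc_fit
#' @export
tidy.tsc_fit <- function(x, ...) {
  k <- ncol(x$dictionary)
  gc <- x$config$grid_cols
  thr <- 0.01 * max(abs(x$codes))
  tibble::tibble(
    atom = seq_len(k),
    grid_row = (seq_len(k) - 1) %/% gc + 1,
    grid_col = (seq_len(k) - 1) %% gc + 1,
    atom_norm = col_norms(x$dictionary),
    mean_abs_code = rowMeans(abs(x$codes)),
    activation_rate = rowMeans(abs(x$codes) > thr))
}

#' One-row summary of a sparse-coding fit
#' @param x A `tsc_fit`.
#' @param ... Unused.
#' @return A tibble with the final objective decomposition, iteration
#'   count, and code sparsity (share of near-zero coefficients).
#' @method glance tsc_fit
#' @export
glance.tsc_fit <- function(x, ...) {
  last <- x$trace[nrow(x$trace), ]
  thr <- 0.01 * max(abs(x$codes))
  tibble::tibble(
    n_atoms = ncol(x$dictionary), n_samples = ncol(x$codes),
    outer_iters = nrow(x$trace), objective = last$J_full,
    reconstruction = last$reconstruction, penalty = last$penalty,
    decay = last$decay, sparsity = mean(abs(x$codes) <= thr))
}

#' Objective-trace plot of a sparse-coding fit
#' @param object A `tsc_fit`.
#' @param ... Unused.
#' @return A ggplot of the full-data objective and its terms per outer
#'   iteration.
#' @method autoplot tsc_fit
#' @export
autoplot.tsc_fit <- function(object, ...) {
  tr <- dplyr::select(object$trace, "outer", "J_full", "reconstruction",
                      "penalty", "decay")
  long <- tidyr::pivot_longer(tr, -"outer", names_to = "term",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$outer, y = .data$value,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "outer iteration", y = "objective value",
                  title = "Topographic sparse coding: objective trace") +
    ggplot2::theme_minimal()
}

#' Per-class metric bar chart
#' @param object A `topo_metrics` table from [metrics_report()].
#' @param ... Unused.
#' @return A ggplot faceted by metric.
#' @method autoplot topo_metrics
#' @export
autoplot.topo_metrics <- function(object, ...) {
  per <- dplyr::filter(object, !.data$class %in% c("macro", "overall"))
  long <- tidyr::pivot_longer(
    dplyr::select(per, "class", "sensitivity", "specificity", "precision",
                  "f1", "accuracy"),
    -"class", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, title = "Per-phase evaluation metrics") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Glance at a pipeline run
#' @param x A `topo_run` from [run_pipeline()].
#' @param ... Unused.
#' @return A one-row tibble with arm, sample counts, multi-class accuracy
#'   and error rate.
#' @method glance topo_run
#' @export
glance.topo_run <- function(x, ...) {
  acc <- x$metrics$accuracy[x$metrics$class == "overall"]
  tibble::tibble(arm = x$arm,
                 n_test = nrow(x$predictions),
                 accuracy = acc, error_rate = 1 - acc)
}
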