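# Plots of the accuracy summaries (requires ggplot2, in Suggests).

#' Cumulative relative-frequency histogram of errors
#'
#' The standard accuracy display for benchmark runs: the fraction of triangles
#' with error below a threshold, drawn over the error range; a curve hugging the
#' top-left corner means an accurate estimator. Accepts a named list of error
#' vectors to compare algorithms or parameter settings.
#'
#' @param errors numeric vector or named list of numeric vectors; `NA` values
#'   count as `max_error`.
#' @param max_error clip value (x-axis range).
#' @param n_bins number of bins.
#' @return a ggplot object.
#' @export
plot_error_histogram <- function(errors, max_error = 1, n_bins = 20) {
  rlang::check_installed("ggplot2")
  if (!is.list(errors)) errors <- list(errors = errors)
  if (is.null(names(errors))) names(errors) <- paste0("set", seq_along(errors))
  edges <- seq(0, max_error, length.out = n_bins + 1)
  dfs <- lapply(names(errors), function(nm) {
    e <- errors[[nm]]
    e[is.na(e)] <- max_error
    e <- pmax(0, pmin(e, max_error))
    data.frame(set = nm, error = edges,
               cumulative = vapply(edges, function(x) mean(e <= x), numeric(1)))
  })
  df <- do.call(rbind, dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error, y = .data$cumulative,
                                   color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "error", y = "cumulative relative frequency",
                  color = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Plot a benchmark accuracy table
#'
#' Pooled-curvature AUC (percent) against `radius_hit`, one line per algorithm,
#' from the output of [run_benchmark_table()].
#'
#' @param table tibble returned by [run_benchmark_table()].
#' @return a ggplot object.
#' @export
plot_benchmark_table <- function(table) {
  rlang::check_installed("ggplot2")
  ggplot2::ggplot(table, ggplot2::aes(x = .data$rh, y = .data$auc_both,
                                      color = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius_hit (voxels)",
                  y = "AUC of pooled curvature errors (%)", color = NULL) +
    ggplot2::theme_minimal()
}
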