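# Accuracy evaluation: orientation-invariant vector errors, relative curvature
# errors, cumulative-histogram summaries (normalized area under the cumulative
# relative-frequency curve; higher = more accurate) and the benchmark table
# protocol (per algorithm and radius_hit).

#' Vector error between a true and an estimated direction
#'
#' `1 - |v_t . v_e|` for unit vectors: 0 when parallel or antiparallel
#' (orientation-sign invariant), 1 when perpendicular.
#'
#' @param v_t,v_e unit vectors, either length-3 vectors or n x 3 matrices.
#' @return error(s) in `[0, 1]`.
#' @export
vector_error <- function(v_t, v_e) {
  if (is.null(dim(v_t))) v_t <- matrix(v_t, 1)
  if (is.null(dim(v_e))) v_e <- matrix(v_e, 1)
  e <- 1 - abs(rowSums(v_t * v_e))
  pmax(0, pmin(1, e))
}

#' Relative error of an estimated curvature
#'
#' `|kappa_t - kappa_e| / |kappa_t|`; undefined for zero true curvature (use an
#' absolute error there, e.g. for the plane or the cylinder's `kappa_2`).
#'
#' @param kappa_t true curvature(s), non-zero.
#' @param kappa_e estimated curvature(s).
#' @return non-negative error(s).
#' @export
scalar_relative_error <- function(kappa_t, kappa_e) {
  if (any(kappa_t == 0)) stop("relative error undefined for zero true curvature")
  abs(kappa_t - kappa_e) / abs(kappa_t)
}

#' Normalized area under the cumulative error histogram
#'
#' Errors are clipped to `[0, max_error]`; the cumulative relative frequency is
#' evaluated at the `n_bins + 1` equal-width bin edges and integrated by the
#' trapezoid rule, normalized to `[0, 1]`. An all-zero error set gives 1; errors
#' all at or beyond `max_error` give at most `1 / (2 n_bins)`; `NA` errors
#' (failed triangles) count as `max_error` so that failures penalize the score.
#'
#' @param errors numeric vector (non-empty); `NA` treated as `max_error`.
#' @param max_error clip value (1 for vector and relative errors).
#' @param n_bins number of histogram bins.
#' @return a fraction in `[0, 1]`.
#' @export
cumulative_auc <- function(errors, max_error = 1, n_bins = 20) {
  if (length(errors) == 0L) stop("empty error vector")
  errors[is.na(errors)] <- max_error
  errors <- pmax(0, pmin(errors, max_error))
  edges <- seq(0, max_error, length.out = n_bins + 1)
  cdf <- vapply(edges, function(e) mean(errors <= e), numeric(1))
  # trapezoid over the cumulative curve, normalized by the x-range
  sum((cdf[-1] + cdf[-length(cdf)]) / 2) / n_bins
}

# per-triangle curvature errors against a benchmark truth: relative where the
# truth is non-zero, absolute otherwise; NA estimates stay NA (handled by AUC)
curvature_errors <- function(kappa_t, kappa_e) {
  ifelse(kappa_t == 0, abs(kappa_e), abs(kappa_t - kappa_e) / abs(kappa_t))
}

#' Evaluate estimated curvatures against benchmark truth
#'
#' Computes per-triangle errors of both principal curvatures (relative where the
#' truth is non-zero, absolute otherwise) and, where truth directions exist,
#' vector errors of the principal directions and normals.
#'
#' @param mesh a `triangle_mesh` carrying estimation results.
#' @param truth truth tibble of a `benchmark_surface` (same triangle order).
#' @param keep optional logical/integer subset of triangles to evaluate (e.g.
#'   after border exclusion).
#' @return a tibble with columns `err_kappa_1`, `err_kappa_2` and, when
#'   available, `err_normal`, `err_t_1`, `err_t_2`, plus `failed`.
#' @export
evaluate_against_truth <- function(mesh, truth, keep = NULL) {
  dat <- mesh$data
  stopifnot(nrow(dat) == nrow(truth))
  if (!is.null(keep)) {
    dat <- dat[keep, , drop = FALSE]
    truth <- truth[keep, , drop = FALSE]
  }
  out <- tibble::tibble(
    err_kappa_1 = curvature_errors(truth$kappa_1, dat$kappa_1),
    err_kappa_2 = curvature_errors(truth$kappa_2, dat$kappa_2),
    failed = if ("cv_failed" %in% names(dat)) dat$cv_failed else FALSE
  )
  if (all(c("n_v_x", "n_x") %in% c(names(dat), names(truth)))) {
    out$err_normal <- vector_error(cbind(truth$n_x, truth$n_y, truth$n_z),
                                   cbind(dat$n_v_x, dat$n_v_y, dat$n_v_z))
  }
  if (all(c("t_1_x", "t_2_x") %in% names(truth)) &&
        all(c("t_1_x", "t_2_x") %in% names(dat))) {
    out$err_t_1 <- vector_error(cbind(truth$t_1_x, truth$t_1_y, truth$t_1_z),
                                cbind(dat$t_1_x, dat$t_1_y, dat$t_1_z))
    out$err_t_2 <- vector_error(cbind(truth$t_2_x, truth$t_2_y, truth$t_2_z),
                                cbind(dat$t_2_x, dat$t_2_y, dat$t_2_z))
  }
  out
}

#' Benchmark accuracy table (AUC of cumulative error histograms)
#'
#' Runs the full estimation pipeline (normal voting, then each curvature
#' algorithm) on a benchmark surface for every combination of `algorithms` and
#' `rh_values`, and summarizes the principal-curvature errors as normalized
#' cumulative-histogram areas (in percent), for `kappa_1`, `kappa_2` and both
#' pooled. Triangles within `exclusion` geodesic distance of a border are
#' excluded from the evaluation (the estimation itself runs on the full mesh).
#' A run in which no triangle receives a curvature estimate is marked failed
#' and reported as 0.
#'
#' @param shape a `benchmark_surface`.
#' @param algorithms character vector from `"AVV"`, `"RVV"`, `"NVV"`, `"SSVV"`.
#' @param rh_values numeric vector of `radius_hit` values (voxels).
#' @param exclusion geodesic border-exclusion distance (voxels).
#' @param n_bins histogram bins for [cumulative_auc()].
#' @param csv optional path; when given the table is also written as CSV.
#' @return a tibble with columns `algorithm`, `rh`, `auc_k1`, `auc_k2`,
#'   `auc_both` (percent), `n_triangles`, `n_failed`, `failed_run`.
#' @export
run_benchmark_table <- function(shape, algorithms = c("RVV", "AVV", "SSVV"),
                                rh_values = 5:10, exclusion = 0, n_bins = 20,
                                csv = NULL) {
  stopifnot(inherits(shape, "benchmark_surface"))
  graph <- build_surface_graph(shape$mesh)
  keep <- border_distances(graph) > exclusion
  rows <- list()
  for (rh in rh_values) {
    mesh_n <- estimate_normals(shape$mesh, graph, rh)
    for (alg in algorithms) {
      est <- estimate_curvature(mesh_n, graph, rh, algorithm = alg)
      ev <- evaluate_against_truth(est, shape$truth, keep = keep)
      all_failed <- all(ev$failed)
      auc1 <- if (all_failed) 0 else 100 * cumulative_auc(ev$err_kappa_1,
                                                          n_bins = n_bins)
      auc2 <- if (all_failed) 0 else 100 * cumulative_auc(ev$err_kappa_2,
                                                          n_bins = n_bins)
      aucb <- if (all_failed) 0 else
        100 * cumulative_auc(c(ev$err_kappa_1, ev$err_kappa_2), n_bins = n_bins)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        algorithm = alg, rh = rh, auc_k1 = auc1, auc_k2 = auc2,
        auc_both = aucb, n_triangles = nrow(ev), n_failed = sum(ev$failed),
        failed_run = all_failed
      )
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
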