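# Additive (delta-method) bias adjustment: per grid cell and calendar month,
# the offset between the observed and simulated climatology over a
# calibration window is added to the entire simulated series. The underlying
# assumption is that model biases are stationary, so an offset estimated on
# the calibration window remains valid outside it.

#' Per-month additive bias offsets
#'
#' `offsets[m, i, j]` is the reference minus simulated mean for calendar
#' month `m` over the calibration window at cell `(i, j)`; cells missing in
#' the reference carry missing offsets.
#'
#' @param grid a [regular_grid()].
#' @param offsets numeric array `[12, n_lat, n_lon]`, degC.
#' @param calibration_window `c(first_year, last_year)`.
#' @param model_id model the offsets were computed for.
#' @return an object of class `bias_offsets`.
#' @export
bias_offsets <- function(grid, offsets, calibration_window, model_id = NULL) {
  stopifnot(inherits(grid, "regular_grid"),
            identical(dim(offsets), c(12L, grid$n_lat, grid$n_lon)))
  structure(
    list(grid = grid, offsets = offsets,
         calibration_window = as.integer(calibration_window),
         model_id = model_id),
    class = "bias_offsets"
  )
}

#' @export
print.bias_offsets <- function(x, ...) {
  cat(sprintf(
    "<bias_offsets> model %s, window %d-%d, %d x %d grid\n",
    x$model_id %||% "?", x$calibration_window[1], x$calibration_window[2],
    x$grid$n_lat, x$grid$n_lon
  ))
  invisible(x)
}

#' Compute additive bias offsets against a reference climatology
#'
#' For each grid cell and calendar month, the offset is the reference mean
#' minus the simulated mean over the calibration window (default 1961-1990).
#' Cells missing in the reference produce missing offsets.
#'
#' @param sim simulated [monthly_field()].
#' @param ref reference [monthly_field()] on the same grid.
#' @param window calibration window `c(first_year, last_year)`.
#' @return a [bias_offsets()] object.
#' @export
compute_offsets <- function(sim, ref, window = c(1961L, 1990L)) {
  stopifnot(inherits(sim, "monthly_field"), inherits(ref, "monthly_field"))
  if (!grids_identical(sim$grid, ref$grid)) {
    stop("sim and ref must be on the same grid", call. = FALSE)
  }
  idx_sim <- month_window_indices(sim$time, window[1], window[2])
  idx_ref <- month_window_indices(ref$time, window[1], window[2])
  sim_mon <- time_year_month(sim$time)$month[idx_sim]
  ref_mon <- time_year_month(ref$time)$month[idx_ref]
  sim_mat <- field_matrix(sim)
  ref_mat <- field_matrix(ref)
  n_cell <- sim$grid$n_lat * sim$grid$n_lon
  off <- matrix(NA_real_, 12L, n_cell)
  for (m in 1:12) {
    off[m, ] <- colMeans(ref_mat[idx_ref[ref_mon == m], , drop = FALSE]) -
      colMeans(sim_mat[idx_sim[sim_mon == m], , drop = FALSE])
  }
  off[, which(ref$missing_mask)] <- NA_real_
  dim(off) <- c(12L, sim$grid$n_lat, sim$grid$n_lon)
  bias_offsets(sim$grid, off, window, model_id = sim$attrs$model_id)
}

#' Apply additive bias offsets to a simulated series
#'
#' Adds the calendar-month offset of each cell to every month of the series,
#' including months far outside the calibration window (the stationarity
#' assumption). Cells with missing offsets (missing in the reference) become
#' missing in the output rather than passing through unadjusted.
#'
#' @param sim simulated [monthly_field()].
#' @param offsets a [bias_offsets()] on the same grid.
#' @return bias-adjusted [monthly_field()].
#' @export
apply_offsets <- function(sim, offsets) {
  stopifnot(inherits(sim, "monthly_field"), inherits(offsets, "bias_offsets"))
  if (!grids_identical(sim$grid, offsets$grid)) {
    stop("offsets grid does not match field grid", call. = FALSE)
  }
  if (!is.null(offsets$model_id) && !is.null(sim$attrs$model_id) &&
      !identical(offsets$model_id, sim$attrs$model_id)) {
    stop(sprintf("offsets were computed for model '%s', not '%s'",
                 offsets$model_id, sim$attrs$model_id), call. = FALSE)
  }
  mon <- time_year_month(sim$time)$month
  vals <- field_matrix(sim)
  off <- offsets$offsets
  n_cell <- sim$grid$n_lat * sim$grid$n_lon
  dim(off) <- c(12L, n_cell)
  for (m in 1:12) {
    rows <- which(mon == m)
    vals[rows, ] <- vals[rows, , drop = FALSE] +
      rep(off[m, ], each = length(rows))
  }
  missing_mask <- matrix(is.na(off[1L, ]), sim$grid$n_lat, sim$grid$n_lon) |
    sim$missing_mask
  vals[, which(missing_mask)] <- NA_real_
  dim(vals) <- dim(sim$values)
  monthly_field(sim$grid, sim$time, vals, missing_mask = missing_mask,
                attrs = c(sim$attrs, list(
                  bias_adjusted = TRUE,
                  calibration_window = offsets$calibration_window
                )))
}
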