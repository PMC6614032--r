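# Grid geometry, monthly time axis, and the gridded-field containers shared by
# every stage of the pipeline.

#' Regular latitude-longitude grid
#'
#' A regular grid is defined by its south-west cell edge, the cell steps, and
#' the cell counts. Cells are half-open intervals `[edge, edge + step)` in both
#' axes, with values treated as point samples at cell centers
#' (`edge + step/2`). Longitudes use the internal `[-180, 180)` convention.
#'
#' @param lat_edge_south southern edge of the southernmost cell row (degrees).
#' @param lon_edge_west western edge of the westernmost cell column (degrees).
#' @param lat_step,lon_step positive cell sizes in degrees.
#' @param n_lat,n_lon number of rows / columns.
#' @return an object of class `regular_grid`.
#' @examples
#' standard_grid()          # the global 0.5-degree analysis grid
#' global_grid(2)           # a coarser global grid for desk-scale runs
#' @export
regular_grid <- function(lat_edge_south, lon_edge_west, lat_step, lon_step,
                         n_lat, n_lon) {
  stopifnot(
    lat_step > 0, lon_step > 0,
    n_lat >= 1, n_lon >= 1,
    n_lat * lat_step <= 180 + 1e-9,
    n_lon * lon_step <= 360 + 1e-9
  )
  g <- structure(
    list(
      lat_edge_south = as.numeric(lat_edge_south),
      lon_edge_west = normalize_lon(as.numeric(lon_edge_west)),
      lat_step = as.numeric(lat_step),
      lon_step = as.numeric(lon_step),
      n_lat = as.integer(n_lat),
      n_lon = as.integer(n_lon)
    ),
    class = "regular_grid"
  )
  g
}

#' @rdname regular_grid
#' @param step cell size in degrees for a global grid starting at (-90, -180).
#' @export
global_grid <- function(step) {
  regular_grid(-90, -180, step, step, round(180 / step), round(360 / step))
}

#' @rdname regular_grid
#' @details `standard_grid()` returns the global 0.5-degree grid (360 x 720,
#'   centers at -89.75..89.75 and -179.75..179.75) onto which all model fields
#'   are interpolated and on which the observed reference climatology lives.
#' @export
standard_grid <- function() global_grid(0.5)

#' @export
print.regular_grid <- function(x, ...) {
  cat(sprintf(
    "<regular_grid> %d x %d cells, %.4g x %.4g deg, SW edge (%.4g, %.4g)\n",
    x$n_lat, x$n_lon, x$lat_step, x$lon_step, x$lat_edge_south, x$lon_edge_west
  ))
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid a [regular_grid()].
#' @return numeric vector of center latitudes (or longitudes, in [-180, 180)).
#' @export
grid_lat_centers <- function(grid) {
  grid$lat_edge_south + (seq_len(grid$n_lat) - 0.5) * grid$lat_step
}

#' @rdname grid_lat_centers
#' @export
grid_lon_centers <- function(grid) {
  normalize_lon(grid$lon_edge_west + (seq_len(grid$n_lon) - 0.5) * grid$lon_step)
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$n_lat == b$n_lat && a$n_lon == b$n_lon &&
    abs(a$lat_edge_south - b$lat_edge_south) < tol &&
    abs(normalize_lon(a$lon_edge_west - b$lon_edge_west)) < tol &&
    abs(a$lat_step - b$lat_step) < tol &&
    abs(a$lon_step - b$lon_step) < tol
}

#' Locate the grid cell containing a point
#'
#' Cells are half-open in both axes, so a point lying exactly on a shared edge
#' belongs to the higher-index cell; the northern edge of the northernmost row
#' is treated as closed so that every latitude in the grid span maps to a cell.
#' Longitude wraps modulo 360.
#'
#' @param grid a [regular_grid()].
#' @param lat,lon point coordinates in degrees (any longitude convention).
#' @return integer vector `c(lat_index, lon_index)` (1-based).
#' @examples
#' cell_of(standard_grid(), 51.5072, -0.1275)  # London's 0.5-degree cell
#' @export
cell_of <- function(grid, lat, lon) {
  stopifnot(length(lat) == 1L, length(lon) == 1L, is.finite(lat), is.finite(lon))
  span_n <- grid$lat_edge_south + grid$n_lat * grid$lat_step
  if (lat < grid$lat_edge_south || lat > span_n) {
    stop(sprintf(
      "latitude %.4f outside grid span [%.4f, %.4f]",
      lat, grid$lat_edge_south, span_n
    ), call. = FALSE)
  }
  i <- floor((lat - grid$lat_edge_south) / grid$lat_step) + 1
  if (i > grid$n_lat) i <- grid$n_lat  # closed top edge
  dlon <- (normalize_lon(lon) - grid$lon_edge_west) %% 360
  j <- floor(dlon / grid$lon_step) + 1
  if (j > grid$n_lon) {
    # only reachable when the grid does not span 360 degrees
    if (grid$n_lon * grid$lon_step >= 360 - 1e-9) j <- 1L
    else stop(sprintf("longitude %.4f outside grid span", lon), call. = FALSE)
  }
  c(lat_index = as.integer(i), lon_index = as.integer(j))
}

#' Monthly time axis
#'
#' A gap-free monthly sequence starting at `start_year`/`start_month` with
#' `n_months` entries. Index-to-(year, month) conversion is bijective.
#'
#' @param start_year first calendar year.
#' @param start_month first calendar month (1-12).
#' @param n_months number of months.
#' @return an object of class `month_time`.
#' @export
month_time <- function(start_year, start_month = 1L, n_months) {
  stopifnot(start_month >= 1, start_month <= 12, n_months >= 1)
  structure(
    list(
      start_year = as.integer(start_year),
      start_month = as.integer(start_month),
      n_months = as.integer(n_months)
    ),
    class = "month_time"
  )
}

#' @rdname month_time
#' @param first_year,last_year inclusive year range (January-December).
#' @export
years_time <- function(first_year, last_year) {
  month_time(first_year, 1L, 12L * (last_year - first_year + 1L))
}

#' @export
print.month_time <- function(x, ...) {
  ym <- time_year_month(x)
  n <- x$n_months
  cat(sprintf(
    "<month_time> %d months: %d-%02d .. %d-%02d\n",
    n, ym$year[1], ym$month[1], ym$year[n], ym$month[n]
  ))
  invisible(x)
}

#' Calendar year and month for each index of a monthly time axis
#' @param time a [month_time()].
#' @return list with integer vectors `year` and `month` of length `n_months`.
#' @export
time_year_month <- function(time) {
  k <- time$start_month - 1L + seq_len(time$n_months) - 1L
  list(year = time$start_year + k %/% 12L, month = k %% 12L + 1L)
}

#' Indices of a whole-year window on a monthly time axis
#'
#' Returns the time indices covering January of `first_year` through December
#' of `last_year`; every calendar month contributes the same number of indices.
#' Used to form 30-year period climatologies.
#'
#' @param time a [month_time()].
#' @param first_year,last_year inclusive window bounds.
#' @return integer vector of `12 * (last_year - first_year + 1)` indices.
#' @export
month_window_indices <- function(time, first_year, last_year) {
  stopifnot(first_year <= last_year)
  ym <- time_year_month(time)
  if (first_year < ym$year[1] || last_year > ym$year[time$n_months] ||
      (ym$year[1] == first_year && ym$month[1] > 1) ||
      (ym$year[time$n_months] == last_year && ym$month[time$n_months] < 12)) {
    stop(sprintf(
      "window %d-%d not fully covered by the series", first_year, last_year
    ), call. = FALSE)
  }
  which(ym$year >= first_year & ym$year <= last_year)
}

#' Gridded monthly temperature field
#'
#' The container carried through the pipeline: a grid, a gap-free monthly time
#' axis, and a `[time x lat x lon]` array of monthly mean temperatures in
#' degrees Celsius. `missing_mask` marks cells with no data (e.g. ocean cells
#' in the observed reference dataset).
#'
#' @param grid a [regular_grid()].
#' @param time a [month_time()].
#' @param values numeric array `[n_months, n_lat, n_lon]`, degC.
#' @param missing_mask logical `[n_lat, n_lon]` matrix, `TRUE` = no data.
#' @param attrs optional named list of provenance metadata.
#' @return an object of class `monthly_field`.
#' @export
monthly_field <- function(grid, time, values, missing_mask = NULL, attrs = list()) {
  stopifnot(inherits(grid, "regular_grid"), inherits(time, "month_time"))
  dv <- dim(values)
  if (length(dv) != 3L || dv[1] != time$n_months || dv[2] != grid$n_lat ||
      dv[3] != grid$n_lon) {
    stop("values must be a [n_months x n_lat x n_lon] array matching grid and time",
         call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
  }
  stopifnot(identical(dim(missing_mask), c(grid$n_lat, grid$n_lon)))
  ok_cells <- !missing_mask
  if (any(ok_cells)) {
    # finite wherever not masked; check via one pass over the flattened array
    m <- values
    dim(m) <- c(dv[1], dv[2] * dv[3])
    if (!all(is.finite(m[, which(ok_cells)]))) {
      stop("non-finite values at unmasked cells", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, time = time, values = values,
         missing_mask = missing_mask, attrs = attrs),
    class = "monthly_field"
  )
}

#' @export
print.monthly_field <- function(x, ...) {
  cat(sprintf(
    "<monthly_field> %d months on %d x %d grid (%.4g deg), %d masked cells\n",
    x$time$n_months, x$grid$n_lat, x$grid$n_lon, x$grid$lat_step,
    sum(x$missing_mask)
  ))
  invisible(x)
}

# Flatten the [time, lat, lon] array into a [time, cell] matrix; cell index is
# lat_index + (lon_index - 1) * n_lat (column-major over the lat x lon plane).
field_matrix <- function(field) {
  m <- field$values
  dim(m) <- c(field$time$n_months, field$grid$n_lat * field$grid$n_lon)
  m
}

cell_flat_index <- function(grid, lat_index, lon_index) {
  as.integer(lat_index + (lon_index - 1L) * grid$n_lat)
}

#' Land-sea mask
#'
#' @param grid a [regular_grid()].
#' @param is_land logical `[n_lat, n_lon]` matrix; at least one `TRUE` cell.
#' @return an object of class `land_mask`.
#' @export
land_mask <- function(grid, is_land) {
  stopifnot(inherits(grid, "regular_grid"),
            identical(dim(is_land), c(grid$n_lat, grid$n_lon)))
  if (!any(is_land)) stop("mask has no land cells", call. = FALSE)
  structure(list(grid = grid, is_land = is_land), class = "land_mask")
}

#' @export
print.land_mask <- function(x, ...) {
  cat(sprintf(
    "<land_mask> %d x %d grid, land fraction %.3f\n",
    x$grid$n_lat, x$grid$n_lon, mean(x$is_land)
  ))
  invisible(x)
}
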