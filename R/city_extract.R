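# Mapping cities to grid cells and pulling their monthly series. A city in a
# non-land cell (coastal or island cities at coarse resolution) is relocated
# to the land cell whose center is nearest by great-circle distance.

#' Locate the grid cell for a city
#'
#' Returns the cell containing the city's coordinates if that cell is land;
#' otherwise the land cell whose center minimizes the great-circle
#' (haversine) distance to the city, with exact-distance ties broken by the
#' lowest latitude index, then the lowest longitude index.
#'
#' @param city a list or one-row data.frame with `lat` and `lon`.
#' @param grid a [regular_grid()].
#' @param mask a [land_mask()] on `grid`.
#' @return list with `cell` (integer `c(lat_index, lon_index)`) and
#'   `relocated` (logical).
#' @export
locate_city_cell <- function(city, grid, mask) {
  stopifnot(inherits(mask, "land_mask"))
  if (!grids_identical(mask$grid, grid)) {
    stop("mask grid does not match", call. = FALSE)
  }
  own <- cell_of(grid, city$lat, city$lon)
  if (mask$is_land[own[1], own[2]]) {
    return(list(cell = own, relocated = FALSE))
  }
  land <- which(mask$is_land, arr.ind = TRUE)
  lat_c <- grid_lat_centers(grid)[land[, 1]]
  lon_c <- grid_lon_centers(grid)[land[, 2]]
  d <- haversine_km(city$lat, normalize_lon(city$lon), lat_c, lon_c)
  dmin <- min(d)
  cand <- which(d <= dmin + 1e-9)
  pick <- cand[order(land[cand, 1], land[cand, 2])][1]
  list(cell = c(lat_index = land[pick, 1], lon_index = land[pick, 2]),
       relocated = TRUE)
}

#' Extract city monthly series from a gridded field
#'
#' Pulls, for each city, the unmodified monthly values of its (possibly
#' relocated) grid cell.
#'
#' @param field a [monthly_field()]; must be non-missing at every located cell.
#' @param cities a city table (see [generate_city_table()]); needs columns
#'   `city_id`, `lat`, `lon`.
#' @param mask a [land_mask()] on the field's grid.
#' @param model_id,scenario identifiers recorded in the output (defaults
#'   taken from the field's `attrs`).
#' @return long-format `data.frame` with one row per city-month: `city_id`,
#'   `model_id`, `scenario`, `year`, `month`, `tmean_c`, `lat_index`,
#'   `lon_index`, `relocated`.
#' @export
extract_city_series <- function(field, cities, mask,
                                model_id = field$attrs$model_id,
                                scenario = field$attrs$scenario) {
  stopifnot(inherits(field, "monthly_field"), nrow(cities) >= 0)
  if (!grids_identical(mask$grid, field$grid)) {
    stop("mask grid does not match field grid", call. = FALSE)
  }
  ym <- time_year_month(field$time)
  vals <- field_matrix(field)
  n_t <- field$time$n_months
  pieces <- vector("list", nrow(cities))
  for (k in seq_len(nrow(cities))) {
    city <- cities[k, ]
    loc <- locate_city_cell(city, field$grid, mask)
    flat <- cell_flat_index(field$grid, loc$cell[1], loc$cell[2])
    v <- vals[, flat]
    if (anyNA(v)) {
      stop(sprintf(
        "field is missing at cell (%d, %d) for city '%s'",
        loc$cell[1], loc$cell[2], city$city_id
      ), call. = FALSE)
    }
    pieces[[k]] <- data.frame(
      city_id = rep(city$city_id, n_t),
      model_id = rep(model_id %||% NA_character_, n_t),
      scenario = rep(scenario %||% NA_character_, n_t),
      year = ym$year, month = ym$month, tmean_c = v,
      lat_index = rep(loc$cell[1], n_t),
      lon_index = rep(loc$cell[2], n_t),
      relocated = rep(loc$relocated, n_t),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
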