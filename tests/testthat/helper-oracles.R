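# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately share no code with the implementation paths
# they check.

# Scan every cell and test half-open interval membership directly.
brute_cell_of <- function(grid, lat, lon) {
  lon <- ((lon + 180) %% 360) - 180
  for (i in seq_len(grid$n_lat)) {
    s <- grid$lat_edge_south + (i - 1) * grid$lat_step
    in_lat <- (lat >= s && lat < s + grid$lat_step) ||
      (i == grid$n_lat && lat == s + grid$lat_step)
    if (!in_lat) next
    for (j in seq_len(grid$n_lon)) {
      w <- ((grid$lon_edge_west + (j - 1) * grid$lon_step + 180) %% 360) - 180
      d <- (lon - w) %% 360
      if (d >= 0 && d < grid$lon_step) return(c(i, j))
    }
  }
  stop("no containing cell")
}

# Explicit 4-neighbour bilinear interpolation of one month at one point.
brute_bilinear <- function(field, lat, lon) {
  g <- field$grid
  slat <- grid_lat_centers(g)
  slon <- grid_lon_centers(g)
  n <- length(slat)
  if (lat <= slat[1]) { i0 <- 1; i1 <- 1; wl <- 0 }
  else if (lat >= slat[n]) { i0 <- n; i1 <- n; wl <- 0 }
  else {
    i0 <- max(which(slat <= lat)); i1 <- i0 + 1
    wl <- (lat - slat[i0]) / (slat[i1] - slat[i0])
  }
  d <- (lon - slon) %% 360
  j0 <- which.min(d)
  j1 <- j0 %% length(slon) + 1
  gap <- (slon[j1] - slon[j0]) %% 360
  if (gap == 0) gap <- 360
  wj <- d[j0] / gap
  v <- field$values[1, , ]
  (1 - wl) * ((1 - wj) * v[i0, j0] + wj * v[i0, j1]) +
    wl * ((1 - wj) * v[i1, j0] + wj * v[i1, j1])
}

# Exhaustive great-circle scan over all land cells, ties by lowest lat then
# lon index. Uses geosphere's haversine as the independent distance.
brute_nearest_land <- function(city, grid, mask) {
  land <- which(mask$is_land, arr.ind = TRUE)
  latc <- grid_lat_centers(grid)[land[, 1]]
  lonc <- grid_lon_centers(grid)[land[, 2]]
  d <- geosphere::distHaversine(cbind(city$lon, city$lat),
                                cbind(lonc, latc), r = 6371008.8) / 1000
  cand <- which(d <= min(d) + 1e-9)
  pick <- cand[order(land[cand, 1], land[cand, 2])][1]
  unname(land[pick, ])
}

# Constant-valued field on a given grid.
const_field <- function(grid, value, n_months = 3L, start_year = 2000L) {
  monthly_field(grid, month_time(start_year, 1L, n_months),
                array(value, c(n_months, grid$n_lat, grid$n_lon)))
}

# Field whose month-1 values follow f(lat, lon) at cell centers.
fun_field <- function(grid, f, n_months = 1L) {
  latc <- grid_lat_centers(grid)
  lonc <- grid_lon_centers(grid)
  v <- array(NA_real_, c(n_months, grid$n_lat, grid$n_lon))
  for (t in seq_len(n_months)) {
    v[t, , ] <- outer(latc, lonc, f)
  }
  monthly_field(grid, month_time(2000L, 1L, n_months), v)
}

# Long-format series with one value per (year, month) from a function.
make_series <- function(first_year, last_year, value_fn,
                        city_id = "c1", model_id = "m1", scenario = "s1") {
  years <- first_year:last_year
  grid <- expand.grid(month = 1:12, year = years)
  data.frame(
    city_id = city_id, model_id = model_id, scenario = scenario,
    year = grid$year, month = grid$month,
    tmean_c = mapply(value_fn, grid$year, grid$month),
    stringsAsFactors = FALSE
  )
}

# Small noiseless truth with a single model and simple trajectories.
tiny_truth <- function(noise_sd = 0, deltas = c(low = 1.1, high = 4.15),
                       biases = c(m1 = 0)) {
  synthetic_truth(
    scenarios = list(
      low = list(delta_2100 = unname(deltas["low"]),
                 ramp = list(type = "linear", start = 1990, end = 2050)),
      high = list(delta_2100 = unname(deltas["high"]),
                  ramp = list(type = "quadratic", start = 1990, end = 2100))
    ),
    model_biases = biases, noise_sd = noise_sd, seed = 42L
  )
}
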