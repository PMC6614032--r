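# Synthetic stand-ins for the gridded inputs: multi-model monthly temperature
# fields with a known injected warming signal, an unbiased observed-style
# reference field, a land mask, and a stratified city table. The generator
# defines the desk-scale study conditions and carries its own closed-form
# truth so the full pipeline can be checked against exact answers.

#' Ground-truth parameters for the synthetic climate generator
#'
#' The generated monthly mean temperature at a cell with center latitude
#' `lat`, calendar month `m`, year `y`, for model `id` under scenario `s` is
#'
#'   T = mu(lat) + A(lat) cos(2 pi (m - peak(lat)) / 12)
#'       + delta_2100(s) * w_s(y) * amp(lat) + b_id + noise
#'
#' where `mu(lat) = mean_equator - mean_pole_drop (lat/90)^2` is the
#' latitudinal mean profile, `A(lat) = amp_seasonal_max |lat|/90` the seasonal
#' half-range with peak month `peak_month_north` in the northern hemisphere
#' and six months later south of the equator, and
#' `amp(lat) = 1 + amplification_polar_excess (lat/90)^2` the polar
#' amplification of warming. The scenario trajectory `w_s` is a calibrated
#' rescaling of a monotone shape `g_s(y)` in `[0, 1]`,
#' `w_s(y) = (g_s(y) - gbar_base) / (gbar_far - gbar_base)`, so that
#' `delta_2100` is exactly the realized equatorial change of the far-future
#' window (default 2071-2100) relative to the baseline window (1988-2017).
#' Model biases `b_id` are constant in time (the stationarity assumption that
#' the additive bias adjustment relies on); noise is independent
#' `N(0, noise_sd^2)` per month and cell.
#'
#' @param scenarios named list of scenarios; each has `delta_2100` (degC,
#'   realized equatorial far-future warming) and `ramp`, a list with `type`
#'   ("linear" rise then plateau, or "quadratic" acceleration), `start` and
#'   `end` years. Defaults: a mitigation-like "low" pathway (1.10 degC,
#'   linear 1990-2050 then flat) and a business-as-usual "high" pathway
#'   (4.15 degC, quadratic through 2100).
#' @param mean_equator,mean_pole_drop degC; equatorial annual mean and its
#'   drop towards the poles.
#' @param amp_seasonal_max degC; seasonal cosine half-range at the poles.
#' @param peak_month_north calendar month of the northern-hemisphere seasonal
#'   maximum (southern hemisphere is offset by 6 months).
#' @param amplification_polar_excess polar excess of the warming
#'   amplification factor (0 = uniform warming; 2 = poles warm 3x equator).
#' @param model_biases named numeric vector of constant per-model offsets, degC.
#' @param noise_sd degC; standard deviation of month-to-month noise.
#' @param seasonal_sharpening optional fractional increase of the seasonal
#'   amplitude per unit of normalized warming (default 0: warming shifts the
#'   mean level only).
#' @param baseline_window,far_window year windows used to calibrate the
#'   trajectories (defaults 1988-2017 and 2071-2100).
#' @param seed default seed used by the simulators when none is given.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(scenarios = default_scenarios(),
                            mean_equator = 28,
                            mean_pole_drop = 48,
                            amp_seasonal_max = 20,
                            peak_month_north = 7L,
                            amplification_polar_excess = 2,
                            model_biases = c(
                              gcm01 = -2.1, gcm02 = -1.2, gcm03 = -0.4,
                              gcm04 = 0.6, gcm05 = 1.3, gcm06 = 2.4
                            ),
                            noise_sd = 0.5,
                            seasonal_sharpening = 0,
                            baseline_window = c(1988L, 2017L),
                            far_window = c(2071L, 2100L),
                            seed = 1L) {
  stopifnot(length(scenarios) >= 1, !is.null(names(scenarios)))
  deltas <- vapply(scenarios, function(s) s$delta_2100, numeric(1))
  if (any(deltas < 0)) stop("delta_2100 must be non-negative", call. = FALSE)
  structure(
    list(
      scenarios = scenarios,
      mean_equator = mean_equator,
      mean_pole_drop = mean_pole_drop,
      amp_seasonal_max = amp_seasonal_max,
      peak_month_north = as.integer(peak_month_north),
      amplification_polar_excess = amplification_polar_excess,
      model_biases = model_biases,
      noise_sd = noise_sd,
      seasonal_sharpening = seasonal_sharpening,
      baseline_window = as.integer(baseline_window),
      far_window = as.integer(far_window),
      seed = as.integer(seed)
    ),
    class = "synthetic_truth"
  )
}

#' @rdname synthetic_truth
#' @export
default_scenarios <- function() {
  list(
    low = list(
      delta_2100 = 1.10,
      ramp = list(type = "linear", start = 1990, end = 2050)
    ),
    high = list(
      delta_2100 = 4.15,
      ramp = list(type = "quadratic", start = 1990, end = 2100)
    )
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  d <- vapply(x$scenarios, function(s) s$delta_2100, numeric(1))
  cat(sprintf(
    "<synthetic_truth> scenarios: %s; noise_sd %.3g degC; %d models\n",
    paste(sprintf("%s (%.2f degC)", names(d), d), collapse = ", "),
    x$noise_sd, length(x$model_biases)
  ))
  invisible(x)
}

# Monotone trajectory shape g(year) in [0, 1]; zero at and before ramp start.
ramp_g <- function(ramp, years) {
  x <- pmin(pmax((years - ramp$start) / (ramp$end - ramp$start), 0), 1)
  switch(ramp$type,
    linear = x,
    quadratic = x^2,
    stop(sprintf("unknown ramp type '%s'", ramp$type), call. = FALSE)
  )
}

mean_g_window <- function(ramp, window) {
  mean(ramp_g(ramp, seq(window[1], window[2])))
}

get_scenario <- function(truth, scenario) {
  s <- truth$scenarios[[scenario]]
  if (is.null(s)) {
    stop(sprintf("unknown scenario '%s'", scenario), call. = FALSE)
  }
  s
}

# Calibrated warming trajectory w(year): 0 on average over the baseline
# window, 1 on average over the far-future window.
warming_weight <- function(truth, scenario, years) {
  s <- get_scenario(truth, scenario)
  gb <- mean_g_window(s$ramp, truth$baseline_window)
  gf <- mean_g_window(s$ramp, truth$far_window)
  if (gf <= gb) {
    # degenerate flat trajectory (e.g. delta 0): no warming anywhere
    return(rep(0, length(years)))
  }
  (ramp_g(s$ramp, years) - gb) / (gf - gb)
}

#' Latitude amplification factor of the injected warming
#' @param truth a [synthetic_truth()].
#' @param lat latitude in degrees.
#' @return multiplicative factor (1 at the equator, larger poleward).
#' @export
amplification_factor <- function(truth, lat) {
  1 + truth$amplification_polar_excess * (lat / 90)^2
}

#' Closed-form injected temperature change
#'
#' The exact change in climatological mean temperature between two whole-year
#' windows implied by the generator, at a location with the given latitude.
#' Because warming shifts the mean level identically in every calendar month
#' (unless seasonal sharpening is enabled), this is simultaneously the true
#' change in the annual mean and in the hottest- and coldest-month means.
#'
#' @param truth a [synthetic_truth()].
#' @param scenario scenario name.
#' @param lat latitude in degrees (scalar or vector).
#' @param future `c(first_year, last_year)` future window.
#' @param baseline baseline window (default the truth's calibration baseline).
#' @return change in degC.
#' @export
true_change <- function(truth, scenario, lat, future,
                        baseline = truth$baseline_window) {
  s <- get_scenario(truth, scenario)
  gb0 <- mean_g_window(s$ramp, truth$baseline_window)
  gf0 <- mean_g_window(s$ramp, truth$far_window)
  if (gf0 <= gb0) return(rep(0, length(lat)))
  gF <- mean_g_window(s$ramp, future)
  gB <- mean_g_window(s$ramp, baseline)
  s$delta_2100 * (gF - gB) / (gf0 - gb0) * amplification_factor(truth, lat)
}

# Deterministic (noise-free, bias-free) monthly values as a [time x lat]
# matrix; identical for every longitude column.
climate_matrix <- function(truth, scenario, lat_centers, time) {
  ym <- time_year_month(time)
  mu <- truth$mean_equator - truth$mean_pole_drop * (lat_centers / 90)^2
  A <- truth$amp_seasonal_max * abs(lat_centers) / 90
  peak <- ifelse(lat_centers >= 0, truth$peak_month_north,
                 (truth$peak_month_north + 5L) %% 12L + 1L)
  amp <- amplification_factor(truth, lat_centers)
  w <- warming_weight(truth, scenario, ym$year)
  delta <- get_scenario(truth, scenario)$delta_2100
  # seasonal term [time x lat]
  phase <- outer(ym$month, peak, `-`)
  seas <- cos(2 * pi * phase / 12)
  if (truth$seasonal_sharpening != 0) {
    seas <- seas * (1 + truth$seasonal_sharpening * w)
  }
  seas <- sweep(seas, 2, A, `*`)
  trend <- outer(delta * w, amp, `*`)
  sweep(seas + trend, 2, mu, `+`)
}

#' Simulate a model temperature field
#'
#' Generates a global monthly mean temperature series for one model and
#' scenario on an arbitrary regular grid, following the generative equation
#' documented in [synthetic_truth()]. Model fields have no missing cells
#' (model output covers ocean and land alike).
#'
#' @param grid a [regular_grid()] (the model's native grid).
#' @param scenario scenario name known to `truth`.
#' @param model_id model name; must be present in `truth$model_biases`.
#' @param truth a [synthetic_truth()].
#' @param years `c(first_year, last_year)`; default 1901-2100.
#' @param seed RNG seed (default derived from `truth$seed` and the model id).
#' @return a [monthly_field()].
#' @export
simulate_model_field <- function(grid, scenario, model_id, truth,
                                 years = c(1901L, 2100L), seed = NULL) {
  b <- truth$model_biases[model_id]
  if (length(b) != 1L || is.na(b)) {
    stop(sprintf("unknown model '%s'", model_id), call. = FALSE)
  }
  get_scenario(truth, scenario)
  if (is.null(seed)) {
    seed <- derive_seed(truth$seed, paste0("model:", model_id, ":", scenario))
  }
  time <- years_time(years[1], years[2])
  base <- climate_matrix(truth, scenario, grid_lat_centers(grid), time) + as.numeric(b)
  n_cell <- grid$n_lat * grid$n_lon
  vals <- matrix(base, nrow = time$n_months, ncol = n_cell)  # recycle over lon
  if (truth$noise_sd > 0) {
    vals <- vals + with_seed(seed, matrix(
      stats::rnorm(time$n_months * n_cell, sd = truth$noise_sd),
      nrow = time$n_months
    ))
  }
  dim(vals) <- c(time$n_months, grid$n_lat, grid$n_lon)
  monthly_field(grid, time, vals,
                attrs = list(model_id = model_id, scenario = scenario,
                             kind = "simulated"))
}

#' Simulate the observed reference field
#'
#' Same generative equation as [simulate_model_field()] but with zero model
#' bias (the reference is the unbiased truth, plus optional observation
#' noise) and with ocean cells missing according to the land mask, emulating
#' a land-only gridded observational climatology.
#'
#' @param grid a [regular_grid()] (typically the analysis target grid).
#' @param truth a [synthetic_truth()].
#' @param years year range of the observed record; default 1901-2013.
#' @param mask a [land_mask()] on `grid`, or `NULL` for all-land.
#' @param scenario trajectory used for the (small) observed-era trend.
#' @param noise_sd observation noise, degC (default the truth's noise_sd).
#' @param seed RNG seed.
#' @return a [monthly_field()] with ocean cells masked.
#' @export
simulate_reference_field <- function(grid, truth, years = c(1901L, 2013L),
                                     mask = NULL,
                                     scenario = names(truth$scenarios)[1],
                                     noise_sd = truth$noise_sd, seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(truth$seed, "reference")
  time <- years_time(years[1], years[2])
  base <- climate_matrix(truth, scenario, grid_lat_centers(grid), time)
  n_cell <- grid$n_lat * grid$n_lon
  vals <- matrix(base, nrow = time$n_months, ncol = n_cell)
  if (noise_sd > 0) {
    vals <- vals + with_seed(seed, matrix(
      stats::rnorm(time$n_months * n_cell, sd = noise_sd),
      nrow = time$n_months
    ))
  }
  if (is.null(mask)) {
    missing_mask <- matrix(FALSE, grid$n_lat, grid$n_lon)
  } else {
    stopifnot(inherits(mask, "land_mask"))
    if (!grids_identical(mask$grid, grid)) {
      stop("mask grid does not match field grid", call. = FALSE)
    }
    missing_mask <- !mask$is_land
    vals[, which(missing_mask)] <- NA_real_
  }
  dim(vals) <- c(time$n_months, grid$n_lat, grid$n_lon)
  monthly_field(grid, time, vals, missing_mask = missing_mask,
                attrs = list(kind = "reference"))
}

#' Generate a land-sea mask
#'
#' @param grid a [regular_grid()].
#' @param mode `"all-land"`, `"latband-continents"` (a deterministic pattern
#'   of continent-like longitude bands with polar ocean caps), or
#'   `"random-blobs"` (a thresholded smooth random field giving contiguous
#'   land masses at a configured coverage fraction).
#' @param fraction target land fraction for `"random-blobs"`.
#' @param seed RNG seed (used by `"random-blobs"` only).
#' @return a [land_mask()].
#' @export
make_land_mask <- function(grid, mode = c("random-blobs", "latband-continents",
                                          "all-land"),
                           fraction = 0.3, seed = 1L) {
  mode <- match.arg(mode)
  is_land <- switch(mode,
    "all-land" = matrix(TRUE, grid$n_lat, grid$n_lon),
    "latband-continents" = {
      lat <- grid_lat_centers(grid)
      lon <- grid_lon_centers(grid)
      band <- (floor((lon + 180) / 60) %% 2) == 0
      outer(abs(lat) < 72, band, `&`)
    },
    "random-blobs" = {
      stopifnot(fraction > 0, fraction <= 1)
      # coarse random field, bilinearly upsampled, thresholded at the
      # (1 - fraction) quantile: land coverage matches fraction closely and
      # comes out in contiguous blobs
      nb_lat <- max(4L, round(grid$n_lat / 12))
      nb_lon <- max(8L, round(grid$n_lon / 12))
      coarse_grid <- regular_grid(-90, -180, 180 / nb_lat, 360 / nb_lon,
                                  nb_lat, nb_lon)
      z <- with_seed(seed, matrix(stats::rnorm(nb_lat * nb_lon), nb_lat, nb_lon))
      zf <- monthly_field(coarse_grid, month_time(2000L, 1L, 1L),
                          array(z, c(1L, nb_lat, nb_lon)))
      smooth <- regrid(zf, grid, method = "bilinear")$values[1, , ]
      thr <- stats::quantile(smooth, 1 - fraction, names = FALSE)
      m <- smooth > thr
      if (!any(m)) m[which.max(smooth)] <- TRUE
      m
    }
  )
  land_mask(grid, is_land)
}

#' Generate a stratified city table
#'
#' Draws `n` cities stratified by national-income band, ecoregion domain and
#' WHO region. Per-stratum counts follow proportional largest-remainder
#' allocation (a stratified design fixes the counts; the seed only shuffles
#' which city gets which stratum). City latitude is drawn from a latitude
#' band consistent with
#' the ecoregion domain (polar cities at high latitude, humid tropical cities
#' near the equator); longitude is uniform. Populations are log-uniform above
#' the 15,000 inclusion floor.
#'
#' @param n number of cities.
#' @param strata_config named list with elements `gni` (4 bands), `ecoregion`
#'   (4 domains) and `who_region` (6 regions), each a named numeric vector of
#'   proportions summing to 1, plus `north_fraction` (probability of the
#'   northern hemisphere). See `default_strata_config()`.
#' @param seed RNG seed.
#' @return a `data.frame` (class `city_table`) with columns `city_id`, `name`,
#'   `lat`, `lon`, `population`, `gni_stratum`, `ecoregion_domain`,
#'   `who_region`.
#' @export
generate_city_table <- function(n, strata_config = default_strata_config(),
                                seed = 1L) {
  stopifnot(n >= 0)
  for (axis in c("gni", "ecoregion", "who_region")) {
    p <- strata_config[[axis]]
    if (is.null(p) || is.null(names(p)) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop(sprintf("strata proportions for '%s' must be named and sum to 1", axis),
           call. = FALSE)
    }
  }
  cols <- c("city_id", "name", "lat", "lon", "population",
            "gni_stratum", "ecoregion_domain", "who_region")
  if (n == 0) {
    out <- data.frame(
      city_id = character(), name = character(), lat = numeric(),
      lon = numeric(), population = numeric(), gni_stratum = character(),
      ecoregion_domain = character(), who_region = character(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("city_table", "data.frame")
    return(out)
  }
  bands <- list(
    "polar" = c(60, 85),
    "dry" = c(15, 45),
    "humid temperate" = c(30, 60),
    "humid tropical" = c(0, 23.5)
  )
  out <- with_seed(seed, {
    eco <- sample(allocate_strata(n, strata_config$ecoregion))
    gni <- sample(allocate_strata(n, strata_config$gni))
    who <- sample(allocate_strata(n, strata_config$who_region))
    band <- do.call(rbind, bands[eco])
    alat <- stats::runif(n, band[, 1], band[, 2])
    hemi <- ifelse(stats::runif(n) < (strata_config$north_fraction %||% 0.75),
                   1, -1)
    lat <- alat * hemi
    lon <- normalize_lon(stats::runif(n, -180, 180))
    population <- round(10^stats::runif(n, log10(15000), 7.3))
    data.frame(
      city_id = sprintf("city_%04d", seq_len(n)),
      name = sprintf("Synthville-%04d", seq_len(n)),
      lat = lat, lon = lon, population = population,
      gni_stratum = gni, ecoregion_domain = eco, who_region = who,
      stringsAsFactors = FALSE
    )
  })
  class(out) <- c("city_table", "data.frame")
  out[, cols]
}

# Proportional (largest-remainder) allocation of n units to strata: the
# stratified design fixes per-stratum counts, randomness only shuffles the
# assignment across cities.
allocate_strata <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  rep(names(props), base)
}

#' @rdname generate_city_table
#' @export
default_strata_config <- function() {
  list(
    gni = c("low" = 0.10, "lower-middle" = 0.25,
            "upper-middle" = 0.30, "high" = 0.35),
    ecoregion = c("polar" = 0.05, "dry" = 0.15,
                  "humid temperate" = 0.45, "humid tropical" = 0.35),
    who_region = c("Africa" = 0.08, "Americas" = 0.23,
                   "Eastern Mediterranean" = 0.08, "Europe" = 0.22,
                   "South-East Asia" = 0.16, "Western Pacific" = 0.23),
    north_fraction = 0.75
  )
}
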