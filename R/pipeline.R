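# End-to-end orchestration: configuration, the staged pipeline
# (simulate/ingest -> regrid -> bias_adjust -> extract -> climatology ->
# summarize), output writing and the reproducibility manifest.

#' Native grid sizes for the default synthetic model ensemble
#'
#' Six global grids spanning the range of resolutions typical of coupled
#' climate model archives (64 x 128 up to 192 x 320 cells).
#' @return named list of `c(n_lat, n_lon)` pairs.
#' @export
default_model_grids <- function() {
  list(
    gcm01 = c(64L, 128L), gcm02 = c(96L, 192L), gcm03 = c(90L, 144L),
    gcm04 = c(128L, 256L), gcm05 = c(96L, 144L), gcm06 = c(64L, 128L)
  )
}

model_grid_from_dims <- function(dims) {
  regular_grid(-90, -180, 180 / dims[1], 360 / dims[2], dims[1], dims[2])
}

#' Pipeline run configuration
#'
#' Collects every tunable of an end-to-end run. The default configuration is
#' the desk-scale synthetic study: 6 models on heterogeneous native grids, 2
#' scenarios, 50 cities, a 2-degree global analysis grid, monthly series
#' 1901-2100, reference coverage 1901-2013, calibration window 1961-1990 and
#' 30-year periods labelled 2017/2050/2100. Pass
#' `target_grid = standard_grid()` for the full-resolution 0.5-degree
#' analysis grid.
#'
#' @param synthetic generate inputs synthetically (`TRUE`) or read them from
#'   `inputs` files.
#' @param n_cities number of synthetic cities.
#' @param models named list of model native grid sizes (`c(n_lat, n_lon)`).
#' @param scenarios character vector of scenario names.
#' @param target_grid the analysis [regular_grid()].
#' @param periods named list of 30-year windows (see [default_periods()]).
#' @param baseline_label label of the baseline period.
#' @param calibration_window bias-adjustment window, inside the reference
#'   coverage.
#' @param sim_years,ref_years year spans of simulated and reference series.
#' @param regrid_method `"bilinear"` or `"nearest"`.
#' @param ensemble,extreme_month see [changes_table()].
#' @param exceedance list of exceedance definitions
#'   (`list(quantity=, cutoff=, comparison=)`).
#' @param mask_mode,land_fraction see [make_land_mask()].
#' @param noise_sd synthetic noise standard deviation, degC.
#' @param truth optional [synthetic_truth()]; built from defaults otherwise.
#' @param seed root seed; per-stage sub-seeds are derived from it.
#' @param out_dir output directory (a fresh temporary directory if `NULL`).
#' @param inputs for `synthetic = FALSE`: list with `cities_file`,
#'   `mask_file`, `ref_file` and `model_files` (nested list
#'   `model_files[[scenario]][[model]]` of field files).
#' @return an object of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE,
                       n_cities = 50L,
                       models = default_model_grids(),
                       scenarios = c("low", "high"),
                       target_grid = global_grid(2),
                       periods = default_periods(),
                       baseline_label = "2017",
                       calibration_window = c(1961L, 1990L),
                       sim_years = c(1901L, 2100L),
                       ref_years = c(1901L, 2013L),
                       regrid_method = "bilinear",
                       ensemble = "before_extremes",
                       extreme_month = "per_period",
                       exceedance = list(
                         list(quantity = "d_hottest", cutoff = 2,
                              comparison = ">"),
                         list(quantity = "abs_hottest_future", cutoff = 40,
                              comparison = ">")
                       ),
                       mask_mode = "random-blobs",
                       land_fraction = 0.3,
                       noise_sd = 0.5,
                       truth = NULL,
                       seed = 1L,
                       out_dir = NULL,
                       inputs = NULL) {
  if (is.null(truth) && synthetic) {
    biases <- stats::setNames(
      seq(-2.2, 2.2, length.out = max(length(models), 2))[seq_along(models)],
      names(models)
    )
    truth <- synthetic_truth(model_biases = biases, noise_sd = noise_sd,
                             seed = derive_seed(seed, "truth"))
  }
  cfg <- structure(
    list(
      synthetic = synthetic, n_cities = as.integer(n_cities), models = models,
      scenarios = scenarios, target_grid = target_grid, periods = periods,
      baseline_label = baseline_label,
      calibration_window = as.integer(calibration_window),
      sim_years = as.integer(sim_years), ref_years = as.integer(ref_years),
      regrid_method = regrid_method, ensemble = ensemble,
      extreme_month = extreme_month, exceedance = exceedance,
      mask_mode = mask_mode, land_fraction = land_fraction,
      noise_sd = noise_sd, truth = truth, seed = as.integer(seed),
      out_dir = out_dir, inputs = inputs
    ),
    class = "run_config"
  )
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  for (lbl in names(cfg$periods)) {
    win <- cfg$periods[[lbl]]
    if (win[1] < cfg$sim_years[1] || win[2] > cfg$sim_years[2]) {
      stop(sprintf("period %s (%d-%d) outside the simulated series %d-%d",
                   lbl, win[1], win[2], cfg$sim_years[1], cfg$sim_years[2]),
           call. = FALSE)
    }
  }
  if (!(cfg$baseline_label %in% names(cfg$periods))) {
    stop("baseline_label must name one of the periods", call. = FALSE)
  }
  cw <- cfg$calibration_window
  if (cw[1] < cfg$ref_years[1] || cw[2] > cfg$ref_years[2]) {
    stop(sprintf("calibration window %d-%d outside reference coverage %d-%d",
                 cw[1], cw[2], cfg$ref_years[1], cfg$ref_years[2]),
         call. = FALSE)
  }
  if (cfg$synthetic) {
    missing_models <- setdiff(names(cfg$models), names(cfg$truth$model_biases))
    if (length(missing_models) > 0) {
      stop(sprintf("models without a bias in truth: %s",
                   paste(missing_models, collapse = ", ")), call. = FALSE)
    }
    for (s in cfg$scenarios) get_scenario(cfg$truth, s)
  }
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s; %d models x %d scenarios, %d cities, target %d x %d grid, seed %d\n",
    if (x$synthetic) "synthetic" else "file inputs",
    length(x$models), length(x$scenarios), x$n_cities,
    x$target_grid$n_lat, x$target_grid$n_lon, x$seed
  ))
  invisible(x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes simulate/ingest -> regrid -> bias_adjust -> extract ->
#' climatology -> summarize, writes all result tables and a manifest to the
#' output directory, and returns the results. Identical configuration and
#' seed produce byte-identical output files.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param quiet suppress progress messages.
#' @return an object of class `urbheat_run`: the configuration, the city
#'   table, per-model climatology table, ensemble changes table, stratified
#'   summary, exceedance reports, scatter exports, manifest and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- tempfile("urbheat_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  target <- config$target_grid
  seed <- config$seed

  if (config$synthetic) {
    truth <- config$truth
    cities <- run_stage("simulate", generate_city_table(
      config$n_cities, seed = derive_seed(seed, "cities")
    ))
    mask <- run_stage("simulate", make_land_mask(
      target, config$mask_mode, fraction = config$land_fraction,
      seed = derive_seed(seed, "mask")
    ))
    ref <- run_stage("simulate", simulate_reference_field(
      target, truth, years = config$ref_years, mask = mask,
      seed = derive_seed(seed, "reference")
    ))
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("[stage ingest] inputs required when synthetic = FALSE",
                           call. = FALSE)
    cities <- run_stage("ingest", read_city_table(inp$cities_file))
    mask <- run_stage("ingest", read_mask(inp$mask_file))
    ref <- run_stage("bias_adjust", {
      if (is.null(inp$ref_file) || !file.exists(inp$ref_file %||% "")) {
        stop("reference field file not found", call. = FALSE)
      }
      read_field(inp$ref_file)
    })
  }

  clim_pieces <- list()
  n_series_rows <- 0L
  for (scn in config$scenarios) {
    for (mid in names(config$models)) {
      say("processing %s / %s", scn, mid)
      sim <- if (config$synthetic) {
        run_stage("simulate", simulate_model_field(
          model_grid_from_dims(config$models[[mid]]), scn, mid, config$truth,
          years = config$sim_years,
          seed = derive_seed(seed, paste0("field:", scn, ":", mid))
        ))
      } else {
        run_stage("ingest", {
          f <- config$inputs$model_files[[scn]][[mid]]
          if (is.null(f) || !file.exists(f)) {
            stop(sprintf("model field file for %s/%s not found", scn, mid),
                 call. = FALSE)
          }
          read_field(f)
        })
      }
      reg <- run_stage("regrid",
                       regrid(sim, target, method = config$regrid_method))
      rm(sim)
      adj <- run_stage("bias_adjust", {
        offs <- compute_offsets(reg, ref, window = config$calibration_window)
        apply_offsets(reg, offs)
      })
      rm(reg)
      series <- run_stage("extract",
                          extract_city_series(adj, cities, mask,
                                              model_id = mid, scenario = scn))
      rm(adj)
      n_series_rows <- n_series_rows + nrow(series)
      clim_pieces[[paste(scn, mid, sep = ":")]] <- run_stage(
        "climatology", climatology_table(series, periods = config$periods)
      )
      rm(series)
    }
  }

  clim <- do.call(rbind, clim_pieces)
  rownames(clim) <- NULL
  changes <- run_stage("climatology", changes_table(
    clim, baseline_label = config$baseline_label,
    ensemble = config$ensemble, extreme_month = config$extreme_month
  ))
  summary_tab <- run_stage("summarize", stratified_table(changes, cities))
  exceedances <- run_stage("summarize", lapply(config$exceedance, function(e) {
    exceedance_report(changes, e$quantity, e$cutoff,
                      comparison = e$comparison %||% ">", cities = cities)
  }))
  future_labels <- setdiff(names(config$periods), config$baseline_label)
  scatters <- run_stage("summarize", {
    out <- list()
    for (ax in c("latitude", "seasonal_range", "log10_population")) {
      for (scn in config$scenarios) {
        for (lbl in future_labels) {
          out[[paste(ax, scn, lbl, sep = "_")]] <-
            scatter_export(changes, cities, ax, period = lbl, scenario = scn)
        }
      }
    }
    out
  })

  manifest <- list(
    package = "urbheat",
    version = as.character(utils::packageVersion("urbheat")),
    config = serialize_config(config),
    counts = list(
      cities = nrow(cities), models = length(config$models),
      scenarios = length(config$scenarios),
      series_rows = n_series_rows, climatology_rows = nrow(clim),
      change_rows = nrow(changes)
    )
  )

  write_city_table(cities, file.path(out_dir, "cities.csv"))
  utils::write.csv(clim, file.path(out_dir, "climatology.csv"),
                   row.names = FALSE)
  utils::write.csv(changes, file.path(out_dir, "changes.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(summary_tab),
                   file.path(out_dir, "summary_table.csv"), row.names = FALSE)
  for (i in seq_along(exceedances)) {
    e <- config$exceedance[[i]]
    utils::write.csv(
      as.data.frame(exceedances[[i]]),
      file.path(out_dir, sprintf("exceedance_%s_%g.csv", e$quantity, e$cutoff)),
      row.names = FALSE
    )
  }
  for (nm in names(scatters)) {
    utils::write.csv(scatters[[nm]],
                     file.path(out_dir, sprintf("scatter_%s.csv", nm)),
                     row.names = FALSE)
  }
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  structure(
    list(config = config, cities = cities, clim = clim, changes = changes,
         summary_table = summary_tab, exceedances = exceedances,
         scatters = scatters, manifest = manifest, out_dir = out_dir),
    class = "urbheat_run"
  )
}

serialize_config <- function(cfg) {
  x <- unclass(cfg)
  x$target_grid <- unclass(x$target_grid)
  if (!is.null(x$truth)) {
    x$truth <- unclass(x$truth)
    x$truth$model_biases <- as.list(x$truth$model_biases)
  }
  x$models <- lapply(x$models, as.integer)
  x$periods <- lapply(x$periods, as.integer)
  x$out_dir <- NULL
  x
}

#' Ensemble-mean changes averaged over cities
#'
#' The headline quantities of a run: the unweighted mean over cities of the
#' ensemble change in the annual, coldest-month and hottest-month mean
#' temperature, per scenario and future period.
#'
#' @param changes a [changes_table()] result (or an `urbheat_run`).
#' @return `data.frame` with one row per (scenario, period).
#' @export
mean_changes <- function(changes) {
  if (inherits(changes, "urbheat_run")) changes <- changes$changes
  out <- stats::aggregate(
    cbind(d_annual, d_coldest, d_hottest) ~ scenario + period,
    data = changes, FUN = mean
  )
  out[order(out$scenario, out$period), ]
}

#' @export
print.urbheat_run <- function(x, ...) {
  cat(sprintf(
    "<urbheat_run> %d cities, %d models, scenarios %s; outputs in %s\n",
    nrow(x$cities), length(x$config$models),
    paste(x$config$scenarios, collapse = "/"), x$out_dir
  ))
  invisible(x)
}

#' @export
summary.urbheat_run <- function(object, ...) {
  cat("City-mean ensemble changes relative to baseline (degC):\n")
  print(mean_changes(object$changes), row.names = FALSE, digits = 3)
  invisible(object)
}

#' Load a run configuration from a YAML file
#'
#' Reads the subset of [run_config()] fields present in the file; grids may
#' be given as `target_grid: {step: 2}` or full edge/step/count lists.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  simple <- c("synthetic", "n_cities", "scenarios", "baseline_label",
              "regrid_method", "ensemble", "extreme_month", "mask_mode",
              "land_fraction", "noise_sd", "seed", "out_dir", "inputs",
              "exceedance")
  for (k in simple) if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  for (k in c("calibration_window", "sim_years", "ref_years")) {
    if (!is.null(y[[k]])) args[[k]] <- as.integer(unlist(y[[k]]))
  }
  if (!is.null(y$models)) {
    args$models <- lapply(y$models, function(d) as.integer(unlist(d)))
  }
  if (!is.null(y$periods)) {
    args$periods <- lapply(y$periods, function(d) as.integer(unlist(d)))
  }
  if (!is.null(y$target_grid)) {
    tg <- y$target_grid
    args$target_grid <- if (!is.null(tg$step)) global_grid(tg$step)
    else regular_grid(tg$lat_edge_south, tg$lon_edge_west, tg$lat_step,
                      tg$lon_step, tg$n_lat, tg$n_lon)
  }
  if (!is.null(y$truth)) {
    ty <- y$truth
    if (!is.null(ty$model_biases)) ty$model_biases <- unlist(ty$model_biases)
    args$truth <- do.call(synthetic_truth, ty)
  }
  do.call(run_config, args)
}
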