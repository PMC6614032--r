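# Reduction of city monthly series to 30-year period climatologies, the
# multi-model ensemble mean, and changes relative to the baseline period.
# Period labels follow the convention of naming a 30-year window by its last
# year: 2017 = 1988-2017 (baseline), 2050 = 2021-2050, 2100 = 2071-2100.

#' Default 30-year analysis periods
#' @return named list of `c(first_year, last_year)` windows.
#' @export
default_periods <- function() {
  list("2017" = c(1988L, 2017L),
       "2050" = c(2021L, 2050L),
       "2100" = c(2071L, 2100L))
}

monthly_stats <- function(monthly_means) {
  stopifnot(length(monthly_means) == 12L)
  hm <- which.max(monthly_means)  # lowest month index on ties
  cm <- which.min(monthly_means)
  list(
    annual_mean = mean(monthly_means),
    hottest_month = as.integer(hm), hottest_value = monthly_means[[hm]],
    coldest_month = as.integer(cm), coldest_value = monthly_means[[cm]]
  )
}

#' Period climatology of one city series
#'
#' Averages a monthly series over a whole-year window: 12 climatological
#' monthly means, their annual mean (the mean of the 12 values), and the
#' hottest and coldest months (ties go to the earliest month).
#'
#' @param series long-format series for a single city/model/scenario, with
#'   columns `year`, `month`, `tmean_c` (as produced by
#'   [extract_city_series()]).
#' @param period `c(first_year, last_year)`; the series must cover every
#'   month of the window exactly once.
#' @param label period label stored on the result (default `last_year`).
#' @return an object of class `period_climatology`.
#' @export
period_climatology <- function(series, period, label = as.character(period[2])) {
  sel <- series$year >= period[1] & series$year <= period[2]
  sub <- series[sel, , drop = FALSE]
  n_years <- period[2] - period[1] + 1L
  counts <- tabulate(sub$month, 12L)
  if (any(counts != n_years)) {
    stop(sprintf("series does not fully cover %d-%d", period[1], period[2]),
         call. = FALSE)
  }
  mm <- as.numeric(tapply(sub$tmean_c, sub$month, mean))
  st <- monthly_stats(mm)
  structure(
    c(list(
      city_id = series$city_id[1] %||% NA_character_,
      model_id = if ("model_id" %in% names(series)) series$model_id[1] else NA_character_,
      scenario = if ("scenario" %in% names(series)) series$scenario[1] else NA_character_,
      period = as.integer(period), label = label,
      monthly_means = mm, n_models = 1L
    ), st),
    class = "period_climatology"
  )
}

#' @export
print.period_climatology <- function(x, ...) {
  cat(sprintf(
    "<period_climatology> %s %s %s %d-%d: annual %.2f degC, hottest m%d %.2f, coldest m%d %.2f (%d model%s)\n",
    x$city_id, x$model_id, x$scenario, x$period[1], x$period[2],
    x$annual_mean, x$hottest_month, x$hottest_value,
    x$coldest_month, x$coldest_value, x$n_models, if (x$n_models > 1) "s" else ""
  ))
  invisible(x)
}

#' Ensemble mean of per-model period climatologies
#'
#' Averages the 12 climatological monthly means across models (unweighted),
#' then re-derives the annual mean and the hottest/coldest months from the
#' ensemble monthly means. All inputs must share city, scenario and period.
#'
#' @param per_model list of [period_climatology()] objects, one per model.
#' @return a [period_climatology()] with `model_id = "ensemble"`.
#' @export
ensemble_climatology <- function(per_model) {
  stopifnot(length(per_model) >= 1)
  first <- per_model[[1]]
  for (pc in per_model) {
    if (!identical(pc$city_id, first$city_id) ||
        !identical(pc$scenario, first$scenario) ||
        !identical(pc$period, first$period)) {
      stop("ensemble inputs must share city, scenario and period", call. = FALSE)
    }
  }
  mm <- rowMeans(vapply(per_model, `[[`, numeric(12), "monthly_means"))
  st <- monthly_stats(mm)
  structure(
    c(list(
      city_id = first$city_id, model_id = "ensemble",
      scenario = first$scenario, period = first$period, label = first$label,
      monthly_means = mm,
      n_models = sum(vapply(per_model, `[[`, integer(1), "n_models"))
    ), st),
    class = "period_climatology"
  )
}

#' Temperature change between two period climatologies
#'
#' Changes in the annual, hottest-month and coldest-month means of a future
#' period relative to the baseline. By default the hottest and coldest months
#' are identified independently in each period (they may differ between
#' epochs); `fix_baseline_month = TRUE` instead evaluates the future change
#' at the baseline's extreme months.
#'
#' @param baseline,future [period_climatology()] objects for the same city
#'   and scenario; `baseline` must be the baseline period.
#' @param fix_baseline_month logical flag, see above.
#' @return an object of class `change_record` with `d_annual`, `d_hottest`,
#'   `d_coldest`, `abs_hottest_future` (future hottest-month level, degC) and
#'   `seasonal_range_baseline` (baseline hottest minus coldest value).
#' @export
compute_change <- function(baseline, future, fix_baseline_month = FALSE) {
  if (!identical(baseline$city_id, future$city_id) ||
      !identical(baseline$scenario, future$scenario)) {
    stop("baseline and future must share city and scenario", call. = FALSE)
  }
  if (fix_baseline_month) {
    fut_hot <- future$monthly_means[[baseline$hottest_month]]
    fut_cold <- future$monthly_means[[baseline$coldest_month]]
  } else {
    fut_hot <- future$hottest_value
    fut_cold <- future$coldest_value
  }
  structure(
    list(
      city_id = baseline$city_id, scenario = baseline$scenario,
      period = future$label,
      d_annual = future$annual_mean - baseline$annual_mean,
      d_hottest = fut_hot - baseline$hottest_value,
      d_coldest = fut_cold - baseline$coldest_value,
      abs_hottest_future = future$hottest_value,
      seasonal_range_baseline = baseline$hottest_value - baseline$coldest_value,
      n_models = future$n_models
    ),
    class = "change_record"
  )
}

#' @export
print.change_record <- function(x, ...) {
  cat(sprintf(
    "<change_record> %s %s %s: d_annual %+.2f, d_hottest %+.2f, d_coldest %+.2f degC\n",
    x$city_id, x$scenario, x$period, x$d_annual, x$d_hottest, x$d_coldest
  ))
  invisible(x)
}

#' Period climatologies for many series at once
#'
#' Vectorized driver over a long-format series table covering many cities,
#' models and scenarios.
#'
#' @param series long-format series table ([extract_city_series()] output,
#'   possibly row-bound over models/scenarios).
#' @param periods named list of windows, as [default_periods()].
#' @return long-format `data.frame` with columns `city_id`, `model_id`,
#'   `scenario`, `period`, `month`, `tmean_c` (12 rows per group).
#' @export
climatology_table <- function(series, periods = default_periods()) {
  pieces <- lapply(names(periods), function(lbl) {
    win <- periods[[lbl]]
    sel <- series$year >= win[1] & series$year <= win[2]
    sub <- series[sel, , drop = FALSE]
    if (nrow(sub) == 0) {
      stop(sprintf("series does not cover period %s", lbl), call. = FALSE)
    }
    agg <- stats::aggregate(
      tmean_c ~ city_id + model_id + scenario + month,
      data = sub, FUN = mean
    )
    n_years <- win[2] - win[1] + 1L
    cnt <- stats::aggregate(
      tmean_c ~ city_id + model_id + scenario + month,
      data = sub, FUN = length
    )
    if (any(cnt$tmean_c != n_years)) {
      stop(sprintf("incomplete coverage of period %s", lbl), call. = FALSE)
    }
    agg$period <- lbl
    agg
  })
  out <- do.call(rbind, pieces)
  out[, c("city_id", "model_id", "scenario", "period", "month", "tmean_c")]
}

#' Ensemble-mean climatology table
#'
#' Averages climatological monthly means across models for every
#' city/scenario/period/month.
#'
#' @param clim a [climatology_table()] result.
#' @return same format with `model_id = "ensemble"`; the number of models is
#'   recorded in attribute `n_models`.
#' @export
ensemble_table <- function(clim) {
  n_models <- length(unique(clim$model_id))
  agg <- stats::aggregate(
    tmean_c ~ city_id + scenario + period + month, data = clim, FUN = mean
  )
  agg$model_id <- "ensemble"
  out <- agg[, c("city_id", "model_id", "scenario", "period", "month", "tmean_c")]
  attr(out, "n_models") <- n_models
  out
}

# Per-group (12 monthly means) statistics for a climatology table.
clim_stats <- function(clim) {
  key <- interaction(clim$city_id, clim$model_id, clim$scenario, clim$period,
                     drop = TRUE)
  groups <- split(clim, key)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$month), ]
    st <- monthly_stats(g$tmean_c)
    data.frame(
      city_id = g$city_id[1], model_id = g$model_id[1],
      scenario = g$scenario[1], period = g$period[1],
      annual_mean = st$annual_mean,
      hottest_month = st$hottest_month, hottest_value = st$hottest_value,
      coldest_month = st$coldest_month, coldest_value = st$coldest_value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Changes table relative to the baseline period
#'
#' Computes, for every city and scenario, the ensemble change in annual,
#' hottest-month and coldest-month mean temperature of each future period
#' relative to the baseline.
#'
#' @param clim per-model [climatology_table()] result.
#' @param baseline_label label of the baseline period (default `"2017"`).
#' @param ensemble `"before_extremes"` (default): average monthly
#'   climatologies across models first, then identify extreme months and
#'   take changes; `"after_changes"`: compute per-model changes, then average
#'   them across models.
#' @param extreme_month `"per_period"` (default) or `"baseline"`, see
#'   [compute_change()].
#' @return `data.frame` with one row per (city, scenario, future period):
#'   `d_annual`, `d_hottest`, `d_coldest`, `abs_hottest_future`,
#'   `seasonal_range_baseline`, `n_models`.
#' @export
changes_table <- function(clim, baseline_label = "2017",
                          ensemble = c("before_extremes", "after_changes"),
                          extreme_month = c("per_period", "baseline")) {
  ensemble <- match.arg(ensemble)
  extreme_month <- match.arg(extreme_month)
  fix <- extreme_month == "baseline"
  work <- if (ensemble == "before_extremes") ensemble_table(clim) else clim
  n_models <- if (ensemble == "before_extremes") {
    attr(work, "n_models")
  } else {
    length(unique(clim$model_id))
  }
  key <- interaction(work$city_id, work$model_id, work$scenario, drop = TRUE)
  rows <- lapply(split(work, key), function(g) {
    labs <- unique(g$period)
    if (!(baseline_label %in% labs)) {
      stop(sprintf("baseline period '%s' absent for city %s",
                   baseline_label, g$city_id[1]), call. = FALSE)
    }
    mk_pc <- function(lbl) {
      sub <- g[g$period == lbl, ]
      sub <- sub[order(sub$month), ]
      st <- monthly_stats(sub$tmean_c)
      structure(c(list(
        city_id = g$city_id[1], model_id = g$model_id[1],
        scenario = g$scenario[1], period = c(NA_integer_, NA_integer_),
        label = lbl, monthly_means = sub$tmean_c, n_models = 1L
      ), st), class = "period_climatology")
    }
    base <- mk_pc(baseline_label)
    futs <- setdiff(labs, baseline_label)
    do.call(rbind, lapply(futs, function(lbl) {
      ch <- compute_change(base, mk_pc(lbl), fix_baseline_month = fix)
      data.frame(
        city_id = ch$city_id, model_id = g$model_id[1], scenario = ch$scenario,
        period = ch$period, d_annual = ch$d_annual, d_hottest = ch$d_hottest,
        d_coldest = ch$d_coldest, abs_hottest_future = ch$abs_hottest_future,
        seasonal_range_baseline = ch$seasonal_range_baseline,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (ensemble == "after_changes") {
    out <- stats::aggregate(
      cbind(d_annual, d_hottest, d_coldest, abs_hottest_future,
            seasonal_range_baseline) ~ city_id + scenario + period,
      data = out, FUN = mean
    )
  } else {
    out$model_id <- NULL
  }
  out$n_models <- n_models
  out <- out[order(out$city_id, out$scenario, out$period), ]
  rownames(out) <- NULL
  out
}
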