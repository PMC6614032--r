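# Result surfaces: stratified change tables by WHO region and ecoregion
# domain, threshold-exceedance reports, and scatter-style exports of city
# changes against latitude, baseline seasonal range, or log population.

#' Stratified table of ensemble changes
#'
#' Unweighted means of `d_annual`, `d_coldest` and `d_hottest` over the
#' cities of each (WHO region, ecoregion domain) stratum, for every scenario
#' and future period, plus the stratum city count. Cities lacking either
#' stratum attribute are excluded (with a message); empty strata are emitted
#' with count 0 and missing means.
#'
#' @param changes a [changes_table()] result.
#' @param cities a city table with `city_id`, `who_region`,
#'   `ecoregion_domain`.
#' @return `data.frame` of class `summary_table`: one row per
#'   (who_region, ecoregion_domain), a `n_cities` column, and columns
#'   `<scenario>_<period>_<d_annual|d_coldest|d_hottest>`.
#' @export
stratified_table <- function(changes, cities) {
  orphan <- setdiff(unique(changes$city_id), cities$city_id)
  if (length(orphan) > 0) {
    stop(sprintf("change records for unknown cities: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  attrs <- cities[, c("city_id", "who_region", "ecoregion_domain")]
  complete <- !is.na(attrs$who_region) & !is.na(attrs$ecoregion_domain)
  if (any(!complete)) {
    message(sprintf("excluding %d cities lacking stratum attributes",
                    sum(!complete)))
  }
  attrs <- attrs[complete, ]
  merged <- merge(changes, attrs, by = "city_id")
  regions <- sort(unique(cities$who_region[!is.na(cities$who_region)]))
  domains <- sort(unique(cities$ecoregion_domain[!is.na(cities$ecoregion_domain)]))
  out <- expand.grid(who_region = regions, ecoregion_domain = domains,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$who_region, out$ecoregion_domain), ]
  rownames(out) <- NULL
  strat_key <- paste(attrs$who_region, attrs$ecoregion_domain, sep = "|")
  out_key <- paste(out$who_region, out$ecoregion_domain, sep = "|")
  out$n_cities <- as.integer(table(factor(strat_key, levels = out_key)))
  combos <- unique(merged[, c("scenario", "period")])
  combos <- combos[order(combos$scenario, combos$period), ]
  for (r in seq_len(nrow(combos))) {
    sel <- merged$scenario == combos$scenario[r] &
      merged$period == combos$period[r]
    sub <- merged[sel, ]
    sub_key <- paste(sub$who_region, sub$ecoregion_domain, sep = "|")
    for (q in c("d_annual", "d_coldest", "d_hottest")) {
      means <- tapply(sub[[q]], factor(sub_key, levels = out_key), mean)
      col <- paste(combos$scenario[r], combos$period[r], q, sep = "_")
      out[[col]] <- as.numeric(means)
    }
  }
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Threshold-exceedance report
#'
#' Lists, per scenario and future period, the cities whose value of a chosen
#' change quantity passes a cutoff (strict `>` by default, matching
#' "greater than" phrasing; the comparison operator is configurable).
#'
#' @param changes a [changes_table()] result.
#' @param quantity one of the numeric columns of `changes`, e.g.
#'   `"d_hottest"` or `"abs_hottest_future"`.
#' @param cutoff threshold in degC.
#' @param comparison `">"` (default) or `">="`.
#' @param cities optional city table supplying display names (falls back to
#'   `city_id`).
#' @return `data.frame` of class `exceedance_report`: one row per
#'   (scenario, period) with `n` and a semicolon-joined, alphabetically
#'   sorted `cities` column; the threshold definition is kept in attributes.
#' @export
exceedance_report <- function(changes, quantity, cutoff,
                              comparison = c(">", ">="), cities = NULL) {
  comparison <- match.arg(comparison)
  if (!quantity %in% names(changes) || !is.numeric(changes[[quantity]])) {
    stop(sprintf("unknown quantity '%s'", quantity), call. = FALSE)
  }
  nm <- changes$city_id
  if (!is.null(cities)) {
    nm <- cities$name[match(changes$city_id, cities$city_id)]
    nm[is.na(nm)] <- changes$city_id[is.na(nm)]
  }
  hit <- if (comparison == ">") changes[[quantity]] > cutoff
         else changes[[quantity]] >= cutoff
  combos <- unique(changes[, c("scenario", "period")])
  combos <- combos[order(combos$scenario, combos$period), ]
  rows <- lapply(seq_len(nrow(combos)), function(r) {
    sel <- changes$scenario == combos$scenario[r] &
      changes$period == combos$period[r]
    listed <- sort(nm[sel & hit])
    data.frame(
      scenario = combos$scenario[r], period = combos$period[r],
      n = length(listed), cities = paste(listed, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "quantity") <- quantity
  attr(out, "cutoff") <- cutoff
  attr(out, "comparison") <- comparison
  class(out) <- c("exceedance_report", "data.frame")
  out
}

#' Scatter-style export of city changes
#'
#' One row per city with the hottest-month change and a chosen x-axis
#' attribute, for a given scenario and future period. Cities with the x
#' attribute missing are excluded from that export only.
#'
#' @param changes a [changes_table()] result.
#' @param cities city table.
#' @param x_axis `"latitude"`, `"seasonal_range"` (baseline hottest minus
#'   coldest month) or `"log10_population"`.
#' @param period future period label.
#' @param scenario scenario name.
#' @return `data.frame` with `city_id`, `name`, `x`, `d_hottest`,
#'   `ecoregion_domain`.
#' @export
scatter_export <- function(changes, cities,
                           x_axis = c("latitude", "seasonal_range",
                                      "log10_population"),
                           period, scenario) {
  x_axis <- match.arg(x_axis)
  sel <- changes$period == period & changes$scenario == scenario
  sub <- changes[sel, ]
  m <- match(sub$city_id, cities$city_id)
  if (anyNA(m)) stop("change records for unknown cities", call. = FALSE)
  x <- switch(x_axis,
    latitude = cities$lat[m],
    seasonal_range = sub$seasonal_range_baseline,
    log10_population = log10(cities$population[m])
  )
  out <- data.frame(
    city_id = sub$city_id,
    name = cities$name[m],
    x = x,
    d_hottest = sub$d_hottest,
    ecoregion_domain = cities$ecoregion_domain[m],
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$x), ]
  out <- out[order(out$city_id), ]
  rownames(out) <- NULL
  out
}
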