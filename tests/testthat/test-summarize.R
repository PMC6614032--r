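mk_changes <- function(df) {
  need <- c("d_annual", "d_coldest", "d_hottest", "abs_hottest_future",
            "seasonal_range_baseline")
  for (q in setdiff(need, names(df))) df[[q]] <- 1
  df
}

mk_cities <- function(ids, who = "Europe", eco = "dry", lat = 45,
                      population = 1e6) {
  data.frame(
    city_id = ids, name = toupper(ids), lat = lat, lon = 0,
    population = population, gni_stratum = "high", who_region = who,
    ecoregion_domain = eco, stringsAsFactors = FALSE
  )
}

test_that("stratified table averages cities within strata and counts them all", {
  cities <- mk_cities(c("a", "b", "c"),
                      who = c("Europe", "Europe", "Africa"),
                      eco = c("dry", "dry", "polar"))
  changes <- mk_changes(data.frame(
    city_id = c("a", "b", "c"), scenario = "high", period = "2100",
    d_annual = c(1, 3, 5), d_coldest = c(0.5, 1.5, 2),
    d_hottest = c(1.0, 3.0, 4.0), stringsAsFactors = FALSE
  ))
  tab <- stratified_table(changes, cities)
  eu_dry <- tab[tab$who_region == "Europe" & tab$ecoregion_domain == "dry", ]
  expect_equal(eu_dry$n_cities, 2L)
  expect_equal(eu_dry$high_2100_d_annual, 2)      # mean of 1 and 3
  expect_equal(eu_dry$high_2100_d_hottest, 2)     # mean of 1 and 3
  af_polar <- tab[tab$who_region == "Africa" & tab$ecoregion_domain == "polar", ]
  expect_equal(af_polar$high_2100_d_annual, 5)    # single city
  # empty stratum emitted with count 0 and missing means
  af_dry <- tab[tab$who_region == "Africa" & tab$ecoregion_domain == "dry", ]
  expect_equal(af_dry$n_cities, 0L)
  expect_true(is.na(af_dry$high_2100_d_annual))
  # counts sum to the attribute-complete city count
  expect_equal(sum(tab$n_cities), 3L)
})

test_that("cities lacking stratum attributes are excluded but counted", {
  cities <- mk_cities(c("a", "b"))
  cities$who_region[2] <- NA
  changes <- mk_changes(data.frame(
    city_id = c("a", "b"), scenario = "low", period = "2050",
    d_annual = c(1, 2), d_coldest = c(1, 2), d_hottest = c(1, 2),
    stringsAsFactors = FALSE
  ))
  expect_message(tab <- stratified_table(changes, cities), "excluding 1")
  expect_equal(sum(tab$n_cities), 1L)
  # orphan change record errors
  orphan <- mk_changes(data.frame(
    city_id = "ghost", scenario = "low", period = "2050",
    d_annual = 1, d_coldest = 1, d_hottest = 1, stringsAsFactors = FALSE
  ))
  expect_error(stratified_table(orphan, cities), "unknown cities")
})

test_that("exceedance report applies the configured comparison at the boundary", {
  cities <- mk_cities(c("a", "b", "c"))
  changes <- mk_changes(data.frame(
    city_id = c("a", "b", "c"), scenario = "high", period = "2100",
    d_hottest = c(1.9, 2.1, 2.0), d_annual = 1, d_coldest = 1,
    stringsAsFactors = FALSE
  ))
  rep_strict <- exceedance_report(changes, "d_hottest", 2.0, ">", cities)
  expect_equal(rep_strict$n, 1L)
  expect_equal(rep_strict$cities, "B")
  rep_ge <- exceedance_report(changes, "d_hottest", 2.0, ">=", cities)
  expect_equal(sort(strsplit(rep_ge$cities, ";")[[1]]), c("B", "C"))
  # cutoff below everything lists all, above everything lists none
  expect_equal(exceedance_report(changes, "d_hottest", -10, cities = cities)$n, 3L)
  expect_equal(exceedance_report(changes, "d_hottest", 10, cities = cities)$n, 0L)
  expect_error(exceedance_report(changes, "no_such", 1), "unknown quantity")
})

test_that("scatter exports compute the requested x axis and apply exclusions", {
  cities <- mk_cities(c("a", "b"), lat = c(10, 60))
  cities$population <- c(1e6, NA)
  changes <- mk_changes(data.frame(
    city_id = c("a", "b"), scenario = "high", period = "2100",
    d_annual = 1, d_coldest = 1, d_hottest = c(2, 4),
    seasonal_range_baseline = c(5, 25), stringsAsFactors = FALSE
  ))
  pop <- scatter_export(changes, cities, "log10_population", "2100", "high")
  expect_equal(pop$city_id, "a")
  expect_equal(pop$x, 6)     # log10(1,000,000)
  lat <- scatter_export(changes, cities, "latitude", "2100", "high")
  expect_equal(nrow(lat), 2)  # missing population does not exclude here
  expect_equal(lat$x, c(10, 60))
  sr <- scatter_export(changes, cities, "seasonal_range", "2100", "high")
  expect_equal(sr$x, c(5, 25))
})

test_that("summary table round-trips through CSV unchanged", {
  cities <- mk_cities(c("a", "b", "c"),
                      who = c("Europe", "Europe", "Africa"),
                      eco = c("dry", "dry", "polar"))
  changes <- mk_changes(data.frame(
    city_id = rep(c("a", "b", "c"), 2),
    scenario = rep(c("low", "high"), each = 3),
    period = "2100",
    d_annual = c(1.25, 3.5, 5.125, 0.5, 1.5, 2.75),
    d_coldest = 1, d_hottest = 2, stringsAsFactors = FALSE
  ))
  tab <- stratified_table(changes, cities)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), p, row.names = FALSE)
  back <- read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back, as.data.frame(tab))
})
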