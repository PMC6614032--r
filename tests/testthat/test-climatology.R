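test_that("period climatology reduces 30-year windows correctly", {
  s <- make_series(1988, 2017, function(y, m) 20)
  pc <- period_climatology(s, c(1988, 2017))
  expect_equal(pc$monthly_means, rep(20, 12))
  expect_equal(pc$annual_mean, 20)
  expect_equal(pc$hottest_value, 20)
  expect_equal(pc$hottest_month, 1L)  # earliest month on ties
  expect_equal(pc$coldest_month, 1L)

  # monthly means 0..11: annual 5.5, extremes at the ends
  s2 <- make_series(2000, 2000, function(y, m) m - 1)
  pc2 <- period_climatology(s2, c(2000, 2000))
  expect_equal(pc2$monthly_means, 0:11)
  expect_equal(pc2$annual_mean, 5.5)
  expect_equal(pc2$hottest_value, 11)
  expect_equal(pc2$coldest_value, 0)

  expect_error(period_climatology(s, c(1980, 2009)), "cover")
})

test_that("hottest month matches the seasonal closed form for a northern city", {
  g <- global_grid(10)
  tr <- tiny_truth()
  f <- simulate_model_field(g, "low", "m1", tr, years = c(1988, 2017))
  mask <- make_land_mask(g, "all-land")
  cities <- data.frame(city_id = "nh", lat = 52, lon = 7)
  series <- extract_city_series(f, cities, mask, model_id = "m1",
                                scenario = "low")
  pc <- period_climatology(series, c(1988, 2017))
  expect_equal(pc$hottest_month, 7L)  # cosine peak month, northern hemisphere
  cities_s <- data.frame(city_id = "sh", lat = -38, lon = 145)
  pcs <- period_climatology(
    extract_city_series(f, cities_s, mask, model_id = "m1", scenario = "low"),
    c(1988, 2017)
  )
  expect_equal(pcs$hottest_month, 1L)  # phase opposition across the equator
})

test_that("shift equivariance of climatology statistics", {
  set.seed(13)
  base_vals <- matrix(rnorm(360, 15, 8), nrow = 30)
  s <- make_series(1988, 2017, function(y, m) base_vals[y - 1987, m])
  pc <- period_climatology(s, c(1988, 2017))
  s_shift <- s
  s_shift$tmean_c <- s$tmean_c + 2.3
  pcs <- period_climatology(s_shift, c(1988, 2017))
  expect_equal(pcs$annual_mean, pc$annual_mean + 2.3)
  expect_equal(pcs$hottest_value, pc$hottest_value + 2.3)
  expect_equal(pcs$coldest_value, pc$coldest_value + 2.3)
  expect_equal(pcs$hottest_value - pcs$coldest_value,
               pc$hottest_value - pc$coldest_value)
})

test_that("ensemble climatology averages monthly means then re-derives extremes", {
  s1 <- make_series(1988, 2017, function(y, m) m, model_id = "m1")
  s2 <- make_series(1988, 2017, function(y, m) m + 2, model_id = "m2")
  p1 <- period_climatology(s1, c(1988, 2017))
  p2 <- period_climatology(s2, c(1988, 2017))
  ens <- ensemble_climatology(list(p1, p2))
  expect_equal(ens$monthly_means, (1:12) + 1)  # midpoint of a constant offset
  expect_equal(ens$n_models, 2L)
  # all models identical -> ensemble equals any input
  same <- ensemble_climatology(list(p1, p1))
  expect_equal(same$monthly_means, p1$monthly_means)
  expect_equal(same$annual_mean, p1$annual_mean)
  # mixed keys rejected
  s3 <- make_series(1988, 2017, function(y, m) m, city_id = "other")
  expect_error(ensemble_climatology(list(p1, period_climatology(s3, c(1988, 2017)))),
               "share")
})

test_that("changes use per-period extremes by default, baseline month on request", {
  mm_base <- c(5, 6, 8, 12, 18, 22, 25, 24, 20, 14, 9, 6)  # July hottest, 25
  # +2 everywhere except August +4: August becomes the new maximum at 28
  mm_fut <- mm_base + 2
  mm_fut[8] <- mm_base[8] + 4
  mk <- function(mm, years) {
    period_climatology(make_series(years[1], years[2],
                                   function(y, m) mm[m]), years)
  }
  base <- mk(mm_base, c(1988, 2017))
  fut <- mk(mm_fut, c(2071, 2100))
  ch <- compute_change(base, fut)
  expect_equal(base$hottest_month, 7L)
  expect_equal(fut$hottest_month, 8L)
  expect_equal(ch$d_hottest, 28 - 25)
  # fixed-baseline-month alternative evaluates the future at July
  ch_fix <- compute_change(base, fut, fix_baseline_month = TRUE)
  expect_equal(ch_fix$d_hottest, mm_fut[7] - 25)

  # future = baseline -> all changes zero; uniform shift -> all changes c
  z <- compute_change(base, mk(mm_base, c(2071, 2100)))
  expect_equal(c(z$d_annual, z$d_hottest, z$d_coldest), c(0, 0, 0))
  u <- compute_change(base, mk(mm_base + 3, c(2071, 2100)))
  expect_equal(c(u$d_annual, u$d_hottest, u$d_coldest), c(3, 3, 3))
  expect_equal(u$seasonal_range_baseline, 25 - 5)

  other <- mk(mm_base, c(2071, 2100))
  other$city_id <- "someone-else"
  expect_error(compute_change(base, other), "share")
})

test_that("with per-period extremes, d_hottest is at least the change at the baseline's hottest month", {
  set.seed(99)
  for (k in 1:50) {
    mm_base <- rnorm(12, 15, 6)
    mm_fut <- mm_base + rnorm(12, 2, 1)
    mk <- function(mm, years) {
      period_climatology(make_series(years[1], years[2],
                                     function(y, m) mm[m]), years)
    }
    base <- mk(mm_base, c(1988, 2017))
    ch <- compute_change(base, mk(mm_fut, c(2071, 2100)))
    expect_gte(ch$d_hottest,
               mm_fut[base$hottest_month] - mm_base[base$hottest_month] - 1e-12)
  }
})

test_that("ensemble-then-change equals change-then-ensemble for annual means", {
  set.seed(55)
  series <- do.call(rbind, lapply(sprintf("m%d", 1:4), function(mid) {
    vals <- rnorm(200 * 12, 10, 5) + rep(seq(0, 3, length.out = 200), each = 12)
    s <- make_series(1901, 2100, function(y, m) 0, model_id = mid)
    s$tmean_c <- vals
    s
  }))
  clim <- climatology_table(series)
  a <- changes_table(clim, ensemble = "before_extremes")
  b <- changes_table(clim, ensemble = "after_changes")
  expect_equal(a$d_annual, b$d_annual, tolerance = 1e-12)

  # and the orderings agree for hottest-month changes on a noiseless
  # synthetic city (all models share the seasonal shape up to a constant)
  series2 <- do.call(rbind, lapply(1:3, function(k) {
    s <- make_series(1901, 2100, function(y, m) {
      10 * cos(2 * pi * (m - 7) / 12) + 3 * max(0, (y - 1990) / 110) + k
    }, model_id = sprintf("m%d", k))
    s
  }))
  clim2 <- climatology_table(series2)
  a2 <- changes_table(clim2, ensemble = "before_extremes")
  b2 <- changes_table(clim2, ensemble = "after_changes")
  expect_equal(a2$d_hottest, b2$d_hottest, tolerance = 1e-12)
})

test_that("climatology_table validates coverage", {
  s <- make_series(1988, 2016, function(y, m) 1)  # one year short
  expect_error(climatology_table(s, list("2017" = c(1988, 2017))),
               "coverage|cover")
})
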