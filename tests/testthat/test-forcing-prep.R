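test_that("VPD follows the Magnus saturation curve and clips at zero", {
  # independent Magnus evaluation: e_sat(20 C) ~ 2338 Pa
  esat20 <- 610.8 * exp(17.27 * 20 / (20 + 237.3))
  expect_equal(vpd_from_vapour_pressure(20, 10), esat20 - 1000)
  expect_equal(vpd_from_vapour_pressure(20, 10), 1337, tolerance = 2e-3)
  # saturated and supersaturated air give zero deficit, never negative
  expect_equal(vpd_from_vapour_pressure(20, esat20 / 100), 0)
  expect_equal(vpd_from_vapour_pressure(20, 40), 0)
})

test_that("monthly PAR handles polar night and is monotone in sunshine", {
  pole <- site_meta(90, 0, 0)
  expect_equal(monthly_par(pole, 0.5, 12), 0)
  expect_gt(monthly_par(pole, 0.5, 6), 0)
  s <- test_site()
  expect_lt(monthly_par(s, 1, 6), monthly_par(s, 0, 6))
  # elevation increases transmissivity
  expect_gt(monthly_par(test_site(3000), 0.5, 6),
            monthly_par(test_site(0), 0.5, 6))
})

test_that("monthly PAR matches a brute-force quadrature of solar geometry", {
  # oracle: integrate instantaneous TOA irradiance over the day at 1-minute
  # resolution for each day of June, then apply the same transmissivity
  lat <- 34
  phi <- lat * pi / 180
  days <- seq(sum(c(31, 28, 31, 30, 31)) + 1, length.out = 30)
  toa <- 0
  for (doy in days) {
    decl <- (23.45 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
    e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
    hours <- seq(-12, 12, by = 1 / 60) * pi / 12   # hour angle
    cosz <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(hours)
    toa <- toa + sum(pmax(cosz, 0)) * (60) * 1361 * e0  # dt = 60 s
  }
  site <- site_meta(lat, 0, 0)
  oracle <- toa * (0.25 + 0.50 * 1) * 2.04e-6
  expect_equal(monthly_par(site, 0, 6), oracle, tolerance = 0.01)
})

test_that("atmospheric pressure follows the standard atmosphere", {
  expect_equal(atmospheric_pressure(0), 101325)
  # independent evaluation of the barometric formula with 6.5 K/km lapse
  expect_equal(atmospheric_pressure(2630),
               101325 * (1 - 0.0065 * 2630 / 288.15)^5.2559,
               tolerance = 1e-4)
  expect_equal(atmospheric_pressure(2630) / 1000, 73.1, tolerance = 0.01)
  z <- seq(0, 5000, by = 250)
  expect_true(all(diff(atmospheric_pressure(z)) < 0))
})

test_that("moisture index saturates when wet and vanishes when dry", {
  wet <- generate_monthly_climate(synthetic_climate_config(
    n_years = 3, annual_precip = 20000, noise_sd_precip_lognormal = 0))
  expect_equal(moisture_index_alpha(wet), rep(1.26, 36))
  dry <- generate_monthly_climate(synthetic_climate_config(
    n_years = 3, annual_precip = 0, noise_sd_precip_lognormal = 0))
  expect_equal(moisture_index_alpha(dry), rep(0, 36))
})

test_that("doubling precipitation never decreases the moisture index", {
  for (seed in c(2, 9)) {
    f <- generate_monthly_climate(synthetic_climate_config(n_years = 6,
                                                           seed = seed))
    a1 <- moisture_index_alpha(f)
    f2 <- f
    f2$pre <- f2$pre * 2
    a2 <- moisture_index_alpha(f2)
    expect_true(all(a2 - a1 >= -1e-12))
    expect_true(all(a1 >= 0 & a1 <= 1.26))
  }
})

test_that("elevation correction is identity for equal climatologies", {
  f <- generate_monthly_climate(synthetic_climate_config(n_years = 4))
  clim <- data.frame(month = 1:12, tmp = 5, pre = 60, vap = 8, cld = 0.4)
  g <- elevation_correct(f, clim, clim)
  expect_equal(g$tmp, f$tmp)
  expect_equal(g$pre, f$pre)
})

test_that("elevation correction applies additive and ratio adjustments", {
  f <- generate_monthly_climate(synthetic_climate_config(n_years = 4))
  coarse <- data.frame(month = 1:12, tmp = 5, pre = 60)
  fine <- data.frame(month = 1:12, tmp = 2, pre = 60)
  fine$pre[1] <- 90   # January ratio 1.5
  g <- elevation_correct(f, coarse, fine)
  expect_equal(g$tmp, f$tmp - 3)
  jan <- f$month == 1
  expect_equal(g$pre[jan], f$pre[jan] * 1.5)
  expect_equal(g$pre[!jan], f$pre[!jan])
  # zero coarse normal falls back to additive
  coarse$pre[2] <- 0
  fine$pre[2] <- 10
  h <- elevation_correct(f, coarse, fine)
  feb <- f$month == 2
  expect_equal(h$pre[feb], f$pre[feb] + 10)
})

test_that("glacial bias correction shifts by modern minus control exactly", {
  f <- generate_monthly_climate(synthetic_climate_config(n_years = 5))
  pic <- data.frame(month = 1:12, tmp = rnorm(12), vap = runif(12, 5, 10))
  modern <- data.frame(month = 1:12, tmp = pic$tmp + seq(-2, 2, length.out = 12),
                       vap = pic$vap + 0.5)
  g <- bias_correct_lgm(f, pic, modern)
  shift <- (modern$tmp - pic$tmp)[f$month]
  expect_equal(g$tmp - f$tmp, shift)
  expect_equal(g$vap - f$vap, rep(0.5, nrow(f)))
  # identical climatologies leave the series untouched
  h <- bias_correct_lgm(f, pic, pic)
  expect_equal(h$tmp, f$tmp)
  # a control 2 C warmer than modern cools every July by 2 C
  warm <- pic
  warm$tmp[7] <- modern$tmp[7] + 2
  k <- bias_correct_lgm(f, warm, modern)
  jul <- f$month == 7
  expect_equal(k$tmp[jul], f$tmp[jul] - 2)
})

test_that("growing-season threshold is strict at -1 C", {
  expect_equal(growing_season_mask(c(10, -1, -0.9, -1.1)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("accumulation window covers July(y-2) to June(y) and annualises", {
  years <- rep(1948:1952, each = 12)
  months <- rep(1:12, 5)
  # encode year and month so the selected cells are verifiable
  coded <- years * 100 + months
  got <- accumulation_window(coded, years, months, 1950, stat = "mean")
  want_keys <- c(194807:194812, 194901:194912, 195001:195006)
  expect_equal(got, mean(want_keys))
  # constant value, sum mode, annualised: 24 v / 2 = 12 v
  expect_equal(accumulation_window(rep(3, 60), years, months, 1950), 36)
  # first reportable ring year of a series starting 1903
  y2 <- rep(1903:1910, each = 12)
  m2 <- rep(1:12, 8)
  v2 <- rep(1, 96)
  expect_true(is.na(accumulation_window(v2, y2, m2, 1904)))
  expect_false(is.na(accumulation_window(v2, y2, m2, 1905)))
})

test_that("prepared forcing has finite drivers in valid ranges", {
  f <- make_forcing(n_years = 6, seed = 13)
  fp <- prepare_forcing(f)
  expect_true(all(is.finite(fp$vpd)) && all(fp$vpd >= 0))
  expect_true(all(is.finite(fp$par)) && all(fp$par >= 0))
  expect_true(all(fp$alpha >= 0 & fp$alpha <= 1.26))
  expect_type(fp$growing, "logical")
})

test_that("climate tables reject gaps, duplicates and bad ranges", {
  f <- generate_monthly_climate(synthetic_climate_config(n_years = 2))
  tab <- as.data.frame(f)
  expect_error(forcing_series(tab[-18, ], test_site()), "1902-06")
  expect_error(forcing_series(rbind(tab, tab[3, ]), test_site()),
               "duplicate")
  bad <- tab
  bad$cld[1] <- 1.4
  expect_error(forcing_series(bad, test_site()), "cloud")
})
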