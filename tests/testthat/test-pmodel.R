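test_that("compensation point anchors at 25 C and rises with temperature", {
  expect_equal(gammastar(25), 4.331)
  # tangent-at-25 exponential evaluated at 15 C
  expect_equal(gammastar(15), 2.596, tolerance = 2e-3)
  # within 2% of the full Arrhenius response near the anchor
  arrh <- 4.331 * exp(37830 / 8.31446 * (1 / 298.15 - 1 / 288.15))
  expect_lt(abs(gammastar(15) / arrh - 1), 0.02)
  tt <- seq(0, 40, by = 2)
  expect_true(all(diff(gammastar(tt)) > 0))
  # partial pressure scales with atmospheric pressure
  expect_equal(gammastar(25, 50000), 4.331 * 50000 / 101325)
})

test_that("effective K matches the hand evaluation and its monotonicities", {
  # 39.97 * (1 + 0.20946 * 101325 / 27480)
  expect_equal(effective_K(25), 39.97 * (1 + 0.20946 * 101325 / 27480),
               tolerance = 1e-10)
  expect_equal(effective_K(25), 70.8, tolerance = 1e-3)
  tt <- seq(0, 40, by = 1)
  expect_true(all(diff(effective_K(tt)) > 0))
  expect_lt(effective_K(25, atmospheric_pressure(3000)), effective_K(25))
})

test_that("water viscosity ratio is 1 at 25 C and ~2 at 0 C", {
  expect_equal(viscosity_ratio(25), 1)
  # handbook dynamic viscosities: 1.787 / 0.890 mPa s
  expect_equal(viscosity_ratio(0), 1.787 / 0.890, tolerance = 0.01)
  tt <- seq(-5, 40, by = 1)
  expect_true(all(diff(viscosity_ratio(tt)) < 0))
})

test_that("stomatal sensitivity combines costs as expected", {
  k <- effective_K(25)
  g <- gammastar(25)
  expect_equal(xi_sensitivity(25), sqrt(240 * (k + g) / 1.6))
  expect_equal(xi_sensitivity(25), 106, tolerance = 5e-3)
  # beta = 0 collapses ci to the compensation point
  const0 <- p_constants(beta = 0)
  xi0 <- xi_sensitivity(25, constants = const0)
  expect_equal(xi0, 0)
  expect_equal(ci_leaf(30, 800, xi0, g), g)
  # colder temperature lowers xi (viscosity up, K and gammastar down)
  xs <- xi_sensitivity(seq(0, 25, by = 1))
  expect_true(all(diff(xs) > 0))
})

test_that("optimal ci spans its limits and falls with dryness", {
  g <- gammastar(20)
  xi <- xi_sensitivity(20)
  ca <- 30
  expect_equal(ci_leaf(ca, 0, xi, g), ca)
  expect_equal(ci_leaf(g, 500, xi, g), g)
  d <- seq(0, 4000, by = 100)
  ci <- ci_leaf(ca, d, xi, g)
  expect_true(all(diff(ci) < 0))
  expect_true(all(ci >= g & ci <= ca))
})

test_that("CO2 limitation factor hits its algebraic landmarks", {
  g <- 4.331
  expect_equal(co2_limitation(g, g), 0)
  expect_equal(co2_limitation(4 * g, g), 0.5)
  expect_gt(co2_limitation(1e6, g), 0.999)
  expect_equal(co2_limitation(1, g), 0)  # below compensation floors at 0
})

test_that("ci stays between the compensation point and ambient in full runs", {
  for (seed in c(1, 21)) {
    f <- make_forcing(n_years = 5, seed = seed, co2 = 180 + 100 * (seed == 21))
    pm <- run_pmodel(f)
    expect_true(all(pm$ci >= pm$gammastar - 1e-12))
    expect_true(all(pm$ci <= pm$ca_pa + 1e-12))
    expect_true(all(pm$m >= 0 & pm$m < 1))
    expect_true(all(pm$gpp >= 0))
  }
})

test_that("ci/ca rises with temperature and falls with VPD", {
  ca <- 25
  cica <- function(temp, vpd) {
    g <- gammastar(temp)
    ci_leaf(ca, vpd, xi_sensitivity(temp), g) / ca
  }
  tt <- seq(0, 30, by = 2)
  expect_true(all(diff(vapply(tt, cica, numeric(1), vpd = 800)) > 0))
  dd <- seq(100, 3000, by = 100)
  expect_true(all(diff(vapply(dd, cica, numeric(1), temp = 15)) < 0))
})

test_that("GPP is non-decreasing in CO2, PAR and moisture", {
  f <- prepare_forcing(make_forcing(n_years = 4, seed = 3))
  gpp_at <- function(ppm) sum(run_pmodel(f, ca_ppm = ppm)$gpp)
  expect_true(all(diff(vapply(c(180, 240, 320, 400), gpp_at,
                              numeric(1))) > 0))
  # moisture: rescale the alpha driver directly
  f2 <- f
  f2$alpha <- pmin(f$alpha * 0.5, 1.26)
  expect_lte(sum(run_pmodel(f2, ca_ppm = 300)$gpp),
             sum(run_pmodel(f, ca_ppm = 300)$gpp))
  # beta = 0 shuts photosynthesis off entirely
  expect_equal(sum(run_pmodel(f, p_constants(beta = 0), ca_ppm = 300)$gpp), 0)
})

test_that("the drought factor enters as (alpha/1.26)^(1/4)", {
  f <- prepare_forcing(make_forcing(n_years = 3, seed = 5))
  f1 <- f
  f1$alpha <- rep(1.26, nrow(f))
  f2 <- f
  f2$alpha <- rep(0.6, nrow(f))
  g1 <- run_pmodel(f1, ca_ppm = 300)$gpp
  g2 <- run_pmodel(f2, ca_ppm = 300)$gpp
  keep <- g1 > 0
  expect_equal(g2[keep] / g1[keep],
               rep((0.6 / 1.26)^0.25, sum(keep)))
})

test_that("glacial CO2 raises carboxylation capacity and conductance", {
  f <- prepare_forcing(make_forcing(n_years = 10, seed = 12))
  lo <- annual_pmodel_summary(run_pmodel(f, ca_ppm = 180))
  hi <- annual_pmodel_summary(run_pmodel(f, ca_ppm = 320))
  expect_gt(mean(lo$vcmax25), mean(hi$vcmax25))
  expect_gt(mean(lo$gs), mean(hi$gs))
  # Fick consistency: gs * (ca - ci)/patm = 1.6 * A
  pm <- run_pmodel(f, ca_ppm = 300)
  grow <- pm$growing & pm$gpp > 0
  expect_equal(pm$gs[grow] * (pm$ca_pa[grow] - pm$ci[grow]) /
                 atmospheric_pressure(2630),
               1.6 * pm$gpp[grow] / 12, tolerance = 1e-10)
})

test_that("isotope discrimination converts linearly to ci/ca", {
  expect_equal(cica_from_discrimination(4.4), 0)
  expect_equal(cica_from_discrimination(27), 1)
  expect_equal(cica_from_discrimination(15.9), (15.9 - 4.4) / 22.6)
  expect_warning(cica_from_discrimination(35), "range")
})

test_that("annual ci/ca weighting behaves across degenerate weights", {
  expect_equal(annual_cica(rep(0.55, 6), runif(6)), 0.55)
  expect_equal(annual_cica(c(0.4, 0.6, 0.8), c(0, 1, 0)), 0.6)
  expect_equal(annual_cica(c(0.4, 0.6), c(2, 2)), 0.5)
  expect_equal(annual_cica(c(0.4, 0.6), c(0, 0)), 0.5)
})
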