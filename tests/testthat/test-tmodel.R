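test_that("height-diameter curve has slope a at the origin and asymptote h_max", {
  p <- species_params()
  expect_equal(height_from_diameter(0, p), 0)
  expect_equal(height_from_diameter(1e6, p), p$h_max)
  d_small <- 1e-5   # a*d/h_max ~ 5e-5
  expect_equal(height_from_diameter(d_small, p) / (p$a * d_small), 1,
               tolerance = 1e-3)
  expect_true(all(diff(height_from_diameter(seq(0, 2, 0.05), p)) > 0))
})

test_that("crown area reduces to c_ratio times stem section for small trees", {
  p <- species_params()
  expect_equal(crown_area(0, 0, p), 0)
  d <- 1e-5
  h <- height_from_diameter(d, p)
  expect_equal(crown_area(d, h, p) / (pi * d^2 / 4), p$c_ratio,
               tolerance = 1e-3)
  p2 <- species_params(c_ratio = 2 * p$c_ratio)
  expect_equal(crown_area(0.3, 10, p2), 2 * crown_area(0.3, 10, p))
})

test_that("biomass pools follow the stated allometries", {
  p <- species_params(rho_s = 205)
  d <- 0.3
  b <- biomass_pools(d, p)
  h <- p$h_max * (1 - exp(-p$a * d / p$h_max))   # independent evaluation
  expect_equal(b$w_stem, pi / 8 * 205 * d^2 * h)
  expect_equal(b$w_foliage, b$crown_area * p$lai / p$sla)
  expect_equal(b$w_root, p$zeta * b$crown_area * p$lai)
  # zeta scales roots only
  p2 <- species_params(rho_s = 205, zeta = 2 * p$zeta)
  b2 <- biomass_pools(d, p2)
  expect_equal(b2$w_root, 2 * b$w_root)
  expect_equal(b2$w_stem, b$w_stem)
  expect_equal(b2$w_foliage, b$w_foliage)
})

test_that("fAPAR obeys Beer's law and stays below one", {
  expect_equal(fapar(0, 0.5), 0)
  expect_equal(fapar(2, 0.5), 1 - exp(-1))
  expect_true(all(fapar(seq(0, 50, 0.5), 0.5) < 1))
})

test_that("NPP accounting collapses correctly in limiting cases", {
  p <- species_params()
  expect_equal(npp_annual(0, 0.3, p), 0)
  # yield 1, negligible respiration: NPP equals whole-tree GPP
  p1 <- species_params(yield = 1, r_s = 1e-12, r_r = 1e-12,
                       foliage_resp_frac = 1e-12)
  b <- biomass_pools(0.3, p1)
  p_tree <- 2 * fapar(p1$lai, p1$k_ext) * b$crown_area
  expect_equal(npp_annual(2, 0.3, p1), p_tree, tolerance = 1e-9)
  # respiration rates strictly reduce NPP
  expect_lt(npp_annual(2, 0.3, species_params(r_r = 1.2)),
            npp_annual(2, 0.3, p))
  expect_lt(npp_annual(2, 0.3, species_params(r_s = 0.1)),
            npp_annual(2, 0.3, p))
})

test_that("diameter increment solves the exact mass balance", {
  p <- species_params()
  d <- 0.3
  b <- biomass_pools(d, p)
  turnover <- b$w_foliage / p$tau_f + b$w_root / p$tau_r
  expect_equal(diameter_increment(turnover, d, p), 0)
  # independent bisection oracle on the exact mass balance
  oracle <- function(npp) {
    f <- function(dd) {
      b1 <- biomass_pools(d + dd, p)
      (b1$w_stem + b1$w_foliage + b1$w_root) -
        (b$w_stem + b$w_foliage + b$w_root) + turnover - npp
    }
    stats::uniroot(f, c(0, 1), tol = 1e-14)$root
  }
  npps <- turnover + c(1, 5, 20, 60)
  for (npp in npps) {
    dd <- diameter_increment(npp, d, p)
    expect_equal(dd, oracle(npp), tolerance = 1e-8)
  }
  # increments grow with NPP
  dds <- vapply(npps, diameter_increment, numeric(1), d = d, params = p)
  expect_true(all(diff(dds) > 0))
})

test_that("the one-step linearised increment agrees with the solver for small rings", {
  p <- species_params()
  d <- 0.3
  b <- biomass_pools(d, p)
  turnover <- b$w_foliage / p$tau_f + b$w_root / p$tau_r
  # NPP levels giving realistic rings (a fraction of a mm up to ~1 mm)
  for (npp in turnover + c(0.5, 1, 2)) {
    exact <- diameter_increment(npp, d, p, method = "exact")
    lin <- diameter_increment(npp, d, p, method = "linear")
    expect_lt(exact / d, 0.05)
    expect_lt(abs(lin / exact - 1), 0.01)
  }
})

test_that("allocation fractions sum to one and shift with zeta", {
  p <- species_params()
  npp <- 20
  dd <- diameter_increment(npp, 0.3, p)
  fr <- allocation_fractions(npp, 0.3, dd, p)
  expect_equal(unname(sum(fr)), 1, tolerance = 1e-9)
  f_root <- vapply(c(0.1, 0.2, 0.4), function(z) {
    pz <- species_params(zeta = z)
    ddz <- diameter_increment(npp, 0.3, pz)
    allocation_fractions(npp, 0.3, ddz, pz)[["f_root"]]
  }, numeric(1))
  expect_true(all(diff(f_root) > 0))
  expect_true(all(is.na(allocation_fractions(0, 0.3, 0, p))))
})

test_that("no light means no growth", {
  g <- data.frame(year = 2001:2010, gpp = 0)
  sim <- grow_tree(g, species_params())
  expect_equal(sim$rw_mm, rep(0, 10))
  expect_equal(sim$diameter, rep(0.3, 10))
})

test_that("constant climate drives rings smoothly to a stable asymptote", {
  f <- make_forcing(n_years = 40, noise_sd_temp = 0,
                    noise_sd_precip_lognormal = 0)
  sim <- simulate_growth(f)
  expect_true(all(sim$rw_mm >= 0))
  expect_gt(sim$rw_mm[1], 0)
  # smooth concave approach: increments positive but steadily shrinking
  inc <- diff(sim$rw_mm)
  expect_true(all(inc > 0))
  expect_true(all(diff(inc) < 0))
  expect_lt(inc[length(inc)], inc[1] / 4)
})

test_that("doubling CO2 widens every ring", {
  f180 <- make_forcing(n_years = 15, seed = 4, co2 = 180)
  f360 <- make_forcing(n_years = 15, seed = 4, co2 = 360)
  lo <- simulate_growth(f180)
  hi <- simulate_growth(f360)
  expect_true(all(hi$rw_mm > lo$rw_mm))
})

test_that("each simulated year closes the carbon balance and the ring sum telescopes", {
  f <- make_forcing(n_years = 25, seed = 10)
  sim <- simulate_growth(f, d0 = 0.25)
  expect_true(all(sim$rw_mm > 0))
  expect_true(all(sim$balance_resid < 1e-6, na.rm = TRUE))
  expect_equal(2 * sum(sim$rw_mm) / 1000, sim$diameter[nrow(sim)] - 0.25,
               tolerance = 1e-12)
})

test_that("the batch forward equals per-tree simulation", {
  f <- prepare_forcing(make_forcing(n_years = 15, seed = 2))
  pm <- run_pmodel(f)
  g <- window_gpp(pm, sort(unique(f$year)))
  g <- g[!is.na(g$gpp), ]
  p <- species_params()
  combos <- rbind(c(1.8, 0.17), c(0.9, 0.35), c(3.2, 0.08))
  batch <- ptgrowth:::grow_mean_rw_batch(g$gpp, p, combos[, 1], combos[, 2])
  for (i in 1:3) {
    pi_ <- species_params(lai = combos[i, 1], zeta = combos[i, 2])
    expect_equal(batch[i], mean(grow_tree(g, pi_)$rw_mm), tolerance = 1e-12)
  }
})
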