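#' Percentage change relative to a baseline
#'
#' @param baseline Baseline value (non-zero).
#' @param experiment Experiment value.
#' @return `100 * (experiment - baseline) / baseline`.
#' @export
percent_change <- function(baseline, experiment) {
  if (any(baseline == 0)) stop("baseline must be non-zero")
  100 * (experiment - baseline) / baseline
}

#' Validate simulated growth against an observed ring-width series
#'
#' Simulates ring widths under the supplied forcing and compares them with
#' the observed series over the overlapping years: mean widths, Pearson
#' correlation of the annual values, and correlation of 10-year running
#' means (the decadal-trend comparison).
#'
#' @param forcing A [forcing_series()] with CO2 attached.
#' @param observed A [ring_series()].
#' @param params A [species_params()].
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @param smooth_years Width of the running mean for the trend comparison.
#' @return List with `n_overlap`, `mean_sim`, `mean_obs`, `mean_diff`,
#'   `correlation`, `correlation_p`, `correlation_smoothed` (NA when a
#'   series is constant), and the merged annual table.
#' @export
run_modern_validation <- function(forcing, observed,
                                  params = species_params(), d0 = 0.3,
                                  constants = p_constants(),
                                  smooth_years = 10) {
  stopifnot(inherits(observed, "ring_series"))
  sim <- simulate_growth(forcing, params, d0, constants)
  merged <- merge(data.frame(year = sim$year, sim = sim$rw_mm),
                  data.frame(year = observed$year, obs = observed$rw_mm),
                  by = "year")
  if (nrow(merged) < 10) stop("fewer than 10 overlapping years")
  const <- sd(merged$sim) == 0 || sd(merged$obs) == 0
  r <- if (const) NA_real_ else cor(merged$sim, merged$obs)
  p <- if (const) NA_real_ else
    stats::cor.test(merged$sim, merged$obs)$p.value
  roll <- function(x) {
    as.numeric(stats::filter(x, rep(1 / smooth_years, smooth_years),
                             sides = 2))
  }
  ss <- roll(merged$sim)
  so <- roll(merged$obs)
  ok <- !is.na(ss) & !is.na(so)
  r_s <- if (const || sum(ok) < 3 || sd(ss[ok]) == 0 || sd(so[ok]) == 0) {
    NA_real_
  } else {
    cor(ss[ok], so[ok])
  }
  list(n_overlap = nrow(merged),
       mean_sim = mean(merged$sim), mean_obs = mean(merged$obs),
       mean_diff = mean(merged$sim) - mean(merged$obs),
       correlation = r, correlation_p = p,
       correlation_smoothed = r_s,
       annual = merged)
}

per_year_cica <- function(pm) {
  years <- sort(unique(pm$year))
  vapply(years, function(y) {
    g <- pm[pm$year == y & pm$growing, , drop = FALSE]
    if (nrow(g) == 0) return(NA_real_)
    annual_cica(g$cica, g$gpp)
  }, numeric(1))
}

#' ci/ca elevation profile across sites
#'
#' Recomputes the annual GPP-weighted ci/ca for each site by transposing
#' one base forcing series to the site elevation: atmospheric pressure and
#' PAR transmissivity respond to elevation, and temperature is optionally
#' shifted by a lapse rate (vapour pressure is held, so humidity rises as
#' temperature falls). Reports the mean and a two-standard-deviation
#' interannual band per site.
#'
#' @param sites List of [site_meta()] objects.
#' @param forcing A [forcing_series()] with CO2 attached (the base site).
#' @param lapse_rate Temperature lapse rate, degrees C per m (0 disables
#'   the temperature adjustment).
#' @param constants A [p_constants()] list.
#' @return Data frame with one row per site: `elevation`, `cica`,
#'   `cica_lo`, `cica_hi` (mean plus/minus 2 SD), `gpp` (mean annual,
#'   kg C m-2 a-1).
#' @export
run_cica_profile <- function(sites, forcing, lapse_rate = 0,
                             constants = p_constants()) {
  stopifnot(is.list(sites), length(sites) >= 1,
            all(vapply(sites, inherits, logical(1), "site_meta")))
  base_elev <- attr(forcing, "site")$elevation
  rows <- lapply(sites, function(s) {
    f <- forcing
    f$tmp <- f$tmp - lapse_rate * (s$elevation - base_elev)
    attr(f, "site") <- s
    attr(f, "prepared") <- NULL
    f <- prepare_forcing(f, constants)
    pm <- run_pmodel(f, constants)
    cc <- per_year_cica(pm)
    ann <- annual_pmodel_summary(pm)
    data.frame(elevation = s$elevation,
               cica = mean(cc, na.rm = TRUE),
               cica_lo = mean(cc, na.rm = TRUE) - 2 * sd(cc, na.rm = TRUE),
               cica_hi = mean(cc, na.rm = TRUE) + 2 * sd(cc, na.rm = TRUE),
               gpp = mean(ann$gpp))
  })
  do.call(rbind, rows)
}

#' Temperature/VPD swap experiment for ci/ca
#'
#' Computes the annual ci/ca under four scenarios: full glacial, modern
#' temperature with glacial VPD, glacial temperature with modern VPD, and
#' both modern (temperature and VPD are the only two climate variables
#' that enter the ci/ca calculation). PAR, the moisture index and ambient
#' CO2 are held at the glacial baseline in all four scenarios; the
#' growing-season mask and the temperature responses follow the active
#' temperature.
#'
#' @param modern,glacial Prepared [forcing_series()] for the same site, of
#'   equal length (longer series are truncated to the common length by
#'   position).
#' @param constants A [p_constants()] list.
#' @param ca_ppm Ambient CO2 for all scenarios (default: the glacial CO2
#'   series mean).
#' @return Data frame with columns `scenario` (`glacial`,
#'   `modernT_glacialVPD`, `glacialT_modernVPD`, `modern`) and `cica`.
#' @export
run_cica_swap <- function(modern, glacial, constants = p_constants(),
                          ca_ppm = NULL) {
  stopifnot(inherits(modern, "forcing_series"),
            inherits(glacial, "forcing_series"))
  if (!is_prepared(modern)) modern <- prepare_forcing(modern, constants)
  if (!is_prepared(glacial)) glacial <- prepare_forcing(glacial, constants)
  if (is.null(ca_ppm)) {
    co2 <- attr(glacial, "co2")
    if (is.null(co2)) stop("glacial forcing has no CO2 series; give ca_ppm")
    ca_ppm <- mean(co2$ppm)
  }
  patm <- atmospheric_pressure(attr(glacial, "site")$elevation)
  n <- min(nrow(modern), nrow(glacial))
  modern <- as.data.frame(modern)[seq_len(n), ]
  glacial <- as.data.frame(glacial)[seq_len(n), ]
  ca <- ca_ppm * 1e-6 * patm
  scen <- function(temp, vpd) {
    gs <- gammastar(temp, patm, constants)
    xi <- xi_sensitivity(temp, patm, constants)
    ci <- ci_leaf(ca, vpd, xi, gs)
    m <- co2_limitation(ci, gs)
    drought <- (pmin(glacial$alpha, constants$drought_ref_alpha) /
                  constants$drought_ref_alpha)^constants$drought_exponent
    grow <- growing_season_mask(temp)
    gpp <- ifelse(grow, constants$phi0 * glacial$par * m * drought, 0)
    yrs <- glacial$year
    cc <- vapply(sort(unique(yrs)), function(y) {
      i <- which(yrs == y & grow)
      if (length(i) == 0) return(NA_real_)
      annual_cica(ci[i] / ca, gpp[i])
    }, numeric(1))
    mean(cc, na.rm = TRUE)
  }
  data.frame(
    scenario = c("glacial", "modernT_glacialVPD", "glacialT_modernVPD",
                 "modern"),
    cica = c(scen(glacial$tmp, glacial$vpd),
             scen(modern$tmp, glacial$vpd),
             scen(glacial$tmp, modern$vpd),
             scen(modern$tmp, modern$vpd)))
}

#' Allocation parameters along a CO2 gradient
#'
#' Calls [optimize_allocation()] at each CO2 level under the glacial
#' forcing, holding all other parameters fixed, and reports the optimised
#' leaf area index and fine-root to leaf-area ratio together with their
#' percentage change relative to the reference level (320 ppm when
#' present, otherwise the highest level). Failures at individual levels
#' yield `NA` rows with a warning rather than aborting the gradient.
#'
#' @param forcing_glacial A [forcing_series()] (glacial climate).
#' @param target_rw Target mean ring width, mm.
#' @param params A [species_params()] (modern calibrated set).
#' @param levels CO2 levels, ppm.
#' @param config An [abc_config()].
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @return Data frame per level: `co2`, `lai`, `zeta`, `acceptance_rate`,
#'   `lai_pct`, `zeta_pct`.
#' @export
run_co2_gradient <- function(forcing_glacial, target_rw,
                             params = species_params(),
                             levels = seq(320, 160, by = -20),
                             config = abc_config(),
                             d0 = 0.3, constants = p_constants()) {
  if (!is_prepared(forcing_glacial)) {
    forcing_glacial <- prepare_forcing(forcing_glacial, constants)
  }
  rows <- lapply(levels, function(lev) {
    res <- tryCatch(
      optimize_allocation(forcing_glacial, lev, target_rw, params,
                          config, d0, constants),
      error = function(e) {
        warning(sprintf("CO2 level %g ppm failed: %s", lev,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(res)) {
      data.frame(co2 = lev, lai = NA_real_, zeta = NA_real_,
                 acceptance_rate = NA_real_)
    } else {
      data.frame(co2 = lev, lai = res$lai, zeta = res$zeta,
                 acceptance_rate = res$abc$acceptance_rate)
    }
  })
  out <- do.call(rbind, rows)
  ref <- if (320 %in% out$co2) which(out$co2 == 320) else
    which.max(out$co2)
  out$lai_pct <- percent_change(out$lai[ref], out$lai)
  out$zeta_pct <- percent_change(out$zeta[ref], out$zeta)
  out
}

## diagnose relative humidity (fraction) of a forcing series
relative_humidity <- function(series) {
  pmin(pmax(series$vap * 100 / esat_pa(series$tmp), 0), 1)
}

#' Climate-variable substitution sensitivity experiments
#'
#' Reruns the growth simulation under the glacial baseline with modern
#' values substituted for individual climate variables or combinations,
#' holding everything else (including CO2) at glacial values. The state
#' variables are temperature, precipitation and relative humidity; vapour
#' pressure is recomputed from the active humidity and temperature.
#' Experiments: `H` (modern relative humidity), `P` (modern
#' precipitation), `T` (modern temperature), `TP`, `TPH`, and `Full`
#' (all climate variables modern, including diurnal range and cloud; only
#' CO2 stays glacial).
#'
#' @param glacial A [forcing_series()] with glacial CO2 attached (the
#'   baseline).
#' @param modern A [forcing_series()] for the same site; both series are
#'   truncated to their common length by position.
#' @param params A [species_params()] (the glacial-optimised set).
#' @param experiments Character vector among `H`, `P`, `T`, `TP`, `TPH`,
#'   `Full`.
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @return Data frame per experiment (baseline first): `experiment`,
#'   `mean_rw` (mm), `pct_change` versus the glacial baseline.
#' @export
run_climate_substitution <- function(glacial, modern,
                                     params = species_params(),
                                     experiments = c("H", "P", "T", "TP",
                                                     "TPH", "Full"),
                                     d0 = 0.3,
                                     constants = p_constants()) {
  stopifnot(inherits(glacial, "forcing_series"),
            inherits(modern, "forcing_series"))
  experiments <- match.arg(experiments, several.ok = TRUE)
  n <- min(nrow(glacial), nrow(modern))
  co2 <- attr(glacial, "co2")
  site <- attr(glacial, "site")
  g <- drop_derived(glacial)[seq_len(n), ]
  m <- drop_derived(modern)[seq_len(n), ]
  subs <- list(baseline = character(0),
               H = "rh", P = "pre", T = "tmp",
               TP = c("tmp", "pre"), TPH = c("tmp", "pre", "rh"),
               Full = c("tmp", "pre", "rh", "dtr", "cld"))
  build <- function(vars) {
    rh <- if ("rh" %in% vars) relative_humidity(m) else relative_humidity(g)
    out <- g
    if ("tmp" %in% vars) out$tmp <- m$tmp
    if ("pre" %in% vars) out$pre <- m$pre
    if ("dtr" %in% vars) out$dtr <- m$dtr
    if ("cld" %in% vars) out$cld <- m$cld
    out$vap <- rh * esat_pa(out$tmp) / 100
    forcing_series(out, site = site, co2 = co2)
  }
  run_one <- function(vars) {
    mean(simulate_growth(build(vars), params, d0, constants)$rw_mm)
  }
  base_rw <- run_one(character(0))
  rows <- lapply(experiments, function(e) {
    rw <- run_one(subs[[e]])
    data.frame(experiment = e, mean_rw = rw,
               pct_change = percent_change(base_rw, rw))
  })
  rbind(data.frame(experiment = "glacial", mean_rw = base_rw,
                   pct_change = 0),
        do.call(rbind, rows))
}

#' Accumulation-window regression diagnostic
#'
#' For each candidate window length (months ending in June of the ring
#' year), accumulates the five climate drivers — total PAR, mean
#' temperature, mean moisture index alpha, mean VPD and mean CO2 — and
#' fits an ordinary least-squares multiple regression of ring width on
#' them. The window maximising R-squared is flagged; the two-year window
#' is expected to win for rings formed by the two-year carbon accumulation
#' treatment. A high condition number of the predictor matrix triggers a
#' collinearity warning but the fit is still reported.
#'
#' @param observed A [ring_series()].
#' @param forcing A prepared [forcing_series()] with CO2 attached.
#' @param windows Candidate window lengths in months.
#' @param constants A [p_constants()] list.
#' @return List with `table` (data frame `window`, `r_squared`, `n`,
#'   `best`) and `fits` (the `lm` objects, named by window).
#' @export
accumulation_window_regression <- function(observed, forcing,
                                           windows = c(12, 24, 36),
                                           constants = p_constants()) {
  stopifnot(inherits(observed, "ring_series"), length(windows) >= 1)
  if (!is_prepared(forcing)) forcing <- prepare_forcing(forcing, constants)
  co2_monthly <- co2_for_years(forcing, forcing$year)
  acc <- function(values, ring_years, w, stat) {
    accumulation_window(values, forcing$year, forcing$month, ring_years,
                        stat = stat, window_months = w)
  }
  ## restrict to ring years for which the longest window is complete
  wmax <- max(windows)
  candidate <- observed$year
  complete <- !is.na(acc(forcing$tmp, candidate, wmax, "mean"))
  years <- candidate[complete]
  if (length(years) < 20) stop("fewer than 20 usable overlapping years")
  rw <- observed$rw_mm[match(years, observed$year)]
  fits <- list()
  rows <- lapply(windows, function(w) {
    df <- data.frame(
      rw = rw,
      par = acc(forcing$par, years, w, "sum"),
      mat = acc(forcing$tmp, years, w, "mean"),
      alpha = acc(forcing$alpha, years, w, "mean"),
      vpd = acc(forcing$vpd, years, w, "mean"),
      co2 = acc(co2_monthly, years, w, "mean"))
    x <- as.matrix(df[, -1])
    varying <- apply(x, 2, sd) > 0
    if (sum(varying) >= 2 &&
        kappa(cbind(1, scale(x[, varying, drop = FALSE]))) > 1e8) {
      warning(sprintf("window %d: predictors nearly collinear", w))
    }
    fit <- lm(rw ~ par + mat + alpha + vpd + co2, data = df)
    fits[[as.character(w)]] <<- fit
    data.frame(window = w, r_squared = summary(fit)$r.squared,
               n = length(years))
  })
  table <- do.call(rbind, rows)
  table$best <- table$r_squared == max(table$r_squared)
  list(table = table, fits = fits)
}
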