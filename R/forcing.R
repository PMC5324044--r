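#' Site metadata
#'
#' @param latitude Latitude in decimal degrees (positive north).
#' @param longitude Longitude in decimal degrees (positive east).
#' @param elevation Elevation in metres above sea level.
#'
#' @return An object of class `site_meta`.
#' @examples
#' site_meta(36.95, -118.92, 2630)
#' @export
site_meta <- function(latitude, longitude, elevation) {
  stopifnot(is.finite(latitude), is.finite(longitude), is.finite(elevation))
  if (abs(latitude) > 90) stop("latitude must be in [-90, 90]")
  if (elevation < -500 || elevation > 9000) {
    stop("elevation outside plausible range (-500..9000 m)")
  }
  structure(list(latitude = latitude, longitude = longitude,
                 elevation = elevation),
            class = "site_meta")
}

#' Monthly climate forcing series
#'
#' Bundles a gap-free monthly climate table with site metadata and an
#' optional annual CO2 series. This is the single input currency of the
#' simulation pipeline; derived drivers (VPD, PAR, moisture index, growing
#' season) are added by [prepare_forcing()].
#'
#' @param climate Data frame with columns `year`, `month` (1-12), `tmp`
#'   (mean temperature, degrees C), `dtr` (diurnal temperature range,
#'   degrees C), `pre` (precipitation, mm), `vap` (vapour pressure, hPa),
#'   `cld` (cloud fraction, 0-1).
#' @param site A [site_meta()] object.
#' @param co2 Optional data frame with columns `year`, `ppm`.
#'
#' @return An object of class `forcing_series` (a data frame with `site`
#'   and `co2` attributes).
#' @export
forcing_series <- function(climate, site, co2 = NULL) {
  required <- c("year", "month", "tmp", "dtr", "pre", "vap", "cld")
  missing_cols <- setdiff(required, names(climate))
  if (length(missing_cols) > 0) {
    stop("climate table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  climate <- as.data.frame(climate)[required]
  for (v in required) {
    if (!is.numeric(climate[[v]]) || anyNA(climate[[v]]) ||
        any(!is.finite(climate[[v]]))) {
      stop("column '", v, "' must be finite numeric without gaps")
    }
  }
  if (any(climate$month < 1 | climate$month > 12 |
          climate$month != round(climate$month))) {
    stop("month must be an integer in 1..12")
  }
  climate <- climate[order(climate$year, climate$month), , drop = FALSE]
  rownames(climate) <- NULL
  key <- climate$year * 12L + climate$month
  if (anyDuplicated(key)) {
    dup <- climate[duplicated(key), c("year", "month")][1, ]
    stop(sprintf("duplicate month %04d-%02d", dup$year, dup$month))
  }
  full <- seq(min(key), max(key))
  gap <- setdiff(full, key)
  if (length(gap) > 0) {
    lab <- sprintf("%04d-%02d", (gap - 1) %/% 12, (gap - 1) %% 12 + 1)
    stop("gaps in monthly series: ", paste(lab, collapse = ", "))
  }
  if (any(climate$pre < 0)) stop("precipitation must be >= 0")
  if (any(climate$vap < 0)) stop("vapour pressure must be >= 0")
  if (any(climate$cld < 0 | climate$cld > 1)) stop("cloud fraction must be in [0, 1]")
  if (any(abs(climate$tmp) > 70)) stop("temperature outside plausible range")
  stopifnot(inherits(site, "site_meta"))
  structure(climate, site = site, co2 = validate_co2(co2),
            class = c("forcing_series", "data.frame"))
}

validate_co2 <- function(co2) {
  if (is.null(co2)) return(NULL)
  stopifnot(all(c("year", "ppm") %in% names(co2)))
  co2 <- as.data.frame(co2)[c("year", "ppm")]
  if (any(co2$ppm <= 0) || anyNA(co2$ppm)) stop("CO2 levels must be positive")
  if (anyDuplicated(co2$year)) stop("duplicate CO2 years")
  co2[order(co2$year), , drop = FALSE]
}

#' Attach an annual CO2 series to a forcing series
#'
#' @param series A [forcing_series()].
#' @param co2 Data frame with columns `year`, `ppm`.
#' @return The forcing series with the CO2 series attached.
#' @export
set_co2 <- function(series, co2) {
  stopifnot(inherits(series, "forcing_series"))
  attr(series, "co2") <- validate_co2(co2)
  series
}

#' @export
print.forcing_series <- function(x, ...) {
  s <- attr(x, "site")
  cat(sprintf("<forcing_series> %d months (%d-%02d to %d-%02d)\n",
              nrow(x), x$year[1], x$month[1],
              x$year[nrow(x)], x$month[nrow(x)]))
  cat(sprintf("  site: %.2f deg lat, %.2f deg lon, %.0f m a.s.l.\n",
              s$latitude, s$longitude, s$elevation))
  cat(sprintf("  CO2 series: %s; prepared: %s\n",
              if (is.null(attr(x, "co2"))) "none" else
                sprintf("%d years", nrow(attr(x, "co2"))),
              if (isTRUE(attr(x, "prepared"))) "yes" else "no"))
  invisible(x)
}

co2_for_years <- function(series, years) {
  co2 <- attr(series, "co2")
  if (is.null(co2)) stop("forcing series has no CO2 series; use set_co2()")
  idx <- match(years, co2$year)
  if (anyNA(idx)) {
    stop("CO2 series missing years: ",
         paste(unique(years[is.na(idx)]), collapse = ", "))
  }
  co2$ppm[idx]
}

#' Saturation vapour pressure of water (Magnus form)
#'
#' @param temp Air temperature, degrees C.
#' @return Saturation vapour pressure in Pa.
#' @export
esat_pa <- function(temp) {
  610.8 * exp(17.27 * temp / (temp + 237.3))
}

#' Vapour pressure deficit from vapour pressure
#'
#' `D = max(0, e_sat(temp) - vap)`, with saturation vapour pressure from the
#' Magnus formula. Supersaturated input is clipped to zero deficit.
#'
#' @param temp Air temperature, degrees C.
#' @param vap Actual vapour pressure, hPa.
#' @return VPD in Pa.
#' @export
vpd_from_vapour_pressure <- function(temp, vap) {
  stopifnot(all(vap >= 0))
  pmax(0, esat_pa(temp) - vap * 100)
}

#' Atmospheric pressure from elevation
#'
#' Standard-atmosphere barometric formula (sea-level pressure 101325 Pa,
#' lapse rate 6.5 K/km).
#'
#' @param elevation Elevation, m a.s.l.
#' @return Pressure in Pa.
#' @export
atmospheric_pressure <- function(elevation) {
  stopifnot(all(is.finite(elevation)))
  101325 * (1 - 0.0065 * elevation / 288.15)^(9.80665 * 0.0289644 /
                                                (8.31446 * 0.0065))
}

## Day-of-year bounds of each calendar month (365-day calendar).
month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
month_end_doy <- cumsum(month_days)
month_start_doy <- month_end_doy - month_days + 1L

#' Daily top-of-atmosphere solar irradiation
#'
#' Closed-form daily integral of extraterrestrial irradiance from solar
#' declination and sunset hour angle.
#'
#' @param latitude Latitude, decimal degrees.
#' @param doy Day of year (1-365).
#' @return Irradiation in J m-2 day-1 (0 during polar night).
#' @export
daily_toa_insolation <- function(latitude, doy) {
  s0 <- 1361
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- (23.45 * pi / 180) * sin(2 * pi * (284 + doy) / 365)
  phi <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  ws <- acos(x)
  h0 <- (86400 / pi) * s0 * e0 *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  pmax(h0, 0)
}

#' Monthly photosynthetically active radiation
#'
#' Top-of-atmosphere insolation is integrated analytically per day and
#' summed over the calendar month, attenuated by an Angstrom-type
#' transmissivity that increases with sunshine fraction (1 - cloud) and
#' with elevation, and converted to PAR photon flux.
#'
#' @param site A [site_meta()].
#' @param cloud_fraction Cloud cover fraction in `[0, 1]` (scalar or one per
#'   month entry).
#' @param month Calendar month 1-12 (vectorised; recycled against
#'   `cloud_fraction`).
#' @param constants A [p_constants()] list (radiation coefficients).
#' @return PAR in mol photon m-2 month-1.
#' @export
monthly_par <- function(site, cloud_fraction, month,
                        constants = p_constants()) {
  stopifnot(inherits(site, "site_meta"),
            all(cloud_fraction >= 0 & cloud_fraction <= 1))
  toa12 <- vapply(1:12, function(m) {
    sum(daily_toa_insolation(site$latitude,
                             seq(month_start_doy[m], month_end_doy[m])))
  }, numeric(1))
  n <- max(length(cloud_fraction), length(month))
  month <- rep_len(month, n)
  cloud_fraction <- rep_len(cloud_fraction, n)
  tau <- (constants$angstrom_a +
            constants$angstrom_b * (1 - cloud_fraction)) *
    (1 + constants$elev_transmissivity * site$elevation)
  toa12[month] * tau * constants$par_j_to_mol
}

#' Growing-season mask from monthly temperature
#'
#' A month is in the growing season iff its mean temperature is strictly
#' above the threshold (default -1 degrees C, reflecting photosynthesis at
#' sub-zero temperatures in temperate climates).
#'
#' @param temp Monthly mean temperature, degrees C.
#' @param threshold Threshold temperature, degrees C.
#' @return Logical vector.
#' @export
growing_season_mask <- function(temp, threshold = -1) {
  temp > threshold
}

#' Monthly moisture index from a single-bucket water balance
#'
#' Equilibrium evapotranspiration is computed from net radiation via the
#' Priestley-Taylor relation; actual evapotranspiration is limited by
#' precipitation plus a soil store. `alpha = AET / EET`, capped at the
#' Priestley-Taylor coefficient 1.26. A spin-up year of the mean
#' climatology precedes the reported series. Months with no evaporative
#' demand report the cap (no moisture limitation).
#'
#' @param series A [forcing_series()].
#' @param soil_capacity Plant-available soil water capacity, mm.
#' @param constants A [p_constants()] list.
#' @return Numeric vector of monthly alpha in `[0, 1.26]`, one per row.
#' @export
moisture_index_alpha <- function(series, soil_capacity = 150,
                                 constants = p_constants()) {
  stopifnot(inherits(series, "forcing_series"), soil_capacity > 0)
  site <- attr(series, "site")
  sw <- monthly_par(site, series$cld, series$month, constants) /
    constants$par_j_to_mol            # back to J m-2 month-1 shortwave
  rn <- (1 - constants$albedo) * sw   # net radiation proxy
  ## slope of saturation vapour pressure curve (Pa/K) and psychrometric
  ## constant (Pa/K) at site pressure
  s <- 4098 * esat_pa(series$tmp) / (series$tmp + 237.3)^2
  patm <- atmospheric_pressure(site$elevation)
  gamma <- 0.000665 * patm
  lambda <- 2.45e6                    # J/kg latent heat
  eet <- pmax(0, (s / (s + gamma)) * rn / lambda)  # mm/month
  demand <- constants$pt_coeff * eet
  run_bucket <- function(pre, demand, eet, store) {
    alpha <- numeric(length(pre))
    for (i in seq_along(pre)) {
      supply <- pre[i] + store
      aet <- min(supply, demand[i])
      alpha[i] <- if (eet[i] > 0) aet / eet[i] else constants$pt_coeff
      store <- min(soil_capacity, supply - aet)
    }
    list(alpha = pmin(alpha, constants$pt_coeff), store = store)
  }
  ## spin-up: one year of monthly climatology, starting from a full bucket
  clim_pre <- tapply(series$pre, series$month, mean)[as.character(1:12)]
  clim_dem <- tapply(demand, series$month, mean)[as.character(1:12)]
  clim_eet <- tapply(eet, series$month, mean)[as.character(1:12)]
  spin <- run_bucket(clim_pre, clim_dem, clim_eet, soil_capacity)
  run_bucket(series$pre, demand, eet, spin$store)$alpha
}

#' Derive the photosynthesis drivers for a forcing series
#'
#' Adds per-month columns `vpd` (Pa), `par` (mol photon m-2 month-1),
#' `alpha` (moisture index) and `growing` (growing-season flag), and stores
#' the site atmospheric pressure.
#'
#' @inheritParams moisture_index_alpha
#' @param growing_threshold Growing-season temperature threshold, degrees C.
#' @return The forcing series with derived columns and `prepared = TRUE`.
#' @export
prepare_forcing <- function(series, constants = p_constants(),
                            soil_capacity = 150, growing_threshold = -1) {
  stopifnot(inherits(series, "forcing_series"))
  site <- attr(series, "site")
  series$vpd <- vpd_from_vapour_pressure(series$tmp, series$vap)
  series$par <- monthly_par(site, series$cld, series$month, constants)
  series$alpha <- moisture_index_alpha(series, soil_capacity, constants)
  series$growing <- growing_season_mask(series$tmp, growing_threshold)
  attr(series, "patm") <- atmospheric_pressure(site$elevation)
  attr(series, "prepared") <- TRUE
  series
}

is_prepared <- function(series) isTRUE(attr(series, "prepared"))

#' Elevation correction against a fine-scale climatology
#'
#' Applies per-calendar-month corrections derived from the difference
#' between a fine-resolution climatology at the site and the coarse-grid
#' climatology: additive for temperature, diurnal range and vapour
#' pressure; multiplicative for precipitation and cloud (falling back to
#' additive in months where the coarse normal is zero). Cloud is clipped to
#' `[0, 1]`, precipitation and vapour pressure to non-negative.
#'
#' @param series A [forcing_series()].
#' @param coarse_clim,fine_clim Data frames of monthly normals with columns
#'   `month` plus any of `tmp`, `dtr`, `pre`, `vap`, `cld`.
#' @return The corrected forcing series (derived columns dropped).
#' @export
elevation_correct <- function(series, coarse_clim, fine_clim) {
  stopifnot(inherits(series, "forcing_series"))
  check_clim <- function(cl) {
    stopifnot(is.data.frame(cl), "month" %in% names(cl))
    if (!setequal(cl$month, 1:12)) stop("climatology must cover months 1..12")
    cl[order(cl$month), , drop = FALSE]
  }
  coarse_clim <- check_clim(coarse_clim)
  fine_clim <- check_clim(fine_clim)
  vars <- intersect(intersect(names(coarse_clim), names(fine_clim)),
                    c("tmp", "dtr", "pre", "vap", "cld"))
  m <- series$month
  out <- series
  for (v in vars) {
    fine <- fine_clim[[v]]
    coarse <- coarse_clim[[v]]
    if (v %in% c("tmp", "dtr", "vap")) {
      out[[v]] <- out[[v]] + (fine - coarse)[m]
    } else {
      ratio <- ifelse(coarse != 0, fine / coarse, NA_real_)
      add <- fine - coarse
      out[[v]] <- ifelse(is.na(ratio[m]),
                         out[[v]] + add[m],
                         out[[v]] * ratio[m])
    }
  }
  out$pre <- pmax(out$pre, 0)
  out$vap <- pmax(out$vap, 0)
  out$dtr <- pmax(out$dtr, 0)
  out$cld <- pmin(pmax(out$cld, 0), 1)
  drop_derived(out)
}

#' Bias-correct a glacial simulation against a modern climatology
#'
#' Adds, per calendar month and variable, the difference between the
#' modern climatology and the control-run climatology to the glacial
#' series, so that a control run identical to the modern climatology leaves
#' the series unchanged. Precipitation is clipped at zero, cloud at
#' `[0, 1]`.
#'
#' @param series The glacial-run [forcing_series()].
#' @param picontrol_clim Monthly normals of the control simulation
#'   (long-term mean), columns `month` plus variables.
#' @param modern_clim Monthly normals of the observed modern climate at the
#'   site, same layout.
#' @return The corrected forcing series (derived columns dropped).
#' @export
bias_correct_lgm <- function(series, picontrol_clim, modern_clim) {
  stopifnot(inherits(series, "forcing_series"))
  check_clim <- function(cl) {
    stopifnot(is.data.frame(cl), "month" %in% names(cl))
    if (!setequal(cl$month, 1:12)) stop("climatology must cover months 1..12")
    cl[order(cl$month), , drop = FALSE]
  }
  picontrol_clim <- check_clim(picontrol_clim)
  modern_clim <- check_clim(modern_clim)
  vars <- intersect(intersect(names(picontrol_clim), names(modern_clim)),
                    c("tmp", "dtr", "pre", "vap", "cld"))
  m <- series$month
  out <- series
  for (v in vars) {
    shift <- modern_clim[[v]] - picontrol_clim[[v]]
    out[[v]] <- out[[v]] + shift[m]
  }
  out$pre <- pmax(out$pre, 0)
  out$vap <- pmax(out$vap, 0)
  out$dtr <- pmax(out$dtr, 0)
  out$cld <- pmin(pmax(out$cld, 0), 1)
  drop_derived(out)
}

drop_derived <- function(series) {
  keep <- setdiff(names(series), c("vpd", "par", "alpha", "growing"))
  out <- series[keep]
  attr(out, "site") <- attr(series, "site")
  attr(out, "co2") <- attr(series, "co2")
  attr(out, "prepared") <- NULL
  class(out) <- c("forcing_series", "data.frame")
  out
}

#' Accumulate a monthly quantity over the two-year carbon window
#'
#' The effective growing season of a ring formed in calendar year `y` runs
#' from July of `y - 2` to June of `y` (24 months). Sums are annualised by
#' dividing by two; means are plain means over the window. An incomplete
#' window returns `NA` (the first two ring years of any run are
#' unavailable).
#'
#' @param values Monthly values, aligned with `years`/`months`.
#' @param years,months Calendar year and month (1-12) of each value.
#' @param ring_year Calendar year of ring formation (vectorised).
#' @param stat `"sum"` (annualised) or `"mean"`.
#' @param window_months Window length in months, ending in June of the ring
#'   year (default 24).
#' @return Accumulated value(s); `NA` where the window is incomplete.
#' @export
accumulation_window <- function(values, years, months, ring_year,
                                stat = c("sum", "mean"),
                                window_months = 24) {
  stat <- match.arg(stat)
  stopifnot(length(values) == length(years), length(years) == length(months),
            window_months >= 1)
  key <- years * 12L + months
  one <- function(y) {
    end <- y * 12L + 6L                      # June of the ring year
    idx <- match(seq(end - window_months + 1L, end), key)
    if (anyNA(idx)) return(NA_real_)
    if (stat == "sum") {
      sum(values[idx]) / (window_months / 12)
    } else {
      mean(values[idx])
    }
  }
  vapply(ring_year, one, numeric(1))
}
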