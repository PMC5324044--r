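#' Configuration of the synthetic monthly-climate generator
#'
#' Defaults emulate a high-elevation southern Sierra Nevada juniper site:
#' cool mediterranean climate with a strongly winter-dominated
#' precipitation regime, moderate cloudiness, and modest interannual
#' persistence in temperature.
#'
#' @param n_years Number of years to generate.
#' @param mean_annual_temp Mean annual temperature, degrees C.
#' @param seasonal_amplitude Amplitude of the seasonal temperature cycle,
#'   degrees C (July peak in the northern hemisphere).
#' @param diurnal_range Diurnal temperature range, degrees C.
#' @param annual_precip Mean annual precipitation, mm.
#' @param precip_winter_fraction Fraction of annual precipitation falling
#'   in the winter half-year (October-March in the north).
#' @param mean_relative_humidity Mean relative humidity, fraction.
#' @param cloud_fraction Mean cloud cover fraction.
#' @param ar1_coefficient AR(1) coefficient of monthly temperature noise,
#'   in `[0, 1)`.
#' @param noise_sd_temp Stationary SD of temperature noise, degrees C.
#' @param noise_sd_precip_lognormal SD of the multiplicative lognormal
#'   precipitation noise (log scale).
#' @param seed Integer RNG seed.
#' @param southern_hemisphere Logical; shifts the seasonal phase by six
#'   months.
#' @return A `synthetic_climate_config` list.
#' @export
synthetic_climate_config <- function(n_years = 90,
                                     mean_annual_temp = 7.5,
                                     seasonal_amplitude = 9,
                                     diurnal_range = 13,
                                     annual_precip = 700,
                                     precip_winter_fraction = 0.8,
                                     mean_relative_humidity = 0.55,
                                     cloud_fraction = 0.4,
                                     ar1_coefficient = 0.3,
                                     noise_sd_temp = 1,
                                     noise_sd_precip_lognormal = 0.35,
                                     seed = 1,
                                     southern_hemisphere = FALSE) {
  cfg <- list(n_years = n_years, mean_annual_temp = mean_annual_temp,
              seasonal_amplitude = seasonal_amplitude,
              diurnal_range = diurnal_range, annual_precip = annual_precip,
              precip_winter_fraction = precip_winter_fraction,
              mean_relative_humidity = mean_relative_humidity,
              cloud_fraction = cloud_fraction,
              ar1_coefficient = ar1_coefficient,
              noise_sd_temp = noise_sd_temp,
              noise_sd_precip_lognormal = noise_sd_precip_lognormal,
              seed = seed, southern_hemisphere = southern_hemisphere)
  num <- cfg[setdiff(names(cfg), "southern_hemisphere")]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                    is.finite(x), logical(1)))) {
    stop("all configuration values must be finite numbers")
  }
  stopifnot(n_years >= 1,
            precip_winter_fraction >= 0, precip_winter_fraction <= 1,
            mean_relative_humidity >= 0, mean_relative_humidity <= 1,
            cloud_fraction >= 0, cloud_fraction <= 1,
            ar1_coefficient >= 0, ar1_coefficient < 1,
            noise_sd_temp >= 0, noise_sd_precip_lognormal >= 0,
            annual_precip >= 0, diurnal_range >= 0, seasonal_amplitude >= 0)
  structure(cfg, class = "synthetic_climate_config")
}

#' Generate a synthetic monthly climate series
#'
#' Monthly temperature is a sinusoid peaking in July (northern hemisphere)
#' plus stationary AR(1) noise; precipitation splits the annual total
#' between winter and summer half-years with mean-preserving multiplicative
#' lognormal noise; vapour pressure is relative humidity times the Magnus
#' saturation vapour pressure of the monthly temperature; cloud fraction is
#' constant plus a small noise proportional to the temperature noise SD.
#' Generation is exactly reproducible for a given seed.
#'
#' @param config A [synthetic_climate_config()].
#' @param site A [site_meta()]; defaults to a 2630 m Sierra Nevada site.
#' @param start_year First calendar year of the series.
#' @return A [forcing_series()] (without CO2; see [set_co2()]).
#' @export
generate_monthly_climate <- function(config = synthetic_climate_config(),
                                     site = site_meta(36.95, -118.92, 2630),
                                     start_year = 1901) {
  stopifnot(inherits(config, "synthetic_climate_config"))
  n <- config$n_years * 12L
  month <- rep(1:12, config$n_years)
  year <- rep(seq(start_year, length.out = config$n_years), each = 12L)
  phase_month <- if (config$southern_hemisphere) 1 else 7
  seasonal <- config$mean_annual_temp +
    config$seasonal_amplitude * cos(2 * pi * (month - phase_month) / 12)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  ## stationary AR(1): innovation sd scaled so the marginal sd equals
  ## noise_sd_temp
  e <- numeric(n)
  if (config$noise_sd_temp > 0) {
    innov_sd <- config$noise_sd_temp * sqrt(1 - config$ar1_coefficient^2)
    z <- rnorm(n, 0, innov_sd)
    e[1] <- rnorm(1, 0, config$noise_sd_temp)
    for (i in seq_len(n)[-1]) e[i] <- config$ar1_coefficient * e[i - 1] + z[i]
  }
  tmp <- seasonal + e

  winter <- if (config$southern_hemisphere) c(4:9) else c(10:12, 1:3)
  base <- ifelse(month %in% winter,
                 config$annual_precip * config$precip_winter_fraction / 6,
                 config$annual_precip * (1 - config$precip_winter_fraction) / 6)
  s <- config$noise_sd_precip_lognormal
  pre <- if (s > 0) base * exp(rnorm(n, -s^2 / 2, s)) else base

  cld_noise_sd <- 0.02 * config$noise_sd_temp
  cld <- pmin(pmax(config$cloud_fraction +
                     (if (cld_noise_sd > 0) rnorm(n, 0, cld_noise_sd) else 0),
                   0), 1)
  vap <- config$mean_relative_humidity * esat_pa(tmp) / 100  # hPa
  forcing_series(data.frame(year = year, month = month, tmp = tmp,
                            dtr = config$diurnal_range, pre = pre,
                            vap = vap, cld = cld),
                 site = site)
}

#' Monthly anomaly configuration
#'
#' Per-calendar-month additive shifts for constructing glacial-style
#' scenarios: temperature (degrees C), precipitation (mm; results clipped
#' at zero) and relative humidity (fraction). Scalars are recycled to 12
#' months. Reconstructions of the glacial climate in the study region
#' suggest year-round cooling of 2-6 degrees C, 100-300 mm more annual
#' precipitation, and higher relative humidity.
#'
#' @param delta_temp Temperature shift(s), degrees C (length 1 or 12).
#' @param delta_precip Precipitation shift(s), mm per month (1 or 12).
#' @param delta_rh Relative humidity shift(s), fraction (1 or 12).
#' @return An `anomaly_config` list of three length-12 vectors.
#' @export
anomaly_config <- function(delta_temp = -4, delta_precip = 200 / 12,
                           delta_rh = 0.05) {
  f <- function(x, nm) {
    if (!length(x) %in% c(1L, 12L) || !is.numeric(x) || anyNA(x)) {
      stop(nm, " must be numeric of length 1 or 12")
    }
    rep_len(x, 12L)
  }
  structure(list(delta_temp = f(delta_temp, "delta_temp"),
                 delta_precip = f(delta_precip, "delta_precip"),
                 delta_rh = f(delta_rh, "delta_rh")),
            class = "anomaly_config")
}

#' Apply monthly anomalies to a forcing series
#'
#' Temperature and precipitation are shifted additively per calendar month
#' (precipitation clipped at zero). Relative humidity, diagnosed from the
#' original vapour pressure and temperature, is shifted (clipped to
#' `[0, 1]`) before vapour pressure is recomputed at the shifted
#' temperature, so humidity rather than vapour pressure is the conserved
#' quantity. Where no clipping occurs the operation is exactly inverted by
#' negating the anomaly.
#'
#' @param series A [forcing_series()].
#' @param anomaly An [anomaly_config()].
#' @return The shifted forcing series (derived columns dropped).
#' @export
apply_anomalies <- function(series, anomaly) {
  stopifnot(inherits(series, "forcing_series"),
            inherits(anomaly, "anomaly_config"))
  m <- series$month
  rh <- series$vap * 100 / esat_pa(series$tmp)
  rh <- pmin(pmax(rh + anomaly$delta_rh[m], 0), 1)
  out <- series
  out$tmp <- series$tmp + anomaly$delta_temp[m]
  out$pre <- pmax(series$pre + anomaly$delta_precip[m], 0)
  out$vap <- rh * esat_pa(out$tmp) / 100
  drop_derived(out)
}

#' Generate an annual CO2 series
#'
#' @param years Calendar years (e.g. `1903:1985`).
#' @param mode `"constant"` (one level for all years) or `"ramp"` (linear
#'   between two endpoint levels).
#' @param level ppm level (constant mode) or length-2 endpoints (ramp).
#' @return Data frame with columns `year`, `ppm`.
#' @examples
#' generate_co2_series(1903:1985, "ramp", c(296, 339))
#' @export
generate_co2_series <- function(years, mode = c("constant", "ramp"),
                                level = 180) {
  mode <- match.arg(mode)
  stopifnot(all(level > 0), !anyDuplicated(years))
  ppm <- switch(mode,
                constant = {
                  stopifnot(length(level) == 1)
                  rep(level, length(years))
                },
                ramp = {
                  stopifnot(length(level) == 2)
                  seq(level[1], level[2], length.out = length(years))
                })
  data.frame(year = years, ppm = ppm)
}

#' Generate a synthetic observed ring-width series with known truth
#'
#' Runs the full forward model (photosynthesis plus allocation) under the
#' supplied forcing and parameters and adds Gaussian observation noise, so
#' that calibration can be tested against a known truth. The true
#' parameters, noise level and seed are stored as attributes.
#'
#' @param params A [species_params()] (the truth).
#' @param forcing A [forcing_series()] with CO2 attached.
#' @param obs_noise_sd Observation noise SD, mm.
#' @param seed Integer RNG seed for the noise.
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @return A `ring_series` with attributes `true_params`, `obs_noise_sd`,
#'   `seed`.
#' @export
generate_synthetic_rings <- function(params, forcing, obs_noise_sd = 0,
                                     seed = 1, d0 = 0.3,
                                     constants = p_constants()) {
  stopifnot(obs_noise_sd >= 0)
  sim <- simulate_growth(forcing, params, d0, constants)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  rw <- pmax(0, sim$rw_mm + rnorm(nrow(sim), 0, obs_noise_sd))
  out <- ring_series(sim$year, rw)
  attr(out, "true_params") <- params
  attr(out, "obs_noise_sd") <- obs_noise_sd
  attr(out, "seed") <- seed
  out
}
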