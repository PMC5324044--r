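#' Constants of the light-use-efficiency photosynthesis model
#'
#' Returns the default constant set, overridable by name. `phi0` is the
#' maximum quantum efficiency in mass units, 0.816 g C mol-1 photon,
#' equivalent to 0.085 mol C mol-1 photon times 12 g C mol-1 with a leaf
#' absorptance of 0.8. `beta` is the ratio of the unit costs of
#' carboxylation and transpiration at 25 degrees C; it is not directly
#' observable and is the constant most worth varying in sensitivity work.
#' `gammastar25` (4.331 Pa) and the exponential coefficient
#' `gammastar_exp` (0.0512 per degree C, the tangent of the Arrhenius curve
#' at 25 degrees C) set the photorespiratory compensation point.
#' Michaelis-Menten and activation-energy constants follow the standard
#' Bernacchi-type parameterisation, expressed in Pa at sea level and scaled
#' linearly with atmospheric pressure.
#'
#' @param ... Named overrides of any default.
#' @return A named list of constants.
#' @examples
#' p_constants(beta = 146)$beta
#' @export
p_constants <- function(...) {
  defaults <- list(
    phi0 = 0.816,              # g C / mol photon (incl. absorptance)
    quantum_yield = 0.085,     # mol C / mol photon
    leaf_absorptance = 0.8,
    beta = 240,                # unit-cost ratio at 25 C
    gammastar25 = 4.331,       # Pa at 25 C, sea level
    gammastar_exp = 0.0512,    # 1/C
    dha_gammastar = 37830,     # J/mol, Arrhenius reference for gammastar
    kc25 = 39.97,              # Pa
    ko25 = 27480,              # Pa
    ea_kc = 79430,             # J/mol
    ea_ko = 36380,             # J/mol
    ea_vcmax = 65330,          # J/mol
    o2_mole_fraction = 0.20946,
    drought_ref_alpha = 1.26,
    drought_exponent = 0.25,
    ## radiation / transmissivity (used by forcing preparation)
    angstrom_a = 0.25,
    angstrom_b = 0.50,
    elev_transmissivity = 2.67e-5,   # per m
    par_j_to_mol = 2.04e-6,          # mol PAR photon per J shortwave
    albedo = 0.17,
    pt_coeff = 1.26
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown constants: ", paste(unknown, collapse = ", "))
  }
  defaults[names(dots)] <- dots
  if (any(vapply(defaults, function(x) !is.numeric(x) || x < 0, logical(1)))) {
    stop("all constants must be non-negative numbers")
  }
  defaults
}

arrhenius_factor <- function(temp, ea) {
  exp(ea / 8.31446 * (1 / 298.15 - 1 / (temp + 273.15)))
}

#' Photorespiratory compensation point
#'
#' Exponential temperature response anchored at 4.331 Pa (25 degrees C, sea
#' level), scaled linearly with atmospheric pressure:
#' `gammastar = gammastar25 * exp(0.0512 * (temp - 25)) * patm / 101325`.
#'
#' @param temp Leaf/air temperature, degrees C.
#' @param patm Atmospheric pressure, Pa.
#' @param constants A [p_constants()] list.
#' @return Compensation point in Pa.
#' @export
gammastar <- function(temp, patm = 101325, constants = p_constants()) {
  constants$gammastar25 * exp(constants$gammastar_exp * (temp - 25)) *
    patm / 101325
}

#' Effective Michaelis-Menten coefficient for Rubisco-limited photosynthesis
#'
#' `K = Kc * (1 + pO2 / Ko)` with `Kc`, `Ko` following Arrhenius responses
#' from their 25 degree C reference values, both expressed as partial
#' pressures and scaled linearly with atmospheric pressure;
#' `pO2 = 0.20946 * patm`.
#'
#' @inheritParams gammastar
#' @return Effective K in Pa.
#' @export
effective_K <- function(temp, patm = 101325, constants = p_constants()) {
  scale <- patm / 101325
  kc <- constants$kc25 * scale * arrhenius_factor(temp, constants$ea_kc)
  ko <- constants$ko25 * scale * arrhenius_factor(temp, constants$ea_ko)
  po2 <- constants$o2_mole_fraction * patm
  kc * (1 + po2 / ko)
}

#' Viscosity of water relative to 25 degrees C
#'
#' Ratio of the dynamic viscosity of pure water at `temp` to its value at
#' 25 degrees C, using the Korson-type correlation for viscosity relative
#' to 20 degrees C (accurate to about 0.1 percent between 0 and 40
#' degrees C).
#'
#' @param temp Water (leaf) temperature, degrees C.
#' @return Dimensionless viscosity ratio; 1 at 25 degrees C.
#' @export
viscosity_ratio <- function(temp) {
  stopifnot(all(temp > -20))
  rel20 <- function(t) {
    dt <- 20 - t
    10^((dt / (t + 96)) *
          (1.2378 - 1.303e-3 * dt + 3.06e-6 * dt^2 + 2.55e-8 * dt^3))
  }
  rel20(temp) / rel20(25)
}

#' Stomatal sensitivity of the least-cost model
#'
#' `xi = sqrt(beta * (K + gammastar) / (1.6 * eta_star))`, where `eta_star`
#' is the water viscosity ratio. Larger `xi` keeps the leaf-internal CO2
#' closer to ambient as VPD rises.
#'
#' @inheritParams gammastar
#' @return xi in Pa^0.5.
#' @export
xi_sensitivity <- function(temp, patm = 101325, constants = p_constants()) {
  k <- effective_K(temp, patm, constants)
  gs <- gammastar(temp, patm, constants)
  sqrt(constants$beta * (k + gs) / (1.6 * viscosity_ratio(temp)))
}

#' Least-cost optimal leaf-internal CO2 partial pressure
#'
#' `ci = gammastar + (ca - gammastar) * xi / (xi + sqrt(D))`. The result
#' lies in `[gammastar, ca]`; at zero VPD `ci = ca`. Ambient CO2 below the
#' compensation point returns `ci = ca` (assimilation is zero downstream).
#'
#' @param ca Ambient CO2 partial pressure, Pa.
#' @param vpd Vapour pressure deficit, Pa (non-negative).
#' @param xi Stomatal sensitivity, Pa^0.5 (from [xi_sensitivity()]).
#' @param gammastar Photorespiratory compensation point, Pa.
#' @return ci in Pa.
#' @export
ci_leaf <- function(ca, vpd, xi, gammastar) {
  stopifnot(all(vpd >= 0))
  ci <- gammastar + (ca - gammastar) * xi / (xi + sqrt(vpd))
  ifelse(ca < gammastar, ca, ci)
}

#' CO2 limitation factor of light-use efficiency
#'
#' `m = max(0, (ci - gammastar) / (ci + 2 * gammastar))`: zero at the
#' compensation point, approaching one as ci grows large.
#'
#' @param ci Leaf-internal CO2 partial pressure, Pa.
#' @param gammastar Compensation point, Pa.
#' @return Fraction in `[0, 1)`.
#' @export
co2_limitation <- function(ci, gammastar) {
  stopifnot(all(ci >= 0))
  pmax(0, (ci - gammastar) / (ci + 2 * gammastar))
}

#' ci/ca from carbon-isotope discrimination
#'
#' Simple two-endpoint conversion `ci/ca = (Delta - a) / (b - a)` with
#' diffusive fractionation `a = 4.4` permil and Rubisco fractionation
#' `b = 27` permil.
#'
#' @param delta13 Photosynthetic discrimination, permil.
#' @param a,b Fractionation endpoints, permil.
#' @return ci/ca fraction; warns when input is outside 0-30 permil.
#' @export
cica_from_discrimination <- function(delta13, a = 4.4, b = 27) {
  if (any(delta13 < 0 | delta13 > 30)) {
    warning("discrimination outside the plausible 0-30 permil range")
  }
  (delta13 - a) / (b - a)
}

#' GPP-weighted annual ci/ca
#'
#' Weighted mean of monthly ci/ca over growing-season months using monthly
#' GPP as weights; with all-zero weights the unweighted mean is used.
#'
#' @param cica Monthly ci/ca values (growing-season months).
#' @param weights Monthly GPP weights, same length.
#' @return Annual ci/ca fraction.
#' @export
annual_cica <- function(cica, weights) {
  stopifnot(length(cica) == length(weights), length(cica) >= 1,
            all(weights >= 0))
  if (sum(weights) > 0) {
    weighted.mean(cica, weights)
  } else {
    mean(cica)
  }
}

#' Run the photosynthesis model over a prepared forcing series
#'
#' Computes, per month: the compensation point, effective K, stomatal
#' sensitivity, optimal ci, ci/ca, the CO2 limitation factor `m`, potential
#' GPP per unit ground area (g C m-2 month-1, zero outside the growing
#' season), a coordination estimate of carboxylation capacity normalised to
#' 25 degrees C, and stomatal conductance from Fick's law. Monthly GPP is
#' `phi0 * PAR * m * (alpha/1.26)^(1/4)` on growing-season months.
#'
#' `vcmax25` and `gs` are reported in consistent relative units (mol-based,
#' per month); they are diagnostic outputs and do not feed back into GPP.
#'
#' @param series A [forcing_series()]; prepared automatically if needed.
#' @param constants A [p_constants()] list.
#' @param ca_ppm Optional constant ambient CO2 (ppm) overriding the
#'   attached CO2 series.
#' @return Data frame with one row per month: `year`, `month`, `ca_pa`,
#'   `gammastar`, `ci`, `cica`, `m`, `gpp`, `vcmax25`, `gs`, `growing`.
#' @export
run_pmodel <- function(series, constants = p_constants(), ca_ppm = NULL) {
  stopifnot(inherits(series, "forcing_series"))
  if (!is_prepared(series)) series <- prepare_forcing(series, constants)
  patm <- attr(series, "patm")
  ppm <- if (is.null(ca_ppm)) co2_for_years(series, series$year) else
    rep_len(ca_ppm, nrow(series))
  ca <- ppm * 1e-6 * patm
  gs_pt <- gammastar(series$tmp, patm, constants)
  xi <- xi_sensitivity(series$tmp, patm, constants)
  ci <- ci_leaf(ca, series$vpd, xi, gs_pt)
  m <- co2_limitation(ci, gs_pt)
  drought <- (pmin(series$alpha, constants$drought_ref_alpha) /
                constants$drought_ref_alpha)^constants$drought_exponent
  gpp <- ifelse(series$growing,
                constants$phi0 * series$par * m * drought, 0)
  ## coordination estimate of carboxylation capacity (mol-based, monthly),
  ## normalised to 25 C by the inverse Arrhenius factor
  k <- effective_K(series$tmp, patm, constants)
  phi0_mol <- constants$phi0 / 12
  vcmax <- ifelse(series$growing & ci > gs_pt,
                  phi0_mol * series$par * (ci + k) / (ci + 2 * gs_pt),
                  NA_real_)
  vcmax25 <- vcmax / arrhenius_factor(series$tmp, constants$ea_vcmax)
  a_mol <- gpp / 12                       # mol C m-2 month-1
  gs_cond <- ifelse(ca > ci, 1.6 * a_mol / ((ca - ci) / patm), NA_real_)
  data.frame(year = series$year, month = series$month,
             ca_pa = ca, gammastar = gs_pt, ci = ci, cica = ci / ca,
             m = m, gpp = gpp, vcmax25 = vcmax25, gs = gs_cond,
             growing = series$growing)
}

#' Annual photosynthesis summaries
#'
#' Per-year GPP (kg C m-2 a-1, calendar-year sum of monthly values),
#' GPP-weighted annual ci/ca, and GPP-weighted mean `vcmax25` and `gs` over
#' growing-season months.
#'
#' @param pm Output of [run_pmodel()].
#' @return Data frame with columns `year`, `gpp`, `cica`, `vcmax25`, `gs`.
#' @export
annual_pmodel_summary <- function(pm) {
  years <- sort(unique(pm$year))
  one <- function(y) {
    rows <- pm[pm$year == y, , drop = FALSE]
    grow <- rows[rows$growing, , drop = FALSE]
    if (nrow(grow) == 0) {
      return(data.frame(year = y, gpp = 0, cica = NA_real_,
                        vcmax25 = NA_real_, gs = NA_real_))
    }
    w <- grow$gpp
    data.frame(
      year = y,
      gpp = sum(rows$gpp) / 1000,
      cica = annual_cica(grow$cica, w),
      vcmax25 = if (sum(w) > 0) weighted.mean(grow$vcmax25, w, na.rm = TRUE)
                else mean(grow$vcmax25, na.rm = TRUE),
      gs = if (sum(w) > 0) weighted.mean(grow$gs, w, na.rm = TRUE)
           else mean(grow$gs, na.rm = TRUE))
  }
  do.call(rbind, lapply(years, one))
}

#' Annualised potential GPP over the two-year carbon window
#'
#' Accumulates monthly potential GPP over the 24-month window ending in
#' June of each requested ring year and annualises (kg C m-2 a-1).
#'
#' @param pm Output of [run_pmodel()].
#' @param ring_years Calendar years of ring formation.
#' @return Data frame `year`, `gpp` (NA where the window is incomplete).
#' @export
window_gpp <- function(pm, ring_years) {
  g <- accumulation_window(pm$gpp, pm$year, pm$month, ring_years,
                           stat = "sum") / 1000
  data.frame(year = ring_years, gpp = g)
}
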