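#' Species parameters of the carbon-allocation tree model
#'
#' Geometry, allocation and respiration parameters of the geometric tree
#' growth model, with generic needleleaf defaults from the allometric
#' literature. The canonical core set comprises: `a` (initial slope of
#' the height-diameter curve), `c_ratio` (initial crown area : stem
#' cross-section ratio), `h_max` (asymptotic height), `rho_s` (sapwood/stem
#' density in carbon units), `lai` (leaf area index within the crown, L),
#' `sla` (specific leaf area, sigma), `tau_f` and `tau_r` (foliage and
#' fine-root turnover times), `r_s` and `r_r` (sapwood and fine-root
#' specific maintenance respiration), `zeta` (fine-root mass per unit leaf
#' area) and `yield` (growth-respiration yield). `k_ext` (canopy light
#' extinction), `huber_inv` (leaf area per unit sapwood cross-section) and
#' `foliage_resp_frac` (fraction of GPP respired by foliage) complete the
#' closure.
#'
#' @param a Initial height-diameter slope, m m-1.
#' @param c_ratio Initial crown area to stem cross-sectional area ratio.
#' @param h_max Maximum tree height, m.
#' @param rho_s Wood density, kg C m-3.
#' @param lai Leaf area index within the crown (L).
#' @param sla Specific leaf area, m2 kg-1 C.
#' @param tau_f Foliage turnover time, years.
#' @param tau_r Fine-root turnover time, years.
#' @param r_s Sapwood specific respiration, a-1.
#' @param r_r Fine-root specific respiration, a-1.
#' @param zeta Fine-root mass per unit leaf area, kg C m-2.
#' @param yield Growth-respiration yield (0-1).
#' @param k_ext PAR extinction coefficient of the canopy.
#' @param huber_inv Leaf area per unit sapwood cross-section, m2 m-2.
#' @param foliage_resp_frac Fraction of GPP respired by foliage.
#' @return An object of class `species_params` (named list).
#' @examples
#' species_params(lai = 1.6, zeta = 0.2)
#' @export
species_params <- function(a = 116, c_ratio = 390.43, h_max = 25.33,
                           rho_s = 200, lai = 1.8, sla = 14,
                           tau_f = 4, tau_r = 1.04,
                           r_s = 0.044, r_r = 0.913,
                           zeta = 0.17, yield = 0.6,
                           k_ext = 0.5, huber_inv = 3000,
                           foliage_resp_frac = 0.1) {
  p <- list(a = a, c_ratio = c_ratio, h_max = h_max, rho_s = rho_s,
            lai = lai, sla = sla, tau_f = tau_f, tau_r = tau_r,
            r_s = r_s, r_r = r_r, zeta = zeta, yield = yield,
            k_ext = k_ext, huber_inv = huber_inv,
            foliage_resp_frac = foliage_resp_frac)
  bad <- vapply(p, function(x) !is.numeric(x) || length(x) != 1 ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) stop("non-positive parameter(s): ",
                     paste(names(p)[bad], collapse = ", "))
  if (yield > 1) stop("yield must be <= 1")
  if (foliage_resp_frac >= 1) stop("foliage_resp_frac must be < 1")
  structure(p, class = "species_params")
}

#' Tree height from stem diameter
#'
#' Saturating height-diameter trajectory
#' `H = h_max * (1 - exp(-a * d / h_max))`: slope `a` at the origin,
#' asymptote `h_max`.
#'
#' @param d Stem diameter at breast height, m.
#' @param params A [species_params()].
#' @return Height in m.
#' @export
height_from_diameter <- function(d, params) {
  stopifnot(all(d >= 0))
  params$h_max * (1 - exp(-params$a * d / params$h_max))
}

#' Projected crown area from diameter and height
#'
#' `A_c = (pi * c_ratio / (4 * a)) * d * H`; for small trees this equals
#' `c_ratio` times the stem cross-sectional area.
#'
#' @param d Stem diameter, m.
#' @param h Tree height, m (from [height_from_diameter()]).
#' @inheritParams height_from_diameter
#' @return Crown area in m2.
#' @export
crown_area <- function(d, h, params) {
  stopifnot(all(d >= 0), all(h >= 0))
  (pi * params$c_ratio / (4 * params$a)) * d * h
}

#' Biomass pools at a given stem diameter
#'
#' Stem mass uses a paraboloid form factor of one half
#' (`W_s = pi/8 * rho_s * d^2 * H`); foliage mass is crown area times LAI
#' over specific leaf area; fine-root mass is `zeta` times foliage area;
#' sapwood mass follows the pipe model (leaf area over `huber_inv` gives
#' the conducting cross-section, with mean conducting length `H/2`).
#'
#' @inheritParams height_from_diameter
#' @return List with `height`, `crown_area`, `w_stem`, `w_sapwood`,
#'   `w_foliage`, `w_root` (kg C).
#' @export
biomass_pools <- function(d, params) {
  h <- height_from_diameter(d, params)
  ac <- crown_area(d, h, params)
  leaf_area <- ac * params$lai
  list(height = h,
       crown_area = ac,
       w_stem = (pi / 8) * params$rho_s * d^2 * h,
       w_sapwood = params$rho_s * (leaf_area / params$huber_inv) * h / 2,
       w_foliage = leaf_area / params$sla,
       w_root = params$zeta * leaf_area)
}

## total mass of the allocated pools (stem + foliage + fine root) and its
## analytic derivative with respect to diameter
allocated_mass <- function(d, params) {
  p <- biomass_pools(d, params)
  p$w_stem + p$w_foliage + p$w_root
}

allocated_mass_deriv <- function(d, params) {
  h <- height_from_diameter(d, params)
  dh <- params$a * exp(-params$a * d / params$h_max)
  dws <- (pi / 8) * params$rho_s * (2 * d * h + d^2 * dh)
  dac <- (pi * params$c_ratio / (4 * params$a)) * (h + d * dh)
  dwf <- (params$lai / params$sla) * dac
  dwr <- params$zeta * params$lai * dac
  list(stem = dws, foliage = dwf, root = dwr, total = dws + dwf + dwr)
}

#' Fraction of PAR absorbed by the canopy
#'
#' Beer's law: `fAPAR = 1 - exp(-k_ext * lai)`.
#'
#' @param lai Leaf area index within the crown.
#' @param k_ext Extinction coefficient.
#' @return Fraction in `[0, 1)`.
#' @export
fapar <- function(lai, k_ext) {
  stopifnot(all(lai >= 0), all(k_ext >= 0))
  1 - exp(-k_ext * lai)
}

#' Annual net primary production of a tree
#'
#' Whole-tree GPP is potential GPP per unit ground area times fAPAR times
#' crown area. NPP deducts foliage respiration (a fixed fraction of GPP),
#' maintenance respiration of sapwood and fine roots, and growth
#' respiration through the yield factor:
#' `NPP = yield * (P * (1 - f_resp) - r_s * W_sap - r_r * W_root)`,
#' floored at zero.
#'
#' @param gpp_potential Potential GPP, kg C m-2 a-1.
#' @param d Stem diameter, m.
#' @inheritParams height_from_diameter
#' @return NPP in kg C a-1 per tree.
#' @export
npp_annual <- function(gpp_potential, d, params) {
  stopifnot(all(gpp_potential >= 0))
  p <- biomass_pools(d, params)
  p_tree <- gpp_potential * fapar(params$lai, params$k_ext) * p$crown_area
  pmax(0, params$yield * (p_tree * (1 - params$foliage_resp_frac) -
                            params$r_s * p$w_sapwood -
                            params$r_r * p$w_root))
}

#' Annual diameter increment from the carbon balance
#'
#' Solves the allocation balance
#' `NPP = [W(d + dd) - W(d)] + W_f / tau_f + W_r / tau_r`
#' for the diameter increment `dd`, where `W` is the total mass of the
#' allocated pools (stem + foliage + fine roots). The default solver is a
#' safeguarded Newton iteration on the exact mass balance whose first
#' iterate is the linearised step `dd0 = available / W'(d)`;
#' `method = "linear"` stops at that first step. The increment is floored
#' at zero when turnover exceeds NPP.
#'
#' @param npp Annual NPP, kg C a-1 (non-negative).
#' @param d Stem diameter, m.
#' @inheritParams height_from_diameter
#' @param method `"exact"` (Newton on the exact balance) or `"linear"`.
#' @return Diameter increment in m.
#' @export
diameter_increment <- function(npp, d, params,
                               method = c("exact", "linear")) {
  method <- match.arg(method)
  stopifnot(length(npp) == 1, npp >= 0, length(d) == 1, d >= 0)
  p <- biomass_pools(d, params)
  avail <- npp - p$w_foliage / params$tau_f - p$w_root / params$tau_r
  if (avail <= 0) return(0)
  w0 <- allocated_mass(d, params)
  dd <- avail / allocated_mass_deriv(d, params)$total
  if (method == "linear") return(dd)
  for (i in 1:50) {
    resid <- allocated_mass(d + dd, params) - w0 - avail
    if (abs(resid) <= 1e-12 * max(avail, 1)) break
    step <- resid / allocated_mass_deriv(d + dd, params)$total
    dd <- max(dd - step, dd / 10)   # safeguard: mass is increasing in d
  }
  dd
}

#' Allocation fractions of one simulated year
#'
#' Fractions of NPP allocated to foliage (increment plus turnover), fine
#' roots (increment plus turnover) and stem, computed from the exact pool
#' increments over the year. Undefined (all `NA`) when NPP is zero.
#'
#' @param npp Annual NPP, kg C a-1.
#' @param d Diameter at the start of the year, m.
#' @param dd Diameter increment of the year, m.
#' @inheritParams height_from_diameter
#' @return Named numeric vector `f_foliage`, `f_root`, `f_stem` (sums to 1
#'   when the increment closes the balance).
#' @export
allocation_fractions <- function(npp, d, dd, params) {
  if (npp <= 0) {
    return(c(f_foliage = NA_real_, f_root = NA_real_, f_stem = NA_real_))
  }
  p0 <- biomass_pools(d, params)
  p1 <- biomass_pools(d + dd, params)
  fol <- (p1$w_foliage - p0$w_foliage) + p0$w_foliage / params$tau_f
  root <- (p1$w_root - p0$w_root) + p0$w_root / params$tau_r
  stem <- p1$w_stem - p0$w_stem
  c(f_foliage = fol / npp, f_root = root / npp, f_stem = stem / npp)
}

#' Simulate annual growth from annualised potential GPP
#'
#' Core annual loop of the tree model: for each ring year, compute NPP from
#' the annualised potential GPP, solve the allocation balance for the
#' diameter increment, record the ring width (`dd/2` in mm) and update the
#' tree state.
#'
#' @param gpp Data frame with columns `year` and `gpp` (kg C m-2 a-1), one
#'   row per ring year (e.g. from [window_gpp()]); rows with `NA` are
#'   dropped.
#' @param params A [species_params()].
#' @param d0 Initial stem diameter, m.
#' @return A `ring_series` data frame with columns `year`, `rw_mm`,
#'   `diameter` (end of year, m), `npp`, `gpp_tree`, `f_foliage`,
#'   `f_root`, `f_stem`, `balance_resid` (relative closure error of the
#'   carbon balance; `NA` in years with no growth).
#' @export
grow_tree <- function(gpp, params, d0 = 0.3) {
  stopifnot(is.data.frame(gpp), all(c("year", "gpp") %in% names(gpp)),
            d0 > 0)
  gpp <- gpp[!is.na(gpp$gpp), , drop = FALSE]
  n <- nrow(gpp)
  out <- data.frame(year = gpp$year, rw_mm = numeric(n),
                    diameter = numeric(n), npp = numeric(n),
                    gpp_tree = numeric(n),
                    f_foliage = numeric(n), f_root = numeric(n),
                    f_stem = numeric(n), balance_resid = numeric(n))
  d <- d0
  for (i in seq_len(n)) {
    pools <- biomass_pools(d, params)
    gpp_tree <- gpp$gpp[i] * fapar(params$lai, params$k_ext) *
      pools$crown_area
    npp <- npp_annual(gpp$gpp[i], d, params)
    turnover <- pools$w_foliage / params$tau_f + pools$w_root / params$tau_r
    dd <- diameter_increment(npp, d, params)
    fr <- allocation_fractions(npp, d, dd, params)
    resid <- if (npp > turnover) {
      dw <- allocated_mass(d + dd, params) - allocated_mass(d, params)
      abs(npp - (dw + turnover)) / npp
    } else NA_real_
    d <- d + dd
    out$rw_mm[i] <- dd / 2 * 1000
    out$diameter[i] <- d
    out$npp[i] <- npp
    out$gpp_tree[i] <- gpp_tree
    out$f_foliage[i] <- fr["f_foliage"]
    out$f_root[i] <- fr["f_root"]
    out$f_stem[i] <- fr["f_stem"]
    out$balance_resid[i] <- resid
  }
  structure(out, d0 = d0, params = params,
            class = c("ring_series", "data.frame"))
}

## Mean ring width for many (lai, zeta) candidates at once.
## Runs the annual allocation loop a single time with the tree state held
## as a vector across candidates; numerically identical to per-candidate
## grow_tree() runs (same Newton solve, per-element tolerance). This is the
## forward model the ABC calibration evaluates thousands of times.
grow_mean_rw_batch <- function(gpp, params, lai, zeta, d0 = 0.3) {
  n <- max(length(lai), length(zeta))
  lai <- rep_len(lai, n)
  zeta <- rep_len(zeta, n)
  crown_c <- pi * params$c_ratio / (4 * params$a)
  mass <- function(dv, laiv, zetav) {
    hv <- params$h_max * (1 - exp(-params$a * dv / params$h_max))
    acl <- crown_c * dv * hv * laiv
    (pi / 8) * params$rho_s * dv^2 * hv + acl / params$sla + zetav * acl
  }
  dmass <- function(dv, laiv, zetav) {
    ex <- exp(-params$a * dv / params$h_max)
    hv <- params$h_max * (1 - ex)
    dhv <- params$a * ex
    dac <- crown_c * (hv + dv * dhv)
    (pi / 8) * params$rho_s * (2 * dv * hv + dv^2 * dhv) +
      (laiv / params$sla + zetav * laiv) * dac
  }
  fap <- 1 - exp(-params$k_ext * lai)
  d <- rep(d0, n)
  sum_rw <- numeric(n)
  gpp <- gpp[!is.na(gpp)]
  for (g in gpp) {
    h <- params$h_max * (1 - exp(-params$a * d / params$h_max))
    ac <- crown_c * d * h
    la <- ac * lai
    w_fol <- la / params$sla
    w_root <- zeta * la
    w_sap <- params$rho_s * (la / params$huber_inv) * h / 2
    npp <- pmax(0, params$yield *
                  (g * fap * ac * (1 - params$foliage_resp_frac) -
                     params$r_s * w_sap - params$r_r * w_root))
    avail <- npp - w_fol / params$tau_f - w_root / params$tau_r
    pos <- which(avail > 0)
    dd <- numeric(n)
    if (length(pos) > 0) {
      ds <- d[pos]; ls <- lai[pos]; zs <- zeta[pos]; as <- avail[pos]
      w0 <- mass(ds, ls, zs)
      x <- as / dmass(ds, ls, zs)
      for (k in 1:50) {
        resid <- mass(ds + x, ls, zs) - w0 - as
        if (all(abs(resid) <= 1e-12 * pmax(as, 1))) break
        x <- pmax(x - resid / dmass(ds + x, ls, zs), x / 10)
      }
      dd[pos] <- x
    }
    sum_rw <- sum_rw + dd / 2 * 1000
    d <- d + dd
  }
  sum_rw / length(gpp)
}

#' Simulate ring widths from a monthly forcing series
#'
#' Runs the photosynthesis model over the forcing, accumulates potential
#' GPP over the two-year carbon window of each ring year, and runs the
#' annual growth loop from an initial diameter (default 0.3 m). The first
#' two ring years of the forcing period are unavailable (incomplete
#' window).
#'
#' @param forcing A [forcing_series()] with a CO2 series attached;
#'   prepared automatically if needed.
#' @param params A [species_params()].
#' @param d0 Initial stem diameter, m.
#' @param constants A [p_constants()] list.
#' @return A `ring_series` data frame (see [grow_tree()]).
#' @export
simulate_growth <- function(forcing, params = species_params(), d0 = 0.3,
                            constants = p_constants()) {
  stopifnot(inherits(forcing, "forcing_series"))
  if (!is_prepared(forcing)) forcing <- prepare_forcing(forcing, constants)
  pm <- run_pmodel(forcing, constants)
  years <- sort(unique(forcing$year))
  gpp <- window_gpp(pm, years)
  if (all(is.na(gpp$gpp))) {
    stop("forcing too short: no ring year has a complete 24-month window")
  }
  grow_tree(gpp, params, d0)
}

#' Construct a ring-width series
#'
#' @param year Calendar years of ring formation.
#' @param rw_mm Ring widths, mm (non-negative).
#' @return A `ring_series` data frame.
#' @export
ring_series <- function(year, rw_mm) {
  stopifnot(length(year) == length(rw_mm), all(rw_mm >= 0),
            !anyDuplicated(year))
  structure(data.frame(year = year, rw_mm = rw_mm),
            class = c("ring_series", "data.frame"))
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %d rings (%d-%d), mean width %.3f mm\n",
              nrow(x), min(x$year), max(x$year), mean(x$rw_mm)))
  invisible(x)
}
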