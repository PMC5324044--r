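---
title: "A coupled light-use efficiency and carbon-allocation model of tree-ring growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled light-use efficiency and carbon-allocation model of tree-ring growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptgrowth)
```

## The problem

Tree rings are widely used to reconstruct climate, yet ring width is not a
direct record of photosynthesis: carbon gained by the canopy is divided
among stem, foliage and fine roots, and the division itself responds to the
environment. Under glacial atmospheres (~180 ppm CO2), leaf-internal CO2 in
C3 conifers sat barely above the photorespiratory compensation point, which
should have depressed gross primary production substantially — yet
glacial-age junipers grew rings as wide as their modern descendants.
`ptgrowth` implements the modelling chain needed to study that apparent
paradox: a light-use-efficiency photosynthesis model with optimality-based
stomatal behaviour, a geometric carbon-allocation model of annual radial
growth, a calibration layer, and the sensitivity experiments that decompose
glacial-versus-modern growth differences into their climatic and
physiological parts.

## The photosynthesis model

Monthly potential gross primary production per unit ground area is

$$\mathrm{GPP} = \varphi_0 \, I_{\mathrm{PAR}} \; m \;
  \left(\alpha / 1.26\right)^{1/4},$$

where $\varphi_0 = 0.816$ g C mol$^{-1}$ photon is the maximum quantum
efficiency in mass units (0.085 mol C mol$^{-1}$ photon $\times$ 12 g C
mol$^{-1}$ $\times$ a leaf absorptance of 0.8), $I_{\mathrm{PAR}}$ is the
photosynthetically active radiation incident during the growing season
(months with mean temperature strictly above $-1$ °C), $m$ is the CO2
limitation factor and $(\alpha/1.26)^{1/4}$ is an empirical drought
reduction driven by the moisture index $\alpha$ (the ratio of actual to
equilibrium evapotranspiration, capped at the Priestley–Taylor coefficient
1.26).

The CO2 limitation factor depends on the leaf-internal CO2 partial pressure
$c_i$ and the photorespiratory compensation point $\Gamma^*$:

$$m = \max\!\left(0, \frac{c_i - \Gamma^*}{c_i + 2\Gamma^*}\right), \qquad
  c_i = \Gamma^* + (c_a - \Gamma^*)\,\frac{\xi}{\xi + \sqrt{D}}, \qquad
  \xi = \sqrt{\frac{\beta\,(K + \Gamma^*)}{1.6\,\eta^*}}.$$

$c_i$ follows the least-cost optimality hypothesis: stomata are regulated
so that the combined unit costs of transpiration and carboxylation are
minimal, which makes the $c_i/c_a$ ratio fall with vapour pressure deficit
$D$ and rise with temperature (through the water viscosity ratio $\eta^*$
and the kinetic terms $K$ and $\Gamma^*$). These two dependencies act in
opposite directions under glacial climates — colder *and* wetter — which is
the mechanism that can hold $c_i/c_a$ stable while $c_a$ collapses.

Numerical notes:

* $\Gamma^* = 4.331\,\mathrm{Pa} \times e^{0.0512\,(T-25)} \times
  p/p_0$. The coefficient 0.0512 °C$^{-1}$ is the tangent of the Arrhenius
  response ($\Delta H_a = 37830$ J mol$^{-1}$) at 25 °C. The exponential
  agrees with full Arrhenius kinetics to better than 2 % between roughly
  10 and 35 °C but is about 12 % high at 0 °C; a single exponential in
  $\Delta T$ cannot track an Arrhenius curve to 2 % over the whole 0–35 °C
  range, and the package keeps the conventional tangent coefficient rather
  than a compromise fit. Both $\Gamma^*$ and the Michaelis–Menten
  constants scale linearly with atmospheric pressure, because they are
  partial-pressure quantities; this is what makes simulated $c_i/c_a$
  decline with elevation.
* $K = K_c (1 + p_{\mathrm{O_2}}/K_o)$ uses the standard Bernacchi-type
  constants ($K_{c,25} = 39.97$ Pa, $K_{o,25} = 27480$ Pa, activation
  energies 79430 and 36380 J mol$^{-1}$).
* $\eta^*$ uses the Korson-type correlation for the viscosity of pure
  water, accurate to ~0.1 % over 0–40 °C.
* $\beta$ (the unit-cost ratio at 25 °C) defaults to 240 and is the single
  most consequential tunable constant; it sets the absolute level of
  $c_i/c_a$ and should be the first target of any site-level sensitivity
  analysis.
* The drought factor is applied monthly. Whether it should instead apply
  to the annual total is genuinely open; monthly application is the
  default because $\alpha$ and the radiation load co-vary within the year,
  and an annual variant can be emulated by overwriting the `alpha` column
  of a prepared forcing series.
* Carboxylation capacity normalised to 25 °C ($V_{cmax,25}$, via the
  coordination hypothesis with $\Delta H_V = 65330$ J mol$^{-1}$) and
  stomatal conductance (Fick's law with the 1.6 diffusivity ratio) are
  diagnostic outputs only; they do not feed back into GPP.

## Driver preparation

`prepare_forcing()` turns a monthly climate table (temperature, diurnal
range, precipitation, vapour pressure, cloud) into the model drivers:

* **VPD** from the Magnus saturation curve, clipped at zero.
* **PAR** from an analytic daily top-of-atmosphere integral (solar
  declination and sunset hour angle), summed per month, attenuated by an
  Ångström-type transmissivity $\tau = (0.25 + 0.50\,s)(1 + 2.67\times
  10^{-5} z)$ with sunshine fraction $s = 1 - \mathrm{cloud}$ and elevation
  $z$, and converted at 2.04 µmol photon per joule of shortwave. All three
  coefficients are exposed in `p_constants()`.
* **$\alpha$** from a single-bucket monthly water balance: equilibrium
  evapotranspiration from net radiation (albedo 0.17) via the
  Priestley–Taylor relation, actual evapotranspiration limited by
  precipitation plus a 150 mm soil store, one climatology spin-up year
  starting from a full bucket. Months with no evaporative demand report
  the cap (1.26), so the drought factor is exactly 1 there.
* **Growing season**: strictly above $-1$ °C, so a month at exactly
  $-1$ °C is excluded.

Two correction utilities mirror the standard palaeo workflow:
`elevation_correct()` (additive for temperature and vapour pressure,
multiplicative for precipitation and cloud, with an additive fallback when
a coarse normal is zero) and `bias_correct_lgm()` (purely additive,
per calendar month, control-run climatology versus modern climatology —
precipitation clipped at zero). Additive precipitation correction for the
glacial series is a deliberate choice; a ratio variant can be obtained by
passing ratio-corrected climatologies through `elevation_correct()`
instead.

## The tree growth model

Annual allocation follows a geometric tree model with a saturating
height–diameter curve $H = H_{max}(1 - e^{-aD/H_{max}})$, crown area
$A_c = (\pi c / 4a) D H$, a paraboloid stem ($W_s = \tfrac{\pi}{8}\rho_s
D^2 H$), foliage $W_f = A_c L / \sigma$, fine roots $W_r = \zeta A_c L$
and a pipe-model sapwood pool (leaf area over a Huber-value cross-section,
mean conducting length $H/2$). Whole-tree NPP is

$$\mathrm{NPP} = y\,\bigl(\mathrm{GPP}\cdot f_{\mathrm{APAR}} \cdot A_c
  \,(1 - f_{resp}) - r_s W_{sap} - r_r W_r\bigr),$$

with $f_{\mathrm{APAR}} = 1 - e^{-kL}$ (Beer's law). The diameter
increment solves the annual balance

$$\mathrm{NPP} = \bigl[W(D + \Delta D) - W(D)\bigr] +
  W_f/\tau_f + W_r/\tau_r$$

exactly, by a safeguarded Newton iteration whose first step is the
linearised increment $\Delta D_0 = \text{available}/W'(D)$. The exact
solve (rather than stopping at the linear step) is a deliberate design
choice: for realistic conifer geometry the linearisation error is about
$\tfrac{1}{2}(W''/W')\Delta D$, i.e. ~3 % at $\Delta D / D = 0.05$, which
would leak carbon out of the annual balance. With the exact solve, every
simulated year closes the carbon ledger to solver precision and the ring
widths telescope exactly: $2\sum \mathrm{rw} = D_{final} - D_0$. The
one-step scheme remains available as `method = "linear"` in
`diameter_increment()`.

Ring width is the radius increment $\Delta D / 2$ (no bark or density
correction), carbon is accumulated over a two-year effective growing
season (July of year $-2$ to June of the ring year, annualised by halving
— the water-limited-species convention), and NPP is floored at zero with
no reserve pool or mortality. Under a constant repeated climatology the
model produces rings that rise smoothly to a stable asymptote: once height
saturates, both the available carbon and the marginal mass cost scale
linearly with diameter, so mature ring width tends to a constant — the
model's characteristic (and realistic) homoeostasis of mature radial
growth.

Default species parameters are a generic needleleaf set from the
allometric literature ($a = 116$, $c = 390.43$, $H_{max} = 25.33$ m,
$\rho_s = 200$ kg C m$^{-3}$, $L = 1.8$, $\sigma = 14$ m$^2$ kg$^{-1}$ C,
$\tau_f = 4$ a, $\tau_r = 1.04$ a, $r_s = 0.044$ a$^{-1}$,
$r_r = 0.913$ a$^{-1}$, $\zeta = 0.17$ kg C m$^{-2}$, $y = 0.6$,
$k = 0.5$, Huber value $1/3000$, foliage respiration fraction 0.10). They
are placeholders for site calibration, not juniper measurements.

## Calibration by rejection ABC

`abc_rejection()` draws parameter vectors from independent truncated
normal priors (median of the published values, sd half the median,
truncated to $(0, 4 \times \mathrm{median}]$), runs the forward model, and
accepts draws whose mean simulated ring width falls within ±2.5 % of the
observed mean. The point estimate is the posterior mean (configurable to
the median). Rejection sampling — rather than an SMC or MCMC scheme — is
the minimal reproducible reading of a fixed ±2.5 % convergence band, and
zero acceptances raise an error instead of silently widening the band.

`optimize_allocation()` frees only the two allocation parameters $L$ and
$\zeta$. Because potential GPP per unit ground area does not depend on the
tree parameters, the photosynthesis chain is evaluated once per CO2 level
and only the cheap annual allocation loop runs per draw; the loop is
vectorised across draws, so a 5000-draw calibration takes about a second.

**Identifiability caveat.** The single summary statistic (mean ring width)
constrains a one-dimensional ridge in the $(L, \zeta)$ plane, not a point.
Mean ring width is non-monotone in $L$ (Beer's-law light capture saturates
while foliage and root costs grow linearly), and the ridge is flat in $L$
on its upper side, so the posterior mean of $L$ sits systematically above
the truth (~10–17 % in the package's synthetic recovery runs) even with
noise-free observations, while $\zeta$ is recovered to within a few
percent. Conclusions about $L$ from this calibration should therefore
lean on relative changes across CO2 levels (which difference the bias
away), not on its absolute value.

## The synthetic forcing generator

`generate_monthly_climate()` emulates a monthly gridded-climate extract
for a single site: a sinusoidal seasonal temperature cycle (July peak in
the north) with stationary AR(1) noise, winter-dominated precipitation
with mean-preserving multiplicative lognormal noise, vapour pressure as
relative humidity times the Magnus saturation pressure (so synthetic
humidity is self-consistent with the VPD computed later), constant diurnal
range, and near-constant cloud. The defaults describe a cool
high-elevation southern Sierra Nevada juniper site (7.5 °C mean annual
temperature, 9 °C seasonal amplitude, 700 mm a$^{-1}$ with 80 % falling
October–March, relative humidity 0.55, cloud 0.4). Glacial-style scenarios
are built with `apply_anomalies()` — the default anomaly (−4 °C year
round, +200 mm a$^{-1}$, +0.05 relative humidity) sits mid-range of the
regional palaeo-reconstructions — and relative humidity, not vapour
pressure, is the quantity conserved through temperature shifts. The
interannual variance of the glacial series is a free knob (the underlying
coupled-model variability is internal, not forced); the generator keeps
the modern noise settings unless told otherwise.

What the generator deliberately does not emulate: daily weather, spatial
fields, low-frequency (decadal-plus) climate modes beyond AR(1)
persistence, volcanic/solar forcing, and observation error structure in
real ring-width series (which is between-tree, not i.i.d. Gaussian).
Passing tests on synthetic data therefore demonstrate internal
consistency and the documented response directions, not skill against
real chronologies.

## The experiment suite

* `run_modern_validation()` — simulated versus observed mean width,
  interannual correlation, and correlation of 10-year running means.
* `run_cica_profile()` — annual GPP-weighted $c_i/c_a$ across site
  elevations (pressure and transmissivity respond; an optional lapse rate
  shifts temperature).
* `run_cica_swap()` — the four-way temperature/VPD factorial between a
  modern and a glacial forcing. Temperature and VPD are the only climate
  variables entering $c_i/c_a$; CO2, PAR and $\alpha$ stay at the glacial
  baseline in all four scenarios so the decomposition is clean.
* `run_co2_gradient()` — re-optimises $(L, \zeta)$ at each CO2 level
  against a fixed target width and reports percentage changes against the
  320 ppm reference.
* `run_climate_substitution()` — substitutes modern temperature,
  precipitation and/or relative humidity (state variables: T, P, RH;
  vapour pressure is recomputed from the active pair) into the glacial
  baseline, holding CO2 glacial; `Full` also substitutes diurnal range
  and cloud. Modern and glacial series are aligned by position after
  truncation to their common length.
* `accumulation_window_regression()` — OLS of ring width on five
  accumulated drivers (total PAR, mean temperature, mean $\alpha$, mean
  VPD, mean CO2) for each candidate window length; on rings generated by
  the model itself the 24-month window attains the highest $R^2$ among
  {12, 24, 36} months.

A caution from the package's own experiments: the sign of the
temperature-substitution response depends on the site. At a warm lowland
site the modern (warmer, drier) temperatures reduce simulated glacial
ring width through VPD, photorespiration and drought; at a cool
high-elevation site the same substitution *increases* growth because
growing-season extension dominates. Substitution experiments should be run
at the site whose climate question is being asked.

## Problem sizes and reproducibility

The bundled tests run entirely on synthetic data built at test time:
forcing series of 3–90 years, ABC with 600–5000 draws, and a 500-year
series only for the generator's long-run moment checks; the whole suite
completes in a few seconds on one core. Every stochastic step (generator,
observation noise, ABC draws) is seeded explicitly and restores the
caller's RNG state, so all results are bit-reproducible given the
configuration. `scripts/acceptance.R` recomputes the package's reference
quantity from a fresh session (see the README).

## Known limitations

* Electron-transport ($J_{max}$) limitation, temperature dependence of
  $\varphi_0$, C4 photosynthesis and nutrient feedbacks are out of scope.
* The exact forms of the published tree model could not all be recovered
  from the sources at hand; the reconstruction honours every stated
  constraint (asymptotic height, initial crown:stem ratio, Beer's law,
  pool definitions, turnover) but parity with the original code is not
  guaranteed. The sapwood pool in particular is a pipe-model construction
  whose constant is absorbed by the calibrated sapwood respiration rate.
* Single-tree, single-species: no competition, mortality, bark, or
  within-ring density.
* The ABC layer matches one summary statistic; see the identifiability
  caveat above before interpreting absolute posterior locations.
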