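# ptgrowth

Simulation of annual tree-ring growth from monthly climate, for
plant-ecophysiology and palaeo-ecology questions of the form: *how could
trees keep growing normal rings under a glacial atmosphere of ~180 ppm
CO2?* The package couples

* a **light-use-efficiency photosynthesis model** in which the
  leaf-internal CO2 partial pressure follows the least-cost optimality
  hypothesis,

  GPP = φ₀ · I_PAR · m · (α/1.26)^¼,  m = (cᵢ − Γ\*)/(cᵢ + 2Γ\*),
  cᵢ = Γ\* + (cₐ − Γ\*)·ξ/(ξ + √D),  ξ = √(β(K + Γ\*)/1.6η\*),

  with Γ\* = 4.331 Pa at 25 °C scaled by an exponential temperature
  response and by atmospheric pressure, and

* a **geometric carbon-allocation tree model** that divides annual NPP
  between stem, foliage and fine roots under allometric constraints
  (saturating height–diameter curve, crown:stem ratio, Beer's-law canopy
  absorption, pool turnover) and returns ring width as half the annual
  diameter increment, with the carbon ledger closed exactly every year.

Around the core sit a synthetic monthly-climate and CO2 generator with
glacial-style anomaly construction, driver preparation (VPD, solar-geometry
PAR, a Priestley–Taylor bucket moisture index, elevation and paleo bias
corrections, the two-year carbon accumulation window), rejection-ABC
calibration of the allocation parameters (leaf area index L and fine-root
mass per leaf area ζ) against an observed mean ring width, the
glacial-versus-modern experiment suite (validation, cᵢ/cₐ elevation
profiles, temperature/VPD swaps, CO2-gradient allocation optimisation,
climate-variable substitutions, accumulation-window regression), and
Tucson/RWL plus plain tabular file I/O. The methods vignette
(`vignettes/pt-growth-model.Rmd`) documents the model forms, constants and
design choices in full.

## Worked example

Build a modern and a glacial scenario for a warm lowland site (a tar-pit
locality analogue: 34.06° N, 80 m a.s.l.), compare the photosynthesis
diagnostics, and run two of the headline experiments:

```r
library(ptgrowth)

site <- site_meta(34.06, -118.36, 80)
cfg <- synthetic_climate_config(n_years = 60, mean_annual_temp = 17,
  seasonal_amplitude = 5, diurnal_range = 9, annual_precip = 380,
  precip_winter_fraction = 0.85, mean_relative_humidity = 0.65,
  cloud_fraction = 0.35, seed = 2)
modern  <- generate_monthly_climate(cfg, site)
modern  <- set_co2(modern, generate_co2_series(unique(modern$year), "constant", 320))
glacial <- apply_anomalies(modern, anomaly_config(delta_temp = -4,
             delta_precip = 200 / 12, delta_rh = 0.05))
glacial <- set_co2(glacial, generate_co2_series(unique(glacial$year), "constant", 180))
modern  <- prepare_forcing(modern)
glacial <- prepare_forcing(glacial)

ann_m <- annual_pmodel_summary(run_pmodel(modern))
ann_g <- annual_pmodel_summary(run_pmodel(glacial))

run_cica_swap(modern, glacial)
run_climate_substitution(glacial, modern, species_params(),
                         experiments = c("T", "P", "TPH"))
```

which prints (numbers as produced by the code above):

```
GPP  modern 4.53  glacial 4.75 kg C m-2 a-1
ci/ca modern 0.749  glacial 0.759
Vcmax25 glacial/modern 1.56   gs glacial/modern 1.93

           scenario      cica
            glacial 0.7589140
 modernT_glacialVPD 0.8017667
 glacialT_modernVPD 0.7214786
             modern 0.7689119

 experiment  mean_rw pct_change
    glacial 7.504969    0.00000
          T 6.219137  -17.13308
          P 5.668845  -24.46545
        TPH 4.523468  -39.72703
```

Reading the output: the glacial scenario (cooler, wetter, 180 ppm) holds
annual cᵢ/cₐ essentially at the modern value — the swap table shows why:
substituting the warmer modern temperature alone *raises* cᵢ/cₐ (0.759 →
0.802) while substituting the drier modern VPD alone *lowers* it (0.759 →
0.721), two nearly equal and opposite effects. Carboxylation capacity and
stomatal conductance are substantially higher under glacial CO2 (ratios
1.56 and 1.93). The substitution experiments show that replacing the
favourable glacial climate with modern temperature, precipitation, or
all three state variables reduces simulated glacial ring width by 17 %,
24 % and 40 % respectively: the regional glacial climate did real work in
sustaining growth at low CO2.

Calibration of the allocation parameters against an observed mean ring
width is one call:

```r
res <- optimize_allocation(glacial, co2_level = 180, target_mean_rw = 1.83,
                           params = species_params(),
                           config = abc_config(n_draws = 5000, seed = 1))
res$lai; res$zeta          # point estimates (posterior means)
res$abc$acceptance_rate
```

and `run_co2_gradient()` repeats it along a 320→160 ppm gradient,
reporting the percentage change of L and ζ against the 320 ppm reference.

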