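# Shared fixtures: all synthetic, built in code at test time.

test_site <- function(elevation = 2630) {
  site_meta(36.95, -118.92, elevation)
}

# Cool high-elevation calibration-site analogue (generator defaults).
make_forcing <- function(n_years = 30, seed = 1, co2_mode = "constant",
                         co2 = 300, ...) {
  cfg <- synthetic_climate_config(n_years = n_years, seed = seed, ...)
  f <- generate_monthly_climate(cfg)
  set_co2(f, generate_co2_series(unique(f$year), co2_mode, co2))
}

# Warm lowland tar-pit-site analogue (LA-area climate normals).
labrea_config <- function(...) {
  synthetic_climate_config(mean_annual_temp = 17, seasonal_amplitude = 5,
                           diurnal_range = 9, annual_precip = 380,
                           precip_winter_fraction = 0.85,
                           mean_relative_humidity = 0.65,
                           cloud_fraction = 0.35, ...)
}

labrea_site <- function() site_meta(34.06, -118.36, 80)

# Modern / glacial forcing pair at the warm lowland site: glacial is the
# modern climate shifted by the standard anomaly (-4 C, +200 mm/a,
# +0.05 RH) with 180 ppm CO2, modern holds 320 ppm.
labrea_pair <- function(n_years = 60, seed = 2) {
  f <- generate_monthly_climate(labrea_config(n_years = n_years, seed = seed),
                                labrea_site())
  modern <- set_co2(f, generate_co2_series(unique(f$year), "constant", 320))
  glacial <- apply_anomalies(f, anomaly_config())
  glacial <- set_co2(glacial,
                     generate_co2_series(unique(glacial$year), "constant", 180))
  list(modern = prepare_forcing(modern), glacial = prepare_forcing(glacial))
}
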