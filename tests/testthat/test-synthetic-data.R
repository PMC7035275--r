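# The synthetic campaign generator: determinism, forward model, design
# counts and covariate structure.

test_that("the same seed reproduces the campaign exactly", {
  cfg <- tiny_scenario(seed = 5)
  a <- generate_campaign(cfg)
  b <- generate_campaign(cfg)
  expect_identical(a$closures, b$closures)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$truth$closure_truth, b$truth$closure_truth)
  c_ <- generate_campaign(tiny_scenario(seed = 6))
  expect_false(identical(a$closures$ppm, c_$closures$ppm))
})

test_that("zero noise and zero curvature give exactly linear closures", {
  cfg <- tiny_scenario(
    seed = 5,
    noise_ppm_sd = list(static_stem = c(CH4 = 0, N2O = 0),
                        dynamic_soil = c(CH4 = 0, N2O = 0, CO2 = 0))
  )
  camp <- generate_campaign(cfg)
  key <- paste(camp$closures$chamber_id, camp$closures$closure_start,
               camp$closures$gas)
  some <- camp$closures[key %in% head(unique(key), 12), ]
  for (piece in split(some, paste(some$chamber_id, some$closure_start, some$gas))) {
    d2 <- diff(diff(piece$ppm) / diff(piece$t_seconds))
    expect_lt(max(abs(d2)), 1e-9)
  }
})

test_that("stem campaigns count 5, 6 and 4 measurement sets per period by default", {
  cfg <- scenario_config()
  days <- stemflux:::stem_measurement_days(cfg)
  period <- stemflux:::campaign_days(cfg)
  counts <- table(period$period[period$day %in% days])
  expect_identical(as.integer(counts[c("pre", "experiment", "post")]),
                   c(5L, 6L, 4L))
  # and the generated closures honour the configured sets
  camp <- shared_campaign()
  stem_cl <- camp$closures[grepl("_H", camp$closures$chamber_id), ]
  per_period <- tapply(substr(stem_cl$closure_start, 1, 10), stem_cl$period,
                       function(x) length(unique(x)))
  expect_identical(as.integer(per_period[c("pre", "experiment", "post")]),
                   as.integer(camp$config$stem_sets[c("pre", "experiment", "post")]))
})

test_that("the estimator inverts the noiseless forward model for every chamber kind", {
  cfg <- tiny_scenario(
    seed = 9,
    noise_ppm_sd = list(static_stem = c(CH4 = 0, N2O = 0),
                        dynamic_soil = c(CH4 = 0, N2O = 0, CO2 = 0))
  )
  camp <- generate_campaign(cfg)
  fluxes <- estimate_fluxes(camp$closures, camp$chambers)
  joined <- dplyr::inner_join(
    fluxes, camp$truth$closure_truth,
    by = c("chamber_id", "closure_start", "gas", "plot_id", "period")
  )
  expect_identical(nrow(joined), nrow(fluxes))
  expect_true(all(c("static_stem", "dynamic_soil") %in% joined$kind))
  rel <- abs(joined$flux_ug_m2_h - joined$true_flux) /
    pmax(abs(joined$true_flux), 1e-12)
  expect_lt(max(rel), 1e-8)
})

test_that("simulate_closure validates inputs and matches its stated forward model", {
  ch <- soil_chamber()
  s <- simulate_closure(36, ch, 0:10, gas = "CH4", noise_ppm_sd = 0)
  mass <- ppm_to_mass(s$ppm, "CH4", 290)
  expect_equal(diff(mass), rep(36 / 3600 / 0.2, 10), tolerance = 1e-10)
  expect_error(simulate_closure(1, ch, numeric(0)), class = "stemflux_error_config")
  expect_error(simulate_closure(1, ch, 0:5, noise_ppm_sd = -1),
               class = "stemflux_error_config")
  expect_error(simulate_closure(1, ch, 0:5, lambda = -1),
               class = "stemflux_error_config")
})

test_that("covariates carry the flooding structure and flux-covariate signs", {
  camp <- generate_campaign(small_scenario(seed = 3, soil_closures_per_day = 1))
  cov <- camp$covariates
  cp <- cov[cov$plot_id == "CP", ]
  fp <- cov[cov$plot_id == "FP", ]
  # control plot stays near baseline; flooded plot steps up during flooding
  expect_lt(max(abs(cp$swc - 0.30)), 0.05)
  expect_gt(mean(fp$swc[fp$period == "experiment"]) - mean(fp$swc[fp$period == "pre"]), 0.15)
  # nitrate dips while ammonium rises under flooding
  expect_lt(mean(fp$no3_mg_kg[fp$period == "experiment"]),
            mean(fp$no3_mg_kg[fp$period == "pre"]))
  expect_gt(mean(fp$nh4_mg_kg[fp$period == "experiment"]),
            mean(fp$nh4_mg_kg[fp$period == "pre"]))
  d <- dplyr::inner_join(camp$truth$daily, cov, by = c("plot_id", "day", "period"))
  soil_ch4 <- d[d$gas == "CH4" & d$source == "soil", ]
  soil_n2o <- d[d$gas == "N2O" & d$source == "soil", ]
  expect_gt(cor(soil_ch4$swc, soil_ch4$true_level), 0)
  expect_lt(cor(soil_n2o$nh4_mg_kg, soil_n2o$true_level), 0)
})

test_that("delayed CH4 and transient N2O responses shape the true flux field", {
  cfg <- scenario_config()
  days <- stemflux:::campaign_days(cfg)
  m_ch4 <- stemflux:::flood_multiplier(days$day, cfg$soil_truth$CH4, cfg)
  # no response during the lag, persistent response afterwards
  expect_identical(m_ch4[days$period == "pre"], rep(1, 14))
  expect_identical(m_ch4[15:18], rep(1, 4))
  expect_identical(m_ch4[19:28], rep(3, 10))
  expect_identical(m_ch4[days$period == "post"], rep(12, 14))
  m_n2o <- stemflux:::flood_multiplier(days$day, cfg$soil_truth$N2O, cfg)
  expect_equal(max(m_n2o), 8)
  expect_identical(which.max(m_n2o), 15L)  # pulse peaks at flooding onset
  expect_lt(m_n2o[42], 1)                  # relaxes below baseline post-flood
})

test_that("invalid scenario configurations name the offending fields", {
  expect_error(scenario_config(stem_sets = c(pre = 20, experiment = 6, post = 4)),
               class = "stemflux_error_config", regexp = "stem_sets")
  expect_error(
    scenario_config(noise_ppm_sd = list(static_stem = c(CH4 = -1, N2O = 0),
                                        dynamic_soil = c(CH4 = 0, N2O = 0, CO2 = 0))),
    class = "stemflux_error_config", regexp = "noise"
  )
  expect_error(scenario_config(n_profile_trees = c(FP = 10, CP = 2)),
               class = "stemflux_error_config", regexp = "n_profile_trees")
})
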