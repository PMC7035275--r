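# Shared fixtures built in code. The tiny scenario trims plot sizes, day
# counts and soil sampling intensity so the mechanical tests run fast; the
# small scenario keeps the full campaign design and only reduces the number
# of automated soil closures per day.

tiny_scenario <- function(seed = 1, ...) {
  scenario_config(
    seed = seed,
    period_days = c(pre = 6, experiment = 6, post = 6),
    stem_sets = c(pre = 2, experiment = 3, post = 2),
    n_trees = c(FP = 4, CP = 2),
    n_profile_trees = c(FP = 3, CP = 1),
    soil_closures_per_day = 2,
    ...
  )
}

small_scenario <- function(seed = 1, soil_closures_per_day = 2, ...) {
  scenario_config(seed = seed, soil_closures_per_day = soil_closures_per_day, ...)
}

# one campaign reused across test files
shared_campaign <- local({
  camp <- NULL
  function() {
    if (is.null(camp)) camp <<- generate_campaign(tiny_scenario(seed = 101))
    camp
  }
})

# assemble a closures table from per-gas (gas, true_flux) pairs for one
# chamber, through the simulate_closure forward model
make_closure <- function(chamber, fluxes, t, temp_k = 290,
                         pressure_pa = STANDARD_PRESSURE, noise_ppm_sd = 0,
                         lambda = 0, period = "experiment",
                         closure_start = "2017-08-10T12:00:00Z",
                         ambient = c(CH4 = 1.9, N2O = 0.33, CO2 = 410)) {
  rows <- lapply(names(fluxes), function(g) {
    s <- simulate_closure(fluxes[[g]], chamber, t, gas = g, temp_k = temp_k,
                          pressure_pa = pressure_pa,
                          noise_ppm_sd = noise_ppm_sd, lambda = lambda,
                          ambient_ppm = ambient[[g]])
    tibble::tibble(
      chamber_id = chamber$chamber_id, closure_start = closure_start,
      period = period, plot_id = chamber$plot_id,
      t_seconds = s$t_seconds, gas = s$gas, ppm = s$ppm,
      temp_k = temp_k, pressure_pa = pressure_pa
    )
  })
  dplyr::bind_rows(rows)
}

soil_chamber <- function(id = "SOIL1", plot = "FP") {
  chamber_spec(id, "dynamic_soil", plot_id = plot)
}

stem_chamber <- function(id = "STEM1", plot = "FP", h = 0.1) {
  chamber_spec(id, "static_stem", plot_id = plot, tree_id = "T1",
               mount_height_m = h)
}

soil_grid_1hz <- seq(0, 540, by = 1)
stem_grid_gc <- c(0, 3600, 7200, 10800)
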