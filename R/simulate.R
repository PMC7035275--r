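#' Synthetic flooding-campaign scenario configuration
#'
#' Defines a complete simulated chamber campaign with known ground truth:
#' a flooded plot (FP) and a control plot (CP), three campaign periods
#' (pre-experimental, experimental flooding, post-experimental), manual
#' static stem chambers in vertical profiles sampled on discrete campaign
#' days, and automated soil chambers measured daily. True fluxes follow
#' the response structure such a flooding manipulation produces: soil
#' water content steps up in the flooded plot and CH4 emissions rise with
#' it after a lag of a few days; N2O emits a transient pulse that decays
#' as nitrate is consumed while ammonium accumulates; stem fluxes decline
#' exponentially with height.
#'
#' @param seed integer seed fixing every random draw.
#' @param period_days named days per period (`pre`, `experiment`, `post`).
#' @param stem_sets stem measurement days per period (campaign design:
#'   5 pre, 6 experimental, 4 post).
#' @param n_trees trees with stem chambers per plot (`FP`, `CP`).
#' @param n_profile_trees trees carrying the full three-height vertical
#'   profile; the remainder have only the lowest chamber.
#' @param heights_m stem chamber heights (m above ground).
#' @param stem_sample_times_s GC syringe sampling times within a stem
#'   closure (s); default the 0/60/120/180 min sequence.
#' @param soil_closures_per_day automated closures per soil chamber per
#'   day (field systems reach about 12; reduce for fast simulations).
#' @param soil_sample_hz analyser sampling frequency (Hz).
#' @param soil_closure_s soil closure duration (s).
#' @param stem_truth,soil_truth per-gas true-flux definitions: `F0`/`base`
#'   baseline flux (ug m-2 h-1 on the source's own area), `k` height-decay
#'   rate (m-1, stems), `flood_mult` flooding response multiplier,
#'   `post_mult` multiplier in the post period (step mode), `lag_days`
#'   delay after flooding onset, `mode` `"step"` (persistent, CH4-like) or
#'   `"pulse"` (transient with `decay_days` e-folding, N2O-like).
#' @param noise_ppm_sd instrument noise (ppm, 1 sd) per chamber kind and gas.
#' @param between_sdlog lognormal sd of fixed between-tree / between-soil-
#'   chamber flux variability.
#' @param day_sdlog lognormal sd of day-to-day flux jitter.
#' @param lambda_s first-order headspace feedback rate (s-1); 0 gives the
#'   purely linear accumulation the flux estimator assumes.
#' @param ambient_ppm ambient mole fractions at closure start.
#' @param pressure_pa chamber pressure.
#' @param swc_coupling multiplier `exp(coupling * (SWC - baseline SWC))`
#'   applied to true CH4 fluxes, tying them to soil moisture.
#' @param stand_density,stand_dbh,stand_height stand geometry shared by
#'   both plots (1500 trees ha-1, 0.17 m DBH, 19.2 m height).
#' @param integration_height_m profile integration height (m).
#' @param start_date first campaign day (ISO date) for closure timestamps.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(
    seed = 1,
    period_days = c(pre = 14, experiment = 14, post = 14),
    stem_sets = c(pre = 5, experiment = 6, post = 4),
    n_trees = c(FP = 9, CP = 4),
    n_profile_trees = c(FP = 6, CP = 2),
    heights_m = c(0.10, 0.80, 1.70),
    stem_sample_times_s = c(0, 3600, 7200, 10800),
    soil_closures_per_day = 12,
    soil_sample_hz = 1.17,
    soil_closure_s = 540,
    stem_truth = list(
      CH4 = list(F0 = 5, k = 1.5, flood_mult = 100, post_mult = 100,
                 lag_days = 4, mode = "step"),
      N2O = list(F0 = 5, k = 1.2, flood_mult = 4, lag_days = 0,
                 mode = "pulse", decay_days = 3, floor = 0.3)
    ),
    soil_truth = list(
      CO2 = list(base = 150000, flood_mult = 1, post_mult = 1,
                 lag_days = 0, mode = "step"),
      CH4 = list(base = 1, flood_mult = 3, post_mult = 12,
                 lag_days = 4, mode = "step"),
      N2O = list(base = 20, flood_mult = 8, lag_days = 0,
                 mode = "pulse", decay_days = 3, floor = 0.3)
    ),
    noise_ppm_sd = list(
      static_stem = c(CH4 = 0.03, N2O = 0.003),
      dynamic_soil = c(CH4 = 0.0015, N2O = 4e-4, CO2 = 0.8)
    ),
    between_sdlog = 0.3,
    day_sdlog = 0.1,
    lambda_s = 0,
    ambient_ppm = c(CH4 = 1.9, N2O = 0.33, CO2 = 410),
    pressure_pa = STANDARD_PRESSURE,
    swc_coupling = 2,
    stand_density = 0.15,
    stand_dbh = 0.17,
    stand_height = 19.2,
    integration_height_m = 1.7,
    start_date = "2017-07-24") {
  cfg <- list(
    seed = seed, period_days = period_days, stem_sets = stem_sets,
    n_trees = n_trees, n_profile_trees = n_profile_trees,
    heights_m = heights_m, stem_sample_times_s = stem_sample_times_s,
    soil_closures_per_day = soil_closures_per_day,
    soil_sample_hz = soil_sample_hz, soil_closure_s = soil_closure_s,
    stem_truth = stem_truth, soil_truth = soil_truth,
    noise_ppm_sd = noise_ppm_sd, between_sdlog = between_sdlog,
    day_sdlog = day_sdlog, lambda_s = lambda_s,
    ambient_ppm = ambient_ppm, pressure_pa = pressure_pa,
    swc_coupling = swc_coupling,
    stand_density = stand_density, stand_dbh = stand_dbh,
    stand_height = stand_height,
    integration_height_m = integration_height_m,
    start_date = start_date
  )
  class(cfg) <- "scenario_config"
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(cfg) {
  bad <- character(0)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) bad <- c(bad, "seed")
  if (any(cfg$period_days < 1)) bad <- c(bad, "period_days")
  if (any(cfg$stem_sets < 1) || any(cfg$stem_sets > cfg$period_days)) bad <- c(bad, "stem_sets")
  if (any(cfg$n_profile_trees > cfg$n_trees)) bad <- c(bad, "n_profile_trees")
  sds <- unlist(cfg$noise_ppm_sd)
  if (any(sds < 0)) bad <- c(bad, "noise_ppm_sd")
  if (cfg$between_sdlog < 0 || cfg$day_sdlog < 0) bad <- c(bad, "between_sdlog/day_sdlog")
  if (cfg$lambda_s < 0) bad <- c(bad, "lambda_s")
  mults <- c(
    vapply(cfg$stem_truth, function(g) g$flood_mult, 1),
    vapply(cfg$soil_truth, function(g) g$flood_mult, 1)
  )
  if (any(mults <= 0)) bad <- c(bad, "flood_mult")
  if (cfg$soil_closures_per_day < 1 || cfg$soil_sample_hz <= 0) bad <- c(bad, "soil sampling")
  if (length(bad) > 0) {
    stop_stemflux("config",
                  paste0("Invalid scenario fields: ", paste(unique(bad), collapse = ", ")))
  }
  invisible(cfg)
}

# campaign day bookkeeping -------------------------------------------------

campaign_days <- function(cfg) {
  pd <- cfg$period_days
  tibble::tibble(
    day = seq_len(sum(pd)),
    period = rep(c("pre", "experiment", "post"), times = pd),
    day_in_period = unlist(lapply(pd, seq_len), use.names = FALSE)
  )
}

stem_measurement_days <- function(cfg) {
  days <- campaign_days(cfg)
  offsets <- c(pre = 0, experiment = cfg$period_days[["pre"]],
               post = cfg$period_days[["pre"]] + cfg$period_days[["experiment"]])
  unlist(lapply(c("pre", "experiment", "post"), function(p) {
    d <- cfg$period_days[[p]]
    n <- cfg$stem_sets[[p]]
    offsets[[p]] + unique(round(seq(1, d, length.out = n)))
  }), use.names = FALSE)
}

# flooding response multiplier for one gas spec, vectorised over days
flood_multiplier <- function(day, spec, cfg) {
  exp_start <- cfg$period_days[["pre"]] + 1
  exp_end <- exp_start + cfg$period_days[["experiment"]] - 1
  onset <- exp_start + (spec$lag_days %||% 0)
  m <- rep(1, length(day))
  if (identical(spec$mode, "pulse")) {
    # transient denitrification burst while nitrate lasts, relaxing to a
    # suppressed floor under sustained anoxia (complete reduction to N2)
    decay <- spec$decay_days %||% 3
    floor_mult <- spec$floor %||% 0.3
    s <- day - onset   # days since pulse onset (0 = onset day)
    act <- day >= onset
    m[act] <- floor_mult + (spec$flood_mult - floor_mult) * exp(-s[act] / decay)
  } else {
    in_exp <- day >= onset & day <= exp_end
    in_post <- day > exp_end
    m[in_exp] <- spec$flood_mult
    m[in_post] <- spec$post_mult %||% spec$flood_mult
  }
  m
}

# deterministic covariate trajectories (before measurement noise)
covariate_det <- function(cfg) {
  days <- campaign_days(cfg)
  exp_start <- cfg$period_days[["pre"]] + 1
  exp_end <- exp_start + cfg$period_days[["experiment"]] - 1
  grid <- tidyr::expand_grid(plot_id = c("FP", "CP"), days)
  d <- grid$day
  flooded <- grid$plot_id == "FP"
  swc <- rep(0.30, nrow(grid))
  in_exp <- flooded & d >= exp_start & d <= exp_end
  in_post <- flooded & d > exp_end
  # ramps to saturation over ~3 days of flooding, drains with 7-day e-folding
  swc[in_exp] <- 0.30 + 0.25 * pmin(1, (d[in_exp] - exp_start + 1) / 3)
  swc[in_post] <- 0.30 + 0.25 * exp(-(d[in_post] - exp_end) / 7)
  no3 <- rep(20, nrow(grid))
  nh4 <- rep(5, nrow(grid))
  # denitrification draws nitrate down while ammonium accumulates under
  # anoxia, partially recovering after drainage
  no3[in_exp] <- 6 + 14 * exp(-(d[in_exp] - exp_start + 1) / 5)
  no3[in_post] <- 6 + 6 * (1 - exp(-(d[in_post] - exp_end) / 10))
  nh4[in_exp] <- 15 - 10 * exp(-(d[in_exp] - exp_start + 1) / 8)
  nh4[in_post] <- 10 + 5 * exp(-(d[in_post] - exp_end) / 10)
  air_t <- 17 + 2 * sin(2 * pi * (d - 10) / sum(cfg$period_days))
  grid$swc <- swc; grid$no3_mg_kg <- no3; grid$nh4_mg_kg <- nh4
  grid$air_temp_c <- air_t
  grid$soil_temp_c <- air_t - 2
  grid
}

covariates_impl <- function(cfg) {
  cov <- covariate_det(cfg)
  n <- nrow(cov)
  cov$swc <- pmax(0.01, cov$swc + rnorm(n, 0, 0.01))
  cov$no3_mg_kg <- pmax(0, cov$no3_mg_kg + rnorm(n, 0, 1))
  cov$nh4_mg_kg <- pmax(0, cov$nh4_mg_kg + rnorm(n, 0, 0.5))
  cov$air_temp_c <- cov$air_temp_c + rnorm(n, 0, 1)
  cov$soil_temp_c <- cov$soil_temp_c + rnorm(n, 0, 0.5)
  cov
}

#' Generate plot-by-day soil covariates for a scenario
#'
#' Deterministic flooding trajectories (soil water content stepping up in
#' the flooded plot during the experiment and draining afterwards, nitrate
#' depletion with ammonium accumulation) plus measurement noise, seeded by
#' the scenario seed.
#'
#' @param cfg a [scenario_config()].
#' @return A tibble: `plot_id`, `day`, `period`, `day_in_period`, `swc`,
#'   `no3_mg_kg`, `nh4_mg_kg`, `air_temp_c`, `soil_temp_c`.
#' @export
generate_covariates <- function(cfg) {
  validate_scenario(cfg)
  set.seed(cfg$seed)
  covariates_impl(cfg)
}

# true daily flux multipliers from deterministic covariates (CH4 couples to
# soil moisture; N2O timing is carried by the pulse shape itself)
covariate_factor <- function(gas, swc_det, cfg) {
  if (gas == "CH4") exp(cfg$swc_coupling * (swc_det - 0.30)) else rep(1, length(swc_det))
}

#' Simulate a single chamber closure
#'
#' Forward model of headspace accumulation over an emitting surface: the
#' mass concentration follows `C(t) = C0 + S * t` with
#' `S = flux/3600 * A/V` for `lambda = 0`, or the first-order feedback
#' form `C(t) = C0 + S * (1 - exp(-lambda t)) / lambda` when the
#' headspace build-up suppresses the flux. The series is converted to ppm
#' and Gaussian instrument noise is added in ppm space (draws come from
#' the current RNG state).
#'
#' @param true_flux true areal flux (ug m-2 h-1) on the chamber's surface.
#' @param chamber a `chamber_spec` row.
#' @param t sample times (s since closure).
#' @param gas gas name.
#' @param temp_k,pressure_pa closure conditions.
#' @param noise_ppm_sd instrument noise sd (ppm), >= 0.
#' @param lambda first-order feedback rate (s-1), >= 0.
#' @param ambient_ppm starting mole fraction (ppm).
#' @param registry gas registry.
#' @return A tibble: `t_seconds`, `gas`, `ppm`.
#' @export
simulate_closure <- function(true_flux, chamber, t, gas = "CH4",
                             temp_k = 290, pressure_pa = STANDARD_PRESSURE,
                             noise_ppm_sd = 0, lambda = 0,
                             ambient_ppm = 1.9, registry = gas_registry()) {
  if (length(t) == 0) stop_stemflux("config", "Sampling scheme is empty.")
  if (noise_ppm_sd < 0) stop_stemflux("config", "noise_ppm_sd must be >= 0.")
  if (lambda < 0) stop_stemflux("config", "lambda must be >= 0.")
  c0 <- ppm_to_mass(ambient_ppm, gas, temp_k, pressure_pa, registry)
  s_mass <- true_flux / 3600 / effective_height(chamber)
  accum <- if (lambda == 0) s_mass * t else s_mass * (1 - exp(-lambda * t)) / lambda
  ppm <- mass_to_ppm(c0 + accum, gas, temp_k, pressure_pa, registry)
  if (noise_ppm_sd > 0) ppm <- ppm + rnorm(length(t), 0, noise_ppm_sd)
  tibble::tibble(t_seconds = t, gas = gas, ppm = pmax(ppm, 0))
}

iso_stamp <- function(start_date, day, secs) {
  format(as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
           (day - 1) * 86400 + secs, "%Y-%m-%dT%H:%M:%SZ")
}

# chamber layout ------------------------------------------------------------

campaign_chambers <- function(cfg) {
  rows <- list()
  for (plot in c("FP", "CP")) {
    nt <- cfg$n_trees[[plot]]
    npro <- cfg$n_profile_trees[[plot]]
    for (i in seq_len(nt)) {
      tree <- sprintf("%s_T%02d", plot, i)
      hts <- if (i <= npro) cfg$heights_m else cfg$heights_m[1]
      for (h in hts) {
        rows[[length(rows) + 1]] <- chamber_spec(
          sprintf("%s_H%03.0f", tree, 100 * h), "static_stem",
          mount_height_m = h, plot_id = plot, tree_id = tree
        )
      }
      rows[[length(rows) + 1]] <- chamber_spec(
        sprintf("%s_S%02d", plot, i), "dynamic_soil",
        plot_id = plot, tree_id = tree
      )
    }
  }
  dplyr::bind_rows(rows)
}

# configured (noise-free) stem share of the stem+soil sum -------------------

configured_shares <- function(cfg) {
  days <- campaign_days(cfg)
  cov <- covariate_det(cfg)
  stem_days <- stem_measurement_days(cfg)
  stands <- stand_spec(c("FP", "CP"), density_trees_m2 = cfg$stand_density,
                       mean_dbh_m = cfg$stand_dbh,
                       mean_tree_height_m = cfg$stand_height,
                       integration_height_m = cfg$integration_height_m)
  out <- list()
  for (plot in c("FP", "CP")) {
    swc_det <- cov$swc[cov$plot_id == plot]
    sai <- stem_area_index(stands[stands$plot_id == plot, ])
    for (gas in names(cfg$stem_truth)) {
      st <- cfg$stem_truth[[gas]]
      so <- cfg$soil_truth[[gas]]
      flood <- plot == "FP"
      mult <- if (flood) flood_multiplier(days$day, st, cfg) else rep(1, nrow(days))
      mult_soil <- if (flood) flood_multiplier(days$day, so, cfg) else rep(1, nrow(days))
      cf <- covariate_factor(gas, swc_det, cfg)
      f0_daily <- st$F0 * mult * cf
      soil_daily <- so$base * mult_soil * cf
      for (p in c("pre", "experiment", "post")) {
        in_p <- days$period == p
        on_stem_days <- in_p & days$day %in% stem_days
        f0_bar <- mean(f0_daily[on_stem_days])
        stem_area_flux <- mean_stem_flux(list(F0 = f0_bar, k = st$k),
                                         cfg$integration_height_m)
        stem_ground <- upscale_stem_flux(stem_area_flux, sai)
        soil_bar <- mean(soil_daily[in_p])
        out[[length(out) + 1]] <- tibble::tibble(
          plot_id = plot, period = p, gas = gas,
          stem_ground_true = stem_ground, soil_true = soil_bar,
          stem_share_pct = 100 * stem_ground / (stem_ground + soil_bar)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Generate a complete synthetic chamber campaign
#'
#' Builds the chamber layout (vertical stem profiles plus soil chambers on
#' paired trees in a flooded and a control plot), draws covariates and
#' fixed between-tree/between-chamber variability, computes the true flux
#' field day by day, and simulates every closure's raw headspace ppm time
#' series. Everything is reproducible from the scenario seed.
#'
#' @param cfg a [scenario_config()].
#' @return A list of class `stemflux_campaign`:
#' \describe{
#'   \item{chambers}{chamber specification table;}
#'   \item{closures}{long-format raw closure table (the pipeline input
#'     schema, see [read_closures()]);}
#'   \item{stands}{per-plot [stand_spec()] rows;}
#'   \item{covariates}{plot-by-day covariate table;}
#'   \item{truth}{ground truth: `closure_truth` (true flux behind every
#'     simulated closure-gas), `daily` (plot-level true daily means per
#'     source and gas), `shares` (configured, noise-free stem share of the
#'     stem+soil sum per plot, period and gas).}
#' }
#' @export
generate_campaign <- function(cfg = scenario_config()) {
  validate_scenario(cfg)
  set.seed(cfg$seed)
  days <- campaign_days(cfg)
  cov <- covariates_impl(cfg)
  cov_det <- covariate_det(cfg)
  chambers <- campaign_chambers(cfg)
  stem_days <- stem_measurement_days(cfg)

  # fixed multiplicative effects: one per tree (shared by its stem chambers)
  # and one per soil chamber
  trees <- unique(chambers$tree_id)
  tree_eff <- setNames(rlnorm(length(trees), 0, cfg$between_sdlog), trees)
  soil_ids <- chambers$chamber_id[chambers$kind == "dynamic_soil"]
  soil_eff <- setNames(rlnorm(length(soil_ids), 0, cfg$between_sdlog), soil_ids)

  # day-level lognormal jitter per plot x day x source x gas
  all_gases <- union(names(cfg$stem_truth), names(cfg$soil_truth))
  jit <- tidyr::expand_grid(plot_id = c("FP", "CP"), day = days$day,
                            source = c("stem", "soil"), gas = all_gases)
  jit$jitter <- rlnorm(nrow(jit), 0, cfg$day_sdlog)

  # daily deterministic plot-level drivers
  daily_mult <- function(plot, gas, spec) {
    if (plot == "FP") flood_multiplier(days$day, spec, cfg) else rep(1, nrow(days))
  }
  truth_daily <- list()
  for (plot in c("FP", "CP")) {
    swc_det <- cov_det$swc[cov_det$plot_id == plot]
    for (gas in all_gases) {
      cf <- covariate_factor(gas, swc_det, cfg)
      if (gas %in% names(cfg$stem_truth)) {
        st <- cfg$stem_truth[[gas]]
        truth_daily[[length(truth_daily) + 1]] <- tibble::tibble(
          plot_id = plot, day = days$day, period = days$period,
          source = "stem", gas = gas,
          true_level = st$F0 * daily_mult(plot, gas, st) * cf, k = st$k
        )
      }
      if (gas %in% names(cfg$soil_truth)) {
        so <- cfg$soil_truth[[gas]]
        truth_daily[[length(truth_daily) + 1]] <- tibble::tibble(
          plot_id = plot, day = days$day, period = days$period,
          source = "soil", gas = gas,
          true_level = so$base * daily_mult(plot, gas, so) * cf, k = NA_real_
        )
      }
    }
  }
  truth_daily <- dplyr::bind_rows(truth_daily) |>
    dplyr::left_join(jit, by = c("plot_id", "day", "source", "gas")) |>
    dplyr::mutate(true_level = .data$true_level * .data$jitter) |>
    dplyr::select(-"jitter")

  air_k <- setNames(273.15 + cov$air_temp_c, paste(cov$plot_id, cov$day))

  # ---- stem closures (vectorised over chambers x measurement days) --------
  stem_ch <- chambers[chambers$kind == "static_stem", ]
  stem_gases <- names(cfg$stem_truth)
  stem_grid <- tidyr::expand_grid(chamber_id = stem_ch$chamber_id,
                                  day = stem_days, gas = stem_gases) |>
    dplyr::left_join(stem_ch, by = "chamber_id") |>
    dplyr::left_join(days, by = "day") |>
    dplyr::left_join(truth_daily[truth_daily$source == "stem", c("plot_id", "day", "gas", "true_level", "k")],
                     by = c("plot_id", "day", "gas"))
  stem_grid$true_flux <- stem_grid$true_level *
    unname(tree_eff[stem_grid$tree_id]) *
    exp(-stem_grid$k * stem_grid$mount_height_m)
  stem_grid$temp_k <- unname(air_k[paste(stem_grid$plot_id, stem_grid$day)])
  stem_grid$closure_start <- iso_stamp(cfg$start_date, stem_grid$day, 12 * 3600)

  t_stem <- cfg$stem_sample_times_s
  stem_samples <- stem_grid[rep(seq_len(nrow(stem_grid)), each = length(t_stem)), ]
  stem_samples$t_seconds <- rep(t_stem, times = nrow(stem_grid))
  stem_samples <- forward_ppm(stem_samples, cfg, kind = "static_stem")

  # ---- soil closures ------------------------------------------------------
  soil_ch <- chambers[chambers$kind == "dynamic_soil", ]
  soil_gases <- names(cfg$soil_truth)
  closure_offsets <- round(seq(6 * 3600, 20 * 3600,
                               length.out = cfg$soil_closures_per_day))
  soil_grid <- tidyr::expand_grid(chamber_id = soil_ch$chamber_id,
                                  day = days$day, offset_s = closure_offsets,
                                  gas = soil_gases) |>
    dplyr::left_join(soil_ch, by = "chamber_id") |>
    dplyr::left_join(days, by = "day") |>
    dplyr::left_join(truth_daily[truth_daily$source == "soil", c("plot_id", "day", "gas", "true_level")],
                     by = c("plot_id", "day", "gas"))
  soil_grid$true_flux <- soil_grid$true_level * unname(soil_eff[soil_grid$chamber_id])
  soil_grid$temp_k <- unname(air_k[paste(soil_grid$plot_id, soil_grid$day)])
  soil_grid$closure_start <- iso_stamp(cfg$start_date, soil_grid$day, soil_grid$offset_s)

  t_soil <- seq(0, cfg$soil_closure_s, by = 1 / cfg$soil_sample_hz)
  soil_samples <- soil_grid[rep(seq_len(nrow(soil_grid)), each = length(t_soil)), ]
  soil_samples$t_seconds <- rep(t_soil, times = nrow(soil_grid))
  soil_samples <- forward_ppm(soil_samples, cfg, kind = "dynamic_soil")

  keep <- c("chamber_id", "closure_start", "period", "plot_id",
            "t_seconds", "gas", "ppm", "temp_k", "pressure_pa")
  closures <- dplyr::bind_rows(stem_samples[, keep], soil_samples[, keep])

  closure_truth <- dplyr::bind_rows(
    stem_grid[, c("chamber_id", "closure_start", "plot_id", "period", "gas", "true_flux")],
    soil_grid[, c("chamber_id", "closure_start", "plot_id", "period", "gas", "true_flux")]
  )

  stands <- stand_spec(c("FP", "CP"), density_trees_m2 = cfg$stand_density,
                       mean_dbh_m = cfg$stand_dbh,
                       mean_tree_height_m = cfg$stand_height,
                       integration_height_m = cfg$integration_height_m)

  structure(
    list(chambers = chambers, closures = closures, stands = stands,
         covariates = cov,
         truth = list(closure_truth = closure_truth, daily = truth_daily,
                      shares = configured_shares(cfg)),
         config = cfg),
    class = "stemflux_campaign"
  )
}

# vectorised forward model: expects columns true_flux, volume_m3, area_m2,
# temp_k, gas, t_seconds; adds ppm and pressure_pa
forward_ppm <- function(samples, cfg, kind) {
  lam <- cfg$lambda_s
  s_mass <- samples$true_flux / 3600 * samples$area_m2 / samples$volume_m3
  accum <- if (lam == 0) s_mass * samples$t_seconds else
    s_mass * (1 - exp(-lam * samples$t_seconds)) / lam
  amb <- cfg$ambient_ppm[samples$gas]
  c0 <- ppm_to_mass(unname(amb), samples$gas, samples$temp_k, cfg$pressure_pa)
  ppm <- mass_to_ppm(c0 + accum, samples$gas, samples$temp_k, cfg$pressure_pa)
  sds <- cfg$noise_ppm_sd[[kind]][samples$gas]
  noisy <- unname(sds) > 0
  ppm[noisy] <- ppm[noisy] + rnorm(sum(noisy), 0, unname(sds)[noisy])
  samples$ppm <- pmax(ppm, 0)
  samples$pressure_pa <- cfg$pressure_pa
  samples
}

#' @export
print.stemflux_campaign <- function(x, ...) {
  cat(sprintf("<stemflux_campaign> %d chambers, %d closure-gas channels, %d sample rows\n",
              nrow(x$chambers),
              nrow(x$truth$closure_truth),
              nrow(x$closures)))
  invisible(x)
}
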