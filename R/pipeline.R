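#' Pipeline configuration
#'
#' Bundles everything one run of the simulate-to-summaries pipeline needs:
#' output directory, seeded scenario, window and QC policies, profile and
#' upscaling settings, and the flux unit basis.
#'
#' @param out_dir directory for stage outputs (created if missing).
#' @param scenario a [scenario_config()] used by the `simulate` stage.
#' @param windows named list of [window_policy()] objects per chamber kind.
#' @param qc a [qc_policy()].
#' @param integration_height_m stem-profile integration height (m). Values
#'   above the highest measured chamber extrapolate the fitted curve and
#'   are flagged in the upscaled output.
#' @param unit_mode `"molecule"` or `"element"` flux basis.
#' @param seed overrides the scenario seed when given.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, scenario = scenario_config(),
                            windows = NULL, qc = qc_policy(),
                            integration_height_m = scenario$integration_height_m,
                            unit_mode = "molecule", seed = NULL) {
  if (!is.null(seed)) scenario$seed <- seed
  if (is.null(windows)) {
    windows <- list(dynamic_soil = window_policy("dynamic_soil"),
                    static_stem = window_policy("static_stem"))
  }
  structure(
    list(out_dir = out_dir, scenario = scenario, windows = windows, qc = qc,
         integration_height_m = integration_height_m, unit_mode = unit_mode),
    class = "pipeline_config"
  )
}

#' Read a long-format closures CSV
#'
#' Schema (one row per closure, sample time and gas): `chamber_id`,
#' `closure_start` (ISO-8601), `period`, `plot_id`, `t_seconds`, `gas`,
#' `ppm`, `temp_k`, `pressure_pa`. Rows may arrive in any order; closures
#' are grouped by `chamber_id` + `closure_start` and validated.
#'
#' @param path CSV file path.
#' @return A validated closures tibble.
#' @export
read_closures <- function(path) {
  if (!file.exists(path)) {
    stop_stemflux("missing_upstream",
                  paste0("Closures file not found: ", path,
                         ". Run the `simulate` stage (or point to campaign data)."))
  }
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         chamber_id = "c", closure_start = "c", period = "c",
                         plot_id = "c", t_seconds = "d", gas = "c", ppm = "d",
                         temp_k = "d", pressure_pa = "d"
                       ))
  validate_closures(x)
}

#' Write a closures table to CSV
#'
#' @param closures closures tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_closures <- function(closures, path) {
  readr::write_csv(validate_closures(closures), path, progress = FALSE)
  invisible(path)
}

read_stage_csv <- function(dir, name, needed_by) {
  path <- file.path(dir, name)
  if (!file.exists(path)) {
    stop_stemflux("missing_upstream",
                  sprintf("`%s` needs %s; run the earlier stage first.", needed_by, name))
  }
  # closure timestamps stay ISO-8601 strings so keys survive the round trip
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  spec <- if ("closure_start" %in% header) {
    readr::cols(closure_start = readr::col_character())
  } else {
    readr::cols()
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE, col_types = spec)
}

#' Run one stage (or all stages) of the flux pipeline
#'
#' Stages and their outputs, all CSV in `cfg$out_dir`:
#' \describe{
#'   \item{simulate}{`closures.csv`, `chambers.csv`, `stands.csv`,
#'     `covariates.csv`, `truth_closures.csv`, `truth_shares.csv`;}
#'   \item{fluxes}{`fluxes.csv` (per-closure per-gas estimates with QC);}
#'   \item{profile}{`profiles.csv` (stem flux-height model per
#'     plot x period x gas);}
#'   \item{upscale}{`upscaled.csv`, `contributions.csv`, `cumulative.csv`;}
#'   \item{summarize}{`summaries.csv` (box statistics per group);}
#'   \item{all}{every stage in order.}
#' }
#' A `manifest.json` records the seed, configuration hash and closure
#' acceptance counts. Reruns with the same configuration reproduce the
#' outputs exactly.
#'
#' @param stage one of `"simulate"`, `"fluxes"`, `"profile"`, `"upscale"`,
#'   `"summarize"`, `"all"`.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a named list of the paths written by the stage(s).
#' @export
run_stage <- function(stage = c("all", "simulate", "fluxes", "profile",
                                "upscale", "summarize"),
                      cfg) {
  stage <- match.arg(stage)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- if (stage == "all") c("simulate", "fluxes", "profile", "upscale", "summarize") else stage
  written <- list()
  for (st in stages) {
    written <- c(written, switch(
      st,
      simulate = stage_simulate(cfg),
      fluxes = stage_fluxes(cfg),
      profile = stage_profile(cfg),
      upscale = stage_upscale(cfg),
      summarize = stage_summarize(cfg)
    ))
  }
  invisible(written)
}

out_path <- function(cfg, name) file.path(cfg$out_dir, name)

write_out <- function(x, cfg, name) {
  readr::write_csv(tibble::as_tibble(x), out_path(cfg, name), progress = FALSE)
  setNames(list(out_path(cfg, name)), sub("\\.csv$", "", name))
}

update_manifest <- function(cfg, fields) {
  path <- out_path(cfg, "manifest.json")
  manifest <- if (file.exists(path)) jsonlite::read_json(path) else list()
  manifest$schema_version <- "1"
  manifest$seed <- cfg$scenario$seed
  manifest$config_hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  manifest[names(fields)] <- fields
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

stage_simulate <- function(cfg) {
  camp <- generate_campaign(cfg$scenario)
  w <- c(
    list(closures = write_closures(camp$closures, out_path(cfg, "closures.csv"))),
    write_out(camp$chambers, cfg, "chambers.csv"),
    write_out(camp$stands, cfg, "stands.csv"),
    write_out(camp$covariates, cfg, "covariates.csv"),
    write_out(camp$truth$closure_truth, cfg, "truth_closures.csv"),
    write_out(camp$truth$shares, cfg, "truth_shares.csv")
  )
  update_manifest(cfg, list(closures_simulated = nrow(camp$truth$closure_truth)))
  w
}

stage_fluxes <- function(cfg) {
  closures <- read_closures(out_path(cfg, "closures.csv"))
  chambers <- read_stage_csv(cfg$out_dir, "chambers.csv", "fluxes")
  fluxes <- estimate_fluxes(closures, chambers, windows = cfg$windows,
                            qc = cfg$qc, unit_mode = cfg$unit_mode)
  counts <- attr(fluxes, "counts")
  update_manifest(cfg, as.list(setNames(as.integer(counts),
                                        paste0("closures_", names(counts)))))
  write_out(fluxes, cfg, "fluxes.csv")
}

stage_profile <- function(cfg) {
  fluxes <- read_stage_csv(cfg$out_dir, "fluxes.csv", "profile")
  write_out(fit_profiles(fluxes), cfg, "profiles.csv")
}

stage_upscale <- function(cfg) {
  fluxes <- read_stage_csv(cfg$out_dir, "fluxes.csv", "upscale")
  profiles <- read_stage_csv(cfg$out_dir, "profiles.csv", "upscale")
  stands <- read_stage_csv(cfg$out_dir, "stands.csv", "upscale")

  h_int <- cfg$integration_height_m
  profiles$mean_stem_flux <- mapply(function(F0, k) {
    mean_stem_flux(list(F0 = F0, k = k), h_int)
  }, profiles$F0, profiles$k)
  sai <- stem_area_index(stands, H_int = h_int)
  profiles$sai <- sai[match(profiles$plot_id, stands$plot_id)]
  profiles$stem_flux_ground <- upscale_stem_flux(profiles$mean_stem_flux, profiles$sai)
  max_h <- max(fluxes$mount_height_m[fluxes$kind == "static_stem"], 0)
  profiles$extrapolated <- h_int > max_h

  soil <- fluxes[fluxes$kind == "dynamic_soil" & fluxes$qc_pass, ] |>
    dplyr::group_by(.data$plot_id, .data$period, .data$gas) |>
    dplyr::summarise(soil_flux = mean(.data$flux_ug_m2_h), .groups = "drop")

  upscaled <- dplyr::inner_join(
    profiles[, c("plot_id", "period", "gas", "form", "F0", "k",
                 "mean_stem_flux", "sai", "stem_flux_ground", "extrapolated")],
    soil, by = c("plot_id", "period", "gas")
  )
  contrib <- dplyr::bind_cols(
    upscaled[, c("plot_id", "period", "gas")],
    contribution(upscaled$stem_flux_ground, upscaled$soil_flux)
  )

  # daily means per source on ground-area basis: soil directly, stems via
  # the profile model of the closure's period scaled by SAI
  day_of <- function(ts) substr(ts, 1, 10)
  soil_daily <- fluxes[fluxes$kind == "dynamic_soil" & fluxes$qc_pass, ] |>
    dplyr::mutate(day = day_of(.data$closure_start), source = "soil") |>
    dplyr::group_by(.data$plot_id, .data$gas, .data$source, .data$period, .data$day) |>
    dplyr::summarise(daily_mean_flux = mean(.data$flux_ug_m2_h), .groups = "drop")
  stem_rows <- fluxes[fluxes$kind == "static_stem" & fluxes$qc_pass, ] |>
    dplyr::left_join(profiles[, c("plot_id", "period", "gas", "F0", "k", "sai")],
                     by = c("plot_id", "period", "gas"))
  stem_daily <- stem_rows |>
    dplyr::mutate(
      # rescale each chamber's flux by the profile's height shape so the
      # daily mean is on the whole-stem, ground-area basis
      shape = exp(-.data$k * .data$mount_height_m),
      whole_stem = .data$flux_ug_m2_h / .data$shape * decay_mean_factor(.data$k, h_int),
      ground = .data$whole_stem * .data$sai,
      day = day_of(.data$closure_start), source = "stem"
    ) |>
    dplyr::group_by(.data$plot_id, .data$gas, .data$source, .data$period, .data$day) |>
    dplyr::summarise(daily_mean_flux = mean(.data$ground), .groups = "drop")
  cumulative <- dplyr::bind_rows(soil_daily, stem_daily) |>
    dplyr::group_by(.data$plot_id, .data$gas, .data$source) |>
    dplyr::group_modify(function(d, key) cumulative_flux(d)) |>
    dplyr::ungroup()

  c(write_out(upscaled, cfg, "upscaled.csv"),
    write_out(contrib, cfg, "contributions.csv"),
    write_out(cumulative, cfg, "cumulative.csv"))
}

stage_summarize <- function(cfg) {
  fluxes <- read_stage_csv(cfg$out_dir, "fluxes.csv", "summarize")
  write_out(period_summary(fluxes), cfg, "summaries.csv")
}

#' Estimate the stem share of the stem-soil flux continuum for a campaign
#'
#' Convenience wrapper running flux estimation, profile fitting and
#' upscaling in memory (no files) and returning the stem contribution per
#' plot, period and gas alongside the campaign's configured share.
#'
#' @param camp a `stemflux_campaign` from [generate_campaign()].
#' @param windows,qc,integration_height_m as in [pipeline_config()].
#' @return A tibble: `plot_id`, `period`, `gas`, `stem_flux_ground`,
#'   `soil_flux`, `stem_pct`, `mixed_sign_flag`, `configured_share_pct`.
#' @export
estimate_stem_share <- function(camp, windows = NULL, qc = qc_policy(),
                                integration_height_m = camp$config$integration_height_m) {
  fluxes <- estimate_fluxes(camp$closures, camp$chambers, windows = windows, qc = qc)
  profiles <- fit_profiles(fluxes)
  h_int <- integration_height_m
  profiles$mean_stem_flux <- mapply(function(F0, k) {
    mean_stem_flux(list(F0 = F0, k = k), h_int)
  }, profiles$F0, profiles$k)
  sai <- stem_area_index(camp$stands, H_int = h_int)
  profiles$stem_flux_ground <- profiles$mean_stem_flux *
    sai[match(profiles$plot_id, camp$stands$plot_id)]
  soil <- fluxes[fluxes$kind == "dynamic_soil" & fluxes$qc_pass, ] |>
    dplyr::group_by(.data$plot_id, .data$period, .data$gas) |>
    dplyr::summarise(soil_flux = mean(.data$flux_ug_m2_h), .groups = "drop")
  joined <- dplyr::inner_join(profiles, soil, by = c("plot_id", "period", "gas"))
  out <- dplyr::bind_cols(
    joined[, c("plot_id", "period", "gas")],
    contribution(joined$stem_flux_ground, joined$soil_flux)
  )
  dplyr::left_join(
    out,
    camp$truth$shares[, c("plot_id", "period", "gas", "stem_share_pct")] |>
      dplyr::rename(configured_share_pct = "stem_share_pct"),
    by = c("plot_id", "period", "gas")
  )
}
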