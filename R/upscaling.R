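#' Stand specification for ground-area upscaling
#'
#' Tree geometry and density used to scale per-stem-surface-area fluxes to
#' ground area. Stems are treated as cylinders of uniform diameter (the
#' diameter at breast height), so the stem surface per tree up to height
#' `H` is `pi * D * H`.
#'
#' @param plot_id plot label.
#' @param density_trees_m2 stem density (trees per m2 of ground;
#'   1500 trees ha-1 = 0.15).
#' @param mean_dbh_m mean stem diameter at breast height (m).
#' @param mean_tree_height_m mean tree height (m), carried for diagnostics
#'   and full-height extrapolation.
#' @param integration_height_m upper height of the flux integration band
#'   (m); defaults to 1.7 m, the highest chamber of the vertical profile.
#' @param basal_area_m2_ha optional stand basal area, diagnostic only.
#' @return A one-row tibble of class `stand_spec`.
#' @examples
#' stand_spec("FP", density_trees_m2 = 0.15, mean_dbh_m = 0.17)
#' @export
stand_spec <- function(plot_id, density_trees_m2 = 0.15, mean_dbh_m = 0.17,
                       mean_tree_height_m = 19.2, integration_height_m = 1.7,
                       basal_area_m2_ha = NA_real_) {
  if (density_trees_m2 <= 0 || mean_dbh_m <= 0 || integration_height_m <= 0) {
    stop_stemflux("stand", "density, mean DBH and integration height must be positive.")
  }
  out <- tibble::tibble(
    plot_id = as.character(plot_id),
    density_trees_m2 = density_trees_m2,
    mean_dbh_m = mean_dbh_m,
    mean_tree_height_m = mean_tree_height_m,
    integration_height_m = integration_height_m,
    basal_area_m2_ha = basal_area_m2_ha
  )
  class(out) <- c("stand_spec", class(out))
  out
}

#' Stem area index of a stand
#'
#' Stem surface area per unit ground area for cylindrical stems:
#' `SAI = pi * D * H_int * density`. Dimensionless (m2 stem per m2 ground).
#'
#' @param stand a [stand_spec()] row.
#' @param H_int integration height (m); defaults to the stand's
#'   `integration_height_m`.
#' @return Stem area index (dimensionless).
#' @examples
#' stem_area_index(stand_spec("FP"))
#' @export
stem_area_index <- function(stand, H_int = NULL) {
  if (is.null(H_int)) H_int <- stand$integration_height_m
  if (H_int <= 0) stop_stemflux("domain", "H_int must be positive.")
  pi * stand$mean_dbh_m * H_int * stand$density_trees_m2
}

#' Upscale a per-stem-area flux to ground area
#'
#' @param flux_stem flux per stem surface area (ug m-2 h-1), e.g. from
#'   [mean_stem_flux()].
#' @param sai stem area index (>= 0), see [stem_area_index()].
#' @return Ground-area flux (ug m-2 ground h-1); sign is preserved.
#' @export
upscale_stem_flux <- function(flux_stem, sai) {
  if (any(sai < 0)) stop_stemflux("domain", "SAI must be >= 0.")
  flux_stem * sai
}

#' Soil-area-equivalent stem flux for a chamber height band
#'
#' Re-expresses a stem-surface flux measured in a chamber band per unit of
#' ground area, so stem and soil fluxes are directly comparable per-height:
#' `flux * pi * D * (band width) * density`. With a uniform profile and the
#' full integration band this reproduces the stem-area-index route exactly.
#' Used for per-height reporting only, not for stand budgets.
#'
#' @param flux_stem flux per stem surface area (ug m-2 h-1).
#' @param stand a [stand_spec()] row.
#' @param band numeric length-2 `c(lower, upper)` heights (m) of the band
#'   the chamber represents.
#' @return Ground-area-equivalent flux (ug m-2 h-1).
#' @export
soil_area_equivalent <- function(flux_stem, stand, band) {
  if (is.null(band) || length(band) != 2 || !all(is.finite(band)) || band[2] <= band[1]) {
    stop_stemflux("config", "`band` must be c(lower, upper) heights in metres with upper > lower.")
  }
  per_tree_surface <- pi * stand$mean_dbh_m * (band[2] - band[1])
  flux_stem * per_tree_surface * stand$density_trees_m2
}

#' Partition the stem-soil continuum flux
#'
#' Expresses the stem contribution as a percentage of the stem + soil sum
#' on a common ground-area basis. When the two fluxes have opposite signs
#' (one compartment emits while the other takes up) the percent-of-sum is
#' undefined, so absolute-magnitude shares are reported with
#' `mixed_sign_flag = TRUE`. Both fluxes zero yields a missing share.
#'
#' @param stem_ground stem flux on ground-area basis (ug m-2 h-1).
#' @param soil soil flux (ug m-2 h-1).
#' @return A tibble: `stem_flux_ground`, `soil_flux`, `stem_pct`,
#'   `soil_pct`, `mixed_sign_flag`.
#' @examples
#' contribution(88, 12)
#' @export
contribution <- function(stem_ground, soil) {
  if (!all(is.finite(c(stem_ground, soil)))) {
    stop_stemflux("domain", "Fluxes must be finite.")
  }
  mixed <- (stem_ground > 0 & soil < 0) | (stem_ground < 0 & soil > 0)
  both_zero <- stem_ground == 0 & soil == 0
  stem_pct <- ifelse(
    both_zero, NA_real_,
    ifelse(mixed,
           100 * abs(stem_ground) / (abs(stem_ground) + abs(soil)),
           100 * stem_ground / (stem_ground + soil))
  )
  tibble::tibble(
    stem_flux_ground = stem_ground, soil_flux = soil,
    stem_pct = stem_pct, soil_pct = 100 - stem_pct,
    mixed_sign_flag = mixed
  )
}

#' Cumulative flux budget from daily means
#'
#' Accumulates daily mean fluxes into a running budget: each sampled day
#' contributes `daily mean (ug m-2 h-1) * 24 h`, i.e. the cumulative series
#' is in ug m-2. Days without measurements are simply absent (no
#' interpolation between sampled days).
#'
#' @param daily tibble with columns `day` (orderable, unique) and
#'   `daily_mean_flux`; optional grouping columns (`plot_id`, `gas`,
#'   `source`, `period`) are carried through.
#' @return The input ordered by day with an added `cumulative_ug_m2`
#'   column.
#' @export
cumulative_flux <- function(daily) {
  daily <- tibble::as_tibble(daily)
  if (!all(c("day", "daily_mean_flux") %in% names(daily))) {
    stop_stemflux("schema", "Need columns `day` and `daily_mean_flux`.")
  }
  if (anyDuplicated(daily$day) > 0) {
    stop_stemflux("duplicate_day", "Duplicate days in the daily-mean series.")
  }
  daily <- daily[order(daily$day), , drop = FALSE]
  daily$cumulative_ug_m2 <- cumsum(daily$daily_mean_flux * 24)
  daily
}

#' Summary statistics of flux estimates per group
#'
#' Box-plot-style order statistics for each plot x period x height x gas
#' group of QC-accepted estimates: n, mean, standard error, median, and the
#' 25th/75th/10th/90th percentiles. Percentiles use linear interpolation
#' between closest ranks (R quantile type 7) so box statistics are exactly
#' reproducible. Empty groups are kept with `n = 0` and missing statistics.
#'
#' @param fluxes flux table from [estimate_fluxes()].
#' @param by character vector of grouping columns.
#' @param keep_rejected include QC-rejected rows (default drops them).
#' @return One summary row per group.
#' @export
period_summary <- function(fluxes,
                           by = c("plot_id", "period", "kind", "mount_height_m", "gas"),
                           keep_rejected = FALSE) {
  fluxes <- tibble::as_tibble(fluxes)
  groups <- dplyr::distinct(fluxes[, intersect(by, names(fluxes)), drop = FALSE])
  if (!keep_rejected) fluxes <- fluxes[fluxes$qc_pass, , drop = FALSE]
  stats_tbl <- fluxes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(intersect(by, names(fluxes))))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$flux_ug_m2_h),
      se = sd(.data$flux_ug_m2_h) / sqrt(dplyr::n()),
      median = median(.data$flux_ug_m2_h),
      p25 = quantile(.data$flux_ug_m2_h, 0.25, names = FALSE, type = 7),
      p75 = quantile(.data$flux_ug_m2_h, 0.75, names = FALSE, type = 7),
      p10 = quantile(.data$flux_ug_m2_h, 0.10, names = FALSE, type = 7),
      p90 = quantile(.data$flux_ug_m2_h, 0.90, names = FALSE, type = 7),
      .groups = "drop"
    )
  out <- dplyr::left_join(groups, stats_tbl, by = intersect(by, names(groups)))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Water depth equivalent of a distributed volume
#'
#' A volume of water spread over an area corresponds to a precipitation
#' depth of `1000 * volume / area` millimetres; used to express a flooding
#' treatment as its rainfall equivalent.
#'
#' @param volume_m3 water volume (m3).
#' @param area_m2 ground area (m2), positive.
#' @return A list with `depth_mm` (exact) and `depth_mm_rounded`
#'   (nearest mm).
#' @examples
#' water_depth_mm(875, 1600)
#' @export
water_depth_mm <- function(volume_m3, area_m2) {
  if (!is.finite(area_m2) || area_m2 <= 0) {
    stop_stemflux("domain", "Area must be positive.")
  }
  depth <- 1000 * volume_m3 / area_m2
  list(depth_mm = depth, depth_mm_rounded = round(depth))
}
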