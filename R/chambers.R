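#' Chamber specification
#'
#' Describes one chamber system: a manual static stem chamber pair sampled
#' by syringe for GC analysis, or an automated dynamic soil chamber
#' circulating headspace air through an online analyser. The ratio
#' `volume / area` is the effective headspace height that converts a
#' concentration slope into an areal flux.
#'
#' @param chamber_id unique identifier.
#' @param kind `"static_stem"` or `"dynamic_soil"`.
#' @param volume_m3 headspace volume (m3). Defaults to the field systems:
#'   0.00119 m3 for a two-chamber stem system, 0.032 m3 for a soil chamber.
#' @param area_m2 enclosed surface (m2): stem surface covered for stem
#'   chambers (default 0.0108), soil surface for soil chambers (default 0.16).
#' @param mount_height_m centre height above ground (m); 0 for soil chambers.
#' @param plot_id plot label.
#' @param tree_id tree identifier; required for stem chambers.
#'
#' @return A one-row tibble of class `chamber_spec` (rows of several specs
#'   bind into a chambers table).
#' @examples
#' chamber_spec("S1", "static_stem", plot_id = "FP", tree_id = "T1",
#'              mount_height_m = 0.1)
#' @export
chamber_spec <- function(chamber_id, kind = c("static_stem", "dynamic_soil"),
                         volume_m3 = NULL, area_m2 = NULL,
                         mount_height_m = 0, plot_id = NA_character_,
                         tree_id = NA_character_) {
  kind <- match.arg(kind)
  if (is.null(volume_m3)) volume_m3 <- if (kind == "static_stem") 0.00119 else 0.032
  if (is.null(area_m2)) area_m2 <- if (kind == "static_stem") 0.0108 else 0.16
  if (!is.finite(volume_m3) || volume_m3 <= 0 || !is.finite(area_m2) || area_m2 <= 0) {
    stop_stemflux("chamber", "Chamber volume and area must be positive and finite.")
  }
  if (kind == "static_stem" && (is.na(tree_id) || mount_height_m < 0)) {
    stop_stemflux("chamber", "Static stem chambers need a tree_id and mount_height_m >= 0.")
  }
  out <- tibble::tibble(
    chamber_id = as.character(chamber_id), kind = kind,
    volume_m3 = volume_m3, area_m2 = area_m2,
    mount_height_m = mount_height_m,
    plot_id = as.character(plot_id), tree_id = as.character(tree_id)
  )
  class(out) <- c("chamber_spec", class(out))
  out
}

#' Effective headspace height of a chamber (m)
#'
#' @param chamber a `chamber_spec` row (or chambers table).
#' @return `volume_m3 / area_m2` in metres.
#' @export
effective_height <- function(chamber) {
  chamber$volume_m3 / chamber$area_m2
}

closure_schema <- c(
  "chamber_id", "closure_start", "period", "plot_id",
  "t_seconds", "gas", "ppm", "temp_k", "pressure_pa"
)

#' Validate a long-format closures table
#'
#' Checks the fixed schema (one row per closure, sample time and gas) and
#' the physical invariants: strictly increasing non-negative times within
#' each closure-gas channel, non-negative mole fractions, positive
#' temperature and pressure, at least two samples per channel.
#'
#' @param closures tibble/data.frame to validate.
#' @return The validated tibble (invisibly usable downstream).
#' @export
validate_closures <- function(closures) {
  closures <- tibble::as_tibble(closures)
  missing_cols <- setdiff(closure_schema, names(closures))
  if (length(missing_cols) > 0) {
    stop_stemflux(
      "schema",
      paste0("Closures table missing column(s): ", paste(missing_cols, collapse = ", "))
    )
  }
  if (any(!is.finite(closures$t_seconds)) || any(closures$t_seconds < 0)) {
    stop_stemflux("closure", "Sample times must be finite and >= 0 seconds.")
  }
  if (any(closures$ppm < 0, na.rm = TRUE)) {
    stop_stemflux("closure", "Mole fractions must be non-negative.")
  }
  check_conditions(closures$temp_k, closures$pressure_pa)
  key <- paste(closures$chamber_id, closures$closure_start, closures$gas, sep = "\r")
  ord <- order(key, closures$t_seconds)
  closures <- closures[ord, , drop = FALSE]
  key <- key[ord]
  dt <- diff(closures$t_seconds)
  same <- key[-1] == key[-length(key)]
  if (length(dt) > 0 && any(same & dt <= 0)) {
    stop_stemflux("closure", "Sample times must be strictly increasing within a closure channel.")
  }
  n_per <- table(key)
  if (any(n_per < 2)) {
    stop_stemflux("closure", "Each closure gas channel needs at least 2 samples.")
  }
  closures
}
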