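#' Fitting-window policy for a chamber kind
#'
#' Automated soil closures discard an initial deadband (chamber placement
#' and mixing artefacts) and fit a fixed-duration window: by default the
#' 150 s window starting 90 s after closure, i.e. samples with
#' `t` in the closed interval `[90, 240]` s. Manual stem closures keep all
#' four discrete GC samples (deadband 0, full 0-10800 s span).
#'
#' @param kind `"dynamic_soil"` or `"static_stem"`.
#' @param deadband_s seconds discarded at the start of the closure.
#' @param fit_duration_s length of the fitting window in seconds.
#' @return A list of class `window_policy`.
#' @export
window_policy <- function(kind = c("dynamic_soil", "static_stem"),
                          deadband_s = NULL, fit_duration_s = NULL) {
  kind <- match.arg(kind)
  if (is.null(deadband_s)) deadband_s <- if (kind == "dynamic_soil") 90 else 0
  if (is.null(fit_duration_s)) fit_duration_s <- if (kind == "dynamic_soil") 150 else 10800
  if (deadband_s < 0 || fit_duration_s <= 0) {
    stop_stemflux("policy", "deadband_s must be >= 0 and fit_duration_s > 0.")
  }
  structure(list(kind = kind, deadband_s = deadband_s, fit_duration_s = fit_duration_s),
            class = "window_policy")
}

#' Restrict a closure to its fitting window
#'
#' Keeps samples with `t_seconds` in the closed interval
#' `[deadband, deadband + fit_duration]`. Window membership is decided by
#' timestamp, so sampling jitter does not shift the window.
#'
#' @param closure long-format rows of a single closure (any subset of gases).
#' @param policy a [window_policy()].
#' @return The windowed rows.
#' @export
select_window <- function(closure, policy) {
  lo <- policy$deadband_s
  hi <- policy$deadband_s + policy$fit_duration_s
  out <- closure[closure$t_seconds >= lo & closure$t_seconds <= hi, , drop = FALSE]
  n_min <- if (nrow(out) == 0) 0L else min(table(out$gas))
  if (n_min < 2) {
    stop_stemflux(
      "insufficient_window",
      sprintf("Fewer than 2 samples in the fitting window [%g, %g] s.", lo, hi)
    )
  }
  out
}

#' Ordinary least-squares line through a concentration time series
#'
#' The flux estimator's core: the slope of mass concentration against time
#' within the fitting window, with the coefficient of determination
#' `R^2 = 1 - SSE/SST`. A constant series (`SST = 0`) is the degenerate
#' no-signal case and returns slope 0 with `R^2 = 0` by convention.
#' Two-point fits have `R^2` identically 1 and are flagged `min-points`
#' downstream.
#'
#' @param t sample times (s), at least two distinct values.
#' @param y concentrations (ug m-3 for flux work, but any linear response).
#' @return A list of class `linear_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_points`, `window` (range of `t`).
#' @export
fit_linear <- function(t, y) {
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 2 || length(unique(t)) < 2) {
    stop_stemflux("degenerate_time", "Linear fit needs >= 2 distinct time points.")
  }
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  sxy <- sum((t - tm) * (y - ym))
  sst <- sum((y - ym)^2)
  if (sst <= 0) {
    slope <- 0; intercept <- ym; r2 <- 0
  } else {
    slope <- sxy / sxx
    intercept <- ym - slope * tm
    sse <- sum((y - intercept - slope * t)^2)
    r2 <- 1 - sse / sst
    r2 <- min(max(r2, 0), 1)
  }
  structure(
    list(slope = slope, intercept = intercept, r_squared = r2,
         n_points = n, window = range(t)),
    class = "linear_fit"
  )
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g ug m-3 s-1, R2 %.4f, n %d, window [%g, %g] s\n",
              x$slope, x$r_squared, x$n_points, x$window[1], x$window[2]))
  invisible(x)
}

#' Areal flux from a headspace concentration slope
#'
#' Closed-chamber mass balance: a concentration slope `dC/dt`
#' (ug m-3 s-1) inside a headspace of volume `V` over an exchanging
#' surface `A` corresponds to a flux `dC/dt * V/A`, converted from
#' per-second to per-hour.
#'
#' @param fit a [fit_linear()] result, or a bare numeric slope (ug m-3 s-1).
#' @param chamber a `chamber_spec` row.
#' @return Flux in ug m-2 h-1 (positive = emission, negative = uptake).
#' @examples
#' soil <- chamber_spec("A1", "dynamic_soil", plot_id = "FP")
#' compute_flux(0.5, soil)
#' @export
compute_flux <- function(fit, chamber) {
  slope <- if (inherits(fit, "linear_fit")) fit$slope else fit
  slope * effective_height(chamber) * 3600
}

#' Quality-control policy for closure acceptance
#'
#' Automated soil chambers co-measure CO2; a closure's CH4 and N2O fits are
#' accepted exactly when the CO2 efflux fit has `R^2` strictly above the
#' threshold (default 0.9), regardless of their own `R^2` — a poor CO2 fit
#' signals leakage or disturbed mixing and rejects the whole closure.
#' Manual GC stem closures measure no CO2; the fallback is either
#' `"accept_flag"` (accept, flagged `no-CO2-gate`) or `"threshold"`
#' (gate each gas on its own `R^2` via `static_r2_threshold`).
#'
#' @param co2_r2_threshold strict lower bound on the CO2 fit `R^2`.
#' @param static_fallback rule for closures without a CO2 channel.
#' @param static_r2_threshold per-gas `R^2` bound used when
#'   `static_fallback = "threshold"`.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(co2_r2_threshold = 0.9,
                      static_fallback = c("accept_flag", "threshold"),
                      static_r2_threshold = 0.9) {
  static_fallback <- match.arg(static_fallback)
  if (co2_r2_threshold <= 0 || co2_r2_threshold >= 1) {
    stop_stemflux("policy", "co2_r2_threshold must lie in (0, 1).")
  }
  structure(list(co2_r2_threshold = co2_r2_threshold,
                 static_fallback = static_fallback,
                 static_r2_threshold = static_r2_threshold),
            class = "qc_policy")
}

#' Apply the CO2-referenced quality gate to one closure's fits
#'
#' @param fits named list of `linear_fit` objects, one per gas measured in
#'   the closure (names are gas identifiers, e.g. `CO2`, `CH4`, `N2O`).
#' @param policy a [qc_policy()].
#' @return A tibble with one row per non-CO2 gas: `gas`, `qc_pass`,
#'   `qc_reason` (empty string when the closure passes cleanly; advisory
#'   flags such as `no-CO2-gate` or `min-points` do not fail a closure and
#'   are reported in `qc_flags`).
#' @export
qc_gate <- function(fits, policy = qc_policy()) {
  gases <- setdiff(names(fits), "CO2")
  has_co2 <- "CO2" %in% names(fits)
  rows <- lapply(gases, function(g) {
    f <- fits[[g]]
    flags <- character(0)
    if (f$n_points <= 2) flags <- c(flags, "min-points")
    if (has_co2) {
      co2_r2 <- fits[["CO2"]]$r_squared
      pass <- co2_r2 > policy$co2_r2_threshold
      reason <- if (pass) "" else sprintf("CO2 R2 <= %g", policy$co2_r2_threshold)
    } else if (policy$static_fallback == "accept_flag") {
      pass <- TRUE; reason <- ""
      flags <- c(flags, "no-CO2-gate")
    } else {
      pass <- f$r_squared > policy$static_r2_threshold
      reason <- if (pass) "" else sprintf("%s R2 <= %g", g, policy$static_r2_threshold)
    }
    tibble::tibble(gas = g, qc_pass = pass, qc_reason = reason,
                   qc_flags = paste(flags, collapse = ";"))
  })
  dplyr::bind_rows(rows)
}

#' Estimate per-gas fluxes for a single chamber closure
#'
#' The full per-closure chain: convert ppm to mass concentration at the
#' closure's temperature and pressure, restrict to the fitting window, fit
#' the line, scale the slope by the chamber's effective headspace height,
#' and apply the CO2 quality gate. Rejected closures keep their flux value
#' with `qc_pass = FALSE` so the rejection rate is auditable.
#'
#' @param closure long-format rows of one closure (all its gas channels).
#' @param chamber the matching `chamber_spec` row.
#' @param window a [window_policy()]; defaults to the chamber kind's policy.
#' @param qc a [qc_policy()].
#' @param gases gases to report fluxes for (CO2 is always fitted when
#'   present, for gating; it is reported too if requested).
#' @param unit_mode `"molecule"` (default) or `"element"` flux basis.
#' @param registry gas registry.
#' @return A tibble with one row per reported gas: identifiers, fit
#'   diagnostics (`slope`, `intercept`, `r_squared`, `n_points`,
#'   `window_start`, `window_end`), `flux_ug_m2_h`, `qc_pass`, `qc_reason`,
#'   `qc_flags`.
#' @export
estimate_closure_fluxes <- function(closure, chamber, window = NULL,
                                    qc = qc_policy(), gases = NULL,
                                    unit_mode = "molecule",
                                    registry = gas_registry()) {
  if (is.null(window)) window <- window_policy(chamber$kind)
  conv <- convert_series(closure, registry = registry)
  win <- select_window(conv, window)
  fit_gases <- unique(win$gas)
  fits <- lapply(setNames(fit_gases, fit_gases), function(g) {
    ch <- win[win$gas == g, ]
    fit_linear(ch$t_seconds, ch$conc_ugm3)
  })
  verdicts <- qc_gate(fits, qc)
  if (is.null(gases)) gases <- setdiff(fit_gases, "CO2")
  rows <- lapply(gases, function(g) {
    f <- fits[[g]]
    v <- verdicts[verdicts$gas == g, ]
    if (nrow(v) == 0) v <- tibble::tibble(qc_pass = TRUE, qc_reason = "", qc_flags = "")
    tibble::tibble(
      chamber_id = chamber$chamber_id,
      closure_start = closure$closure_start[1],
      plot_id = closure$plot_id[1],
      period = closure$period[1],
      tree_id = chamber$tree_id,
      kind = chamber$kind,
      mount_height_m = chamber$mount_height_m,
      gas = g,
      slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared, n_points = f$n_points,
      window_start = f$window[1], window_end = f$window[2],
      flux_ug_m2_h = compute_flux(f, chamber) * flux_unit_factor(g, unit_mode, registry),
      qc_pass = v$qc_pass, qc_reason = v$qc_reason, qc_flags = v$qc_flags
    )
  })
  dplyr::bind_rows(rows)
}

#' Estimate fluxes for a whole campaign of closures
#'
#' Vectorised batch version of [estimate_closure_fluxes()]: converts every
#' sample to mass concentration, restricts each closure to the fitting
#' window of its chamber kind, computes the per-channel least-squares
#' slope and R-squared in closed form, scales slopes by each chamber's
#' effective headspace height, and applies the CO2 quality gate per
#' closure. Identical results to running [estimate_closure_fluxes()]
#' closure by closure. Closures with a degenerate or empty window are
#' dropped with a warning and counted as invalid.
#'
#' @param closures long-format closures table (validated).
#' @param chambers chambers table ([chamber_spec()] rows).
#' @param windows named list of window policies by kind; defaults per kind.
#' @param qc a [qc_policy()].
#' @inheritParams estimate_closure_fluxes
#' @return A flux tibble; attribute `counts` holds
#'   `c(closures_in, accepted, rejected, invalid)`.
#' @export
estimate_fluxes <- function(closures, chambers, windows = NULL,
                            qc = qc_policy(), unit_mode = "molecule",
                            registry = gas_registry()) {
  closures <- validate_closures(closures)
  if (is.null(windows)) {
    windows <- list(dynamic_soil = window_policy("dynamic_soil"),
                    static_stem = window_policy("static_stem"))
  }
  idx <- match(closures$chamber_id, chambers$chamber_id)
  if (anyNA(idx)) {
    stop_stemflux("unknown_chamber",
                  paste0("No chamber spec for chamber_id ",
                         paste(unique(closures$chamber_id[is.na(idx)]), collapse = ", ")))
  }
  kind <- chambers$kind[idx]
  n_closures <- length(unique(paste(closures$chamber_id, closures$closure_start, sep = "\r")))

  closures$conc_ugm3 <- ppm_to_mass(closures$ppm, closures$gas, closures$temp_k,
                                    closures$pressure_pa, registry)
  lo <- vapply(windows, function(w) w$deadband_s, 0)[kind]
  hi <- lo + vapply(windows, function(w) w$fit_duration_s, 0)[kind]
  in_win <- closures$t_seconds >= lo & closures$t_seconds <= hi
  win <- closures[in_win, , drop = FALSE]

  fits <- win |>
    dplyr::group_by(.data$chamber_id, .data$closure_start, .data$plot_id,
                    .data$period, .data$gas) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      tbar = mean(.data$t_seconds), ybar = mean(.data$conc_ugm3),
      sxx = sum((.data$t_seconds - tbar)^2),
      sxy = sum((.data$t_seconds - tbar) * (.data$conc_ugm3 - ybar)),
      sst = sum((.data$conc_ugm3 - ybar)^2),
      window_start = min(.data$t_seconds), window_end = max(.data$t_seconds),
      .groups = "drop"
    )
  degenerate <- fits$sst <= 0 | fits$sxx <= 0
  fits$slope <- ifelse(degenerate, 0, fits$sxy / fits$sxx)
  fits$intercept <- fits$ybar - fits$slope * fits$tbar
  fits$r_squared <- ifelse(degenerate, 0,
                           pmin(pmax(fits$sxy^2 / (fits$sxx * fits$sst), 0), 1))
  # a closure is invalid when any of its gas channels lacks a 2-point window
  closure_key <- paste(fits$chamber_id, fits$closure_start, sep = "\r")
  bad_key <- unique(closure_key[fits$n_points < 2])
  n_invalid <- n_closures - length(unique(closure_key)) + length(bad_key)
  fits <- fits[!(closure_key %in% bad_key), , drop = FALSE]
  if (n_invalid > 0) {
    warn(sprintf("%d closure(s) could not be fitted and were dropped.", n_invalid))
  }

  # CO2 gate: join each closure's CO2 R2; closures without CO2 follow the
  # static-chamber fallback rule
  closure_key <- paste(fits$chamber_id, fits$closure_start, sep = "\r")
  co2_rows <- fits$gas == "CO2"
  co2_map <- setNames(fits$r_squared[co2_rows], closure_key[co2_rows])
  co2_of <- unname(co2_map[closure_key])
  has_co2 <- !is.na(co2_of)
  fluxes <- fits[fits$gas != "CO2", , drop = FALSE]
  co2_of <- co2_of[fits$gas != "CO2"]
  has_co2 <- has_co2[fits$gas != "CO2"]
  fluxes$qc_pass <- ifelse(
    has_co2, co2_of > qc$co2_r2_threshold,
    if (qc$static_fallback == "accept_flag") TRUE else NA
  )
  if (qc$static_fallback == "threshold") {
    fluxes$qc_pass[!has_co2] <- fluxes$r_squared[!has_co2] > qc$static_r2_threshold
  }
  fluxes$qc_reason <- ifelse(
    fluxes$qc_pass, "",
    ifelse(has_co2, sprintf("CO2 R2 <= %g", qc$co2_r2_threshold),
           sprintf("%s R2 <= %g", fluxes$gas, qc$static_r2_threshold))
  )
  flag1 <- ifelse(fluxes$n_points <= 2, "min-points", "")
  flag2 <- ifelse(!has_co2 & qc$static_fallback == "accept_flag", "no-CO2-gate", "")
  fluxes$qc_flags <- gsub("^;|;$", "", paste(flag1, flag2, sep = ";"))

  cidx <- match(fluxes$chamber_id, chambers$chamber_id)
  fluxes$tree_id <- chambers$tree_id[cidx]
  fluxes$kind <- chambers$kind[cidx]
  fluxes$mount_height_m <- chambers$mount_height_m[cidx]
  fluxes$flux_ug_m2_h <- fluxes$slope *
    (chambers$volume_m3[cidx] / chambers$area_m2[cidx]) * 3600 *
    flux_unit_factor(fluxes$gas, unit_mode, registry)
  fluxes <- fluxes[, c("chamber_id", "closure_start", "plot_id", "period",
                       "tree_id", "kind", "mount_height_m", "gas",
                       "slope", "intercept", "r_squared", "n_points",
                       "window_start", "window_end", "flux_ug_m2_h",
                       "qc_pass", "qc_reason", "qc_flags")]
  # a closure counts as accepted when all its reported gases pass QC
  if (nrow(fluxes) > 0) {
    per_closure <- tapply(fluxes$qc_pass,
                          paste(fluxes$chamber_id, fluxes$closure_start, sep = "\r"), all)
    accepted <- sum(per_closure)
    rejected <- length(per_closure) - accepted
  } else {
    accepted <- 0L; rejected <- 0L
  }
  attr(fluxes, "counts") <- c(closures_in = n_closures, accepted = accepted,
                              rejected = rejected, invalid = n_invalid)
  fluxes
}
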