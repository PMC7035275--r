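# Windowed linear flux estimation and the CO2 quality gate.

test_that("soil window keeps the 150 s span after the 90 s deadband", {
  ch <- soil_chamber()
  cl <- make_closure(ch, list(CH4 = 10), seq(0, 539, by = 1))
  win <- select_window(cl, window_policy("dynamic_soil"))
  expect_identical(nrow(win), 151L)
  expect_equal(range(win$t_seconds), c(90, 240))
})

test_that("static stem windows keep all four GC samples", {
  ch <- stem_chamber()
  cl <- make_closure(ch, list(CH4 = 10), stem_grid_gc)
  win <- select_window(cl, window_policy("static_stem"))
  expect_identical(sort(win$t_seconds), stem_grid_gc)
})

test_that("an empty window is an insufficient-window error", {
  ch <- soil_chamber()
  cl <- make_closure(ch, list(CH4 = 10), seq(0, 539, by = 1))
  expect_error(select_window(cl, window_policy("dynamic_soil", deadband_s = 600)),
               class = "stemflux_error_insufficient_window")
})

test_that("fit_linear handles exact lines and the degenerate constant case", {
  f <- fit_linear(c(0, 60, 120, 180), c(0, 60, 120, 180))
  expect_equal(f$slope, 1, tolerance = 1e-14)
  expect_equal(f$r_squared, 1, tolerance = 1e-14)
  const <- fit_linear(c(0, 60, 120, 180), rep(5, 4))
  expect_identical(const$slope, 0)
  expect_identical(const$r_squared, 0)
  expect_error(fit_linear(rep(10, 3), 1:3), class = "stemflux_error_degenerate_time")
})

test_that("fit_linear agrees with the stats::lm oracle on random noisy series", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:60, 1)
    t <- sort(runif(n, 0, 540))
    y <- runif(1, -5, 5) * t + rnorm(n, sd = runif(1, 0.1, 10)) + runif(1, -100, 100)
    f <- fit_linear(t, y)
    ref <- lm(y ~ t)
    expect_equal(f$slope, unname(coef(ref)[2]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
    expect_equal(f$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  }
})

test_that("flux scales the slope by effective headspace height and per-hour", {
  # stem system: V/A = 0.00119/0.0108 m, x 3600 s/h
  expect_equal(compute_flux(1, stem_chamber()), 0.00119 / 0.0108 * 3600,
               tolerance = 1e-12)
  expect_equal(compute_flux(1, stem_chamber()), 396.6667, tolerance = 1e-6)
  expect_identical(compute_flux(0, stem_chamber()), 0)
  expect_equal(compute_flux(0.5, soil_chamber()), 360, tolerance = 1e-12)
})

test_that("the CO2 gate accepts above 0.9 and rejects at and below it", {
  mkfit <- function(r2) structure(list(slope = 1, intercept = 0, r_squared = r2,
                                       n_points = 151, window = c(90, 240)),
                                  class = "linear_fit")
  for (r2 in c(0.95, 0.90, 0.85)) {
    v <- qc_gate(list(CO2 = mkfit(r2), CH4 = mkfit(0.2), N2O = mkfit(0.1)))
    expect_identical(v$qc_pass, rep(r2 > 0.9, 2))
    if (r2 <= 0.9) expect_match(v$qc_reason, "CO2 R2", all = TRUE)
  }
  # own R2 is irrelevant when CO2 passes
  v <- qc_gate(list(CO2 = mkfit(0.95), CH4 = mkfit(0.01)))
  expect_true(v$qc_pass)
  # no CO2 channel: accept-and-flag by default, own-R2 threshold on request
  v <- qc_gate(list(CH4 = mkfit(0.5)))
  expect_true(v$qc_pass)
  expect_match(v$qc_flags, "no-CO2-gate")
  v <- qc_gate(list(CH4 = mkfit(0.5)), qc_policy(static_fallback = "threshold"))
  expect_false(v$qc_pass)
})

test_that("noiseless linear closures are recovered exactly for both chamber kinds", {
  soil <- make_closure(soil_chamber(), list(CO2 = 150000, CH4 = 50), soil_grid_1hz)
  est <- estimate_closure_fluxes(soil, soil_chamber())
  expect_equal(est$flux_ug_m2_h[est$gas == "CH4"], 50, tolerance = 1e-8)
  expect_true(all(est$qc_pass))
  stem <- make_closure(stem_chamber(), list(CH4 = 50, N2O = -7), stem_grid_gc)
  est <- estimate_closure_fluxes(stem, stem_chamber())
  expect_equal(est$flux_ug_m2_h[est$gas == "CH4"], 50, tolerance = 1e-8)
  expect_equal(est$flux_ug_m2_h[est$gas == "N2O"], -7, tolerance = 1e-8)
})

test_that("strong headspace feedback fails the CO2 gate and constants yield zero flux", {
  curved <- make_closure(soil_chamber(), list(CO2 = 150000, CH4 = 50),
                         soil_grid_1hz, lambda = 0.02)
  est <- estimate_closure_fluxes(curved, soil_chamber())
  expect_false(any(est$qc_pass))
  expect_match(est$qc_reason, "CO2 R2", all = TRUE)
  flat <- make_closure(soil_chamber(), list(CO2 = 0, CH4 = 0), soil_grid_1hz)
  est <- estimate_closure_fluxes(flat, soil_chamber())
  expect_identical(est$flux_ug_m2_h, 0)
  expect_false(any(est$qc_pass))  # CO2 R2 = 0 by the constant-series convention
})

test_that("the estimate scales with the generating flux (c = -1, 2, 10)", {
  base <- 35
  est_of <- function(f) {
    cl <- make_closure(soil_chamber(), list(CH4 = f), soil_grid_1hz)
    est <- estimate_closure_fluxes(cl, soil_chamber())
    est$flux_ug_m2_h
  }
  e0 <- est_of(base)
  for (c_ in c(-1, 2, 10)) {
    expect_equal(est_of(c_ * base), c_ * e0, tolerance = 1e-10)
  }
})

test_that("the estimator is unbiased under additive ppm noise", {
  set.seed(31)
  true_flux <- 50
  est <- replicate(1000, {
    cl <- make_closure(stem_chamber(), list(CH4 = true_flux), stem_grid_gc,
                       noise_ppm_sd = 0.03)
    estimate_closure_fluxes(cl, stem_chamber())$flux_ug_m2_h
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_flux), 3 * se)
})

test_that("headspace feedback biases the windowed slope by about exp(-lambda tbar)", {
  lam <- 0.002
  cl <- make_closure(soil_chamber(), list(CH4 = 100), soil_grid_1hz, lambda = lam)
  conv <- convert_series(cl)
  win <- select_window(conv, window_policy("dynamic_soil"))
  f <- fit_linear(win$t_seconds, win$conc_ugm3)
  s_true <- 100 / 3600 / 0.2
  expect_equal(f$slope / s_true, exp(-lam * mean(win$t_seconds)), tolerance = 0.01)
  expect_lt(f$slope, s_true)
})

test_that("CO2 R2 never increases along a curvature sweep", {
  r2 <- vapply(seq(0, 0.02, length.out = 20), function(lam) {
    cl <- make_closure(soil_chamber(), list(CO2 = 150000), soil_grid_1hz,
                       lambda = lam)
    conv <- convert_series(cl)
    win <- select_window(conv, window_policy("dynamic_soil"))
    fit_linear(win$t_seconds, win$conc_ugm3)$r_squared
  }, 0)
  expect_true(all(diff(r2) <= 1e-12))
})

test_that("batch estimation equals the per-closure path and conserves counts", {
  camp <- shared_campaign()
  ids <- unique(camp$closures$chamber_id)[c(1, 2, 14, 15)]
  cl <- camp$closures[camp$closures$chamber_id %in% ids, ]
  keep_starts <- unlist(lapply(split(cl$closure_start, cl$chamber_id),
                               function(s) head(unique(s), 3)))
  cl <- cl[cl$closure_start %in% keep_starts, ]
  batch <- estimate_fluxes(cl, camp$chambers)
  counts <- attr(batch, "counts")
  expect_identical(unname(counts["closures_in"]),
                   unname(counts["accepted"] + counts["rejected"] + counts["invalid"]))
  ref <- dplyr::bind_rows(lapply(
    split(seq_len(nrow(cl)), paste(cl$chamber_id, cl$closure_start)),
    function(i) {
      one <- cl[i, ]
      ch <- camp$chambers[camp$chambers$chamber_id == one$chamber_id[1], ]
      estimate_closure_fluxes(one, ch)
    }
  ))
  ord <- function(d) d[order(d$chamber_id, d$closure_start, d$gas), ]
  expect_equal(as.data.frame(ord(batch)), as.data.frame(ord(ref)),
               tolerance = 1e-12, ignore_attr = TRUE)
})
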