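# Flux-versus-height decay models.

three_heights <- c(0.10, 0.80, 1.70)
noiseless_obs <- function(F0 = 100, k = 1.5) {
  tibble::tibble(height_m = three_heights, flux_ug_m2_h = F0 * exp(-k * three_heights))
}

test_that("noiseless exponential profiles are recovered to machine-level accuracy", {
  # values 86.0708 / 30.1194 / 7.8082 at the three campaign heights
  m <- fit_profile(noiseless_obs())
  expect_identical(m$form, "exp_decay")
  expect_equal(m$F0, 100, tolerance = 1e-6)
  expect_equal(m$k, 1.5, tolerance = 1e-6)
})

test_that("flat and mixed-sign profiles fall back to the constant form", {
  flat <- tibble::tibble(height_m = three_heights, flux_ug_m2_h = rep(10, 3))
  m <- fit_profile(flat)
  expect_identical(m$form, "constant")
  expect_equal(m$F0, 10)
  expect_identical(m$k, 0)
  mixed <- tibble::tibble(height_m = three_heights, flux_ug_m2_h = c(5, -2, 1))
  m <- fit_profile(mixed)
  expect_identical(m$form, "constant")
  expect_false(m$converged)
})

test_that("underdetermined profiles and negative heights are rejected", {
  expect_error(fit_profile(tibble::tibble(height_m = c(0.1, 0.1, 0.1),
                                          flux_ug_m2_h = c(1, 2, 3))),
               class = "stemflux_error_profile_undetermined")
  expect_error(fit_profile(tibble::tibble(height_m = c(-0.1, 0.8, 1.7),
                                          flux_ug_m2_h = c(1, 2, 3))),
               class = "stemflux_error_domain")
  expect_error(predict_flux(fit_profile(noiseless_obs()), -1),
               class = "stemflux_error_domain")
})

test_that("profile predictions follow the closed form", {
  m <- fit_profile(noiseless_obs())
  expect_equal(predict_flux(m, 0), 100, tolerance = 1e-6)
  expect_equal(predict_flux(m, 1.7), 7.808167, tolerance = 1e-5)
  const <- fit_profile(tibble::tibble(height_m = three_heights,
                                      flux_ug_m2_h = rep(4, 3)))
  expect_identical(predict_flux(const, c(0, 5, 30)), rep(4, 3))
})

test_that("parameter recovery stays accurate under 10% multiplicative noise", {
  set.seed(41)
  # minimal design: one observation per height
  k3 <- replicate(500, {
    f <- 100 * exp(-1.5 * three_heights) * (1 + rnorm(3, 0, 0.1))
    fit_profile(tibble::tibble(height_m = three_heights, flux_ug_m2_h = f))$k
  })
  expect_lt(median(abs(k3 - 1.5) / 1.5), 0.10)
  expect_true(all(is.finite(k3)))
  # pooled design (six profile trees): estimator bias below 5%
  h6 <- rep(three_heights, times = 6)
  res <- t(replicate(500, {
    f <- 100 * exp(-1.5 * h6) * (1 + rnorm(length(h6), 0, 0.1))
    m <- fit_profile(tibble::tibble(height_m = h6, flux_ug_m2_h = f))
    c(m$F0, m$k)
  }))
  expect_lt(abs(mean(res[, 1]) - 100) / 100, 0.05)
  expect_lt(abs(mean(res[, 2]) - 1.5) / 1.5, 0.05)
})

test_that("height-averaged flux matches the closed form and its k -> 0 limit", {
  m <- list(F0 = 100, k = 1.5)
  # 100 * (1 - exp(-1.5 * 1.7)) / (1.5 * 1.7)
  expect_equal(mean_stem_flux(m, 1.7), 36.15366, tolerance = 1e-6)
  expect_equal(mean_stem_flux(list(F0 = 100, k = 1e-12), 5), 100, tolerance = 1e-9)
  expect_equal(mean_stem_flux(list(F0 = 100, k = 0), 3), 100)
  expect_error(mean_stem_flux(m, 0), class = "stemflux_error_domain")
})

test_that("closed-form mean agrees with adaptive quadrature on random parameters", {
  set.seed(51)
  for (i in 1:50) {
    F0 <- runif(1, -200, 200)
    k <- runif(1, 0.01, 4)
    H <- runif(1, 0.5, 20)
    quad <- stats::integrate(function(h) F0 * exp(-k * h), 0, H,
                             rel.tol = 1e-10)$value / H
    expect_equal(mean_stem_flux(list(F0 = F0, k = k), H), quad, tolerance = 1e-6)
  }
})

test_that("positive-decay profiles are monotone and the mean is bracketed", {
  m <- fit_profile(noiseless_obs())
  h <- seq(0, 5, by = 0.25)
  expect_true(all(diff(predict_flux(m, h)) < 0))
  H <- seq(0.5, 10, by = 0.5)
  means <- vapply(H, function(x) mean_stem_flux(m, x), 0)
  expect_true(all(diff(means) < 0))
  # prediction at the lowest observed height bounds the mean from above,
  # the prediction at the integration top bounds it from below
  expect_gte(predict_flux(m, min(three_heights)), mean_stem_flux(m, 1.7))
  expect_gte(mean_stem_flux(m, 1.7), predict_flux(m, 1.7))
})

test_that("grouped profile fitting returns one model per plot, period and gas", {
  cfg <- tiny_scenario(
    seed = 9,
    noise_ppm_sd = list(static_stem = c(CH4 = 0, N2O = 0),
                        dynamic_soil = c(CH4 = 0, N2O = 0, CO2 = 0)),
    between_sdlog = 0, day_sdlog = 0
  )
  camp <- generate_campaign(cfg)
  fluxes <- estimate_fluxes(camp$closures, camp$chambers)
  profs <- fit_profiles(fluxes)
  expect_true(all(c("plot_id", "period", "gas", "form", "F0", "k") %in% names(profs)))
  expect_false(any(duplicated(profs[, c("plot_id", "period", "gas")])))
  expect_true(all(is.finite(profs$F0)) && all(is.finite(profs$k)))
  # a homogeneous noiseless period resolves the configured height decay exactly
  row <- profs[profs$plot_id == "FP" & profs$period == "pre" & profs$gas == "CH4", ]
  expect_identical(row$form, "exp_decay")
  expect_equal(row$k, cfg$stem_truth$CH4$k, tolerance = 1e-4)
  expect_equal(row$F0, cfg$stem_truth$CH4$F0, tolerance = 1e-4)
})
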