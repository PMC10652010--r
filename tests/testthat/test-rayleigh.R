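em0 <- em_preset("nh_atmospheric_hg0")
em2 <- em_preset("nh_rainfall_hgII")

test_that("loss fraction follows the Rayleigh residual law", {
  expect_equal(rayleigh_loss_fraction(0)$loss, 0)
  r <- rayleigh_loss_fraction(-0.16, rayleigh_params(0.49))
  expect_equal(r$f_remaining, exp(-0.16 / 0.49), tolerance = 1e-12)
  expect_equal(r$loss, 1 - exp(-0.16 / 0.49), tolerance = 1e-12)
  expect_equal(rayleigh_loss_fraction(-0.49, rayleigh_params(0.49))$loss,
               1 - exp(-1), tolerance = 1e-12)
  # positive shift: flagged, not an exception, zero loss
  p <- rayleigh_loss_fraction(0.05)
  expect_true(p$flagged)
  expect_equal(p$loss, 0)
  expect_error(rayleigh_params(0), "positive")
  expect_error(rayleigh_params(-0.49), "positive")
})

test_that("loss is monotone in the shift magnitude and in the enrichment factor", {
  shifts <- -seq(0.01, 1, by = 0.01)
  losses <- rayleigh_loss_fraction(shifts)$loss
  expect_true(all(diff(losses) > 0))  # larger |shift| -> larger loss
  Es <- seq(0.2, 2, by = 0.1)
  lE <- vapply(Es, function(E) {
    rayleigh_loss_fraction(-0.16, rayleigh_params(E))$loss
  }, numeric(1))
  expect_true(all(diff(lE) < 0))      # larger E -> smaller loss
  # small-shift limit: loss ~ -shift/E to first order
  expect_equal(rayleigh_loss_fraction(-0.001, rayleigh_params(0.49))$loss,
               0.001 / 0.49, tolerance = 2e-3)
})

test_that("slices on the mixing line imply zero profile loss", {
  cfg <- scenario_config(seed = 2, loss_true = 0,
                         noise_2s = c(d202 = 0, D199 = 0, D200 = 0),
                         density_sd = 0)
  g <- generate_core(cfg)
  r <- profile_loss(g$profile, em0, em2, period = c(1800, 2020))
  expect_equal(r$mean_loss, 0, tolerance = 1e-12)
  expect_equal(r$loss_flux, 0, tolerance = 1e-12)
  expect_equal(r$gross_deposition, r$net_flux, tolerance = 1e-12)
})

test_that("profile loss recovers an injected 30 % loss from a noisy core", {
  g <- generate_core(scenario_config(seed = 8, loss_true = 0.30))
  r <- profile_loss(g$profile, em0, em2, period = c(1800, 2020))
  # per-slice loss sd from the injected isotope noise, propagated through
  # the exponential, bounds the recovery error of the mean
  m <- (em0$D199_mean - em2$D199_mean) / (em0$D200_mean - em2$D200_mean)
  s_shift <- sqrt((0.13 / 2)^2 + (m * 0.08 / 2)^2)
  s_loss <- (1 - 0.30) * s_shift / 0.49
  expect_lt(abs(r$mean_loss - 0.30), 3 * s_loss / sqrt(r$n) + 0.02)
  expect_error(profile_loss(g$profile, em0, em2, period = c(1000, 1100)),
               "no slice")
})

test_that("noise-free core reproduces the since-1800 budget identity", {
  gross_true <- 12.7 / (1 - 0.257)
  cfg <- scenario_config(
    seed = 1,
    deposition_history = data.frame(from_CE = 1800, to_CE = 2020,
                                    gross_flux = gross_true),
    alpha_true = 0.64, loss_true = 0.257,
    noise_2s = c(d202 = 0, D199 = 0, D200 = 0), density_sd = 0)
  g <- generate_core(cfg)
  r <- profile_loss(g$profile, em0, em2, period = c(1800, 2020))
  expect_equal(r$mean_loss, 0.257, tolerance = 1e-9)
  expect_equal(r$net_flux, 12.7, tolerance = 1e-6)
  expect_equal(r$gross_deposition, gross_true, tolerance = 1e-6)
  b <- deposition_budget(r, 0.64)
  flux <- setNames(b$flux, b$component)
  expect_equal(unname(flux["hg0_uptake"]), 0.64 * gross_true,
               tolerance = 1e-6)
  expect_equal(unname(flux["rainfall_hgII"]), 0.36 * gross_true,
               tolerance = 1e-6)
  expect_equal(unname(flux["photoreduction_loss"]), 4.4, tolerance = 0.05)
})

test_that("the budget closes to numerical precision for arbitrary inputs", {
  set.seed(21)
  for (i in 1:25) {
    cfg <- scenario_config(
      seed = 100 + i,
      alpha_true = runif(1, 0.2, 0.9), loss_true = runif(1, 0, 0.6))
    g <- generate_core(cfg)
    r <- profile_loss(g$profile, em0, em2, period = c(1800, 2020))
    b <- deposition_budget(r, runif(1, 0, 1), runoff = runif(1, 0, 3))
    flux <- setNames(b$flux, b$component)
    residual <- flux["hg0_uptake"] + flux["rainfall_hgII"] -
      flux["photoreduction_loss"] - flux["runoff_export"] -
      flux["net_accumulation"]
    expect_lt(abs(residual), 1e-9)
  }
  # zero loss, zero runoff: net equals gross, split by alpha
  cfg0 <- scenario_config(seed = 3, loss_true = 0,
                          noise_2s = c(d202 = 0, D199 = 0, D200 = 0),
                          density_sd = 0)
  g0 <- generate_core(cfg0)
  r0 <- profile_loss(g0$profile, em0, em2, period = c(1800, 2020))
  b0 <- deposition_budget(r0, 0.73)
  flux0 <- setNames(b0$flux, b0$component)
  expect_equal(unname(flux0["net_accumulation"]),
               unname(flux0["gross_deposition"]), tolerance = 1e-9)
  expect_equal(unname(flux0["hg0_uptake"]),
               0.73 * unname(flux0["gross_deposition"]), tolerance = 1e-9)
  # inconsistent periods are refused
  expect_error(deposition_budget(r0, 0.73, period = c(1900, 1950)),
               "period")
})
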