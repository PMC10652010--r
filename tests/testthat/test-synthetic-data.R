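em0 <- em_preset("nh_atmospheric_hg0")
em2 <- em_preset("nh_rainfall_hgII")

test_that("noise-free, loss-free cores sit exactly on the end-member line", {
  cfg <- scenario_config(seed = 1, loss_true = 0,
                         noise_2s = c(d202 = 0, D199 = 0, D200 = 0),
                         density_sd = 0)
  g <- generate_core(cfg)
  for (s in g$profile$slices) {
    expect_equal(s$isotopes$D199,
                 mixing_line_prediction(s$isotopes$D200, em0, em2),
                 tolerance = 1e-12)
  }
  # HgAR equals the configured deposition for every slice
  hgar <- vapply(g$profile$slices, hg_accumulation_rate, numeric(1))
  expect_equal(hgar, g$truth$gross_flux, tolerance = 1e-9)
})

test_that("the injected loss shifts every slice by E * ln(1 - L)", {
  cfg <- scenario_config(seed = 1, loss_true = 0.28,
                         noise_2s = c(d202 = 0, D199 = 0, D200 = 0),
                         density_sd = 0)
  g <- generate_core(cfg)
  shift <- vapply(g$profile$slices, function(s) {
    s$isotopes$D199 - mixing_line_prediction(s$isotopes$D200, em0, em2)
  }, numeric(1))
  expect_equal(shift, rep(0.49 * log(0.72), length(shift)),
               tolerance = 1e-12)
  expect_equal(unique(g$truth$shift_true), 0.49 * log(0.72))
  # and HgAR records the net (post-loss) flux
  hgar <- vapply(g$profile$slices, hg_accumulation_rate, numeric(1))
  expect_equal(hgar, g$truth$gross_flux * 0.72, tolerance = 1e-9)
})

test_that("generation is bitwise reproducible for a fixed seed", {
  a <- generate_core(scenario_config(seed = 123))
  b <- generate_core(scenario_config(seed = 123))
  expect_identical(a$truth, b$truth)
  expect_identical(core_as_data_frame(a$profile), core_as_data_frame(b$profile))
  gw1 <- generate_gas_water(scenario_config(seed = 123))
  gw2 <- generate_gas_water(scenario_config(seed = 123))
  expect_identical(gw1$gas$conc, gw2$gas$conc)
  expect_identical(gw1$water$dgm, gw2$water$dgm)
})

test_that("gas and water draws honour the configured compartment structure", {
  cfg0 <- scenario_config(seed = 4, gas_sds = c(atmosphere = 0,
                                                soil_gas_hummock = 0,
                                                soil_gas_lawn = 0),
                          dgm_sd = 0)
  gw0 <- generate_gas_water(cfg0)
  expect_equal(unique(gw0$gas$conc[gw0$gas$compartment == "atmosphere"]),
               1.31)
  expect_equal(unique(gw0$gas$conc[gw0$gas$compartment == "soil_gas_lawn"]),
               0.48)
  # large-n means converge on the configured values within 3 standard errors
  cfg <- scenario_config(seed = 4,
                         n_gas = c(atmosphere = 400,
                                   soil_gas_hummock = 400,
                                   soil_gas_lawn = 400),
                         n_water = 400)
  gw <- generate_gas_water(cfg)
  m_atm <- mean(gw$gas$conc[gw$gas$compartment == "atmosphere"])
  expect_lt(abs(m_atm - 1.31), 3 * 0.17 / sqrt(400))
  m_soil <- mean(gw$gas$conc[grepl("^soil", gw$gas$compartment)])
  expect_lt(abs(m_soil - 0.455), 3 * 0.12 / sqrt(800) + 0.025)
  # downward gradient preserved in every default draw set
  for (s in 1:10) {
    gws <- generate_gas_water(scenario_config(seed = s))
    expect_gt(mean(gws$gas$conc[gws$gas$compartment == "atmosphere"]),
              mean(gws$gas$conc[grepl("^soil", gws$gas$compartment)]))
  }
  # DGM declines with depth below the near-surface maximum (noise-free)
  expect_true(all(diff(gw0$water$dgm[order(gw0$water$depth_below_wt)]) <= 0))
})

test_that("scenario validation refuses inconsistent configurations", {
  expect_error(scenario_config(loss_true = 1), "loss_true")
  expect_error(scenario_config(alpha_true = 1.2), "alpha_true")
  expect_error(scenario_config(deposition_history = data.frame(
    from_CE = c(1800, 1960), to_CE = c(1950, 2020),
    gross_flux = c(10, 20))), "contiguous")
  expect_error(scenario_config(noise_2s = c(d202 = -1, D199 = 0.1,
                                            D200 = 0.1)), "noise")
})

test_that("emitted observation files carry no latent truth columns", {
  dir <- withr::local_tempdir()
  paths <- simulate_scenario(scenario_config(seed = 9), dir)
  expect_true(all(file.exists(paths)))
  core <- read.csv(paths[["core"]])
  leak <- grepl("true|alpha|loss|baseline|gross|net", names(core),
                ignore.case = TRUE)
  expect_false(any(leak))
  truth <- jsonlite::fromJSON(paths[["truth"]])
  expect_equal(truth$loss_true, 0.28)
  expect_true("D199_true" %in% names(truth$per_slice))
  # the observation CSV reloads into a working profile
  prof <- read_core_csv(paths[["core"]])
  expect_s3_class(prof, "core_profile")
})

test_that("full pipeline recovers injected loss and mixing fractions", {
  # forward-simulate cores across a range of loss fractions, then run the
  # analysis chain blind and compare against an analytic expectation of the
  # noisy estimator (clipping positive shifts biases small losses upward;
  # the quadrature expectation accounts for that)
  m <- (em0$D199_mean - em2$D199_mean) / (em0$D200_mean - em2$D200_mean)
  s_shift <- sqrt((0.13 / 2)^2 + (m * 0.08 / 2)^2)
  expected_loss <- function(L) {
    mu <- 0.49 * log(1 - L)
    integrand <- function(s) {
      (1 - exp(pmin(s, 0) / 0.49)) * dnorm(s, mu, s_shift)
    }
    integrate(integrand, mu - 8 * s_shift, mu + 8 * s_shift)$value
  }
  n_cores <- 100L
  set.seed(2024)
  loss_true <- runif(n_cores, 0.1, 0.5)
  alpha_true <- runif(n_cores, 0.4, 0.9)
  err_loss <- numeric(n_cores)
  err_alpha <- numeric(n_cores)
  ns <- integer(n_cores)
  hist <- data.frame(from_CE = 1800, to_CE = 2020, gross_flux = 17)
  for (i in seq_len(n_cores)) {
    cfg <- scenario_config(seed = 5000 + i, deposition_history = hist,
                           alpha_true = alpha_true[i],
                           loss_true = loss_true[i])
    g <- generate_core(cfg)
    r <- profile_loss(g$profile, em0, em2, period = c(1800, 2020))
    d200 <- vapply(g$profile$slices, function(s) s$isotopes$D200, numeric(1))
    a_hat <- mean(endmember_fraction(d200, em0, em2)$alpha)
    err_loss[i] <- r$mean_loss - expected_loss(loss_true[i])
    err_alpha[i] <- a_hat - alpha_true[i]
    ns[i] <- r$n
  }
  s_loss_slice <- (1 - mean(loss_true)) * s_shift / 0.49
  se_core_loss <- s_loss_slice / sqrt(mean(ns))
  # unbiased against the noise-propagated expectation...
  expect_lt(abs(mean(err_loss)), 3 * se_core_loss / sqrt(n_cores))
  # ...and per-core errors sized like the propagated noise
  expect_lt(mean(abs(err_loss)), 2 * se_core_loss)
  s_alpha_slice <- (0.08 / 2) / 0.22
  se_core_alpha <- s_alpha_slice / sqrt(mean(ns))
  expect_lt(abs(mean(err_alpha)), 3 * se_core_alpha / sqrt(n_cores))
  expect_lt(mean(abs(err_alpha)), 2 * se_core_alpha)
})
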