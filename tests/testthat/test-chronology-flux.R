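make_slice <- function(hgar, years, density = 0.05, thickness = 2,
                       depth_top = 0, age_top = 2020) {
  # invert the accumulation-rate formula to get the concentration that
  # yields the requested flux (ug m-2 yr-1)
  conc <- hgar / 10 * years / (density * thickness)
  peat_slice(depth_top, depth_top + thickness, density = density,
             hg_conc = conc, age_top = age_top, age_bottom = age_top - years)
}

test_that("slice and profile validation enforce the unit conventions", {
  expect_error(peat_slice(2, 1, 0.05, 10, 2020, 2010), "depth_bottom")
  expect_error(peat_slice(0, 1, -0.05, 10, 2020, 2010), "density")
  expect_error(peat_slice(0, 1, 0.05, -1, 2020, 2010), "hg_conc")
  expect_error(peat_slice(0, 1, 0.05, 10, 2000, 2010), "age_top")
  s1 <- peat_slice(0, 2, 0.05, 10, 2020, 2010)
  s3 <- peat_slice(4, 6, 0.05, 10, 2000, 1990)
  expect_error(core_profile(list(s1, s3)), "contiguous")
  expect_s3_class(core_profile(list(s1, s3), allow_gaps = TRUE),
                  "core_profile")
})

test_that("age interpolation is piecewise linear within the dated span", {
  m <- age_depth_model(c(0, 10, 30), c(2020, 2000, 1900))
  expect_equal(interpolate_ages(m, 10), 2000)
  expect_equal(interpolate_ages(m, 5), 2010)
  expect_equal(interpolate_ages(m, c(2, 15, 25)),
               c(2020 - 2 * 2, 2000 - 5 * 5, 2000 - 15 * 5))
  ages <- interpolate_ages(m, seq(0, 30, by = 1.5))
  expect_true(all(diff(ages) <= 0))
  expect_error(interpolate_ages(m, 31), "extrapolate")
  expect_error(age_depth_model(c(0, 10), c(1900, 2000)), "non-increasing")
})

test_that("accumulation rate follows concentration x density x thickness / years", {
  s <- peat_slice(0, 1, density = 0.05, hg_conc = 100,
                  age_top = 2020, age_bottom = 2015)
  expect_equal(hg_accumulation_rate(s), 10)  # 1 ng cm-2 yr-1 -> 10 ug m-2 yr-1
  expect_equal(hg_accumulation_rate(
    peat_slice(0, 2, 0.04, 50, 2020, 2016)), 10)
  expect_equal(hg_accumulation_rate(
    peat_slice(0, 1, 0.05, 0, 2020, 2015)), 0)
  expect_error(hg_accumulation_rate(peat_slice(0, 1, 0.05, 10, 2020, 2020)),
               "degenerate")
  # linearity in each factor
  set.seed(3)
  base <- peat_slice(0, 1, 0.05, 100, 2020, 2015)
  f0 <- hg_accumulation_rate(base)
  for (i in 1:10) {
    k <- runif(1, 0.2, 5)
    expect_equal(hg_accumulation_rate(
      peat_slice(0, 1, 0.05, 100 * k, 2020, 2015)), k * f0)
    expect_equal(hg_accumulation_rate(
      peat_slice(0, 1, 0.05 * k, 100, 2020, 2015)), k * f0)
    expect_equal(hg_accumulation_rate(
      peat_slice(0, k, 0.05, 100, 2020, 2015)), k * f0)
    expect_equal(hg_accumulation_rate(
      peat_slice(0, 1, 0.05, 100, 2020, 2020 - 5 * k)), f0 / k)
  }
})

test_that("period means are time-weighted with pro-rata boundary splitting", {
  s1 <- make_slice(10, 10, depth_top = 0, age_top = 2020)   # 2010-2020
  s2 <- make_slice(20, 10, depth_top = 2, age_top = 2010)   # 2000-2010
  s3 <- make_slice(40, 20, depth_top = 4, age_top = 2000)   # 1980-2000
  prof <- core_profile(list(s1, s2, s3))

  # single slice fully inside
  expect_equal(period_mean_flux(prof, c(2012, 2018))$mean, 10)
  # two slices of equal duration
  expect_equal(period_mean_flux(prof, c(2000, 2020))$mean, 15)
  # partial overlap: brute-force year-by-year oracle on a fine grid
  period <- c(1990, 2015)
  grid <- seq(period[1] + 0.0005, period[2] - 0.0005, by = 0.001)
  flux_at <- function(yr) ifelse(yr >= 2010, 10, ifelse(yr >= 2000, 20, 40))
  expect_equal(period_mean_flux(prof, period)$mean,
               mean(flux_at(grid)), tolerance = 1e-4)
  # and the exact hand value: (5*10 + 10*20 + 10*40) / 25
  expect_equal(period_mean_flux(prof, period)$mean, 26)
  expect_error(period_mean_flux(prof, c(1800, 1900)), "no slice")
  expect_error(period_mean_flux(prof, c(2020, 2000)), "start < end")
})

test_that("disjoint-period means combine by duration weighting", {
  set.seed(11)
  g <- generate_core(scenario_config(seed = 11))
  p1 <- c(1850, 1950)
  p2 <- c(1950, 2000)
  f1 <- period_mean_flux(g$profile, p1)
  f2 <- period_mean_flux(g$profile, p2)
  f12 <- period_mean_flux(g$profile, c(1850, 2000))
  expect_equal(f12$mean,
               (f1$mean * f1$years + f2$mean * f2$years) /
                 (f1$years + f2$years),
               tolerance = 1e-10)
})

test_that("core CSV round trip preserves slices and isotopes", {
  g <- generate_core(scenario_config(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- core_as_data_frame(g$profile)
  write.csv(df, path, row.names = FALSE)
  back <- read_core_csv(path, microform = "hummock")
  expect_equal(length(back$slices), length(g$profile$slices))
  expect_equal(vapply(back$slices, hg_accumulation_rate, numeric(1)),
               vapply(g$profile$slices, hg_accumulation_rate, numeric(1)),
               tolerance = 1e-9)
  expect_equal(back$slices[[3]]$isotopes$D200,
               g$profile$slices[[3]]$isotopes$D200, tolerance = 1e-12)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(depth_top_cm = 0), p2, row.names = FALSE)
  expect_error(read_core_csv(p2), "missing required column")
})
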