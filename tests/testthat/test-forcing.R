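test_that("temperature generator follows the heat-hold profile", {
  heat <- scenario_spec("heat", "unshaded", seed = 1)
  amb <- scenario_spec("ambient", "unshaded", seed = 1)
  expect_equal(generate_temperature(heat, 0), 26.4)
  expect_equal(generate_temperature(heat, 20), 32.6)
  expect_equal(generate_temperature(heat, 14), 32.6)
  expect_equal(generate_temperature(heat, 7), 26.4 + (6.2 / 14) * 7)
  expect_equal(generate_temperature(amb, c(0, 11.3, 23)), rep(26.4, 3))
  # ramp + hold must fit in the scenario
  expect_error(scenario_spec("heat", "unshaded", days = 20),
               "ramp_days.*hold_days")
})

test_that("diel PAR: zero at night, DLI statistics and exact shading", {
  spec <- scenario_spec("ambient", "unshaded", seed = 7)
  fs <- generate_forcing(spec)
  night <- (fs$time_days %% 1) < 0.25 | (fs$time_days %% 1) > 0.75
  expect_true(all(fs$par[night] == 0))
  dli <- daily_light_integral(fs, 0:22)
  # the generator reproduces the treatment-mean DLI by construction
  expect_rel_equal(mean(dli), 7.21, 0.02)
  expect_gt(stats::sd(dli), 1)     # day-to-day cloudiness is present
  # shaded series is exactly 0.70 x unshaded, same seed
  sh <- generate_forcing(scenario_spec("ambient", "shaded", seed = 7))
  expect_identical(sh$par, 0.70 * fs$par)
  expect_identical(daily_light_integral(sh, 4), 0.70 * daily_light_integral(fs, 4))
})

test_that("PAR generator is deterministic and leaves the global RNG alone", {
  spec <- scenario_spec("heat", "shaded", seed = 3)
  a <- generate_forcing(spec)
  set.seed(99)
  before <- stats::runif(1)
  b <- generate_forcing(spec)
  expect_identical(a, b)
  set.seed(99)
  expect_identical(before, stats::runif(1))  # generator restored RNG state
})

test_that("nutrient series are plateau redraws with the right statistics", {
  spec <- scenario_spec("ambient", "unshaded", seed = 5)
  nut <- generate_nutrients(spec)
  # 12 draw epochs over 23 days at a 2-day interval
  expect_equal(length(unique(nut$din)), 12)
  expect_true(all(nut$din >= 0) && all(nut$dip >= 0))
  # degenerate sd -> constant series
  s0 <- scenario_spec("ambient", "unshaded", seed = 5, din_sd = 0, dip_sd = 0)
  n0 <- generate_nutrients(s0)
  expect_true(all(n0$din == 3.35) && all(n0$dip == 0.58))
  # long-run mean matches the treatment statistics within Monte-Carlo error
  draws <- unlist(lapply(1:40, function(sd)
    unique(generate_nutrients(scenario_spec("ambient", "unshaded",
                                            seed = sd))$din)))
  expect_lt(abs(mean(draws) - 3.35), 3 * 1.14 / sqrt(length(draws)) + 0.05)
})

test_that("daily light integral integrates the trapezoid exactly", {
  fs <- const_forcing(days = 2, par = 100)
  expect_equal(daily_light_integral(fs, 0), 8.64, tolerance = 1e-9)
  expect_equal(daily_light_integral(const_forcing(2, par = 0), 1), 0)
  # 6-hour square pulse of 1000 umol -> 21.6 mol m-2 d-1
  tt <- seq(0, 1, by = 1 / 2880)
  pulse <- as_forcing_series(data.frame(
    time_days = tt, par = ifelse(tt >= 0.375 & tt < 0.625, 1000, 0),
    temp = 26, din = 1, dip = 1))
  expect_equal(daily_light_integral(pulse, 0), 21.6, tolerance = 0.01)
  expect_error(daily_light_integral(const_forcing(0.5, par = 10), 0),
               "full day")
})

test_that("DHW implements the gated 12-week accumulation", {
  # constant 2 degC anomaly for 7 days -> 2 degC-weeks
  fs <- const_forcing(days = 7, temp = 30.6)
  d <- compute_dhw(fs, mmm = 28.6)
  expect_equal(d$dhw[nrow(d)], 2, tolerance = 1e-12)
  # at the MMM, and below the 1 degC gate, nothing accumulates
  expect_true(all(compute_dhw(const_forcing(7, temp = 28.6))$dhw == 0))
  expect_true(all(compute_dhw(const_forcing(7, temp = 29.5))$dhw == 0))
  # non-decreasing in time for a non-decreasing temperature series
  heat <- generate_forcing(scenario_spec("heat", "unshaded", seed = 2))
  dh <- compute_dhw(heat)
  expect_true(all(diff(dh$dhw) >= 0))
  # zero before the first day whose daily mean anomaly reaches 1 degC,
  # strictly positive afterwards (nominal ramp: day 7 mean is 29.7 degC)
  expect_equal(dh$dhw[dh$time_days == 7], 0)
  expect_gt(dh$dhw[dh$time_days == 8.5], 0)
  expect_error(compute_dhw(heat[0, ]), "empty")
})

test_that("forcing files round-trip at full precision in both dialects", {
  fs <- generate_forcing(scenario_spec("ambient", "shaded", days = 3, seed = 11))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".tsv")
  write_forcing(fs, f1)
  write_forcing(fs, f2, delim = "\t")
  r1 <- read_forcing(f1); r2 <- read_forcing(f2)
  for (cl in c("time_days", "par", "temp", "din", "dip")) {
    expect_identical(r1[[cl]], fs[[cl]])
    expect_identical(r2[[cl]], fs[[cl]])
  }
  # missing required column is named in the error
  tab <- utils::read.csv(f1)
  tab$temp_C <- NULL
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(tab, f3, row.names = FALSE)
  expect_error(read_forcing(f3), "temp_C")
})

test_that("interpolation is linear for par/temp and stepwise for nutrients", {
  fs <- as_forcing_series(data.frame(
    time_days = c(0, 1, 2), par = c(0, 200, 100), temp = c(26, 28, 27),
    din = c(3, 5, 4), dip = c(0.5, 0.7, 0.6)))
  at <- interpolate_forcing(fs, c(0, 0.5, 1.5))
  expect_equal(at$par, c(0, 100, 150))
  expect_equal(at$temp, c(26, 27, 27.5))
  expect_equal(at$din, c(3, 3, 5))   # previous-value plateaus
  expect_equal(at$dip, c(0.5, 0.5, 0.7))
  expect_error(interpolate_forcing(fs, 2.5), "extrapolation")
})

test_that("forcing invariants are enforced on construction", {
  bad <- data.frame(time_days = c(0, 0), par = 0, temp = 26, din = 1, dip = 1)
  expect_error(as_forcing_series(bad), "strictly increasing")
  bad2 <- data.frame(time_days = 0:1, par = c(-1, 0), temp = 26,
                     din = 1, dip = 1)
  expect_error(as_forcing_series(bad2), "par")
})
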