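p0 <- cbm_params()

test_that("the reference initial state matches the published configuration", {
  st <- initial_state(p0)
  expect_equal(st[["chl"]], 5.6786 / 30)           # 0.18929 mg m-2
  expect_equal(st[["r_c"]], (106 / 16) * (12.01 / 14.01) * 0.5)  # 2.8395
  expect_equal(st[["r_n"]], 0.5)
  expect_equal(st[["x_p"]] + st[["x_h"]], st[["chl"]] * 0.2448)
  # per-cell ROS starts at half the bleaching threshold
  expect_equal(st[["ros"]] / cell_density(st[["cs"]], p0),
               p0$photo$ros_threshold / 2)
})

test_that("night derivative: no ROS generation, positive repair", {
  fs <- const_forcing(days = 1, par = 0, temp = 26.4)
  st <- initial_state(p0)
  d <- polyp_derivative(st, 0.05, fs, p0)
  dg <- attr(d, "diag")
  expect_equal(dg[["gen"]], 0)
  expect_lt(d[["q_in"]], 0)       # repair drains the inhibited pool
  expect_gt(d[["q_ox"]], 0)
  expect_equal(attr(d, "budget")[["k_i"]], 0)
})

test_that("above a 2 degC anomaly no photons reach fixation", {
  fs <- const_forcing(days = 1, par = 800, temp = 31.0)  # dT = 2.4
  st <- initial_state(p0)
  d <- polyp_derivative(st, 0.5, fs, p0)
  expect_equal(attr(d, "budget")[["to_fixation"]], 0)
  expect_equal(attr(d, "diag")[["activity"]], 0)
  expect_gt(attr(d, "diag")[["gen"]], 0)
})

test_that("invalid states are rejected with the offending pool named", {
  fs <- const_forcing(days = 1)
  st <- initial_state(p0)
  st[["r_c"]] <- -1
  expect_error(polyp_derivative(st, 0.1, fs, p0), "r_c")
  st2 <- initial_state(p0); st2[["chl"]] <- NaN
  expect_error(polyp_derivative(st2, 0.1, fs, p0), "chl")
})

test_that("dark relaxation reproduces the repair and detox closed forms", {
  # frozen population (packing cap), darkness, no nutrients: the inhibited
  # pool decays exponentially at 268*m_RCII and per-cell ROS relaxes at the
  # reserve-weighted growth rate
  p <- frozen_cell_params(uptake_n = 0, uptake_p = 0)
  fs <- const_forcing(days = 0.02, par = 0, temp = 26.4, din = 0, dip = 0)
  st <- initial_state(p)
  st[["ros"]] <- 2 * st[["ros"]]   # start per-cell ROS at the threshold
  tr <- run_cbm(fs, p, init = st, out_dt = 1 / 1440)
  tau <- 268 * p$photo$m_RCII
  expect_rel_equal(tr$q_in[nrow(tr)],
                   st[["q_in"]] * exp(-tau * 0.02), 1e-3)
  # conservation: the repaired centres arrive in the oxidised pool
  expect_rel_equal(tr$q_ox[nrow(tr)] + tr$q_red[nrow(tr)] + tr$q_in[nrow(tr)],
                   st[["q_ox"]] + st[["q_red"]] + st[["q_in"]], 1e-9)
})

test_that("legacy detox relaxes ROS toward zero; revised floors at theta/2", {
  # frozen population in darkness: no generation, reserves pinned at 0.5, so
  # the reserve-weighted rate is mu_eff = mu_max / 8 and both laws have
  # exact closed forms: legacy x(t) = theta exp(-mu_eff t); revised
  # x(t) = theta/2 (1 + exp(-mu_eff t)), asymptoting to the half-threshold
  th <- p0$photo$ros_threshold
  fs <- const_forcing(days = 6, par = 0, temp = 26.4, din = 0, dip = 0)
  mk <- function(...) frozen_cell_params(uptake_n = 0, uptake_p = 0,
                                         mu_max = 2, ...)
  st <- initial_state(mk())
  st[["ros"]] <- 2 * st[["ros"]]   # start per-cell ROS at the threshold
  mu_eff <- 2 * 0.5^3
  leg <- run_cbm(fs, mk(legacy_detox = TRUE), init = st)
  rev <- run_cbm(fs, mk(), init = st)
  expect_rel_equal(leg$ros_percell[nrow(leg)], th * exp(-mu_eff * 6), 2e-3)
  expect_rel_equal(rev$ros_percell[nrow(rev)],
                   (th / 2) * (1 + exp(-mu_eff * 6)), 2e-3)
  # mid-trajectory closed forms hold too
  i <- which.min(abs(rev$time_days - 2))
  expect_rel_equal(rev$ros_percell[i],
                   (th / 2) * (1 + exp(-mu_eff * rev$time_days[i])), 2e-3)
  # legacy passes below the half-threshold; revised never does
  expect_lt(min(leg$ros_percell), th / 2)
  expect_true(all(rev$ros_percell >= th / 2 * (1 - 1e-12)))
  expect_true(all(diff(rev$ros_percell) <= 1e-20))  # monotone decay
})

test_that("with replete reserves growth is exponential at mu_max", {
  # saturating uptake and fixation hold all reserves at their maxima
  p <- cbm_params(uptake_n = 1e-6, uptake_p = 1e-6, fix_yield = 5e4)
  fs <- const_forcing(days = 2, par = 300, temp = 26.4)
  st <- initial_state(p)
  st[["r_n"]] <- st[["cs"]]
  st[["r_c"]] <- st[["cs"]] * p$symbiont$redfield_c
  st[["r_p"]] <- st[["cs"]] * p$symbiont$redfield_p
  tr <- run_cbm(fs, p, init = st)
  expect_rel_equal(tr$cs[nrow(tr)], exp(p$symbiont$mu_max * 2), 5e-3)
})

test_that("integration is deterministic and consistent under step halving", {
  spec <- scenario_spec("heat", "unshaded", days = 5, seed = 4,
                        ramp_days = 3, hold_days = 2)
  fs <- generate_forcing(spec)
  a <- run_cbm(fs, p0)
  b <- run_cbm(fs, p0)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- run_cbm(fs, p0, dt_max = 0.5 / 1440)
  final_a <- as.numeric(a[nrow(a), coralbleach:::.state_names])
  final_c <- as.numeric(c_[nrow(c_), coralbleach:::.state_names])
  expect_lt(max(abs(final_a - final_c) / pmax(abs(final_c), 1e-30)), 1e-3)
})

test_that("trajectories respect positivity and reserve bounds throughout", {
  for (nm in c("ambient_unshaded", "heat_unshaded")) {
    tr <- run_cbm(preset(nm, seed = 2)$spec, p0)
    sts <- as.data.frame(tr)
    expect_true(all(sts[coralbleach:::.state_names] >= 0))
    expect_true(all(sts$r_n <= sts$cs * (1 + 1e-9)))
    expect_true(all(sts$r_c <= sts$cs * p0$symbiont$redfield_c * (1 + 1e-9)))
    expect_true(all(sts$r_p <= sts$cs * p0$symbiont$redfield_p * (1 + 1e-9)))
    qsum <- sts$q_ox_frac + sts$q_red_frac + sts$q_in_frac
    expect_true(all(abs(qsum - 1) < 1e-9))
  }
})

test_that("diel photochemistry: inhibition peaks near noon, oxidised pre-dawn", {
  tr <- run_cbm(preset("ambient_unshaded", seed = 1)$spec, p0)
  day5 <- tr[tr$time_days >= 5 & tr$time_days < 6, ]
  hr <- (day5$time_days %% 1) * 24
  expect_lt(abs(hr[which.max(day5$q_in_frac)] - 12), 2)
  expect_gt(max(day5$q_in_frac), 0.5)
  # oxidised fraction is maximal during the night hours
  night_ox <- max(day5$q_ox_frac[hr < 6 | hr > 20])
  expect_gt(night_ox, 0.99 * max(day5$q_ox_frac))
})

test_that("spin-up reaches a stable sub-threshold state", {
  st <- spin_up(p0, seed = 1)
  expect_lt(st[["ros"]] / cell_density(st[["cs"]], p0),
            p0$photo$ros_threshold)
  expect_identical(st, spin_up(p0, seed = 1))
  expect_true(all(st >= 0))
})

test_that("bleaching onset detection and interpolation", {
  tr <- run_cbm(preset("ambient_unshaded", seed = 1)$spec, p0)
  expect_true(is.na(bleaching_onset(tr)))
  # synthetic trajectory crossing between samples
  th <- p0$photo$ros_threshold
  fake <- data.frame(time_days = c(0, 1, 2),
                     ros_percell = c(0.5, 1.5, 2) * th)
  class(fake) <- c("cbm_trajectory", "data.frame")
  attr(fake, "params") <- p0
  expect_equal(bleaching_onset(fake), 0.5)
  fake$ros_percell <- rep(2 * th, 3)   # above threshold from the start
  expect_equal(bleaching_onset(fake), 0)
})

test_that("summary fold-changes use interpolated windows", {
  tr <- run_cbm(preset("ambient_unshaded", seed = 1)$spec, p0)
  expect_equal(biomass_fold(tr, 3, 3), 1)
  s <- summary(tr)
  expect_equal(s$biomass_fold,
               tr$cs[nrow(tr)] / tr$cs[1], tolerance = 1e-9)
  expect_true(is.na(s$onset_day))
  expect_output(print(s), "bleaching onset: none")
})

test_that("shade and temperature monotonicity of oxidative stress", {
  pk <- function(nm) max(run_cbm(preset(nm, seed = 3)$spec, p0)$ros_percell)
  on <- function(nm) {
    o <- bleaching_onset(run_cbm(preset(nm, seed = 3)$spec, p0))
    if (is.na(o)) Inf else o
  }
  expect_lte(pk("ambient_shaded"), pk("ambient_unshaded"))
  expect_lte(pk("heat_shaded"), pk("heat_unshaded"))
  expect_lte(pk("ambient_unshaded"), pk("heat_unshaded"))
  expect_gte(on("heat_shaded"), on("heat_unshaded"))
  expect_gte(on("ambient_unshaded"), on("heat_unshaded"))
})

test_that("expulsion occurs exactly when per-cell ROS exceeds the threshold", {
  for (nm in c("ambient_unshaded", "heat_unshaded")) {
    tr <- run_cbm(preset(nm, seed = 1)$spec, p0)
    th <- p0$photo$ros_threshold
    expect_true(all((tr$expulsion > 0) == (tr$ros_percell > th)))
  }
})
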