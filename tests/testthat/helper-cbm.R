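# shared fixtures: small forcing series built in code

# constant-driver forcing on a regular grid
const_forcing <- function(days = 2, par = 0, temp = 26.4, din = 3.35,
                          dip = 0.58, dt = 5 / 1440) {
  tt <- seq(0, days, by = dt)
  as_forcing_series(data.frame(
    time_days = tt, par = rep(par, length(tt)), temp = rep(temp, length(tt)),
    din = rep(din, length(tt)), dip = rep(dip, length(tt))))
}

# parameters that freeze the population (projected area beyond the packing
# cap stops growth, pigment synthesis off) while leaving photophysiology and
# detoxification intact -- used for closed-form relaxation tests
frozen_cell_params <- function(...) {
  # layers >> area_cap => growth cap factor 0
  cbm_params(cell_radius = 1, chl_synth_rate = 1e-12, ...)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), .Machine$double.eps), tol)
}
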