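# Assembly of the full model: initial state, instantaneous derivative,
# fixed-step operator-split integration, bleaching-onset detection and
# trajectory summaries.

.state_names <- c("cs", "r_n", "r_c", "r_p", "chl", "x_p", "x_h",
                  "q_ox", "q_red", "q_in", "ros")

#' Reference initial state
#'
#' The healthy starting state of the single-polyp configuration: structural
#' biomass 1 mg N m^-2 with all reserves at half their structural-equivalent
#' maxima, chlorophyll a at CS*5.6786/30, xanthophylls at the 0.2448
#' total-xanthophyll:Chl ratio split 33% photosynthetic / 67%
#' photoprotective, reaction-centre pools from a pre-experimental spin-up,
#' and per-cell ROS at half the bleaching threshold.
#'
#' @param params a [cbm_params()].
#' @return named numeric state vector (areal units; `ros` is the areal pool,
#'   mg O m^-2).
#' @export
initial_state <- function(params = cbm_params()) {
  sy <- params$symbiont
  cs <- 1
  chl <- cs * 5.6786 / 30
  c(cs = cs,
    r_n = cs * 0.5,
    r_c = cs * sy$redfield_c * 0.5,
    r_p = cs * sy$redfield_p * 0.5,
    chl = chl,
    x_p = chl * sy$xanth_to_chl * 0.33,
    x_h = chl * sy$xanth_to_chl * 0.67,
    q_ox = 1.0607e-7,
    q_red = 7.1695e-9,
    q_in = 1.0108e-7,
    ros = (params$photo$ros_threshold * 0.5) * (cs / sy$m_n))
}

#' Instantaneous state derivative
#'
#' Assembles, per pool, the fluxes from photon absorption and partitioning,
#' reaction-centre transitions and repair, ROS generation and
#' detoxification, reserve-limited growth, nutrient uptake, carbon fixation,
#' pigment synthesis, xanthophyll switching and expulsion, evaluated at time
#' `t` under the given forcing. Intended for inspection and testing; the
#' integrator in [run_cbm()] advances the stiff reaction-centre subsystem by
#' its exact linear solution instead of a raw Euler step on this derivative.
#'
#' @param state named state vector (see [initial_state()]).
#' @param t time, days.
#' @param forcing a `forcing_series` covering `t`.
#' @param params a [cbm_params()].
#' @return named derivative vector, with the photon budget and diagnostic
#'   rates attached as attributes (`budget`, `diag`).
#' @export
polyp_derivative <- function(state, t, forcing, params = cbm_params()) {
  if (any(!is.finite(state)))
    stop("non-finite state entries: ",
         paste(names(state)[!is.finite(state)], collapse = ", "))
  if (any(state < 0))
    stop("negative pools: ",
         paste(names(state)[state < 0], collapse = ", "))
  f <- interpolate_forcing(forcing, t)
  s <- as.list(state)
  ph <- params$photo; sy <- params$symbiont
  cells <- cell_density(s$cs, params)
  abs_ <- photon_absorption(f$par, s$chl, s$x_p, s$x_h, params)
  act <- rubisco_activity(f$temp - ph$mmm)
  rn <- normalised_reserves(state, params)
  part <- partition_photons(abs_, s, act, rn[["r_c"]])
  trans <- rc_transition_rates(part, params)
  repair <- rc_repair_rate(s$q_in, params, f$temp)
  gen <- ros_generation_rate(abs_, s, params)
  ros_pc <- s$ros / cells
  detox <- if (params$simulator$legacy_detox)
    ros_detox_rate_legacy(ros_pc, rn, sy$mu_max) * cells
  else
    ros_detox_rate(ros_pc, rn, sy$mu_max, cells, params)
  layers <- projected_area_layers(s$cs, params)
  mu <- growth_rate(rn, params, area_cap_factor(layers, params))
  gro <- growth_fluxes(s, mu, params)
  up <- nutrient_uptake(s, f$din * .mw_n, f$dip * .mw_p, params)
  fix <- carbon_fixation_flux(part$to_fixation, s, params)
  od <- min(ph$chl_absorb * s$chl + ph$xp_absorb * s$x_p, ph$od_max)
  pig <- pigment_synthesis(s$cs, rn[["r_c"]], part$q_in_frac, od, params)
  xs <- xanthophyll_switch(s$x_p, s$x_h, part$q_in_frac, params)
  e <- expulsion_rate(ros_pc, params)
  d <- c(
    cs = gro$dcs - e * s$cs,
    r_n = gro$dr_n + up$dr_n - e * s$r_n,
    r_c = gro$dr_c + fix - e * s$r_c,
    r_p = gro$dr_p + up$dr_p - e * s$r_p,
    chl = pig$dchl - e * s$chl,
    x_p = pig$dx_p + xs$dx_p - e * s$x_p,
    x_h = xs$dx_h - e * s$x_h,
    q_ox = trans$dq_ox + repair + pig$dq_ox - e * s$q_ox,
    q_red = trans$dq_red - e * s$q_red,
    q_in = trans$dq_in - repair - e * s$q_in,
    ros = gen - detox - e * s$ros
  )
  if (any(!is.finite(d)))
    stop("non-finite derivative for: ",
         paste(.state_names[!is.finite(d)], collapse = ", "))
  attr(d, "budget") <- c(k_i = abs_$k_i, to_heat = abs_$to_heat,
                         to_fixation = part$to_fixation,
                         to_reduction = part$to_reduction,
                         to_inhibition = part$to_inhibition,
                         to_ros = part$to_ros)
  attr(d, "diag") <- c(activity = act, mu = mu, expulsion = e,
                       ros_percell = ros_pc, gen = gen, detox = detox)
  d
}

#' Run the coral bleaching model
#'
#' Integrates the single-polyp model over a scenario. The integrator is a
#' fixed-step operator-split scheme: within each step the reaction-centre
#' state fractions are advanced by the exact solution of their linear
#' kinetics (their timescales are seconds under daylight, far below the
#' step), photon-driven fluxes use the exact step-mean fractions, and the
#' slow pools take a donor-limited Euler step in which no pool can cross
#' zero. Expulsion removes the same fraction from all areal pools.
#'
#' @param x a [scenario_spec()] (forcing generated internally) or a
#'   `forcing_series`.
#' @param params a [cbm_params()].
#' @param dt_max maximum step, days (default from params; 1 min).
#' @param out_dt output cadence, days (default 15 min).
#' @param init initial state (default [initial_state()]).
#' @param days integration span (default: forcing span).
#' @return A `cbm_trajectory`: a data.frame with one row per output time
#'   holding the eleven state variables, diagnostics (per-cell ROS, RuBisCO
#'   activity, growth and expulsion rates, reaction-centre fractions,
#'   normalised reserves, DHW) and the forcing, with the scenario, parameter
#'   snapshot and flux-limiting event counts attached as attributes.
#' @export
run_cbm <- function(x, params = cbm_params(),
                    dt_max = params$simulator$dt_max,
                    out_dt = params$simulator$out_dt,
                    init = initial_state(params),
                    days = NULL) {
  validate_params(params)
  spec <- NULL
  if (inherits(x, "scenario_spec")) {
    spec <- x
    forcing <- generate_forcing(spec)
  } else if (inherits(x, "forcing_series")) {
    forcing <- x
  } else stop("x must be a scenario_spec or forcing_series")
  t_begin <- min(forcing$time_days)
  if (is.null(days)) days <- max(forcing$time_days) - t_begin
  if (days <= 0) stop("non-positive integration span")

  nsteps <- ceiling(days / dt_max - 1e-9)
  dt <- days / nsteps
  k_out <- max(1L, round(out_dt / dt))

  ph <- params$photo; sy <- params$symbiont
  mrcii <- ph$m_RCII; mp2r <- ph$m_P2R; th <- ph$ros_threshold
  th2 <- th / 2
  gam0 <- ph$repair_const * mrcii
  tfun <- ph$repair_temp_factor
  legacy <- params$simulator$legacy_detox
  redc <- sy$redfield_c; redp <- sy$redfield_p
  m_n <- sy$m_n; mumax <- sy$mu_max
  areac <- pi * sy$cell_radius^2

  tgrid <- t_begin + (0:nsteps) * dt
  ff <- interpolate_forcing(forcing, tgrid[-length(tgrid)])
  parv <- ff$par; tempv <- ff$temp
  dinv <- ff$din * .mw_n; dipv <- ff$dip * .mw_p

  s <- as.numeric(init[.state_names])
  names(s) <- .state_names
  cs <- s[["cs"]]; r_n <- s[["r_n"]]; r_c <- s[["r_c"]]; r_p <- s[["r_p"]]
  chl <- s[["chl"]]; x_p <- s[["x_p"]]; x_h <- s[["x_h"]]
  q_ox <- s[["q_ox"]]; q_red <- s[["q_red"]]; q_in <- s[["q_in"]]
  ros <- s[["ros"]]

  out_idx <- seq(0L, nsteps, by = k_out)
  if (out_idx[length(out_idx)] != nsteps) out_idx <- c(out_idx, nsteps)
  nout <- length(out_idx)
  rec <- matrix(NA_real_, nout, 22)
  colnames(rec) <- c(.state_names, "ros_percell", "activity", "mu",
                     "expulsion", "q_ox_frac", "q_red_frac", "q_in_frac",
                     "rn_norm", "rc_norm", "rp_norm", "par")
  rec_t <- tgrid[out_idx + 1L]
  growth_limited <- 0L
  record_row <- function(irow, act, mu, e, par_now) {
    qt <- q_ox + q_red + q_in
    cells <- cs / m_n
    rec[irow, ] <<- c(cs, r_n, r_c, r_p, chl, x_p, x_h, q_ox, q_red, q_in,
                      ros, ros / cells, act, mu, e,
                      q_ox / qt, q_red / qt, q_in / qt,
                      min(r_n / cs, 1), min(r_c / (cs * redc), 1),
                      min(r_p / (cs * redp), 1), par_now)
  }
  # initial row diagnostics
  {
    rn0 <- min(r_n / cs, 1); rc0 <- min(r_c / (cs * redc), 1)
    rp0 <- min(r_p / (cs * redp), 1)
    act0 <- rubisco_activity(tempv[1] - ph$mmm)
    mu0 <- mumax * rn0 * rc0 * rp0 *
      max(0, 1 - ((cs / m_n) * areac / sy$area_cap)^4)
    e0 <- expulsion_rate(ros / (cs / m_n), params)
    record_row(1L, act0, mu0, e0, parv[1])
  }
  next_out <- 2L

  for (i in seq_len(nsteps)) {
    par_now <- parv[i]; temp_now <- tempv[i]
    cells <- cs / m_n
    e_d <- par_now * .par_to_daily
    od <- min(ph$chl_absorb * chl + ph$xp_absorb * x_p, ph$od_max)
    k_i <- e_d * (1 - exp(-od))
    dtt <- temp_now - ph$mmm
    act <- min(max((1 - exp(-(2 - dtt))) / (1 - exp(-2)), 0), 1)
    rn <- min(r_n / cs, 1); rc <- min(r_c / (cs * redc), 1)
    rp <- min(r_p / (cs * redp), 1)
    qt <- q_ox + q_red + q_in
    f <- act * (1 - rc)
    base <- k_i / (mrcii * qt)
    gam <- if (is.null(tfun)) gam0 else gam0 * tfun(temp_now)
    adv <- rc_advance(c(q_ox, q_red, q_in) / qt,
                      base * (1 - f), base, gam, dt)
    q_ox <- adv$p[1] * qt; q_red <- adv$p[2] * qt; q_in <- adv$p[3] * qt
    pbar <- adv$pbar
    # carbon fixation (capped at the structural-equivalent maximum)
    to_fix <- k_i * pbar[1] * f
    add_c <- min(ph$fix_yield * to_fix * dt, max(cs * redc - r_c, 0))
    r_c <- r_c + add_c
    # ROS generation and detoxification
    gen <- k_i * pbar[3] / mrcii / mp2r
    ros_pc <- ros / cells
    gfac <- mumax * rn * rc * rp
    if (legacy) {
      rem <- min(gfac * ros_pc * cells * dt, ros)
    } else {
      detox <- gfac * min(max(ros_pc - th2, 0), th2) * cells
      rem <- min(detox * dt, max(ros - th2 * cells, 0))
    }
    ros <- ros + gen * dt - rem
    # growth (donor-limited so no reserve crosses zero)
    capf <- max(0, 1 - (cells * areac / sy$area_cap)^4)
    mu <- gfac * capf
    mu_dt <- mu * dt
    lim <- min(r_n / cs, r_c / (cs * redc), r_p / (cs * redp))
    if (mu_dt > lim) { mu_dt <- lim; growth_limited <- growth_limited + 1L }
    r_n <- r_n - mu_dt * cs
    r_c <- r_c - mu_dt * cs * redc
    r_p <- r_p - mu_dt * cs * redp
    cs <- cs * (1 + mu_dt)
    cells <- cs / m_n
    # nutrient uptake, saturating at the reserve maxima
    r_n <- min(r_n + sy$uptake_n * dinv[i] * cells * (1 - rn) * dt, cs)
    r_p <- min(r_p + sy$uptake_p * dipv[i] * cells * (1 - rp) * dt, cs * redp)
    # pigment synthesis (Chl, coupled diadinoxanthin and reaction centres)
    dchl <- sy$chl_synth_rate * cs * rc * (1 - rc) * (1 - pbar[3]) *
      exp(-od) * dt
    chl <- chl + dchl
    x_p <- x_p + sy$xanth_to_chl * dchl
    q_ox <- q_ox + sy$qt_chl_ratio * dchl
    # xanthophyll switching (exact exponential transfer over the step)
    if (pbar[3] > 0.5) {
      tr <- x_p * (1 - exp(-ph$xanth_switch_rate * dt))
      x_p <- x_p - tr; x_h <- x_h + tr
    } else {
      tr <- x_h * (1 - exp(-ph$xanth_switch_rate * dt))
      x_h <- x_h - tr; x_p <- x_p + tr
    }
    # expulsion: proportional loss of every areal pool
    ros_pc <- ros / cells
    e <- if (ros_pc > th) sy$expulsion_gain * mumax * (ros_pc - th) / th else 0
    if (e > 0) {
      fac <- max(1 - e * dt, 0)
      cs <- cs * fac; r_n <- r_n * fac; r_c <- r_c * fac; r_p <- r_p * fac
      chl <- chl * fac; x_p <- x_p * fac; x_h <- x_h * fac
      q_ox <- q_ox * fac; q_red <- q_red * fac; q_in <- q_in * fac
      ros <- ros * fac
    }
    if (next_out <= nout && i == out_idx[next_out]) {
      record_row(next_out, act, mu, e, par_now)
      next_out <- next_out + 1L
    }
  }

  out <- data.frame(time_days = rec_t, rec)
  fout <- interpolate_forcing(forcing, rec_t)
  out$temp <- fout$temp; out$din <- fout$din; out$dip <- fout$dip
  dhw <- compute_dhw(forcing, mmm = ph$mmm)
  out$dhw <- stats::approx(dhw$time_days, dhw$dhw, rec_t, rule = 2)$y
  class(out) <- c("cbm_trajectory", "data.frame")
  attr(out, "spec") <- spec
  attr(out, "params") <- params
  attr(out, "events") <- list(growth_reserve_limited_steps = growth_limited)
  attr(out, "dt") <- dt
  out
}

#' Pre-experimental spin-up
#'
#' Runs the model from the reference initial state under ambient forcing for
#' a few days and returns the end state, refreshing the photochemical pools
#' to a stable starting configuration (the photochemistry adjusts within
#' about two days).
#'
#' @param params a [cbm_params()].
#' @param forcing ambient `forcing_series`; by default three days of the
#'   ambient unshaded scenario are generated with `seed`.
#' @param days spin-up length, days.
#' @param seed seed for the default forcing.
#' @return named state vector at the end of the spin-up.
#' @export
spin_up <- function(params = cbm_params(), forcing = NULL,
                    days = params$simulator$spinup_days, seed = 1L) {
  if (is.null(forcing)) {
    spec <- scenario_spec("ambient", "unshaded", days = days, seed = seed)
    forcing <- generate_forcing(spec)
  }
  traj <- run_cbm(forcing, params, days = days)
  last <- as.numeric(traj[nrow(traj), .state_names])
  names(last) <- .state_names
  last
}

#' Bleaching onset time
#'
#' The first time the per-cell ROS concentration strictly exceeds the
#' bleaching threshold, linearly interpolated between trajectory samples;
#' `NA` if the threshold is never exceeded.
#'
#' @param traj a `cbm_trajectory`.
#' @return onset time in days, or `NA_real_`.
#' @export
bleaching_onset <- function(traj) {
  stopifnot(inherits(traj, "cbm_trajectory"))
  th <- attr(traj, "params")$photo$ros_threshold
  x <- traj$ros_percell
  idx <- which(x > th)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  if (i == 1) return(traj$time_days[1])
  t0 <- traj$time_days[i - 1]; t1 <- traj$time_days[i]
  y0 <- x[i - 1]; y1 <- x[i]
  t0 + (th - y0) / (y1 - y0) * (t1 - t0)
}

#' Fold-change in symbiont biomass over a window
#'
#' @param traj a `cbm_trajectory`.
#' @param from,to window endpoints, days (values interpolated).
#' @return biomass(to) / biomass(from).
#' @export
biomass_fold <- function(traj, from = min(traj$time_days),
                         to = max(traj$time_days)) {
  if (to == from) return(1)
  b <- stats::approx(traj$time_days, traj$cs, c(from, to), rule = 2)$y
  b[2] / b[1]
}

#' @export
summary.cbm_trajectory <- function(object, ...) {
  p <- attr(object, "params")
  spec <- attr(object, "spec")
  th <- p$photo$ros_threshold
  tmax <- max(object$time_days)
  pk <- which.max(object$ros_percell)
  out <- list(
    scenario = if (!is.null(spec))
      paste(spec$temperature_treatment, spec$shade_treatment) else "custom forcing",
    days = tmax,
    onset_day = bleaching_onset(object),
    biomass_fold = biomass_fold(object),
    biomass_fold_1_to_14.5 = if (tmax >= 14.5)
      biomass_fold(object, 1, 14.5) else NA_real_,
    chl_fold = object$chl[nrow(object)] / object$chl[1],
    peak_ros_percell = object$ros_percell[pk],
    peak_ros_day = object$time_days[pk],
    final_ros_percell = object$ros_percell[nrow(object)],
    ros_threshold = th,
    max_expulsion = max(object$expulsion),
    min_activity = min(object$activity),
    mean_q_frac = c(ox = mean(object$q_ox_frac),
                    red = mean(object$q_red_frac),
                    inh = mean(object$q_in_frac)),
    final_dhw = object$dhw[nrow(object)]
  )
  class(out) <- "cbm_summary"
  out
}

#' @export
print.cbm_summary <- function(x, ...) {
  cat(sprintf("<cbm_summary> %s, %.1f d\n", x$scenario, x$days))
  cat(sprintf("  bleaching onset: %s\n",
              if (is.na(x$onset_day)) "none" else sprintf("day %.2f", x$onset_day)))
  cat(sprintf("  biomass fold (full run): %.2f", x$biomass_fold))
  if (!is.na(x$biomass_fold_1_to_14.5))
    cat(sprintf("   (day 1 -> 14.5: %.2f)", x$biomass_fold_1_to_14.5))
  cat("\n")
  cat(sprintf("  chlorophyll a fold: %.2f\n", x$chl_fold))
  cat(sprintf("  per-cell ROS: peak %.3g (day %.1f), final %.3g, threshold %.3g mg O cell-1\n",
              x$peak_ros_percell, x$peak_ros_day, x$final_ros_percell,
              x$ros_threshold))
  cat(sprintf("  max expulsion rate: %.3g d-1 | min RuBisCO activity: %.2f\n",
              x$max_expulsion, x$min_activity))
  cat(sprintf("  mean RC fractions ox/red/in: %.2f/%.2f/%.2f | final DHW: %.2f\n",
              x$mean_q_frac[1], x$mean_q_frac[2], x$mean_q_frac[3],
              x$final_dhw))
  invisible(x)
}

#' @export
print.cbm_trajectory <- function(x, ...) {
  cat(sprintf("<cbm_trajectory> %d samples over %.2f d (dt %.3g min)\n",
              nrow(x), diff(range(x$time_days)), attr(x, "dt") * 1440))
  print(summary(x))
  invisible(x)
}
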