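# Photon/energy pathway of the symbiont photosystem: absorption, partitioning
# across reaction-centre states, RuBisCO thermal inactivation, repair,
# xanthophyll cycling, and ROS generation/detoxification kinetics.

#' Temperature-dependent RuBisCO activity
#'
#' Empirical inactivation of RuBisCO-mediated carbon fixation by thermal
#' anomaly relative to the climatological maximum monthly mean:
#' \deqn{a^* = \frac{1 - e^{-(2 - \Delta T)}}{1 - e^{-2}}}
#' clamped to 1 for anomalies at or below 0 degC and to 0 at or above 2 degC.
#' At the 1 degC NOAA bleaching-index threshold the activity is 0.73.
#'
#' @param delta_t temperature anomaly (forcing temperature minus MMM), degC;
#'   vectorised.
#' @return activity in \[0, 1\].
#' @export
#' @examples
#' rubisco_activity(c(-1, 0, 1, 2))
rubisco_activity <- function(delta_t) {
  a <- (1 - exp(-(2 - delta_t))) / (1 - exp(-2))
  pmin(pmax(a, 0), 1)
}

#' Photon absorption by the pigment bed
#'
#' Converts downwelling PAR to a daily photon flux and partitions it by
#' Beer-Lambert self-shading: the photochemical pigments (chlorophyll a and
#' diadinoxanthin) absorb `k_i`, and diatoxanthin intercepts a fraction of the
#' transmitted light as the non-photochemical heat sink. The optical depth
#' argument is capped (`od_max`) so self-shading saturates as the symbiont
#' layer closes.
#'
#' @param par downwelling PAR, umol photon m^-2 s^-1.
#' @param chl,x_p,x_h chlorophyll a, diadinoxanthin and diatoxanthin areal
#'   concentrations, mg m^-2.
#' @param params a [cbm_params()].
#' @return list with `k_i` (photochemical absorption) and `to_heat`
#'   (photoprotective interception), both mol photon m^-2 d^-1, plus the
#'   incident daily flux `e_d`.
#' @export
photon_absorption <- function(par, chl, x_p, x_h, params = cbm_params()) {
  if (any(c(chl, x_p, x_h) < 0)) stop("pigment concentrations must be >= 0")
  if (any(par < 0)) stop("par must be >= 0")
  ph <- params$photo
  e_d <- par * .par_to_daily
  od <- pmin(ph$chl_absorb * chl + ph$xp_absorb * x_p, ph$od_max)
  k_i <- e_d * (1 - exp(-od))
  to_heat <- e_d * exp(-od) * (1 - exp(-ph$xh_absorb * x_h))
  list(k_i = k_i, to_heat = to_heat, e_d = e_d)
}

#' Partition absorbed photons across reaction-centre states
#'
#' Photons land on oxidised, reduced and inhibited reaction centres in
#' proportion to the state fractions. Photons on oxidised centres drive carbon
#' fixation with probability `activity * (1 - r_c_norm)` (active RuBisCO and
#' unfilled carbon reserve) and otherwise reduce the centre; photons on
#' reduced centres inhibit it; photons on inhibited centres generate ROS.
#' The four sinks sum to `k_i` exactly.
#'
#' @param budget list with `k_i` (from [photon_absorption()]).
#' @param rc list or vector with `q_ox`, `q_red`, `q_in` (mg m^-2).
#' @param activity RuBisCO activity in \[0, 1\].
#' @param r_c_norm normalised carbon reserve in \[0, 1\].
#' @return list with `to_fixation`, `to_reduction`, `to_inhibition`, `to_ros`
#'   (mol photon m^-2 d^-1) and the state fractions used.
#' @export
partition_photons <- function(budget, rc, activity, r_c_norm) {
  q <- unlist(rc[c("q_ox", "q_red", "q_in")], use.names = FALSE)
  if (any(q < 0)) stop("reaction-centre pools must be >= 0")
  qt <- sum(q)
  if (qt <= 0) stop("no reaction centres (q_t = 0)")
  frac <- q / qt
  f <- activity * (1 - r_c_norm)
  on_ox <- budget$k_i * frac[1]
  list(
    to_fixation = on_ox * f,
    to_reduction = on_ox * (1 - f),
    to_inhibition = budget$k_i * frac[2],
    to_ros = budget$k_i * frac[3],
    q_ox_frac = frac[1], q_red_frac = frac[2], q_in_frac = frac[3]
  )
}

#' Photochemical reaction-centre transition rates
#'
#' Converts the photon fluxes routed to reduction and inhibition into pool
#' derivatives through the photon:reaction-centre stoichiometry `m_RCII`.
#' The three derivatives sum to zero (the total pool is conserved by state
#' transitions).
#'
#' @inheritParams partition_photons
#' @param partition output of [partition_photons()].
#' @param params a [cbm_params()].
#' @return list `dq_ox`, `dq_red`, `dq_in`, mg m^-2 d^-1.
#' @export
rc_transition_rates <- function(partition, params = cbm_params()) {
  m <- params$photo$m_RCII
  ox_to_red <- partition$to_reduction / m
  red_to_in <- partition$to_inhibition / m
  list(dq_ox = -ox_to_red, dq_red = ox_to_red - red_to_in, dq_in = red_to_in)
}

#' Reaction-centre repair rate
#'
#' First-order repair of inhibited centres back to the oxidised state at rate
#' `repair_const * m_RCII` per day; the flux leaves `q_in` and enters `q_ox`,
#' conserving the total pool. An optional multiplicative temperature factor
#' (`params$photo$repair_temp_factor`, a function of temperature) defaults to
#' the identity.
#'
#' @param q_in inhibited pool, mg m^-2.
#' @param params a [cbm_params()].
#' @param temp water temperature, degC (used only if a repair temperature
#'   factor is configured).
#' @return repair flux, mg m^-2 d^-1.
#' @export
rc_repair_rate <- function(q_in, params = cbm_params(), temp = NULL) {
  if (any(q_in < 0)) stop("q_in must be >= 0")
  fac <- 1
  f <- params$photo$repair_temp_factor
  if (!is.null(f) && !is.null(temp)) fac <- f(temp)
  params$photo$repair_const * params$photo$m_RCII * q_in * fac
}

#' ROS generation rate
#'
#' Photons absorbed by inhibited reaction centres generate ROS:
#' rate = (q_in / q_t) * k_i / m_RCII / m_P2R. All generated ROS enters the
#' areal ROS pool (no diffusion loss).
#'
#' @param budget list with `k_i` (mol photon m^-2 d^-1).
#' @param rc list/vector with `q_ox`, `q_red`, `q_in`.
#' @param params a [cbm_params()].
#' @return areal generation rate, mg O m^-2 d^-1.
#' @export
ros_generation_rate <- function(budget, rc, params = cbm_params()) {
  q <- unlist(rc[c("q_ox", "q_red", "q_in")], use.names = FALSE)
  qt <- sum(q)
  if (qt <= 0) stop("no reaction centres (q_t = 0)")
  (q[3] / qt) * budget$k_i / params$photo$m_RCII / params$photo$m_P2R
}

#' ROS detoxification rate (revised piecewise law)
#'
#' Detoxification is inactive below half the bleaching threshold, rises
#' linearly with the excess above the half-threshold between theta/2 and
#' theta, and saturates at `mu_max * r_n* * r_c* * r_p* * (theta/2)` per cell
#' above the threshold. It is continuous at both breakpoints and scaled by
#' cell density to an areal rate. Healthier (reserve-replete, faster-growing)
#' cells detoxify faster; detoxification can return the per-cell
#' concentration to theta/2 but never below it.
#'
#' @param ros_percell per-cell ROS concentration, mg O cell^-1.
#' @param reserves_norm numeric length-3 `(r_n*, r_c*, r_p*)` in \[0, 1\].
#' @param mu_max maximum symbiont growth rate, d^-1.
#' @param cell_density cells m^-2.
#' @param params a [cbm_params()].
#' @return areal detoxification rate, mg O m^-2 d^-1.
#' @export
ros_detox_rate <- function(ros_percell, reserves_norm, mu_max, cell_density,
                           params = cbm_params()) {
  th <- params$photo$ros_threshold
  g <- mu_max * prod(reserves_norm)
  excess <- pmin(pmax(ros_percell - th / 2, 0), th / 2)
  g * excess * cell_density
}

#' ROS detoxification rate (legacy proportional law)
#'
#' The original formulation: removal proportional to the per-cell ROS
#' concentration at the reserve-weighted growth rate, allowing ROS to relax
#' to zero. Retained for back-compatibility comparison; selected in the
#' simulator by `cbm_params(legacy_detox = TRUE)`.
#'
#' @inheritParams ros_detox_rate
#' @return per-cell detoxification rate, mg O cell^-1 d^-1.
#' @export
ros_detox_rate_legacy <- function(ros_percell, reserves_norm, mu_max) {
  mu_max * prod(reserves_norm) * ros_percell
}

#' Xanthophyll-cycle interconversion
#'
#' When more than half the reaction centres are inhibited the photosynthetic
#' pigment diadinoxanthin converts to photoprotective diatoxanthin at
#' `xanth_switch_rate`; otherwise the reverse conversion runs. The switch
#' conserves the total xanthophyll pool.
#'
#' @param x_p,x_h diadinoxanthin / diatoxanthin, mg m^-2.
#' @param q_in_frac inhibited fraction q_in / q_t.
#' @param params a [cbm_params()].
#' @return list `dx_p`, `dx_h`, mg m^-2 d^-1 (sum is zero).
#' @export
xanthophyll_switch <- function(x_p, x_h, q_in_frac, params = cbm_params()) {
  if (x_p < 0 || x_h < 0) stop("pigments must be >= 0")
  r <- params$photo$xanth_switch_rate
  if (q_in_frac > 0.5) {
    flux <- r * x_p
    list(dx_p = -flux, dx_h = flux)
  } else {
    flux <- r * x_h
    list(dx_p = flux, dx_h = -flux)
  }
}

# ---- exact advance of the linear reaction-centre subsystem ----------------
#
# State fractions p = (p_ox, p_red, p_in) evolve by the cyclic linear kinetics
#   ox --alpha--> red --beta--> in --gamma--> ox
# with per-capita rates alpha = (k_i / (m_RCII * q_t)) * (1 - f) (photons on
# oxidised centres not consumed by fixation), beta = k_i / (m_RCII * q_t),
# gamma = repair_const * m_RCII. These timescales are seconds under daylight,
# far below the integration step, so the subsystem is advanced by its exact
# solution over each step (eliminating p_in via conservation leaves a 2x2
# linear ODE whose matrix exponential has a closed form). Returns the
# end-of-step fractions and the trapezoid step-mean used for photon-flux
# bookkeeping.
rc_advance <- function(p, alpha, beta, gamma, dt) {
  if (beta <= 0) {
    # night: no photon flux, pure repair in -> ox
    decay <- exp(-gamma * dt)
    p_in1 <- p[3] * decay
    p1 <- c(p[1] + p[3] - p_in1, p[2], p_in1)
    pin_mean <- if (gamma > 0) p[3] * (1 - decay) / (gamma * dt) else p[3]
    pbar <- c(p[1] + p[3] - pin_mean, p[2], pin_mean)
    return(list(p = p1, pbar = pbar))
  }
  # reduced coordinates y = (p_ox, p_red); p_in = 1 - sum(y)
  b11 <- -(alpha + gamma); b12 <- -gamma
  b21 <- alpha;            b22 <- -beta
  det <- b11 * b22 - b12 * b21        # = beta*(alpha+gamma) + gamma*alpha > 0
  # steady state: B y_ss = -(gamma, 0)
  yss1 <- (-gamma * b22) / det
  yss2 <- (gamma * b21) / det
  d1 <- p[1] - yss1; d2 <- p[2] - yss2
  tr <- b11 + b22
  disc <- tr * tr - 4 * det
  if (disc >= 0) {
    sq <- sqrt(disc)
    l1 <- (tr + sq) / 2; l2 <- (tr - sq) / 2
    if (abs(l1 - l2) < 1e-12 * max(1, abs(l1))) {
      e <- exp(l1 * dt)
      m11 <- e * (1 + dt * (b11 - l1)); m12 <- e * dt * b12
      m21 <- e * dt * b21;              m22 <- e * (1 + dt * (b22 - l1))
    } else {
      e1 <- exp(l1 * dt); e2 <- exp(l2 * dt)
      c1 <- (e1 - e2) / (l1 - l2)
      c0 <- (l1 * e2 - l2 * e1) / (l1 - l2)
      m11 <- c0 + c1 * b11; m12 <- c1 * b12
      m21 <- c1 * b21;      m22 <- c0 + c1 * b22
    }
  } else {
    s <- tr / 2; w <- sqrt(-disc) / 2
    e <- exp(s * dt); cw <- cos(w * dt); swt <- sin(w * dt) / w
    m11 <- e * (cw + swt * (b11 - s)); m12 <- e * swt * b12
    m21 <- e * swt * b21;              m22 <- e * (cw + swt * (b22 - s))
  }
  y1 <- c(yss1 + m11 * d1 + m12 * d2, yss2 + m21 * d1 + m22 * d2)
  y1 <- pmin(pmax(y1, 0), 1)
  p1 <- c(y1, max(1 - sum(y1), 0))
  p1 <- p1 / sum(p1)
  # exact step mean: ybar = y_ss + B^-1 (expm(B dt) - I) d / dt
  v1 <- (m11 - 1) * d1 + m12 * d2
  v2 <- m21 * d1 + (m22 - 1) * d2
  u1 <- (b22 * v1 - b12 * v2) / det
  u2 <- (b11 * v2 - b21 * v1) / det
  ybar <- c(yss1 + u1 / dt, yss2 + u2 / dt)
  ybar <- pmin(pmax(ybar, 0), 1)
  pbar <- c(ybar, max(1 - sum(ybar), 0))
  pbar <- pbar / sum(pbar)
  list(p = p1, pbar = pbar)
}
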