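# Symbiont population dynamics: Droop-style reserve-limited growth at
# Redfield stoichiometry, diffusion-limited nutrient uptake, pigment
# synthesis, and ROS-triggered proportional cell expulsion.

#' Normalised internal reserves
#'
#' Each reserve is normalised to its structural-equivalent maximum: the
#' maximum internal reserve equals the biomass of the structural material, so
#' `r_n* = r_n / cs`, `r_c* = r_c / (cs * redfield_c)`,
#' `r_p* = r_p / (cs * redfield_p)`.
#'
#' @param pools list/vector with `cs`, `r_n`, `r_c`, `r_p` (mg m^-2).
#' @param params a [cbm_params()].
#' @return named numeric `(r_n, r_c, r_p)` in \[0, 1\].
#' @export
normalised_reserves <- function(pools, params = cbm_params()) {
  cs <- pools[["cs"]]
  if (cs <= 0) stop("cs must be positive to normalise reserves")
  sy <- params$symbiont
  out <- c(r_n = pools[["r_n"]] / cs,
           r_c = pools[["r_c"]] / (cs * sy$redfield_c),
           r_p = pools[["r_p"]] / (cs * sy$redfield_p))
  pmin(pmax(out, 0), 1)
}

#' Symbiont cell density and projected-area layers
#'
#' Cell density is structural biomass over the per-cell structural nitrogen,
#' `cs / m_n`; the projected area in gastrodermal layers is density times the
#' cell cross-section.
#'
#' @param cs structural biomass, mg N m^-2.
#' @param params a [cbm_params()].
#' @return cells m^-2 (`cell_density`) or dimensionless layers
#'   (`projected_area_layers`).
#' @export
cell_density <- function(cs, params = cbm_params()) {
  if (any(cs < 0)) stop("cs must be >= 0")
  cs / params$symbiont$m_n
}

#' @rdname cell_density
#' @export
projected_area_layers <- function(cs, params = cbm_params()) {
  cell_density(cs, params) * pi * params$symbiont$cell_radius^2
}

# smooth cap keeping the projected area below the two-layer anatomy
area_cap_factor <- function(layers, params = cbm_params()) {
  pmax(0, 1 - (layers / params$symbiont$area_cap)^4)
}

#' Reserve-limited growth rate
#'
#' Growth runs at `mu_max` scaled by the product of the three normalised
#' reserves (Droop-style multi-nutrient limitation) and by the two-layer
#' packing cap. Growth ceases only when a reserve is fully exhausted.
#'
#' @param reserves_norm numeric length-3 `(r_n*, r_c*, r_p*)`.
#' @param params a [cbm_params()].
#' @param cap_factor packing cap multiplier in \[0, 1\] (default 1).
#' @return specific growth rate mu, d^-1.
#' @export
growth_rate <- function(reserves_norm, params = cbm_params(), cap_factor = 1) {
  params$symbiont$mu_max * prod(reserves_norm) * cap_factor
}

#' Reserve and structure fluxes from growth
#'
#' Producing new structural material consumes all three reserves at the
#' Redfield ratio: `dcs = +mu*cs`, `dr_n = -mu*cs`,
#' `dr_c = -mu*cs*redfield_c`, `dr_p = -mu*cs*redfield_p`. Because the
#' reserve maxima scale with `cs`, division dilutes the normalised reserves
#' automatically (the discrete two-to-three-cell picture: full nitrogen
#' reserves fall to one-third, phosphorus to one-sixth).
#'
#' @param pools list/vector with `cs` (mg N m^-2).
#' @param mu specific growth rate, d^-1.
#' @param params a [cbm_params()].
#' @return list `dcs`, `dr_n`, `dr_c`, `dr_p`, mg m^-2 d^-1.
#' @export
growth_fluxes <- function(pools, mu, params = cbm_params()) {
  cs <- pools[["cs"]]
  sy <- params$symbiont
  list(dcs = mu * cs, dr_n = -mu * cs, dr_c = -mu * cs * sy$redfield_c,
       dr_p = -mu * cs * sy$redfield_p)
}

#' Diffusion-limited nutrient uptake
#'
#' Areal uptake of dissolved inorganic N and P is linear in the ambient
#' concentration (diffusion-limited per-cell supply through a mass-transfer
#' coefficient), proportional to cell density, and saturates as the reserve
#' fills through the factor `(1 - r_x*)`.
#'
#' @param pools list/vector with `cs`, `r_n`, `r_p`.
#' @param din,dip ambient concentrations, mg N m^-3 and mg P m^-3.
#' @param params a [cbm_params()].
#' @return list `dr_n`, `dr_p`, mg m^-2 d^-1.
#' @export
nutrient_uptake <- function(pools, din, dip, params = cbm_params()) {
  if (din < 0 || dip < 0) stop("nutrient concentrations must be >= 0")
  sy <- params$symbiont
  rn <- normalised_reserves(pools, params)
  dens <- cell_density(pools[["cs"]], params)
  list(dr_n = sy$uptake_n * din * dens * (1 - rn[["r_n"]]),
       dr_p = sy$uptake_p * dip * dens * (1 - rn[["r_p"]]))
}

#' Carbon fixation flux
#'
#' Photons routed to fixation deliver fixed carbon to the internal carbon
#' reserve at the quantum yield `fix_yield`; the reserve is capped at its
#' structural-equivalent maximum.
#'
#' @param to_fixation photon flux routed to fixation, mol photon m^-2 d^-1.
#' @param pools list/vector with `cs`, `r_c` (for the cap); may be omitted to
#'   get the uncapped rate.
#' @param params a [cbm_params()].
#' @return fixation rate dr_c, mg C m^-2 d^-1.
#' @export
carbon_fixation_flux <- function(to_fixation, pools = NULL,
                                 params = cbm_params()) {
  if (any(to_fixation < 0)) stop("to_fixation must be >= 0")
  rate <- params$photo$fix_yield * to_fixation
  if (!is.null(pools)) {
    rc_max <- pools[["cs"]] * params$symbiont$redfield_c
    if (pools[["r_c"]] >= rc_max) rate <- 0
  }
  rate
}

#' Pigment synthesis rate
#'
#' Chlorophyll a synthesis follows the incremental benefit of adding pigment
#' to photosynthesis: proportional to biomass, reduced when carbon reserves
#' are replete (`1 - r_c*`), when the photosystem is inhibited (`1 - q_in*`)
#' and by self-shading (`exp(-optical_depth)`). Synthesis also requires fixed
#' carbon as substrate, so the rate carries a factor `r_c*`: a
#' carbon-starved cell cannot build pigment (the benefit-times-substrate
#' product peaks at half-full carbon reserves). Newly synthesised xanthophyll
#' maintains the total-xanthophyll:chlorophyll mass ratio and enters the
#' photosynthetic (diadinoxanthin) pool; new reaction centres are produced at
#' the fixed reaction-centre:chlorophyll ratio and enter the oxidised state.
#'
#' @param cs structural biomass, mg N m^-2.
#' @param r_c_norm normalised carbon reserve.
#' @param q_in_frac inhibited reaction-centre fraction.
#' @param optical_depth pigment optical depth (dimensionless).
#' @param params a [cbm_params()].
#' @return list `dchl`, `dx_p`, `dq_ox`, mg m^-2 d^-1.
#' @export
pigment_synthesis <- function(cs, r_c_norm, q_in_frac, optical_depth,
                              params = cbm_params()) {
  sy <- params$symbiont
  dchl <- sy$chl_synth_rate * cs * r_c_norm * max(1 - r_c_norm, 0) *
    max(1 - q_in_frac, 0) * exp(-optical_depth)
  list(dchl = dchl, dx_p = sy$xanth_to_chl * dchl,
       dq_ox = sy$qt_chl_ratio * dchl)
}

#' Symbiont cell expulsion rate
#'
#' Bleaching: when the per-cell ROS concentration exceeds the bleaching
#' threshold, a fraction of the population is expelled at a rate proportional
#' to the relative excess, `e = expulsion_gain * mu_max * (ros - theta) /
#' theta`; zero at or below the threshold. Expulsion removes the same
#' fraction from every areal pool, leaving all per-cell contents unchanged.
#'
#' @param ros_percell per-cell ROS, mg O cell^-1.
#' @param params a [cbm_params()].
#' @return expulsion rate, d^-1.
#' @export
expulsion_rate <- function(ros_percell, params = cbm_params()) {
  th <- params$photo$ros_threshold
  ifelse(ros_percell > th,
         params$symbiont$expulsion_gain * params$symbiont$mu_max *
           (ros_percell - th) / th,
         0)
}
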