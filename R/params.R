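# Parameter container for the single-polyp coral bleaching model.
#
# Provenance classes for defaults:
#   "fixed"      -- printed constants of the model formulation
#                   (m_P2R 3500, ROS threshold 1.42e-14 mg O cell^-1,
#                    MMM 28.6 degC, repair constant 268, Redfield ratios,
#                    xanthophyll:chlorophyll mass ratio 0.2448)
#   "calibrated" -- values the formulation leaves free, tuned once against the
#                   published scenario summaries (see the methods vignette)
#   "default"    -- plumbing choices (step sizes, caps)

# Redfield-stoichiometry structural ratios (mg per mg N of structure)
.redfield_c <- (106 / 16) * (12.01 / 14.01)
.redfield_p <- (1 / 16) * (30.97 / 14.01)

# molar masses used to convert dissolved nutrient forcing (umol/l -> mg/m^3)
.mw_n <- 14.01
.mw_p <- 30.97

# umol photon m^-2 s^-1  ->  mol photon m^-2 d^-1
.par_to_daily <- 86400 * 1e-6

# total reaction centres : chlorophyll a mass ratio implied by the reference
# initial state (Q_T0 / Chl0); new centres track pigment synthesis
.qt_chl_ratio <- (1.0607e-7 + 7.1695e-9 + 1.0108e-7) / (5.6786 / 30)

#' Default parameter set of the coral bleaching model
#'
#' Returns the full nested parameter list of the model: the
#' `photo` section (photon pathway and ROS kinetics), the `symbiont` section
#' (population growth, uptake, pigments, expulsion) and the `simulator`
#' section (integration control). All rates are per day, areal quantities per
#' square metre.
#'
#' Constants printed in the model formulation are fixed here
#' (`m_P2R` 3500 mol photon (mg O2)^-1, ROS threshold 1.42e-14 mg O cell^-1,
#' climatological maximum monthly mean 28.6 degC, repair constant 268,
#' Redfield structural ratios). Parameters the formulation leaves free carry
#' calibrated defaults chosen once to reproduce the published four-treatment
#' scenario summaries; see the methods vignette for the calibration protocol.
#'
#' @param legacy_detox logical; if `TRUE` the simulator uses the legacy
#'   proportional ROS detoxification law (removal proportional to
#'   concentration, allowing ROS to relax to zero) instead of the revised
#'   piecewise law with its half-threshold floor.
#' @param m_P2R photons required to generate one ROS,
#'   mol photon (mg O2)^-1. `3500` is the thermally sensitive configuration;
#'   `7000` the legacy one.
#' @param ... named overrides of any leaf parameter, e.g. `mu_max = 0.2`,
#'   `m_RCII = 50`. Unknown names are an error.
#' @return An object of class `cbm_params`: a nested list with sections
#'   `photo`, `symbiont`, `simulator`.
#' @export
#' @examples
#' p <- cbm_params()
#' p$photo$ros_threshold
#' cbm_params(mu_max = 0.2)$symbiont$mu_max
cbm_params <- function(legacy_detox = FALSE, m_P2R = 3500, ...) {
  p <- list(
    photo = list(
      m_P2R = m_P2R,              # mol photon (mg O2)^-1          [fixed]
      m_RCII = 9,                 # mol photon (mol RC)^-1         [calibrated]
      ros_threshold = 1.42e-14,   # mg O cell^-1                   [fixed]
      mmm = 28.6,                 # degC                           [fixed]
      repair_const = 268,         # from the 10 mol photon m-2 d-1
                                  # repair-capacity limit          [fixed]
      chl_absorb = 0.0147,        # m^2 (mg Chl a)^-1, effective   [calibrated]
      xp_absorb = 0.0177,         # m^2 (mg diadinoxanthin)^-1     [calibrated]
      xh_absorb = 0.04,           # m^2 (mg diatoxanthin)^-1       [calibrated]
      xanth_switch_rate = 24,     # d^-1 (~1 h interconversion)    [calibrated]
      fix_yield = 420,            # mg C fixed (mol photon)^-1     [calibrated]
      od_max = 6,                 # ceiling on optical depth       [default]
      repair_temp_factor = NULL   # optional function(temp)->multiplier hook
    ),
    symbiont = list(
      mu_max = 0.14,              # d^-1                           [calibrated]
      m_n = 2e-9,                 # mg N cell^-1 (structural)      [calibrated]
      redfield_c = .redfield_c,   # mg C (mg N)^-1                 [fixed]
      redfield_p = .redfield_p,   # mg P (mg N)^-1                 [fixed]
      uptake_n = 1e-10,           # m^3 cell^-1 d^-1               [calibrated]
      uptake_p = 1e-10,           # m^3 cell^-1 d^-1               [calibrated]
      chl_synth_rate = 0.012,     # mg Chl (mg N)^-1 d^-1          [calibrated]
      xanth_to_chl = 0.2448,      # total xanthophyll : Chl mass   [fixed]
      expulsion_gain = 0.5,       # dimensionless                  [calibrated]
      area_cap = 2,               # gastrodermal layers            [fixed]
      cell_radius = 5e-6,         # m                              [calibrated]
      qt_chl_ratio = .qt_chl_ratio # mg RC (mg Chl)^-1             [fixed]
    ),
    simulator = list(
      dt_max = 1 / 1440,          # d (1 min)                      [default]
      out_dt = 1 / 96,            # d (15 min output cadence)      [default]
      legacy_detox = isTRUE(legacy_detox),
      spinup_days = 3             # pre-experimental spin-up       [fixed]
    )
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("parameter overrides must be named")
    for (nm in names(dots)) {
      hit <- FALSE
      for (sec in names(p)) {
        if (nm %in% names(p[[sec]])) {
          p[[sec]][[nm]] <- dots[[nm]]
          hit <- TRUE
          break
        }
      }
      if (!hit) stop("unknown parameter: ", nm)
    }
  }
  structure(p, class = "cbm_params")
}

validate_params <- function(p) {
  stopifnot(inherits(p, "cbm_params"))
  pos <- c(
    p$photo$m_P2R, p$photo$m_RCII, p$photo$ros_threshold, p$photo$repair_const,
    p$photo$chl_absorb, p$photo$xp_absorb, p$photo$xh_absorb,
    p$photo$xanth_switch_rate, p$photo$fix_yield,
    p$symbiont$mu_max, p$symbiont$m_n,
    p$symbiont$chl_synth_rate, p$symbiont$xanth_to_chl, p$symbiont$area_cap,
    p$symbiont$cell_radius, p$symbiont$qt_chl_ratio,
    p$simulator$dt_max, p$simulator$out_dt
  )
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("all rate/stoichiometry parameters must be finite and positive")
  if (p$symbiont$expulsion_gain < 0) stop("expulsion_gain must be >= 0")
  if (p$symbiont$uptake_n < 0 || p$symbiont$uptake_p < 0)
    stop("uptake coefficients must be >= 0")
  invisible(p)
}

#' @export
print.cbm_params <- function(x, ...) {
  cat("<cbm_params> single-polyp coral bleaching model parameters\n")
  for (sec in names(x)) {
    cat(sprintf("$%s\n", sec))
    vals <- x[[sec]]
    for (nm in names(vals)) {
      v <- vals[[nm]]
      if (is.null(v)) v <- "NULL"
      if (is.function(v)) v <- "<function>"
      cat(sprintf("  %-18s %s\n", nm, format(v, digits = 6)))
    }
  }
  invisible(x)
}
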