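# Environmental forcing: synthetic generators for the light x temperature
# factorial experiment, file I/O, interpolation and the degree-heating-week
# (DHW) thermal stress metric.

# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# fixed offsets deriving per-stream seeds from the scenario seed, so that
# treatments sharing a seed share the same weather
.seed_offset_light <- 1013L
.seed_offset_nutrient <- 2027L

#' Specify a forcing scenario
#'
#' Builds the specification of one treatment of the heat-hold light x
#' temperature experiment: a temperature treatment (constant ambient, or a
#' linear ramp followed by a hold), a shade treatment (a fixed transmission
#' fraction applied to the light series), diel irradiance with prescribed
#' daily-light-integral statistics, and step-sampled nutrient concentrations.
#'
#' The default heat profile ramps from `ambient_temp` (26.4 degC) to
#' `heat_temp` (32.6 degC) over `ramp_days` (14 d, i.e. ~0.443 degC/d) and
#' holds for `hold_days` (9 d). Unshaded light has mean daily light integral
#' `dli_mean` (7.21 mol photon m^-2 d^-1) with day-to-day standard deviation
#' `dli_sd`, and the diel curve is shaped so a nominal day peaks at `par_peak`
#' (818 umol photon m^-2 s^-1). Nutrients are redrawn every
#' `nutrient_sampling_interval` days from truncated normal distributions.
#'
#' @param temperature_treatment `"ambient"` or `"heat"`.
#' @param shade_treatment `"unshaded"` or `"shaded"`.
#' @param days scenario duration, days.
#' @param seed integer scenario seed; light and nutrient streams derive their
#'   own seeds from it by fixed offsets.
#' @param mmm maximum monthly mean climatology, degC.
#' @param ambient_temp,heat_temp ambient and hold temperatures, degC.
#' @param ramp_days duration of the linear ramp, days.
#' @param hold_days duration of the hold at `heat_temp`, days.
#' @param dli_mean,dli_sd daily light integral mean and sd,
#'   mol photon m^-2 d^-1.
#' @param par_peak nominal midday PAR peak, umol photon m^-2 s^-1.
#' @param shade_fraction fraction of light transmitted under shade, in (0, 1].
#' @param din_mean,din_sd,dip_mean,dip_sd dissolved inorganic nitrogen /
#'   phosphorus statistics, umol/l.
#' @param nutrient_sampling_interval days between nutrient redraws.
#' @param photoperiod_h daylight duration, hours.
#' @param grid_minutes forcing grid resolution, minutes (<= 15).
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' spec <- scenario_spec("heat", "unshaded", seed = 1)
#' fs <- generate_forcing(spec)
#' head(fs)
scenario_spec <- function(temperature_treatment = c("ambient", "heat"),
                          shade_treatment = c("unshaded", "shaded"),
                          days = 23, seed = 1L,
                          mmm = 28.6, ambient_temp = 26.4, heat_temp = 32.6,
                          ramp_days = 14, hold_days = 9,
                          dli_mean = 7.21, dli_sd = 2.99, par_peak = 818,
                          shade_fraction = 0.70,
                          din_mean = 3.35, din_sd = 1.14,
                          dip_mean = 0.58, dip_sd = 0.20,
                          nutrient_sampling_interval = 2,
                          photoperiod_h = 12, grid_minutes = 5) {
  temperature_treatment <- match.arg(temperature_treatment)
  shade_treatment <- match.arg(shade_treatment)
  if (!is.finite(days) || days <= 0) stop("days must be positive")
  if (shade_fraction <= 0 || shade_fraction > 1)
    stop("shade_fraction must be in (0, 1]")
  if (dli_mean <= 0) stop("dli_mean must be positive")
  if (dli_sd < 0) stop("dli_sd must be >= 0")
  if (din_mean < 0 || dip_mean < 0) stop("nutrient means must be >= 0")
  if (temperature_treatment == "heat" && ramp_days + hold_days > days)
    stop(sprintf(
      "ramp_days (%g) + hold_days (%g) exceed scenario days (%g)",
      ramp_days, hold_days, days))
  if (grid_minutes <= 0 || grid_minutes > 15)
    stop("grid_minutes must be in (0, 15]")
  structure(list(
    temperature_treatment = temperature_treatment,
    shade_treatment = shade_treatment,
    days = days, seed = as.integer(seed),
    mmm = mmm, ambient_temp = ambient_temp, heat_temp = heat_temp,
    ramp_days = ramp_days,
    ramp_rate = (heat_temp - ambient_temp) / ramp_days,
    hold_days = hold_days,
    dli_mean = dli_mean, dli_sd = dli_sd, par_peak = par_peak,
    shade_fraction = if (shade_treatment == "shaded") shade_fraction else 1,
    din_mean = din_mean, din_sd = din_sd,
    dip_mean = dip_mean, dip_sd = dip_sd,
    nutrient_sampling_interval = nutrient_sampling_interval,
    photoperiod_h = photoperiod_h, grid_minutes = grid_minutes
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> %s / %s, %g d, seed %d\n",
    x$temperature_treatment, x$shade_treatment, x$days, x$seed))
  cat(sprintf("  temperature: %.1f -> %.1f degC (ramp %g d, hold %g d)\n",
              x$ambient_temp,
              if (x$temperature_treatment == "heat") x$heat_temp else x$ambient_temp,
              x$ramp_days, x$hold_days))
  cat(sprintf("  light: DLI %.2f +/- %.2f mol m-2 d-1, transmission %.2f\n",
              x$dli_mean, x$dli_sd, x$shade_fraction))
  cat(sprintf("  nutrients: DIN %.2f +/- %.2f, DIP %.2f +/- %.2f umol/l\n",
              x$din_mean, x$din_sd, x$dip_mean, x$dip_sd))
  invisible(x)
}

scenario_times <- function(spec) {
  seq(0, spec$days, by = spec$grid_minutes / 1440)
}

#' Temperature series of a scenario
#'
#' Ambient treatment: constant `ambient_temp`. Heat treatment: linear ramp
#' from `ambient_temp` to `heat_temp` over `ramp_days`, then a constant hold.
#'
#' @param spec a [scenario_spec()].
#' @param times evaluation times, days (default: the scenario grid).
#' @return numeric vector of water temperature, degC.
#' @export
generate_temperature <- function(spec, times = scenario_times(spec)) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$temperature_treatment == "ambient")
    return(rep(spec$ambient_temp, length(times)))
  pmin(spec$ambient_temp + spec$ramp_rate * times, spec$heat_temp)
}

# mean of sin(x)^s over a half period, by quadrature (vectorised over s)
.sin_pow_mean <- function(s) {
  x <- seq(0, pi, length.out = 20001)
  vapply(s, function(si) mean(sin(x)^si), numeric(1))
}

# diel shape exponent making a nominal day (DLI = dli_mean) peak at par_peak
.diel_exponent <- function(dli_mean, par_peak, photoperiod_h) {
  target <- dli_mean / (par_peak * photoperiod_h * 3600 * 1e-6)
  if (target >= 2 / pi) return(1)  # half-sine already flat enough
  stats::uniroot(function(s) .sin_pow_mean(s) - target,
                 interval = c(1, 400), tol = 1e-10)$root
}

#' Diel PAR series of a scenario
#'
#' Each day is a powered-sinusoid diel curve (zero outside the photoperiod,
#' peak at solar noon); the shape exponent is derived from
#' (`par_peak`, `dli_mean`, `photoperiod_h`) so a nominal day peaks at
#' `par_peak`. Day-to-day variability multiplies each day's daily light
#' integral by a seeded lognormal cloudiness factor; the sampled factors are
#' rescaled so the realised sample-mean DLI of the scenario equals `dli_mean`
#' (the generator reproduces the treatment-mean light dose by construction).
#' The shaded treatment multiplies every value by `shade_fraction`.
#'
#' @inheritParams generate_temperature
#' @return numeric vector of PAR, umol photon m^-2 s^-1.
#' @export
generate_par <- function(spec, times = scenario_times(spec)) {
  stopifnot(inherits(spec, "scenario_spec"))
  ndays <- ceiling(spec$days)
  cv <- spec$dli_sd / spec$dli_mean
  mult <- with_seed(spec$seed + .seed_offset_light, {
    if (cv <= 0) rep(1, ndays) else {
      sdlog <- sqrt(log(1 + cv^2))
      stats::rlnorm(ndays, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    }
  })
  mult <- mult / mean(mult)  # realised mean DLI = dli_mean exactly
  dli_day <- spec$dli_mean * mult
  s <- .diel_exponent(spec$dli_mean, spec$par_peak, spec$photoperiod_h)
  shape_mean <- .sin_pow_mean(s)
  # peak PAR giving that day's DLI under the shaped diel curve
  peak_day <- dli_day / (shape_mean * spec$photoperiod_h * 3600 * 1e-6)
  hour <- (times %% 1) * 24
  rise <- 12 - spec$photoperiod_h / 2
  phase <- (hour - rise) / spec$photoperiod_h  # in [0,1] during daylight
  day_i <- pmin(floor(times) + 1, ndays)
  par <- ifelse(phase > 0 & phase < 1,
                peak_day[day_i] * sin(pi * phase)^s, 0)
  par * spec$shade_fraction
}

# one truncated-normal draw stream, bounded below at zero
.rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Nutrient series of a scenario
#'
#' Dissolved inorganic nitrogen and phosphorus are redrawn every
#' `nutrient_sampling_interval` days from truncated normal distributions
#' (bounded below at zero) and held constant between draws, emulating the
#' experiment's discrete water sampling.
#'
#' @inheritParams generate_temperature
#' @return data.frame with columns `din`, `dip` (umol/l) at `times`.
#' @export
generate_nutrients <- function(spec, times = scenario_times(spec)) {
  stopifnot(inherits(spec, "scenario_spec"))
  epochs <- seq(0, spec$days - 1e-9, by = spec$nutrient_sampling_interval)
  draws <- with_seed(spec$seed + .seed_offset_nutrient, {
    n <- length(epochs)
    list(din = .rtnorm0(n, spec$din_mean, spec$din_sd),
         dip = .rtnorm0(n, spec$dip_mean, spec$dip_sd))
  })
  idx <- findInterval(times, epochs)
  idx[idx < 1] <- 1
  data.frame(din = draws$din[idx], dip = draws$dip[idx])
}

#' Generate the full forcing series of a scenario
#'
#' Assembles PAR, temperature and nutrient series on the scenario grid.
#'
#' @param spec a [scenario_spec()].
#' @return A `forcing_series`: a data.frame with columns `time_days`, `par`
#'   (umol photon m^-2 s^-1), `temp` (degC), `din`, `dip` (umol/l).
#' @export
generate_forcing <- function(spec) {
  times <- scenario_times(spec)
  nut <- generate_nutrients(spec, times)
  as_forcing_series(data.frame(
    time_days = times,
    par = generate_par(spec, times),
    temp = generate_temperature(spec, times),
    din = nut$din, dip = nut$dip
  ))
}

#' Coerce a data.frame to a forcing series
#'
#' Validates the invariants of a forcing table: strictly increasing time,
#' non-negative PAR and nutrient concentrations.
#'
#' @param x data.frame with columns `time_days`, `par`, `temp`, `din`, `dip`.
#' @return `x` with class `forcing_series` prepended.
#' @export
as_forcing_series <- function(x) {
  need <- c("time_days", "par", "temp", "din", "dip")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column ", paste(miss, collapse = ", "))
  if (any(diff(x$time_days) <= 0)) stop("time_days must be strictly increasing")
  if (any(x$par < 0)) stop("par must be >= 0")
  if (any(x$din < 0) || any(x$dip < 0)) stop("nutrients must be >= 0")
  class(x) <- unique(c("forcing_series", class(x)))
  x
}

#' @export
print.forcing_series <- function(x, ...) {
  cat(sprintf(
    "<forcing_series> %d points over %.2f d (grid %.1f min)\n",
    nrow(x), diff(range(x$time_days)),
    stats::median(diff(x$time_days)) * 1440))
  cat(sprintf("  PAR %.0f-%.0f umol m-2 s-1 | temp %.1f-%.1f degC | DIN %.2f-%.2f | DIP %.2f-%.2f umol/l\n",
              min(x$par), max(x$par), min(x$temp), max(x$temp),
              min(x$din), max(x$din), min(x$dip), max(x$dip)))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("  ... ", nrow(x) - 6, " more rows\n", sep = "")
  invisible(x)
}

# file column names <-> internal names
.forcing_cols <- c(time_days = "time_days", par = "par_umol_m2_s",
                   temp = "temp_C", din = "din_umol_l", dip = "dip_umol_l")

#' Read / write a forcing series
#'
#' Plain-text delimited files with header columns `time_days`,
#' `par_umol_m2_s`, `temp_C`, `din_umol_l`, `dip_umol_l` (comma or tab
#' delimited; the delimiter is sniffed on read). Values round-trip at full
#' double precision. Unknown columns are ignored.
#'
#' @param path file path.
#' @param x a `forcing_series`.
#' @param delim delimiter used when writing (`","` default).
#' @return `read_forcing` returns a `forcing_series`; `write_forcing`
#'   invisibly returns `path`.
#' @export
read_forcing <- function(path) {
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(unname(.forcing_cols), names(raw))
  if (length(miss))
    stop("missing column ", paste(miss, collapse = ", "))
  out <- raw[unname(.forcing_cols)]
  names(out) <- names(.forcing_cols)
  as_forcing_series(out)
}

#' @rdname read_forcing
#' @export
write_forcing <- function(x, path, delim = ",") {
  stopifnot(inherits(x, "forcing_series"))
  out <- x[names(.forcing_cols)]
  names(out) <- unname(.forcing_cols)
  txt <- vapply(out, function(col) formatC(col, format = "g", digits = 17),
                character(nrow(out)))
  lines <- c(paste(names(out), collapse = delim),
             apply(matrix(txt, nrow = nrow(out)), 1, paste, collapse = delim))
  writeLines(lines, path)
  invisible(path)
}

#' Interpolate a forcing series
#'
#' Linear interpolation for PAR and temperature (continuous drivers);
#' previous-value (step) interpolation for the nutrient concentrations, which
#' are plateau samples.
#'
#' @param fs a `forcing_series`.
#' @param t evaluation times, days; must lie within the series span.
#' @return data.frame with columns `par`, `temp`, `din`, `dip` at `t`.
#' @export
interpolate_forcing <- function(fs, t) {
  stopifnot(inherits(fs, "forcing_series"))
  rng <- range(fs$time_days)
  if (any(t < rng[1] - 1e-9 | t > rng[2] + 1e-9))
    stop("extrapolation outside forcing span [",
         signif(rng[1], 6), ", ", signif(rng[2], 6), "]")
  t <- pmin(pmax(t, rng[1]), rng[2])
  data.frame(
    par = stats::approx(fs$time_days, fs$par, t, method = "linear")$y,
    temp = stats::approx(fs$time_days, fs$temp, t, method = "linear")$y,
    din = stats::approx(fs$time_days, fs$din, t, method = "constant",
                        f = 0, rule = 2)$y,
    dip = stats::approx(fs$time_days, fs$dip, t, method = "constant",
                        f = 0, rule = 2)$y
  )
}

#' Daily light integral
#'
#' Trapezoidal integral of PAR over one full day, converted to
#' mol photon m^-2 d^-1.
#'
#' @param fs a `forcing_series` (or data.frame with `time_days`, `par`).
#' @param day integer day index (day `d` covers `[d, d+1]`); the series must
#'   cover the whole day.
#' @return DLI in mol photon m^-2 d^-1.
#' @export
daily_light_integral <- function(fs, day) {
  if (length(day) > 1)
    return(vapply(day, function(d) daily_light_integral(fs, d), numeric(1)))
  tol <- 1e-9
  if (min(fs$time_days) > day + tol || max(fs$time_days) < day + 1 - tol)
    stop("series does not cover the full day [", day, ", ", day + 1, "]")
  sel <- fs$time_days >= day - tol & fs$time_days <= day + 1 + tol
  tt <- fs$time_days[sel]; pp <- fs$par[sel]
  # clip the boundary segments exactly to the day
  if (tt[1] < day) {
    pp[1] <- stats::approx(tt[1:2], pp[1:2], day)$y; tt[1] <- day
  }
  n <- length(tt)
  if (tt[n] > day + 1) {
    pp[n] <- stats::approx(tt[(n - 1):n], pp[(n - 1):n], day + 1)$y
    tt[n] <- day + 1
  }
  sum(diff(tt) * (utils::head(pp, -1) + utils::tail(pp, -1)) / 2) * 86400 * 1e-6
}

#' Degree-heating-week thermal stress metric
#'
#' At each time `t`, sums the daily-mean temperature anomalies relative to the
#' maximum monthly mean over the completed days of the most recent `horizon`
#' days, counting only anomalies of at least 1 degC (the activation gate of
#' the NOAA convention), divided by 7 to give degC-weeks.
#'
#' @param fs a `forcing_series` (or data.frame with `time_days`, `temp`).
#' @param mmm maximum monthly mean, degC.
#' @param horizon accumulation window, days (default 84 = 12 weeks).
#' @return data.frame with columns `time_days`, `dhw` (degC-weeks) on the
#'   series grid.
#' @export
compute_dhw <- function(fs, mmm = 28.6, horizon = 84) {
  if (nrow(fs) == 0) stop("empty temperature series")
  t0 <- floor(min(fs$time_days) + 1e-9)
  tend <- max(fs$time_days)
  ndays <- floor(tend - t0 + 1e-9)  # completed days
  if (ndays < 1) {
    return(data.frame(time_days = fs$time_days, dhw = 0))
  }
  day_of <- floor(fs$time_days - t0 + 1e-9)
  dbar <- vapply(seq_len(ndays) - 1, function(k)
    mean(fs$temp[day_of == k]), numeric(1))
  anom <- dbar - mmm
  gated <- ifelse(anom >= 1, anom, 0)
  cum <- c(0, cumsum(gated))
  k_done <- pmax(pmin(floor(fs$time_days - t0 + 1e-9), ndays), 0)
  k_old <- pmax(ceiling(fs$time_days - t0 - horizon), 0)
  data.frame(time_days = fs$time_days,
             dhw = (cum[k_done + 1] - cum[k_old + 1]) / 7)
}
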