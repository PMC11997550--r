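# Configuration files and scenario presets.

#' Load / save a model configuration
#'
#' Configurations are human-editable YAML files with sections `photo`,
#' `symbiont` and `simulator` mirroring [cbm_params()]. Absent keys take the
#' package defaults; unknown sections or keys are an error. An empty file
#' yields the pure default (published) configuration.
#'
#' @param path YAML file path.
#' @param params a [cbm_params()] to save.
#' @return `load_config` returns a validated `cbm_params`; `save_config`
#'   invisibly returns `path`.
#' @export
#' @examples
#' p <- cbm_params(m_P2R = 7000)
#' f <- tempfile(fileext = ".yaml")
#' save_config(p, f)
#' identical(load_config(f)$photo$m_P2R, 7000)
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  p <- cbm_params()
  bad_sec <- setdiff(names(cfg), names(p))
  if (length(bad_sec))
    stop("unknown config section: ", paste(bad_sec, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), names(p[[sec]]))
    if (length(bad))
      stop("unknown config key in section '", sec, "': ",
           paste(bad, collapse = ", "))
    for (nm in names(cfg[[sec]])) p[[sec]][[nm]] <- cfg[[sec]][[nm]]
  }
  validate_params(p)
}

#' @rdname load_config
#' @export
save_config <- function(params, path) {
  validate_params(params)
  x <- unclass(params)
  x$photo$repair_temp_factor <- NULL  # function hook is not serialisable
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' Scenario presets of the four-treatment factorial experiment
#'
#' The orthogonal combination of temperature (ambient 26.4 degC vs heat-hold
#' ramp to 32.6 degC) and shade (unshaded vs 30% shade, i.e. transmission
#' 0.70) over 23 days.
#'
#' @param name one of `"ambient_unshaded"`, `"ambient_shaded"`,
#'   `"heat_unshaded"`, `"heat_shaded"`.
#' @param seed scenario seed (shared across presets so treatments share
#'   weather).
#' @param ... overrides passed to [scenario_spec()].
#' @return list with elements `spec` (a [scenario_spec()]) and `params`
#'   (the default [cbm_params()]).
#' @export
#' @examples
#' preset("heat_shaded")$spec
preset <- function(name, seed = 1L, ...) {
  valid <- c("ambient_unshaded", "ambient_shaded",
             "heat_unshaded", "heat_shaded")
  if (!name %in% valid)
    stop("unknown preset '", name, "'; valid presets: ",
         paste(valid, collapse = ", "))
  parts <- strsplit(name, "_")[[1]]
  list(spec = scenario_spec(parts[1], parts[2], seed = seed, ...),
       params = cbm_params())
}

#' Run a preset scenario
#'
#' Convenience wrapper: generate the preset forcing and integrate the model.
#'
#' @inheritParams preset
#' @param params parameter overrides (default [cbm_params()]).
#' @return a `cbm_trajectory`.
#' @export
run_preset <- function(name, seed = 1L, params = NULL, ...) {
  pr <- preset(name, seed = seed, ...)
  if (is.null(params)) params <- pr$params
  run_cbm(pr$spec, params)
}
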