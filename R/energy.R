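# Specific drying-energy requirement for hot-air drying.
#
# The heating duty delivered to the air stream over the sample plate is
# A * w * rho * Cp * dT (kW when Cp is in kJ/kg/degC), so the energy spent
# per kilogram of sample over a drying run of t hours is
#
#   E = A * w * rho * Cp * dT * t / m   (kWh/kg)
#
# A widely circulated variant of this formula places the drying time in the
# denominator; that form is dimensionally inconsistent with kWh/kg (it
# yields kW/kg/h) and inverts the time trend, but is retained behind
# `formula_variant = "as_printed"` for comparison with reports that use it.

#' Configuration for the specific-energy calculation
#'
#' @param plate_area Sample plate area A, m^2.
#' @param air_velocity Hot-air velocity w, m/s.
#' @param air_density Air density rho, kg/m^3 (default 1.06, dry air near
#'   60 degC).
#' @param air_specific_heat Air specific heat Cp, kJ/kg/degC (default 1.006).
#' @param air_temperature Drying air temperature, degC.
#' @param ambient_temperature Ambient temperature, degC (default 25).
#' @param sample_mass Mass of sample subjected to drying, kg.
#' @param drying_time Drying run length, hours.
#' @param formula_variant `"dimensional"` (default) or `"as_printed"`.
#' @return An object of class `energy_config`.
#' @export
energy_config <- function(plate_area, air_velocity, air_density = 1.06,
                          air_specific_heat = 1.006, air_temperature,
                          ambient_temperature = 25, sample_mass, drying_time,
                          formula_variant = c("dimensional", "as_printed")) {
  formula_variant <- match.arg(formula_variant)
  vals <- list(plate_area = plate_area, air_velocity = air_velocity,
               air_density = air_density, air_specific_heat = air_specific_heat,
               sample_mass = sample_mass, drying_time = drying_time)
  for (nm in names(vals)) {
    if (!is_number(vals[[nm]]) || vals[[nm]] <= 0) {
      stopf("`%s` must be a single positive number", nm)
    }
  }
  if (!is_number(air_temperature) || !is_number(ambient_temperature)) {
    stopf("temperatures must be single numbers")
  }
  if (air_temperature <= ambient_temperature) {
    stopf("air temperature (%g degC) must exceed ambient (%g degC)",
          air_temperature, ambient_temperature)
  }
  structure(c(vals, list(air_temperature = air_temperature,
                         ambient_temperature = ambient_temperature,
                         formula_variant = formula_variant)),
            class = "energy_config")
}

#' Specific drying-energy requirement
#'
#' @param config An [energy_config()].
#' @return Specific energy in kWh per kg of sample (dimensional variant;
#'   the `"as_printed"` variant equals the dimensional value divided by the
#'   square of the drying time).
#' @examples
#' cfg <- energy_config(plate_area = 0.09, air_velocity = 1.2,
#'                      air_temperature = 50, ambient_temperature = 25,
#'                      sample_mass = 0.03, drying_time = 11)
#' specific_energy(cfg)
#' @export
specific_energy <- function(config) {
  stopifnot(inherits(config, "energy_config"))
  dT <- config$air_temperature - config$ambient_temperature
  duty_kw <- config$plate_area * config$air_velocity * config$air_density *
    config$air_specific_heat * dT
  if (config$formula_variant == "dimensional") {
    duty_kw * config$drying_time / config$sample_mass
  } else {
    duty_kw / (config$sample_mass * config$drying_time)
  }
}

#' Specific energy across a temperature schedule
#'
#' Convenience wrapper evaluating [specific_energy()] for a set of drying
#' temperatures and their run lengths under shared air/sample parameters.
#'
#' @param temperatures_C Drying temperatures, degC.
#' @param drying_times_h Drying times, hours (same length).
#' @param ... Shared [energy_config()] arguments (everything except
#'   `air_temperature` and `drying_time`).
#' @return Data frame with `temperature_C`, `drying_time_h`,
#'   `specific_energy_kwh_per_kg`.
#' @export
energy_schedule <- function(temperatures_C, drying_times_h, ...) {
  if (length(temperatures_C) != length(drying_times_h)) stopf("input lengths differ")
  e <- mapply(function(temp, tt) {
    specific_energy(energy_config(air_temperature = temp, drying_time = tt, ...))
  }, temperatures_C, drying_times_h)
  data.frame(temperature_C = temperatures_C, drying_time_h = drying_times_h,
             specific_energy_kwh_per_kg = as.numeric(e))
}
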