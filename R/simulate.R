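# Seeded generators emulating the structure of a thin-layer drying study:
# hourly-weighed 30 g slab samples at a set of air temperatures, a
# diffusivity that follows an Arrhenius law across those temperatures, and
# carotenoid retention falling with temperature. All generators are pure
# functions of their arguments and seed.

# Default run lengths (h) by temperature (degC): longer runs at milder air.
DEFAULT_DRYING_HOURS <- c("50" = 11, "55" = 10, "60" = 9, "65" = 8,
                          "70" = 7, "75" = 6)

default_time_grid <- function(temperature) {
  key <- as.character(temperature)
  hours <- if (key %in% names(DEFAULT_DRYING_HOURS)) {
    DEFAULT_DRYING_HOURS[[key]]
  } else 8
  seq(0, hours)
}

#' Generate a synthetic drying curve
#'
#' Simulates an hourly-weighed drying experiment: the true moisture ratio
#' comes from a registered thin-layer model (or the Fick slab series),
#' additive Gaussian measurement noise is applied on the MR scale at t > 0
#' (truncated at 0), and the series is converted to sample masses through
#' the initial mass and initial wet-basis moisture.
#'
#' @param truth_model Name of a registered thin-layer model, or `"fick"`
#'   for the slab-diffusion series.
#' @param truth_params Named parameters: for a thin-layer model the model's
#'   parameter vector (rates in 1/h); for `"fick"`, `c(d_eff = , )` in
#'   m^2/s (the slab half-thickness comes from `slab_thickness`).
#' @param time_grid_h Observation times, hours (default: hourly grid whose
#'   length follows the temperature, 6-11 h over 75-50 degC).
#' @param noise_sd Additive MR noise standard deviation (default 0.01, the
#'   scale of balance error relative to the dry mass).
#' @param seed RNG seed; the same seed reproduces the curve exactly.
#' @param temperature Nominal drying temperature, degC (default 60).
#' @param slab_thickness Slab thickness, m (default 0.01).
#' @param initial_mass_g Initial sample mass, g (default 30).
#' @param initial_wet_basis Initial wet-basis moisture, percent (default
#'   82.63).
#' @param replicate_id Replicate label (default "R1").
#' @return A [drying_curve()] with the true model and parameters attached
#'   as attributes `truth_model` and `truth_params`.
#' @export
gen_drying_curve <- function(truth_model = "newton",
                             truth_params = c(k = 0.6),
                             time_grid_h = NULL, noise_sd = 0.01, seed = 1L,
                             temperature = 60, slab_thickness = 0.01,
                             initial_mass_g = 30, initial_wet_basis = 82.63,
                             replicate_id = "R1") {
  if (!is_number(noise_sd) || noise_sd < 0) stopf("`noise_sd` must be nonnegative")
  if (is.null(time_grid_h)) time_grid_h <- default_time_grid(temperature)
  mr_true <- true_mr(truth_model, truth_params, time_grid_h, slab_thickness)
  mr <- mr_true
  if (noise_sd > 0) {
    noise <- with_seed(seed, stats::rnorm(length(mr) - 1L, sd = noise_sd))
    mr[-1] <- pmax(mr[-1] + noise, 0)
  }
  m0_db <- wet_to_dry_basis(initial_wet_basis)
  ms <- initial_mass_g * (1 - initial_wet_basis / 100)
  mass <- ms * (1 + mr * m0_db)
  curve <- drying_curve(time_h = time_grid_h, mass_g = mass,
                        temperature = temperature,
                        slab_thickness = slab_thickness,
                        dry_solid_mass = ms, replicate_id = replicate_id)
  attr(curve, "truth_model") <- truth_model
  attr(curve, "truth_params") <- truth_params
  curve
}

true_mr <- function(truth_model, truth_params, time_grid_h, slab_thickness) {
  if (identical(truth_model, "fick")) {
    fick_mr(time_grid_h * 3600, d_eff = truth_params[["d_eff"]],
            half_thickness = slab_thickness / 2)
  } else {
    evaluate_model(truth_model, truth_params, time_grid_h)
  }
}

#' Generate a multi-temperature drying study under an Arrhenius law
#'
#' Draws the per-temperature effective diffusivity from
#' `Deff(T) = D0 exp(-Ea / (R T))`, generates each temperature's
#' moisture-ratio series from the first-term slab solution at t > 0
#' (MR(0) = 1), and adds optional MR noise. Running [estimate_deff()] (fixed
#' intercept) and [fit_arrhenius()] on the noise-free output recovers
#' `(D0, Ea)` exactly.
#'
#' @param d0 Pre-exponential factor, m^2/s.
#' @param e_a Activation energy, J/mol.
#' @param temperatures Drying temperatures, degC (>= 2).
#' @param half_thickness Slab half-thickness L/2, m (default 0.005).
#' @param time_grids_h Optional list of hour grids, one per temperature
#'   (default per-temperature hourly grids).
#' @param noise_sd Additive MR noise at t > 0 (default 0).
#' @param seed RNG seed.
#' @return A list of class `study_set`: `series` (one [mr_series()] per
#'   temperature), `d_eff_true` (named by temperature), `d0`, `e_a`.
#' @export
gen_multi_temperature_study <- function(d0, e_a,
                                        temperatures = seq(50, 75, by = 5),
                                        half_thickness = 0.005,
                                        time_grids_h = NULL, noise_sd = 0,
                                        seed = 1L) {
  if (length(temperatures) < 2L) stopf("at least 2 temperatures are required")
  if (!is_number(d0) || d0 <= 0) stopf("`d0` must be positive")
  d_eff <- d0 * exp(-e_a / (GAS_CONSTANT * (temperatures + 273.15)))
  if (is.null(time_grids_h)) time_grids_h <- lapply(temperatures, default_time_grid)
  series <- vector("list", length(temperatures))
  for (i in seq_along(temperatures)) {
    t_h <- time_grids_h[[i]]
    mr <- fick_mr_first_term(t_h * 3600, d_eff[i], half_thickness)
    mr[t_h == 0] <- 1   # physical initial state; the regression uses t > 0
    if (noise_sd > 0) {
      noise <- with_seed(seed + i, stats::rnorm(sum(t_h > 0), sd = noise_sd))
      mr[t_h > 0] <- pmax(mr[t_h > 0] + noise, 0)
    }
    series[[i]] <- mr_series(time_s = t_h * 3600, mr = pmin(mr, 1.02),
                             temperature = temperatures[i],
                             slab_thickness = 2 * half_thickness)
  }
  structure(list(series = series,
                 d_eff_true = stats::setNames(d_eff, temperatures),
                 d0 = d0, e_a = e_a, temperatures = temperatures),
            class = "study_set")
}

#' Generate a synthetic carotenoid concentration series
#'
#' Concentrations are `c_ref * y(T)` for a registered retention form plus
#' optional Gaussian noise, truncated positive.
#'
#' @param form `"logistic"` or `"exponential"` (see [fit_degradation()]).
#' @param params Named shape parameters for the form plus `c_ref`
#'   (mg/100 g), e.g. `c(s = 0.08, t_mid = 72, c_ref = 100)`.
#' @param temperatures Temperatures, degC, strictly increasing.
#' @param noise_sd Concentration noise SD, mg/100 g (default 0).
#' @param seed RNG seed.
#' @param compound Label (default "lycopene").
#' @return A [carotenoid_series()].
#' @export
gen_carotenoid_series <- function(form = "logistic",
                                  params = c(s = 0.08, t_mid = 72, c_ref = 100),
                                  temperatures = seq(50, 75, by = 5),
                                  noise_sd = 0, seed = 1L,
                                  compound = "lycopene") {
  spec <- retention_forms()[[form]]
  if (is.null(spec)) stopf("unknown retention form '%s'", form)
  conc <- params[["c_ref"]] * spec$y(temperatures, params)
  if (noise_sd > 0) {
    conc <- with_seed(seed, pmax(conc + stats::rnorm(length(conc), sd = noise_sd),
                                 1e-6))
  }
  carotenoid_series(temperatures, conc, compound = compound)
}
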