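# Shared fixtures: printed constants from the bundled tomato-peel drying
# study, and small generators used across tests.

study_deff <- function() {
  utils::read.csv(thinlayer_example("tomato_peel_deff.csv"))
}

study_constants <- function(model = NULL, temperature = NULL) {
  df <- utils::read.csv(thinlayer_example("tomato_peel_model_constants.csv"))
  if (!is.null(model)) df <- df[df$model == model, , drop = FALSE]
  if (!is.null(temperature)) df <- df[df$temperature_C == temperature, , drop = FALSE]
  df
}

# Named parameter vector for one model at one temperature of the bundled study.
study_params <- function(model, temperature) {
  df <- study_constants(model, temperature)
  stats::setNames(df$value, df$param)
}

study_carotenoids <- function() {
  read_carotenoid_csv(thinlayer_example("tomato_peel_carotenoids.csv"))
}

# Noise-free moisture-ratio series holding a model's raw output (the value
# at t = 0 is the model's own intercept, not renormalized to 1).
model_series <- function(model, theta, hours = 0:11, temperature = 60,
                         slab_thickness = 0.01) {
  mr <- evaluate_model(model, theta, hours)
  mr_series(time_s = hours * 3600, mr = mr, temperature = temperature,
            slab_thickness = slab_thickness, normalized = FALSE)
}

# Realistic truth parameters for every registered model (rates in 1/h),
# used in round-trip recovery tests.
recovery_truth <- function() {
  list(
    fick_first_term = c(k = 0.6),
    newton = c(k = 0.6),
    page = c(k = 0.5854, n = 0.8494),
    modified_page = c(k = 0.5324, n = 0.8494),
    henderson_pabis = c(a = 0.9817, k = 0.5002),
    modified_henderson_pabis = c(a = 0.2, k = 0.15, b = 0.5, g = 0.8, c = 0.3, h = 2.0),
    midili = c(a = 1.0004, k = 0.8943, n = 0.7594, b = 0.0011),
    logarithmic = c(a = 0.9652, k = 0.5522, b = 0.0276),
    two_term = c(a = 0.3408, k1 = 0.3562, b = 0.6593, k2 = 1.3215),
    two_term_exponential = c(a = 0.3668, k = 1.0225)
  )
}
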