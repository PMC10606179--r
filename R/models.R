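# Registry of classical thin-layer drying models.
#
# All models express the dimensionless moisture ratio MR as a closed form in
# drying time. Time is in hours and rate constants in 1/h at this interface,
# the unit in which fitted drying constants for multi-hour runs have
# magnitudes near 1. Empirical constants a, b, c, n are dimensionless.
#
#   fick_first_term   MR = (8/pi^2) exp(-k t)         (k = pi^2 Deff / (4 (L/2)^2))
#   newton            MR = exp(-k t)
#   page              MR = exp(-k t^n)
#   modified_page     MR = exp(-(k t)^n)
#   henderson_pabis   MR = a exp(-k t)
#   modified_henderson_pabis  MR = a exp(-k t) + b exp(-g t) + c exp(-h t)
#   midili            MR = a exp(-k t^n) + b t
#   logarithmic       MR = a exp(-k t) + b
#   two_term          MR = a exp(-k1 t) + b exp(-k2 t)
#   two_term_exponential      MR = a exp(-k t) + (1 - a) exp(-k a t)

RATE_BOUNDS <- c(1e-4, 50)     # 1/h
COEF_BOUNDS <- c(-2, 2)        # a, b, c
EXPONENT_BOUNDS <- c(0.1, 5)   # n

model_spec <- function(name, parameter_names, lower, upper, fn, init) {
  structure(list(name = name, parameter_names = parameter_names,
                 lower = stats::setNames(lower, parameter_names),
                 upper = stats::setNames(upper, parameter_names),
                 arity = length(parameter_names), fn = fn, init = init),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Thin-layer model '%s' (%d parameter%s: %s)\n", x$name, x$arity,
              if (x$arity > 1) "s" else "", paste(x$parameter_names, collapse = ", ")))
  invisible(x)
}

# A crude single-exponential rate from the series midpoint; the anchor all
# initializers build on.
init_rate <- function(series) {
  t_h <- series$time_s / 3600
  mr <- series$mr
  usable <- t_h > 0 & mr > 0 & mr < 1
  if (!any(usable)) return(0.5)
  i <- which(usable)[ceiling(sum(usable) / 2)]
  k <- -log(mr[i]) / t_h[i]
  min(max(k, RATE_BOUNDS[1] * 10), RATE_BOUNDS[2] / 10)
}

build_registry <- function() {
  reg <- list(
    fick_first_term = model_spec(
      "fick_first_term", "k", RATE_BOUNDS[1], RATE_BOUNDS[2],
      function(t, p) 8 / pi^2 * exp(-p[["k"]] * t),
      function(series) c(k = init_rate(series))),
    newton = model_spec(
      "newton", "k", RATE_BOUNDS[1], RATE_BOUNDS[2],
      function(t, p) exp(-p[["k"]] * t),
      function(series) c(k = init_rate(series))),
    page = model_spec(
      "page", c("k", "n"),
      c(RATE_BOUNDS[1], EXPONENT_BOUNDS[1]), c(RATE_BOUNDS[2], EXPONENT_BOUNDS[2]),
      function(t, p) exp(-p[["k"]] * t^p[["n"]]),
      function(series) c(k = init_rate(series), n = 1)),
    modified_page = model_spec(
      "modified_page", c("k", "n"),
      c(RATE_BOUNDS[1], EXPONENT_BOUNDS[1]), c(RATE_BOUNDS[2], EXPONENT_BOUNDS[2]),
      function(t, p) exp(-(p[["k"]] * t)^p[["n"]]),
      function(series) c(k = init_rate(series), n = 1)),
    henderson_pabis = model_spec(
      "henderson_pabis", c("a", "k"),
      c(COEF_BOUNDS[1], RATE_BOUNDS[1]), c(COEF_BOUNDS[2], RATE_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k"]] * t),
      function(series) c(a = 1, k = init_rate(series))),
    modified_henderson_pabis = model_spec(
      "modified_henderson_pabis", c("a", "k", "b", "g", "c", "h"),
      c(COEF_BOUNDS[1], RATE_BOUNDS[1], COEF_BOUNDS[1], RATE_BOUNDS[1],
        COEF_BOUNDS[1], RATE_BOUNDS[1]),
      c(COEF_BOUNDS[2], RATE_BOUNDS[2], COEF_BOUNDS[2], RATE_BOUNDS[2],
        COEF_BOUNDS[2], RATE_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["b"]] * exp(-p[["g"]] * t) +
        p[["c"]] * exp(-p[["h"]] * t),
      function(series) {
        k <- init_rate(series)
        c(a = 1 / 3, k = k / 2, b = 1 / 3, g = k, c = 1 / 3, h = 2 * k)
      }),
    midili = model_spec(
      "midili", c("a", "k", "n", "b"),
      c(COEF_BOUNDS[1], RATE_BOUNDS[1], EXPONENT_BOUNDS[1], COEF_BOUNDS[1]),
      c(COEF_BOUNDS[2], RATE_BOUNDS[2], EXPONENT_BOUNDS[2], COEF_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k"]] * t^p[["n"]]) + p[["b"]] * t,
      function(series) c(a = 1, k = init_rate(series), n = 1, b = 0)),
    logarithmic = model_spec(
      "logarithmic", c("a", "k", "b"),
      c(COEF_BOUNDS[1], RATE_BOUNDS[1], COEF_BOUNDS[1]),
      c(COEF_BOUNDS[2], RATE_BOUNDS[2], COEF_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k"]] * t) + p[["b"]],
      function(series) c(a = 1, k = init_rate(series), b = 0)),
    two_term = model_spec(
      "two_term", c("a", "k1", "b", "k2"),
      c(COEF_BOUNDS[1], RATE_BOUNDS[1], COEF_BOUNDS[1], RATE_BOUNDS[1]),
      c(COEF_BOUNDS[2], RATE_BOUNDS[2], COEF_BOUNDS[2], RATE_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k1"]] * t) + p[["b"]] * exp(-p[["k2"]] * t),
      function(series) {
        k <- init_rate(series)
        c(a = 0.5, k1 = k / 2, b = 0.5, k2 = 2 * k)
      }),
    two_term_exponential = model_spec(
      "two_term_exponential", c("a", "k"),
      c(0.01, RATE_BOUNDS[1]), c(COEF_BOUNDS[2], RATE_BOUNDS[2]),
      function(t, p) p[["a"]] * exp(-p[["k"]] * t) +
        (1 - p[["a"]]) * exp(-p[["k"]] * p[["a"]] * t),
      function(series) c(a = 0.5, k = 2 * init_rate(series)))
  )
  reg
}

.registry <- new.env(parent = emptyenv())

#' Registry of thin-layer drying models
#'
#' Returns the ten classical thin-layer models with their parameter names,
#' default bounds and deterministic initialization heuristics. Rate
#' constants are in 1/h; model formulas are listed in the package vignette.
#'
#' @return Named list of `model_spec` objects.
#' @export
thin_layer_models <- function() {
  if (is.null(.registry$models)) .registry$models <- build_registry()
  .registry$models
}

#' Look up a thin-layer model by name
#'
#' @param name One of the registered model names (see [thin_layer_models()]).
#' @return The `model_spec`.
#' @export
lookup_model <- function(name) {
  reg <- thin_layer_models()
  if (!is.character(name) || length(name) != 1L || !name %in% names(reg)) {
    stopf("unknown model '%s'; valid names: %s",
          paste(name, collapse = ","), paste(names(reg), collapse = ", "))
  }
  reg[[name]]
}

#' Evaluate a thin-layer model
#'
#' @param model A `model_spec` or a model name.
#' @param theta Named (or positionally ordered) numeric parameter vector
#'   whose length matches the model's arity. Rates in 1/h.
#' @param t_h Drying times in hours (vectorized).
#' @return Predicted moisture ratios.
#' @examples
#' evaluate_model("newton", c(k = 0.6), t_h = 0:11)
#' @export
evaluate_model <- function(model, theta, t_h) {
  if (is.character(model)) model <- lookup_model(model)
  stopifnot(inherits(model, "model_spec"))
  if (length(theta) != model$arity) {
    stopf("model '%s' takes %d parameter(s) (%s); got %d", model$name,
          model$arity, paste(model$parameter_names, collapse = ", "), length(theta))
  }
  if (is.null(names(theta)) || !all(model$parameter_names %in% names(theta))) {
    names(theta) <- model$parameter_names
  }
  model$fn(t_h, theta)
}

#' Convert a Page rate constant to the Modified Page parameterization
#'
#' The Page model `exp(-k t^n)` and the Modified Page model `exp(-(k' t)^n)`
#' describe the same curve family; for the same `n`, `k' = k^(1/n)`.
#'
#' @param k_page Page rate constant (> 0), 1/h.
#' @param n Shared Page exponent (> 0).
#' @return The equivalent Modified Page rate constant `k^(1/n)`, 1/h.
#' @examples
#' page_to_modified_page(0.5854, 0.8494) # 0.5324
#' @export
page_to_modified_page <- function(k_page, n) {
  if (!is.numeric(k_page) || !is.numeric(n) || any(k_page <= 0) || any(n <= 0)) {
    stopf("`k_page` and `n` must be positive")
  }
  k_page^(1 / n)
}

#' Convert a rate constant between per-hour and per-second units
#'
#' @param k Rate constant(s).
#' @param from,to `"per_hour"` or `"per_second"`.
#' @return Converted rate constant(s).
#' @export
convert_rate <- function(k, from = "per_hour", to = "per_second") {
  units <- c(per_hour = 1 / 3600, per_second = 1)
  if (!from %in% names(units) || !to %in% names(units)) {
    stopf("units must be 'per_hour' or 'per_second'")
  }
  k * units[[from]] / units[[to]]
}
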