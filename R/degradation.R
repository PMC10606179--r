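# Thermal degradation of carotenoids with drying temperature.
#
# Measured concentrations C(T) (mg per 100 g dried material) are modeled as
# C_ref * y(T), where the retention y is a smooth non-increasing function of
# drying temperature and C_ref is a fitted undegraded baseline. Two
# retention forms are registered:
#
#   logistic:     y(T) = 1 / (1 + exp(s * (T - T_m))),  s > 0
#   exponential:  y(T) = exp(-b * max(T - T_0, 0)^p),   b > 0, p >= 1
#
# Both start near 1 at mild temperatures and fall off steeply above a
# threshold, the slow-then-fast pattern carotenoid losses show.

#' Construct a carotenoid concentration-temperature series
#'
#' @param temperatures Drying temperatures, degC, strictly increasing.
#' @param concentrations Concentrations, mg per 100 g dried material (> 0).
#' @param compound Label: `"lycopene"`, `"beta_carotene"` or another string.
#' @param sd Optional standard deviations (replicate spread), same length.
#' @return An object of class `carotenoid_series`.
#' @export
carotenoid_series <- function(temperatures, concentrations,
                              compound = "lycopene", sd = NULL) {
  if (length(temperatures) != length(concentrations)) stopf("input lengths differ")
  if (any(diff(temperatures) <= 0)) stopf("temperatures must be strictly increasing")
  if (any(concentrations <= 0)) stopf("concentrations must be positive")
  if (!is.null(sd) && (length(sd) != length(temperatures) || any(sd < 0))) {
    stopf("`sd` must be nonnegative and match the series length")
  }
  structure(list(temperatures = as.numeric(temperatures),
                 concentrations = as.numeric(concentrations),
                 compound = as.character(compound), sd = sd),
            class = "carotenoid_series")
}

#' @export
print.carotenoid_series <- function(x, ...) {
  cat(sprintf("%s: %d temperatures (%g-%g degC), %.1f-%.1f mg/100 g\n",
              x$compound, length(x$temperatures), min(x$temperatures),
              max(x$temperatures), min(x$concentrations), max(x$concentrations)))
  invisible(x)
}

#' Degradation percentage relative to a reference concentration
#'
#' @param c_ref Reference (baseline) concentration (> 0), typically the
#'   lowest-temperature value.
#' @param c Concentration(s) at the condition of interest (>= 0).
#' @param round_percent Round to whole percent (default FALSE).
#' @return `100 * (c_ref - c) / c_ref`. A concentration above the reference
#'   yields a negative value (apparent gain) with a warning, never a silent
#'   clamp.
#' @examples
#' degradation_percent(95.56, 31.16, round_percent = TRUE) # 67
#' @export
degradation_percent <- function(c_ref, c, round_percent = FALSE) {
  if (!is_number(c_ref) || c_ref <= 0) stopf("`c_ref` must be a single positive number")
  if (!is.numeric(c) || any(c < 0)) stopf("`c` must be nonnegative")
  out <- 100 * (c_ref - c) / c_ref
  if (any(out < 0)) warnf("concentration above the reference: apparent gain reported as negative degradation")
  if (round_percent) round(out) else out
}

retention_forms <- function() {
  list(
    logistic = list(
      shape_names = c("s", "t_mid"),
      lower = c(s = 1e-4, t_mid = 0), upper = c(s = 2, t_mid = 300),
      y = function(T, p) 1 / (1 + exp(p[["s"]] * (T - p[["t_mid"]]))),
      init = function(T, conc) c(s = 0.08, t_mid = stats::median(T) + 10)),
    exponential = list(
      shape_names = c("b", "t_onset", "p"),
      lower = c(b = 1e-8, t_onset = 0, p = 1),
      upper = c(b = 1, t_onset = NA, p = 5),  # t_onset upper set per series
      y = function(T, p) exp(-p[["b"]] * pmax(T - p[["t_onset"]], 0)^p[["p"]]),
      init = function(T, conc) c(b = 0.005, t_onset = min(T), p = 2))
  )
}

# Deterministic starting points for a retention fit. The exponential form
# has a kink at the onset temperature that gives local search a flat
# direction below it, so the onset and exponent are swept over a small grid.
degradation_starts <- function(form, spec, T, conc) {
  base <- spec$init(T, conc)
  starts <- list(base)
  if (form == "logistic") {
    for (s in c(0.04, 0.15)) {
      for (tm in stats::quantile(T, c(0.5, 0.9), names = FALSE)) {
        th <- base; th[["s"]] <- s; th[["t_mid"]] <- tm
        starts[[length(starts) + 1L]] <- th
      }
    }
  } else {
    for (t0 in stats::quantile(T, c(0, 0.25, 0.5), names = FALSE)) {
      for (p in c(1, 1.5, 2.5)) {
        th <- base; th[["t_onset"]] <- t0; th[["p"]] <- p
        starts[[length(starts) + 1L]] <- th
      }
    }
  }
  unique(starts)
}

#' Fit a retention model to a carotenoid series
#'
#' Fits `C(T) = C_ref * y(T)` by bounded Levenberg-Marquardt least squares
#' on the concentration scale (residuals normalized by the
#' lowest-temperature concentration, so the fit is scale invariant), with
#' the baseline `C_ref` a fitted parameter initialized at the
#' lowest-temperature concentration. Goodness-of-fit statistics are
#' reported on the retention scale `y = C / C_ref`.
#'
#' @param series A [carotenoid_series()] with at least 4 points.
#' @param form `"logistic"` (default) or `"exponential"`.
#' @return An object of class `degradation_fit`: `form`, `params` (named:
#'   shape parameters and `c_ref`), `reference_concentration`,
#'   `r_squared`, `chi_squared`, `rmse` (retention scale), `converged`,
#'   `near_degenerate` (TRUE when a shape parameter sits on a bound),
#'   `fitted_range` (degC).
#' @export
fit_degradation <- function(series, form = c("logistic", "exponential")) {
  stopifnot(inherits(series, "carotenoid_series"))
  form <- match.arg(form)
  T <- series$temperatures
  conc <- series$concentrations
  if (length(T) < 4L) stopf("at least 4 points are required; got %d", length(T))
  spec <- retention_forms()[[form]]
  if (form == "exponential") spec$upper[["t_onset"]] <- max(T)
  c0 <- conc[1]
  lower <- c(spec$lower, c_ref = 0.2 * max(conc))
  upper <- c(spec$upper, c_ref = 10 * max(conc))
  par_names <- c(spec$shape_names, "c_ref")
  # residuals on the concentration scale, normalized by the first (baseline)
  # observation: scale-invariant, but not shrinkable by inflating c_ref the
  # way retention-scale residuals conc/c_ref - y would be
  resid_fn <- function(p) {
    names(p) <- par_names
    (conc - p[["c_ref"]] * spec$y(T, p)) / c0
  }
  best <- NULL
  converged <- FALSE
  for (start in degradation_starts(form, spec, T, conc)) {
    par0 <- pmin(pmax(c(start, c_ref = c0), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-12, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(par = fit$par, sse = sse, ok = fit$info %in% 1:4)
    }
    converged <- converged || fit$info %in% 1:4
  }
  if (is.null(best)) stopf("retention fit failed for form '%s'", form)
  par_hat <- stats::setNames(best$par, par_names)
  shape <- par_hat[spec$shape_names]
  on_bound <- any(abs(shape - spec$lower[spec$shape_names]) < 1e-8) ||
    any(abs(shape - spec$upper[spec$shape_names]) < 1e-8)
  y_exp <- conc / par_hat[["c_ref"]]
  y_pred <- spec$y(T, par_hat)
  gof <- gof_stats(y_exp, y_pred, n_params = length(par_hat))
  structure(list(form = form, params = par_hat,
                 reference_concentration = par_hat[["c_ref"]],
                 r_squared = gof$r_squared, chi_squared = gof$chi_squared,
                 rmse = gof$rmse, converged = converged,
                 near_degenerate = on_bound,
                 fitted_range = range(T), compound = series$compound),
            class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  pars <- paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", ")
  cat(sprintf("%s retention fit for %s: %s\n  R^2 = %.4f, RMSE = %.4f (retention scale)%s\n",
              x$form, x$compound, pars, x$r_squared, x$rmse,
              if (x$near_degenerate) "  [near-degenerate]" else ""))
  invisible(x)
}

#' Predict carotenoid concentration from a retention fit
#'
#' @param object A [fit_degradation()] result.
#' @param temperature Temperature(s), degC.
#' @param ... Unused.
#' @return Data frame with `temperature_C`, `concentration` (mg/100 g,
#'   `C_ref * y(T)`), `retention` and `extrapolated` (TRUE outside the
#'   fitted temperature range).
#' @examples
#' \dontrun{predict(fit, temperature = 110)}
#' @export
predict.degradation_fit <- function(object, temperature, ...) {
  if (!object$converged) warnf("predicting from a non-converged retention fit")
  spec <- retention_forms()[[object$form]]
  y <- spec$y(temperature, object$params)
  data.frame(temperature_C = temperature,
             concentration = object$reference_concentration * y,
             retention = as.numeric(y),
             extrapolated = temperature < object$fitted_range[1] |
               temperature > object$fitted_range[2])
}
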