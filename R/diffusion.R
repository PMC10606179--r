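# Fick's second law for an infinite slab drying through both faces.
#
# With uniform initial moisture, a zero-flux midplane and the surface held at
# the equilibrium moisture, the thickness-averaged moisture ratio is
#
#   MR(t) = (8/pi^2) * sum_{j>=0} (2j+1)^-2 * exp(-(2j+1)^2 pi^2 Deff t / (4 (L/2)^2))
#
# For Fourier numbers Fo = Deff t / (L/2)^2 above about 0.2 the first term
# dominates, and ln(MR) is linear in t with intercept ln(8/pi^2); the slope
# of that line yields the effective diffusivity Deff.

#' Universal gas constant (J mol^-1 K^-1)
#' @export
GAS_CONSTANT <- 8.3145

#' Slab-diffusion moisture ratio (Fourier series)
#'
#' Thickness-averaged moisture ratio of an infinite slab drying through both
#' faces, from the separation-of-variables series solution of the diffusion
#' equation.
#'
#' @param t Time since the start of drying, seconds (vectorized, `>= 0`).
#' @param d_eff Effective moisture diffusivity, m^2/s (> 0).
#' @param half_thickness Slab half-thickness L/2, metres (> 0).
#' @param n_terms Number of series terms (>= 1). The series converges fast
#'   for `Fo > 0.05`; 50 terms are ample for any practical time.
#' @return Moisture ratio values in `(0, 1]`, decreasing in `t`.
#' @examples
#' fick_mr(3600, d_eff = 1.0074e-9, half_thickness = 0.005)
#' @export
fick_mr <- function(t, d_eff, half_thickness, n_terms = 50L) {
  check_fick_params(d_eff, half_thickness)
  if (!is.numeric(n_terms) || n_terms < 1) stopf("`n_terms` must be >= 1")
  if (any(t < 0)) stopf("time must be nonnegative")
  j <- seq_len(n_terms) - 1L
  odd <- 2 * j + 1
  rate <- pi^2 * d_eff / (4 * half_thickness^2)
  # outer(t, odd^2): rows = times, cols = series terms
  s <- exp(-outer(t, odd^2) * rate) %*% (1 / odd^2)
  as.numeric(8 / pi^2 * s)
}

#' First-term truncation of the slab-diffusion series
#'
#' `MR = (8/pi^2) exp(-pi^2 Deff t / (4 (L/2)^2))`. Accurate within 0.5
#' percent of the full series for Fourier numbers above 0.2 (long drying
#' times), which is the regime the linearized diffusivity regression uses.
#'
#' @inheritParams fick_mr
#' @return Moisture ratio values.
#' @export
fick_mr_first_term <- function(t, d_eff, half_thickness) {
  fick_mr(t, d_eff, half_thickness, n_terms = 1L)
}

check_fick_params <- function(d_eff, half_thickness) {
  if (!is_number(d_eff) || d_eff <= 0) stopf("`d_eff` must be a positive diffusivity (m^2/s)")
  if (!is_number(half_thickness) || half_thickness <= 0) {
    stopf("`half_thickness` must be a positive length (m)")
  }
  invisible(TRUE)
}

#' Estimate the effective moisture diffusivity from a drying curve
#'
#' Regresses `ln(MR)` on time over the usable points (t > 0 and MR > 0) and
#' converts the slope to a diffusivity via the first-term slab solution:
#' `Deff = -slope * 4 * (L/2)^2 / pi^2`. By default the intercept is fixed
#' at its theoretical value `ln(8/pi^2)` and only the slope is estimated;
#' `intercept_mode = "free"` estimates both (diagnostic use).
#'
#' @param series An [mr_series()].
#' @param intercept_mode `"fixed"` (intercept pinned at `ln(8/pi^2)`,
#'   default) or `"free"` (ordinary two-parameter regression).
#' @param min_fourier Drop usable points below this Fourier number before
#'   regressing (default 0: use all). The first-term model is biased at small
#'   Fo, so restricting to `Fo > 0.2` reduces truncation bias when early
#'   times dominate the data.
#' @return An object of class `deff_estimate` with elements `slope` (1/s),
#'   `intercept`, `d_eff` (m^2/s), `r_squared`, `chi_squared`, `rmse`
#'   (all on the ln(MR) scale), `n_points`, `intercept_mode` and
#'   `non_physical` (TRUE when the slope is nonnegative).
#' @export
estimate_deff <- function(series, intercept_mode = c("fixed", "free"),
                          min_fourier = 0) {
  stopifnot(inherits(series, "mr_series"))
  intercept_mode <- match.arg(intercept_mode)
  lh <- series$slab_thickness / 2
  usable <- series$time_s > 0 & series$mr > 0
  n_dropped <- sum(!usable) - 1L  # t = 0 is dropped by design
  t <- series$time_s[usable]
  y <- log(series$mr[usable])
  if (min_fourier > 0 && length(t) >= 3L) {
    # provisional slope fixes the Fo scale for the cutoff
    b0 <- sum(t * (y - log(8 / pi^2))) / sum(t^2)
    if (b0 < 0) {
      d0 <- -b0 * 4 * lh^2 / pi^2
      keep <- d0 * t / lh^2 >= min_fourier
      if (sum(keep) >= 3L) { t <- t[keep]; y <- y[keep] }
    }
  }
  n <- length(t)
  if (n < 3L) stopf("at least 3 usable points (t > 0, MR > 0) are required; got %d", n)
  if (n_dropped > 0L) {
    message(sprintf("estimate_deff: %d point(s) with MR <= 0 excluded", n_dropped))
  }
  if (intercept_mode == "fixed") {
    c0 <- log(8 / pi^2)
    slope <- sum(t * (y - c0)) / sum(t^2)
    pred <- c0 + slope * t
    n_par <- 1L
    intercept <- c0
  } else {
    fit <- stats::lm(y ~ t)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    pred <- unname(stats::fitted(fit))
    n_par <- 2L
  }
  non_physical <- slope >= 0
  if (non_physical) warnf("nonnegative ln(MR) slope: no drying signal; Deff not physical")
  gof <- gof_stats(y, pred, n_params = n_par)
  structure(list(slope = slope, intercept = intercept,
                 d_eff = -slope * 4 * lh^2 / pi^2,
                 r_squared = gof$r_squared, chi_squared = gof$chi_squared,
                 rmse = gof$rmse, n_points = n,
                 intercept_mode = intercept_mode,
                 temperature = series$temperature,
                 slab_thickness = series$slab_thickness,
                 non_physical = non_physical),
            class = "deff_estimate")
}

#' @export
print.deff_estimate <- function(x, ...) {
  cat(sprintf("Deff estimate at %g degC: %.4g m^2/s (slope %.4g 1/s, %s intercept, R^2 %.4f)\n",
              x$temperature, x$d_eff, x$slope, x$intercept_mode, x$r_squared))
  if (x$non_physical) cat("  WARNING: non-physical (nonnegative slope)\n")
  invisible(x)
}

#' Arrhenius fit of diffusivity against temperature
#'
#' Fits `ln(Deff) = ln(D0) - Ea / (R T)` by ordinary least squares of
#' `ln(Deff)` on `1/T` (T in kelvin), giving the activation energy
#' `Ea = -slope * R` and pre-exponential factor `D0 = exp(intercept)`.
#'
#' @param temperature_C Drying temperatures, degrees Celsius (>= 3 distinct
#'   values).
#' @param d_eff Effective diffusivities at those temperatures, m^2/s (> 0).
#' @return An object of class `arrhenius_fit` with `d0` (m^2/s), `e_a`
#'   (J/mol), `r_squared`, `chi_squared`, `rmse` (on the ln scale, chi^2
#'   denominator N - 2) and `gas_constant`.
#' @examples
#' deff <- c(1.0074, 1.0226, 1.1642, 1.2441, 1.3712, 1.5350) * 1e-9
#' fit <- fit_arrhenius(seq(50, 75, by = 5), deff)
#' fit$e_a / 1000  # activation energy in kJ/mol
#' @export
fit_arrhenius <- function(temperature_C, d_eff) {
  if (length(temperature_C) != length(d_eff)) stopf("input lengths differ")
  if (anyDuplicated(temperature_C)) stopf("duplicate temperatures are not allowed")
  if (length(d_eff) < 3L) stopf("at least 3 temperature points are required")
  if (any(d_eff <= 0)) stopf("all diffusivities must be positive")
  inv_T <- 1 / (temperature_C + 273.15)
  y <- log(d_eff)
  fit <- stats::lm(y ~ inv_T)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  gof <- gof_stats(y, unname(stats::fitted(fit)), n_params = 2L)
  structure(list(d0 = exp(intercept), e_a = -slope * GAS_CONSTANT,
                 slope = slope, intercept = intercept,
                 r_squared = gof$r_squared, chi_squared = gof$chi_squared,
                 rmse = gof$rmse, n_points = length(y),
                 gas_constant = GAS_CONSTANT),
            class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("Arrhenius fit (%d temperatures): Ea = %.2f kJ/mol, D0 = %.4g m^2/s, R^2 = %.4f\n",
              x$n_points, x$e_a / 1000, x$d0, x$r_squared))
  invisible(x)
}

#' Predict diffusivity from an Arrhenius fit
#'
#' @param object An [fit_arrhenius()] result.
#' @param temperature_C Temperatures (degC) at which to predict.
#' @param ... Unused.
#' @return Predicted diffusivities, m^2/s.
#' @export
predict.arrhenius_fit <- function(object, temperature_C, ...) {
  object$d0 * exp(-object$e_a / (object$gas_constant * (temperature_C + 273.15)))
}

#' Finite-difference solution of slab drying
#'
#' Solves the one-dimensional diffusion equation
#' `dMR/dt = Deff d^2MR/dz^2` on `0 <= z <= L/2` with uniform initial
#' condition `MR(z, 0) = 1`, zero flux at the midplane `z = 0` and the
#' surface held at `MR = surface_mr` (0 with negligible equilibrium
#' moisture), and returns the thickness-averaged moisture ratio. Serves as
#' an independent numerical check on the series solution [fick_mr()].
#'
#' Time stepping is implicit (unconditionally stable): Crank-Nicolson with a
#' short backward-Euler startup that damps the oscillations the initial
#' surface discontinuity would otherwise excite, or pure backward Euler.
#' The step size starts small and grows in proportion to elapsed time, so
#' the early boundary-layer transient is resolved without making long runs
#' expensive.
#'
#' @param d_eff Effective diffusivity, m^2/s.
#' @param half_thickness Slab half-thickness L/2, metres.
#' @param times Output times, seconds, sorted and nonnegative (first may be 0).
#' @param n_nodes Number of spatial nodes (>= 11; default 201).
#' @param scheme `"crank_nicolson"` (default) or `"backward_euler"`.
#' @param dt_growth Relative step-size cap: `dt <= dt_growth * t` (default
#'   0.02).
#' @param surface_mr Dirichlet value at the surface (default 0).
#' @return Numeric vector of thickness-averaged moisture ratios at `times`.
#' @export
fd_solve <- function(d_eff, half_thickness, times, n_nodes = 201L,
                     scheme = c("crank_nicolson", "backward_euler"),
                     dt_growth = 0.02, surface_mr = 0) {
  check_fick_params(d_eff, half_thickness)
  scheme <- match.arg(scheme)
  if (!is.numeric(n_nodes) || n_nodes < 11L) stopf("`n_nodes` must be >= 11")
  if (is.unsorted(times) || any(times < 0)) stopf("`times` must be sorted and nonnegative")
  if (!is_number(dt_growth) || dt_growth <= 0) stopf("`dt_growth` must be positive")
  n <- as.integer(n_nodes)
  dz <- half_thickness / (n - 1)
  tau <- half_thickness^2 / d_eff       # diffusion time scale (Fo = t / tau)
  dt_min <- 1e-6 * tau
  n_startup <- if (scheme == "crank_nicolson") 8L else 0L
  u <- rep(1, n)
  u[n] <- surface_mr
  w <- rep(dz, n); w[c(1, n)] <- dz / 2  # trapezoid weights
  w <- w / half_thickness
  out <- numeric(length(times))
  t_now <- 0
  step <- 0L
  for (i in seq_along(times)) {
    t_target <- times[i]
    while (t_now < t_target - 1e-12 * max(dt_min, t_target)) {
      dt <- min(max(dt_min, dt_growth * t_now), t_target - t_now)
      theta <- if (step < n_startup) 1 else 0.5  # Rannacher startup then CN
      r <- d_eff * dt / dz^2
      # (I - theta r A) u_new = (I + (1-theta) r A) u_old, A the Laplacian
      # with reflective (ghost-node) midplane and Dirichlet surface
      rhs <- u
      if (theta < 1) {
        s <- (1 - theta) * r
        lap <- c(2 * (u[2] - u[1]),
                 u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n])
        rhs[1:(n - 1)] <- u[1:(n - 1)] + s * lap
      }
      rhs[n] <- surface_mr
      a <- theta * r
      diag_main <- rep(1 + 2 * a, n)
      lower <- rep(-a, n - 1)
      upper <- rep(-a, n - 1)
      upper[1] <- -2 * a
      diag_main[n] <- 1; lower[n - 1] <- 0
      u <- thomas_solve(lower, diag_main, upper, rhs)
      t_now <- t_now + dt
      step <- step + 1L
    }
    out[i] <- if (t_target == 0) 1 else sum(w * u)
  }
  out
}

# Tridiagonal solver (Thomas algorithm); no pivoting, diagonally dominant here.
thomas_solve <- function(lower, diag_main, upper, rhs) {
  n <- length(diag_main)
  cp <- numeric(n - 1); dp <- numeric(n)
  cp[1] <- upper[1] / diag_main[1]
  dp[1] <- rhs[1] / diag_main[1]
  for (i in 2:n) {
    denom <- diag_main[i] - lower[i - 1] * cp[i - 1]
    if (i < n) cp[i] <- upper[i] / denom
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}
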