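# Moisture accounting for thin-layer drying experiments.
#
# Conventions: time is stored internally in seconds (I/O and model rates use
# hours); moisture is carried on a dry basis (kg water / kg dry solid); the
# moisture ratio MR = (M - Me)/(M0 - Me) is dimensionless with Me = 0 by
# default, so MR = M/M0.

#' Convert wet-basis moisture to dry-basis moisture
#'
#' Wet-basis moisture expresses water as a percentage of total sample mass;
#' dry-basis moisture expresses water mass per unit mass of dry solid.
#'
#' @param m_wb Wet-basis moisture content, percent by weight, in `[0, 100)`.
#'   Vectorized.
#' @return Dry-basis moisture (kg water / kg dry solid),
#'   `m_wb / (100 - m_wb)`.
#' @examples
#' wet_to_dry_basis(82.63) # about 4.757 kg/kg
#' wet_to_dry_basis(50)    # 1: equal water and solid mass
#' @seealso [dry_to_wet_basis()] for the inverse.
#' @export
wet_to_dry_basis <- function(m_wb) {
  if (!is.numeric(m_wb) || anyNA(m_wb)) {
    stopf("wet-basis moisture must be numeric and non-missing")
  }
  bad <- m_wb < 0 | m_wb >= 100
  if (any(bad)) {
    stopf("wet-basis moisture must lie in [0, 100): offending value(s) %s",
          paste(format(m_wb[bad]), collapse = ", "))
  }
  m_wb / (100 - m_wb)
}

#' Convert dry-basis moisture to wet-basis moisture
#'
#' @param m_db Dry-basis moisture (kg water / kg dry solid), nonnegative.
#' @return Wet-basis moisture, percent by weight: `100 * m_db / (1 + m_db)`.
#' @export
dry_to_wet_basis <- function(m_db) {
  if (!is.numeric(m_db) || anyNA(m_db) || any(m_db < 0)) {
    stopf("dry-basis moisture must be numeric and nonnegative")
  }
  100 * m_db / (1 + m_db)
}

#' Construct a drying curve
#'
#' A drying curve holds one temperature's time series of sample observations
#' from an isothermal thin-layer drying experiment, together with the slab
#' geometry and the quantities needed to resolve dry-basis moisture: either
#' the dry-solid mass directly, or the initial wet-basis moisture (from which
#' the dry-solid mass follows as `mass[1] * (1 - initial_wet_basis/100)`).
#'
#' @param time_h Observation times in hours since the start of drying,
#'   strictly increasing, first value 0.
#' @param mass_g Sample masses in grams (optional if `moisture_db` given).
#' @param moisture_db Dry-basis moistures, kg/kg (optional if `mass_g` given).
#' @param temperature Drying air temperature, degrees Celsius (> 0).
#' @param slab_thickness Slab thickness L in metres (> 0). Moisture leaves
#'   through both faces, so the diffusion half-thickness is `L/2`.
#' @param initial_wet_basis Initial wet-basis moisture, percent by weight
#'   (optional if `dry_solid_mass` given).
#' @param dry_solid_mass Mass of dry solid in the sample, grams (optional if
#'   `initial_wet_basis` given).
#' @param equilibrium_moisture Equilibrium dry-basis moisture `Me` (kg/kg),
#'   default 0: the value at infinite drying time, negligible here.
#' @param replicate_id Label for the replicate, default `"R1"`.
#' @return An object of class `drying_curve`.
#' @examples
#' tc <- drying_curve(time_h = 0:3, mass_g = c(30, 18, 11, 7),
#'                    temperature = 60, slab_thickness = 0.01,
#'                    initial_wet_basis = 82.63)
#' moisture_ratio_series(tc)
#' @export
drying_curve <- function(time_h, mass_g = NULL, moisture_db = NULL,
                         temperature, slab_thickness,
                         initial_wet_basis = NULL, dry_solid_mass = NULL,
                         equilibrium_moisture = 0, replicate_id = "R1") {
  if (!is.numeric(time_h) || length(time_h) < 2L || anyNA(time_h)) {
    stopf("`time_h` must be a numeric vector with at least 2 observations")
  }
  if (any(diff(time_h) <= 0)) stopf("observation times must be strictly increasing")
  if (time_h[1] != 0) stopf("the first observation must be at time 0")
  if (is.null(mass_g) && is.null(moisture_db)) {
    stopf("one of `mass_g` or `moisture_db` must be supplied")
  }
  n <- length(time_h)
  if (!is.null(mass_g)) {
    if (length(mass_g) != n || anyNA(mass_g) || any(mass_g <= 0)) {
      stopf("`mass_g` must be positive and match `time_h` in length")
    }
  }
  if (!is.null(moisture_db)) {
    if (length(moisture_db) != n || anyNA(moisture_db) || any(moisture_db < 0)) {
      stopf("`moisture_db` must be nonnegative and match `time_h` in length")
    }
  }
  if (!is_number(temperature) || temperature <= 0) {
    stopf("`temperature` must be a positive temperature in degrees Celsius")
  }
  if (!is_number(slab_thickness) || slab_thickness <= 0) {
    stopf("`slab_thickness` must be a positive length in metres")
  }
  if (!is.null(mass_g) && is.null(initial_wet_basis) && is.null(dry_solid_mass)) {
    stopf(paste("with masses, one of `initial_wet_basis` or `dry_solid_mass`",
                "is needed to resolve dry-basis moisture"))
  }
  if (!is.null(initial_wet_basis)) {
    if (!is_number(initial_wet_basis) || initial_wet_basis < 0 ||
        initial_wet_basis >= 100) {
      stopf("`initial_wet_basis` must lie in [0, 100) percent")
    }
  }
  if (!is.null(dry_solid_mass) &&
      (!is_number(dry_solid_mass) || dry_solid_mass <= 0)) {
    stopf("`dry_solid_mass` must be a positive mass in grams")
  }
  if (!is_number(equilibrium_moisture) || equilibrium_moisture < 0) {
    stopf("`equilibrium_moisture` must be nonnegative")
  }
  curve <- structure(
    list(time_s = time_h * 3600, mass_g = mass_g, moisture_db = moisture_db,
         temperature = temperature, slab_thickness = slab_thickness,
         initial_wet_basis = initial_wet_basis,
         dry_solid_mass = dry_solid_mass,
         equilibrium_moisture = equilibrium_moisture,
         replicate_id = as.character(replicate_id)),
    class = "drying_curve")
  m0 <- resolve_dry_basis(curve)[1]
  if (equilibrium_moisture >= m0 && m0 > 0) {
    stopf("equilibrium moisture (%g) must be below the initial dry-basis moisture (%g)",
          equilibrium_moisture, m0)
  }
  curve
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("Drying curve: %d observations over %.1f h at %g degC (L = %g m, %s)\n",
              length(x$time_s), max(x$time_s) / 3600, x$temperature,
              x$slab_thickness, x$replicate_id))
  invisible(x)
}

#' Resolve the dry-basis moisture sequence of a drying curve
#'
#' If the curve carries dry-basis moistures they are returned as-is.
#' Otherwise `M(t) = (m(t) - m_s) / m_s` with the dry-solid mass `m_s` taken
#' from the curve or derived from the initial wet-basis moisture. Small
#' negative values (balance noise, within 2 percent of `m_s`) are clipped to
#' zero with a warning; larger violations are an error.
#'
#' @param curve A [drying_curve()].
#' @return Numeric vector of dry-basis moistures (kg/kg), one per observation.
#' @export
resolve_dry_basis <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  if (!is.null(curve$moisture_db)) return(curve$moisture_db)
  m <- curve$mass_g
  ms <- curve$dry_solid_mass
  if (is.null(ms)) ms <- m[1] * (1 - curve$initial_wet_basis / 100)
  deficit <- ms - m
  bad <- deficit > 0.02 * ms
  if (any(bad)) {
    stopf("sample mass at t = %g h is below the dry-solid mass (%g g) by more than 2%%",
          curve$time_s[which(bad)[1]] / 3600, ms)
  }
  M <- (m - ms) / ms
  if (any(M < 0)) {
    warnf("%d slightly negative dry-basis moisture value(s) clipped to 0 (balance noise)",
          sum(M < 0))
    M[M < 0] <- 0
  }
  M
}

#' Moisture-ratio series of a drying curve
#'
#' Normalizes the dry-basis moisture to the dimensionless moisture ratio
#' `MR(t) = (M(t) - Me) / (M0 - Me)`, which decays from 1 toward 0 during
#' drying. With the default `Me = 0` this is `M/M0`. `MR(0) = 1` exactly by
#' construction.
#'
#' @param curve A [drying_curve()].
#' @return An object of class `mr_series`: a list with `time_s`, `mr`,
#'   `temperature` (degC) and `slab_thickness` (m).
#' @export
moisture_ratio_series <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  M <- resolve_dry_basis(curve)
  me <- curve$equilibrium_moisture
  if (M[1] <= me) stopf("initial dry-basis moisture must exceed the equilibrium moisture")
  mr <- (M - me) / (M[1] - me)
  mr_series(time_s = curve$time_s, mr = mr,
            temperature = curve$temperature,
            slab_thickness = curve$slab_thickness)
}

#' Construct a moisture-ratio series
#'
#' Low-level constructor for a dimensionless moisture-ratio time series;
#' [moisture_ratio_series()] builds one from a drying curve.
#'
#' @param time_s Times in seconds, ordered, first value 0.
#' @param mr Moisture ratios; `mr[1]` must be 1 and values must lie in
#'   `[0, 1.02]` (small overshoots above 1 tolerate measurement noise).
#' @param temperature Drying temperature, degC.
#' @param slab_thickness Slab thickness L, metres.
#' @param normalized Require `mr[1] == 1` (default TRUE, the invariant of
#'   every experiment-derived series). Model-generated series whose value
#'   at t = 0 is the model's own analytic intercept (e.g. `8/pi^2` for the
#'   first-term slab solution) may set this to FALSE.
#' @return An object of class `mr_series`.
#' @export
mr_series <- function(time_s, mr, temperature, slab_thickness,
                      normalized = TRUE) {
  if (length(time_s) != length(mr)) stopf("`time_s` and `mr` lengths differ")
  if (any(diff(time_s) <= 0)) stopf("times must be strictly increasing")
  if (time_s[1] != 0) stopf("the series must start at time 0")
  if (normalized && abs(mr[1] - 1) > 1e-12) stopf("MR at time 0 must equal 1")
  if (any(mr < 0) || any(mr > 1.02)) {
    stopf("moisture ratios must lie in [0, 1.02]; got range [%g, %g]",
          min(mr), max(mr))
  }
  structure(list(time_s = as.numeric(time_s), mr = as.numeric(mr),
                 temperature = temperature, slab_thickness = slab_thickness),
            class = "mr_series")
}

#' @export
print.mr_series <- function(x, ...) {
  cat(sprintf("Moisture-ratio series: %d points over %.1f h at %g degC (final MR %.3f)\n",
              length(x$mr), max(x$time_s) / 3600, x$temperature,
              x$mr[length(x$mr)]))
  invisible(x)
}
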