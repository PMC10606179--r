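# Nonlinear least-squares fitting of thin-layer models to moisture-ratio
# data, with the goodness-of-fit statistics customary in drying studies:
# the coefficient of determination R^2, the reduced chi-square
# chi^2 = SSE / (N - n), and RMSE = sqrt(SSE / N).

#' Goodness-of-fit statistics for moisture-ratio predictions
#'
#' @param mr_exp Observed moisture ratios.
#' @param mr_pred Predicted moisture ratios (same length).
#' @param n_params Number of fitted model parameters `n` (for the reduced
#'   chi-square denominator `N - n`).
#' @param r2_variant `"conventional"` (default) centers the total sum of
#'   squares on the mean of the observations; `"as_printed"` centers it on
#'   the mean of the predictions, a variant that circulates in the drying
#'   literature.
#' @return List with `r_squared`, `chi_squared`, `rmse` and `sse`.
#'   `r_squared` may be negative for fits worse than the mean; it is not
#'   clamped.
#' @export
gof_stats <- function(mr_exp, mr_pred, n_params,
                      r2_variant = c("conventional", "as_printed")) {
  r2_variant <- match.arg(r2_variant)
  N <- length(mr_exp)
  if (length(mr_pred) != N) stopf("observed and predicted lengths differ (%d vs %d)",
                                  N, length(mr_pred))
  if (N < 1L) stopf("at least one observation is required")
  sse <- sum((mr_pred - mr_exp)^2)
  centre <- if (r2_variant == "conventional") mean(mr_exp) else mean(mr_pred)
  sst <- sum((mr_exp - centre)^2)
  r2 <- if (sst == 0 && sse == 0) 1 else 1 - sse / sst
  chi2 <- if (N > n_params) sse / (N - n_params) else {
    stopf("reduced chi-square needs N > n (got N = %d, n = %d)", N, n_params)
  }
  list(r_squared = r2, chi_squared = chi2, rmse = sqrt(sse / N), sse = sse)
}

# Deterministic multi-start grid: the model's own initializer plus scaled
# variants of it (rates stretched/compressed, exponents nudged), clipped to
# bounds. Order is fixed, so fits are reproducible.
start_grid <- function(model, series, n_starts = 8L) {
  base <- model$init(series)
  rate_pars <- intersect(model$parameter_names, c("k", "k1", "k2", "g", "h"))
  exp_pars <- intersect(model$parameter_names, "n")
  scales <- c(1, 0.5, 2, 0.25, 4, 1, 0.5, 2)
  n_shift <- c(0, 0, 0, 0, 0, 0.5, -0.3, 0.3)
  starts <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    th <- base
    th[rate_pars] <- th[rate_pars] * scales[((i - 1L) %% length(scales)) + 1L]
    if (length(exp_pars)) th[exp_pars] <- th[exp_pars] + n_shift[((i - 1L) %% length(n_shift)) + 1L]
    # spread tied rates so multi-exponential models do not start degenerate
    if (all(c("k1", "k2") %in% names(th)) && i %% 2 == 0) {
      th[["k1"]] <- th[["k1"]] / 2; th[["k2"]] <- th[["k2"]] * 2
    }
    starts[[i]] <- pmin(pmax(th, model$lower), model$upper)
  }
  unique(starts)
}

#' Fit one thin-layer model to a moisture-ratio series
#'
#' Minimizes the sum of squared moisture-ratio residuals over bounded
#' parameters with the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]), started from a deterministic multi-start grid
#' built around the model's initialization heuristic. The best start wins.
#'
#' @param series An [mr_series()].
#' @param model A `model_spec` or model name (see [thin_layer_models()]).
#' @param n_starts Number of deterministic starts (default 8).
#' @param r2_variant Passed to [gof_stats()].
#' @param ftol,ptol Convergence tolerances for the optimizer (default 1e-10).
#' @return An object of class `fit_result`: `model`, `theta_hat` (named,
#'   rates in 1/h), `sse`, `r_squared`, `chi_squared`, `rmse`, `n_obs`,
#'   `n_params`, `converged`, `n_starts_used`.
#' @export
fit_model <- function(series, model, n_starts = 8L,
                      r2_variant = c("conventional", "as_printed"),
                      ftol = 1e-10, ptol = 1e-10) {
  stopifnot(inherits(series, "mr_series"))
  if (is.character(model)) model <- lookup_model(model)
  r2_variant <- match.arg(r2_variant)
  t_h <- series$time_s / 3600
  mr <- series$mr
  N <- length(mr)
  if (N <= model$arity) {
    stopf("model '%s' needs more observations than parameters (N = %d, n = %d)",
          model$name, N, model$arity)
  }
  resid_fn <- function(p) {
    names(p) <- model$parameter_names
    model$fn(t_h, p) - mr
  }
  best <- NULL
  converged <- FALSE
  starts <- start_grid(model, series, n_starts)
  for (th in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th, lower = model$lower, upper = model$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = ptol, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (is.null(best) || sse < best$sse - 1e-15 ||
        (sse <= best$sse && ok && !best$ok)) {
      best <- list(par = stats::setNames(fit$par, model$parameter_names),
                   sse = sse, ok = ok)
    }
    converged <- converged || ok
  }
  if (is.null(best)) {
    stopf("all %d starts failed for model '%s'", length(starts), model$name)
  }
  pred <- model$fn(t_h, best$par)
  gof <- gof_stats(mr, pred, n_params = model$arity, r2_variant = r2_variant)
  structure(list(model = model$name, theta_hat = best$par, sse = gof$sse,
                 r_squared = gof$r_squared, chi_squared = gof$chi_squared,
                 rmse = gof$rmse, n_obs = N, n_params = model$arity,
                 converged = converged, n_starts_used = length(starts),
                 temperature = series$temperature),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  pars <- paste(sprintf("%s = %.4f", names(x$theta_hat), x$theta_hat),
                collapse = "; ")
  cat(sprintf("%s fit (%g degC): %s\n  R^2 = %.4f, chi^2 = %.3g, RMSE = %.4g%s\n",
              x$model, x$temperature, pars, x$r_squared, x$chi_squared, x$rmse,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Fit and rank a set of thin-layer models
#'
#' Fits each requested model to the series and ranks the results by RMSE
#' (ascending). RMSE values within `tie_tol` of each other are treated as
#' tied and broken deterministically by fewer parameters, then by model
#' name. Per-model failures become flagged rows, not errors.
#'
#' @param series An [mr_series()].
#' @param model_names Character vector of registered model names (default:
#'   all ten).
#' @param tie_tol Absolute RMSE difference treated as a tie (default 1e-6).
#' @param ... Passed to [fit_model()].
#' @return An object of class `rank_table`: a data frame with one row per
#'   model (columns `model`, `temperature_C`, `constants`, `r_squared`,
#'   `chi_squared`, `rmse`, `converged`, `rank`, `error`), ordered by rank,
#'   with the full `fit_result` objects in `attr(, "fits")`.
#' @export
fit_all_models <- function(series, model_names = names(thin_layer_models()),
                           tie_tol = 1e-6, ...) {
  if (length(model_names) < 1L) stopf("at least one model name is required")
  fits <- list()
  rows <- list()
  for (nm in model_names) {
    res <- tryCatch(fit_model(series, nm, ...), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[nm]] <- data.frame(
        model = nm, temperature_C = series$temperature, constants = NA_character_,
        r_squared = NA_real_, chi_squared = NA_real_, rmse = NA_real_,
        n_params = lookup_model(nm)$arity, converged = FALSE,
        error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <- res
      rows[[nm]] <- data.frame(
        model = nm, temperature_C = series$temperature,
        constants = paste(sprintf("%s=%.4f", names(res$theta_hat), res$theta_hat),
                          collapse = ";"),
        r_squared = res$r_squared, chi_squared = res$chi_squared,
        rmse = res$rmse, n_params = res$n_params, converged = res$converged,
        error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # rank: RMSE ascending with ties (within tie_tol) broken by parameter
  # count then name; failed fits sink to the bottom
  key_rmse <- tab$rmse
  key_rmse[is.na(key_rmse)] <- Inf
  grp <- round(key_rmse / tie_tol)
  ord <- order(grp, tab$n_params, tab$model)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  structure(tab, class = c("rank_table", "data.frame"),
            fits = fits, criterion = "rmse (ties: fewer parameters, then name)")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Model ranking at %g degC by %s\n",
              x$temperature_C[1], attr(x, "criterion")))
  print.data.frame(x[, c("rank", "model", "r_squared", "chi_squared", "rmse",
                         "converged")], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Hartley's Fmax test for homogeneity of variances
#'
#' Computes `Fmax = max(s_i^2) / min(s_i^2)` over the groups and compares it
#' with a Monte-Carlo critical value obtained by simulating the Fmax
#' statistic for normal groups of the same sizes under homogeneity.
#'
#' @param groups List of numeric vectors (>= 2 groups, each of size >= 2;
#'   the classical statistic assumes equal sizes and a warning is given
#'   otherwise).
#' @param n_sim Number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed for the simulation (default 1).
#' @param alpha Significance level (default 0.05).
#' @return List with `fmax`, `critical` (upper `1 - alpha` quantile under
#'   homogeneity), `homogeneous` (logical decision), `n_groups`,
#'   `group_sizes`, `alpha`, `n_sim`.
#' @export
hartley_fmax <- function(groups, n_sim = 10000L, seed = 1L, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stopf("at least 2 groups are required")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stopf("every group needs at least 2 values")
  if (length(unique(sizes)) > 1L) {
    warnf("unequal group sizes: the classical Fmax statistic assumes equal sizes")
  }
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stopf("a group has zero variance; Fmax is degenerate")
  fmax <- max(v) / min(v)
  k <- length(groups)
  crit <- with_seed(seed, {
    # one column of simulated group variances per draw, groups vectorized
    vs <- vapply(sizes, function(ni) {
      x <- matrix(stats::rnorm(ni * n_sim), nrow = ni)
      (colSums(x^2) - colSums(x)^2 / ni) / (ni - 1)
    }, numeric(n_sim))
    sims <- apply(vs, 1L, max) / apply(vs, 1L, min)
    unname(stats::quantile(sims, 1 - alpha, type = 7))
  })
  list(fmax = fmax, critical = crit, homogeneous = fmax <= crit,
       n_groups = k, group_sizes = as.integer(sizes), alpha = alpha,
       n_sim = as.integer(n_sim))
}
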