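# End-to-end analysis pipeline: drying CSVs -> moisture ratios -> model
# ranking per temperature, diffusivity + Arrhenius activation energy,
# specific energy, and carotenoid degradation fits.

#' Read a pipeline configuration file
#'
#' The configuration is a YAML file with sections `drying_csv` (path),
#' `carotenoid_csv` (optional path), `models` (optional name list),
#' `fitting` (`intercept_mode`, `r2_variant`, `min_fourier`,
#' `replicate_handling`), `energy` (air/sample parameters; optional),
#' `degradation` (`form`), `output_dir` and `seed`. Paths are resolved
#' relative to the configuration file.
#'
#' @param path YAML configuration file.
#' @return A validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("drying_csv", "carotenoid_csv")) {
    if (!is.null(cfg[[key]]) && !grepl("^(/|[A-Za-z]:)", cfg[[key]])) {
      cfg[[key]] <- file.path(base, cfg[[key]])
    }
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$drying_csv)) stopf("config: `drying_csv` is required")
  if (!is.null(cfg$models)) {
    cfg$models <- as.character(unlist(cfg$models))
    if (length(cfg$models) == 0L) stopf("config: `models` must not be empty")
    unknown <- setdiff(cfg$models, names(thin_layer_models()))
    if (length(unknown)) stopf("config: unknown model(s): %s", paste(unknown, collapse = ", "))
  } else cfg$models <- names(thin_layer_models())
  fit_defaults <- list(intercept_mode = "fixed", r2_variant = "conventional",
                       min_fourier = 0, replicate_handling = "mean")
  cfg$fitting <- utils::modifyList(fit_defaults, cfg$fitting %||% list())
  if (!cfg$fitting$replicate_handling %in% c("mean", "per_replicate")) {
    stopf("config: fitting$replicate_handling must be 'mean' or 'per_replicate'")
  }
  cfg$degradation <- utils::modifyList(list(form = "logistic"), cfg$degradation %||% list())
  cfg$seed <- cfg$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "thinlayer-report"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average replicate drying curves into one moisture-ratio series
#'
#' Replicates of one temperature are converted to moisture ratios and
#' averaged pointwise; all replicates must share a time grid.
#'
#' @param curves List of [drying_curve()] objects at one temperature.
#' @return An [mr_series()].
#' @export
average_replicates <- function(curves) {
  series <- lapply(curves, moisture_ratio_series)
  t0 <- series[[1]]$time_s
  for (s in series) {
    if (length(s$time_s) != length(t0) || any(s$time_s != t0)) {
      stopf("replicates must share a time grid to be averaged")
    }
  }
  mr <- rowMeans(vapply(series, `[[`, numeric(length(t0)), "mr"))
  mr_series(time_s = t0, mr = pmin(mr, 1.02),
            temperature = series[[1]]$temperature,
            slab_thickness = series[[1]]$slab_thickness)
}

#' Run the full drying-kinetics analysis pipeline
#'
#' Reads the drying curves, groups them by temperature (averaging
#' replicates by default), fits and ranks the configured thin-layer models
#' per temperature, estimates the effective diffusivity at each temperature
#' and the Arrhenius activation energy across temperatures, computes the
#' specific-energy schedule when an `energy` section is present, and fits a
#' carotenoid retention model when a carotenoid CSV is given. Reports are
#' written as CSV under `output_dir` together with a run log recording the
#' package version, seed and the options in effect.
#'
#' @param config A configuration list (see [read_pipeline_config()]) or the
#'   path to a YAML configuration file.
#' @return Invisibly, the report bundle: `model_table`, `rankings`,
#'   `deff_table`, `arrhenius`, `energy_table` (or NULL), `degradation`
#'   (or NULL), `failures` (per-model fit failures carried as rows).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_pipeline_config(config)
  curves <- read_drying_csv(cfg$drying_csv)
  temps <- vapply(curves, `[[`, numeric(1), "temperature")
  by_temp <- split(curves, temps)

  series_list <- list()
  for (temp_key in names(by_temp)) {
    grp <- by_temp[[temp_key]]
    if (cfg$fitting$replicate_handling == "mean") {
      series_list[[temp_key]] <- list(average_replicates(grp))
    } else {
      series_list[[temp_key]] <- lapply(grp, moisture_ratio_series)
    }
  }

  rankings <- list()
  tables <- list()
  for (temp_key in names(series_list)) {
    for (s in series_list[[temp_key]]) {
      rk <- fit_all_models(s, cfg$models, r2_variant = cfg$fitting$r2_variant)
      rankings[[length(rankings) + 1L]] <- rk
      tables[[length(tables) + 1L]] <- as.data.frame(rk)
    }
  }
  model_table <- do.call(rbind, tables)

  deff_est <- lapply(series_list, function(group) {
    estimate_deff(group[[1]], intercept_mode = cfg$fitting$intercept_mode,
                  min_fourier = cfg$fitting$min_fourier)
  })
  dtab <- deff_table(deff_est)
  arr <- if (nrow(dtab) >= 3L) {
    fit_arrhenius(dtab$temperature_C, dtab$d_eff_m2_per_s)
  } else NULL

  energy_tab <- NULL
  if (!is.null(cfg$energy)) {
    times_h <- vapply(series_list, function(g) max(g[[1]]$time_s) / 3600, numeric(1))
    energy_tab <- do.call(energy_schedule,
                          c(list(temperatures_C = dtab$temperature_C,
                                 drying_times_h = unname(times_h)),
                            cfg$energy))
  }

  degr <- NULL
  if (!is.null(cfg$carotenoid_csv)) {
    caro <- read_carotenoid_csv(cfg$carotenoid_csv)
    degr <- lapply(caro, fit_degradation, form = cfg$degradation$form)
  }

  out <- cfg$output_dir
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(model_table, file.path(out, "model_fits.csv"), row.names = FALSE)
    utils::write.csv(dtab, file.path(out, "deff.csv"), row.names = FALSE)
    if (!is.null(arr)) {
      utils::write.csv(data.frame(d0_m2_per_s = arr$d0, e_a_kj_per_mol = arr$e_a / 1000,
                                  r_squared = arr$r_squared, chi_squared = arr$chi_squared,
                                  rmse = arr$rmse),
                       file.path(out, "arrhenius.csv"), row.names = FALSE)
    }
    if (!is.null(energy_tab)) {
      utils::write.csv(energy_tab, file.path(out, "energy.csv"), row.names = FALSE)
    }
    if (!is.null(degr)) {
      dd <- do.call(rbind, lapply(degr, function(f) {
        data.frame(compound = f$compound, form = f$form,
                   params = paste(sprintf("%s=%.6g", names(f$params), f$params),
                                  collapse = ";"),
                   r_squared = f$r_squared, chi_squared = f$chi_squared,
                   rmse = f$rmse, converged = f$converged)
      }))
      utils::write.csv(dd, file.path(out, "degradation.csv"), row.names = FALSE)
    }
    writeLines(c(
      sprintf("thinlayer %s", as.character(utils::packageVersion("thinlayer"))),
      sprintf("seed: %s", cfg$seed),
      sprintf("models: %s", paste(cfg$models, collapse = ", ")),
      sprintf("intercept_mode: %s", cfg$fitting$intercept_mode),
      sprintf("r2_variant: %s", cfg$fitting$r2_variant),
      sprintf("replicate_handling: %s", cfg$fitting$replicate_handling),
      sprintf("degradation_form: %s", cfg$degradation$form),
      "note: air density, specific heat and ambient temperature defaults are generic dry-air values, not measurements"
    ), file.path(out, "run_log.txt"))
  }

  invisible(list(model_table = model_table, rankings = rankings,
                 deff_table = dtab, arrhenius = arr,
                 energy_table = energy_tab, degradation = degr,
                 failures = model_table[!is.na(model_table$error), , drop = FALSE]))
}
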