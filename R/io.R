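# CSV input/output. All files are UTF-8 with dot decimal separators.
#
# Drying-curve schema: columns `temperature_C, replicate, time_h, mass_g`
# (or `moisture_db` instead of `mass_g`), preceded by an optional header
# block of `# key: value` lines carrying per-file metadata:
#   # slab_thickness_m: 0.01
#   # initial_wet_basis_moisture_pct: 82.63
#   # dry_solid_mass_g: 5.2
#
# Carotenoid schema: `temperature_C, compound, concentration_mg_per_100g`
# with an optional `sd` column.

#' Path to a bundled example data file
#'
#' The package ships small example tables from a hot-air drying study of
#' tomato peels at 50-75 degC: `"tomato_peel_deff.csv"` (per-temperature
#' ln(MR) regression slopes and effective diffusivities),
#' `"tomato_peel_model_constants.csv"` (fitted thin-layer model constants,
#' rates in 1/h) and `"tomato_peel_carotenoids.csv"` (lycopene and
#' beta-carotene concentrations of extracts from the dried peels).
#'
#' @param file File name; with no argument, lists the available files.
#' @return Full path to the file (or the list of file names).
#' @export
thinlayer_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "thinlayer")))
  }
  path <- system.file("extdata", file, package = "thinlayer")
  if (path == "") stopf("no bundled file '%s'", file)
  path
}

read_header_block <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(kv) == 3L) {
      val <- suppressWarnings(as.numeric(kv[3]))
      out[[kv[2]]] <- if (is.na(val)) kv[3] else val
    }
  }
  out
}

check_numeric_column <- function(df, col, path) {
  x <- df[[col]]
  if (is.character(x) || is.factor(x)) {
    if (any(grepl(",", x))) {
      stopf("column '%s' in %s contains comma decimal separators; use dot decimals (e.g. 0.5, not 0,5)",
            col, path)
    }
    stopf("column '%s' in %s is not numeric", col, path)
  }
  invisible(TRUE)
}

#' Read drying curves from CSV
#'
#' @param path CSV file following the drying-curve schema (see the package
#'   vignette): columns `temperature_C, replicate, time_h` and `mass_g` or
#'   `moisture_db`, with a `# key: value` header block for
#'   `slab_thickness_m` and either `initial_wet_basis_moisture_pct` or
#'   `dry_solid_mass_g`.
#' @return List of [drying_curve()] objects, one per (temperature,
#'   replicate) pair, named `"<temperature>_<replicate>"`.
#' @export
read_drying_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  meta <- read_header_block(path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("temperature_C", "replicate", "time_h")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  value_col <- intersect(c("mass_g", "moisture_db"), names(df))
  if (length(value_col) == 0L) {
    stopf("missing required column in %s: one of mass_g, moisture_db", path)
  }
  value_col <- value_col[1]
  for (col in c("temperature_C", "time_h", value_col)) check_numeric_column(df, col, path)
  if (is.null(meta$slab_thickness_m)) {
    stopf("header block of %s must set slab_thickness_m", path)
  }
  df$.row <- seq_len(nrow(df))
  groups <- split(df, list(df$temperature_C, df$replicate), drop = TRUE)
  curves <- list()
  for (g in groups) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (anyDuplicated(g$time_h)) {
      stopf("duplicate time in %s near data row %d (temperature %g, replicate %s)",
            path, g$.row[anyDuplicated(g$time_h)], g$temperature_C[1], g$replicate[1])
    }
    args <- list(time_h = g$time_h, temperature = g$temperature_C[1],
                 slab_thickness = meta$slab_thickness_m,
                 replicate_id = as.character(g$replicate[1]))
    if (value_col == "mass_g") args$mass_g <- g$mass_g else args$moisture_db <- g$moisture_db
    if (!is.null(meta$initial_wet_basis_moisture_pct)) {
      args$initial_wet_basis <- meta$initial_wet_basis_moisture_pct
    }
    if (!is.null(meta$dry_solid_mass_g)) args$dry_solid_mass <- meta$dry_solid_mass_g
    curve <- tryCatch(do.call(drying_curve, args), error = function(e) {
      stopf("invalid drying curve in %s (temperature %g, replicate %s, data rows %d-%d): %s",
            path, g$temperature_C[1], g$replicate[1], min(g$.row), max(g$.row),
            conditionMessage(e))
    })
    curves[[sprintf("%g_%s", g$temperature_C[1], g$replicate[1])]] <- curve
  }
  curves[order(names(curves))]
}

#' Write drying curves to CSV
#'
#' Inverse of [read_drying_csv()]: the generator's output written with this
#' function reads back to identical curves.
#'
#' @param curves List of [drying_curve()] objects sharing one slab
#'   thickness and moisture-resolution metadata.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_drying_csv <- function(curves, path) {
  if (inherits(curves, "drying_curve")) curves <- list(curves)
  first <- curves[[1]]
  hdr <- sprintf("# slab_thickness_m: %.15g", first$slab_thickness)
  if (!is.null(first$dry_solid_mass)) {
    hdr <- c(hdr, sprintf("# dry_solid_mass_g: %.15g", first$dry_solid_mass))
  } else if (!is.null(first$initial_wet_basis)) {
    hdr <- c(hdr, sprintf("# initial_wet_basis_moisture_pct: %.15g", first$initial_wet_basis))
  }
  rows <- lapply(curves, function(cu) {
    d <- data.frame(temperature_C = cu$temperature, replicate = cu$replicate_id,
                    time_h = cu$time_s / 3600, stringsAsFactors = FALSE)
    if (!is.null(cu$mass_g)) d$mass_g <- cu$mass_g else d$moisture_db <- cu$moisture_db
    d
  })
  df <- do.call(rbind, rows)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read carotenoid concentration series from CSV
#'
#' @param path CSV with columns `temperature_C, compound,
#'   concentration_mg_per_100g` and optionally `sd`.
#' @return Named list of [carotenoid_series()], one per compound.
#' @export
read_carotenoid_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("temperature_C", "compound", "concentration_mg_per_100g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in c("temperature_C", "concentration_mg_per_100g")) {
    check_numeric_column(df, col, path)
  }
  out <- lapply(split(df, df$compound), function(g) {
    g <- g[order(g$temperature_C), , drop = FALSE]
    carotenoid_series(g$temperature_C, g$concentration_mg_per_100g,
                      compound = g$compound[1],
                      sd = if ("sd" %in% names(g)) g$sd else NULL)
  })
  out
}

#' Write a per-temperature diffusivity table to CSV
#'
#' @param estimates List of [estimate_deff()] results.
#' @param path Output file.
#' @return The table written, invisibly.
#' @export
write_deff_csv <- function(estimates, path) {
  df <- deff_table(estimates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Assemble a diffusivity table from per-temperature estimates
#'
#' @param estimates List of [estimate_deff()] results.
#' @return Data frame with columns `temperature_C, slope_per_s,
#'   d_eff_m2_per_s, r_squared, chi_squared, rmse`.
#' @export
deff_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(temperature_C = e$temperature, slope_per_s = e$slope,
               d_eff_m2_per_s = e$d_eff, r_squared = e$r_squared,
               chi_squared = e$chi_squared, rmse = e$rmse)
  }))
}
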