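# Table readers/writers and run bookkeeping. Dialect: comma-separated,
# UTF-8, "." decimal separator, mandatory header row. Inputs must not use
# thousands separators: "385.000 t"-style notation is a decimal 385 here.

soil_table_columns <- function() {
  c("site", "survey_year", "distance_cm", "horizon_top_cm",
    "horizon_bottom_cm", "ph_h2o", "ca_exch_mg_g", "mg_exch_mg_g",
    "c_mg_g", "n_mg_g", "s_mg_g", "bulk_density_g_cm3")
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort2(sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")), "schema_error")
  }
}

check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    x <- df[[cl]]
    conv <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(conv))
    if (length(bad)) {
      abort2(sprintf("%s: column `%s` not numeric at data line(s) %s",
                     path, cl, paste(bad, collapse = ", ")), "row_error")
    }
    df[[cl]] <- conv
  }
  df
}

#' Read a soil sample table
#'
#' Expects the dialect
#' `site,survey_year,distance_cm,horizon_top_cm,horizon_bottom_cm,ph_h2o,`
#' `ca_exch_mg_g,mg_exch_mg_g,c_mg_g,n_mg_g,s_mg_g,bulk_density_g_cm3`
#' with an optional `stone_fraction` column; extra columns are kept.
#'
#' @param path CSV file path.
#' @return tibble, one row per sample.
#' @export
read_soil_table <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, soil_table_columns(), path)
  num <- setdiff(names(df), "site")
  df <- check_numeric(df, num, path)
  tibble::as_tibble(df)
}

#' Write a soil sample table
#'
#' @param soil data frame in the soil-table dialect.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_soil_table <- function(soil, path) {
  check_columns(soil, soil_table_columns(), "soil table")
  utils::write.csv(soil, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an annual deposition flux table
#'
#' Dialect `year,tf_s,sf_s,tf_water,sf_water` (S fluxes kg S ha^-1 yr^-1,
#' water fluxes mm yr^-1, both on the stand-area basis). The water columns
#' may be absent; time factors must then be supplied another way (explicit
#' column delays).
#'
#' @param path CSV file path.
#' @return tibble with `year`, `tf_s`, `sf_s` and, when present,
#'   `tf_water`, `sf_water`.
#' @export
read_flux_table <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, c("year", "tf_s", "sf_s"), path)
  df <- check_numeric(df, names(df), path)
  if (any(stats::na.omit(unlist(df[setdiff(names(df), "year")])) < 0)) {
    abort2(paste0(path, ": fluxes must be >= 0"), "invalid_flux")
  }
  tibble::as_tibble(df)
}

#' Read a grid pH table
#'
#' Dialect `x_cm,y_cm,ph_h2o`; stem at the origin.
#'
#' @param path CSV file path.
#' @return tibble.
#' @export
read_grid_table <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  check_columns(df, c("x_cm", "y_cm", "ph_h2o"), path)
  tibble::as_tibble(check_numeric(df, names(df), path))
}

#' Write a tidy result table
#'
#' Plain deterministic CSV (no row names, no quoting of numerics) so that
#' identical inputs give byte-identical files.
#'
#' @param df data frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stand/column configuration file
#'
#' YAML (or JSON, a YAML subset) mirroring the stand fields: top-level
#' `crown_projection_area` (m^2), `base_delay` (years), `strict` (logical,
#' optional) and a `columns` list of records with `distance` (cm),
#' `routing_fraction`, optional `infiltration_area` (m^2; annulus default
#' used when absent) and optional `delay` (years). Unknown keys are
#' rejected.
#'
#' @param path config file path.
#' @return a [stand_spec()].
#' @export
read_stand_config <- function(path) {
  if (!file.exists(path)) abort2(paste0("no such file: ", path), "io_error")
  cfg <- yaml::read_yaml(path)
  known_top <- c("crown_projection_area", "base_delay", "strict", "columns",
                 "stem_radius")
  bad <- setdiff(names(cfg), known_top)
  if (length(bad)) {
    abort2(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
           "config_error")
  }
  if (is.null(cfg$columns) || !length(cfg$columns)) {
    abort2("config must list at least one column", "config_error")
  }
  known_col <- c("distance", "routing_fraction", "infiltration_area", "delay")
  for (cl in cfg$columns) {
    bad <- setdiff(names(cl), known_col)
    if (length(bad)) {
      abort2(paste0("unknown column key(s): ", paste(bad, collapse = ", ")),
             "config_error")
    }
  }
  crown <- cfg$crown_projection_area %||% 50
  dist <- vapply(cfg$columns, `[[`, numeric(1), "distance")
  areas <- default_infiltration_areas(dist, crown,
                                      cfg$stem_radius %||% 25)
  cols <- lapply(seq_along(cfg$columns), function(i) {
    cl <- cfg$columns[[i]]
    column_spec(distance = cl$distance,
                routing_fraction = cl$routing_fraction,
                infiltration_area = cl$infiltration_area %||% areas[i],
                delay = cl$delay)
  })
  stand_spec(cols, crown_projection_area = crown,
             base_delay = cfg$base_delay %||% 12L,
             strict = isTRUE(cfg$strict))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Record a run manifest
#'
#' Small provenance record for one pipeline step: command name, a stable
#' digest of the configuration, the seed, and the files read and written.
#'
#' @param command step name.
#' @param config the configuration object (any R list).
#' @param seed integer seed or `NULL`.
#' @param input_files,output_files character vectors of paths.
#' @param path optional JSON-ish YAML file to write the manifest to.
#' @return the manifest list, invisibly if written.
#' @export
run_manifest <- function(command, config, seed = NULL,
                         input_files = character(), output_files = character(),
                         path = NULL) {
  missing_out <- output_files[!file.exists(output_files)]
  if (length(missing_out)) {
    abort2(paste0("manifest lists non-existent output(s): ",
                  paste(missing_out, collapse = ", ")), "io_error")
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2, compress = FALSE)
  manifest <- list(
    command = command,
    config_hash = unname(tools::md5sum(tf)),
    seed = seed,
    input_files = as.list(input_files),
    output_files = as.list(output_files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  if (!is.null(path)) {
    yaml::write_yaml(manifest, path)
    return(invisible(manifest))
  }
  manifest
}
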