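# Configuration files and table writers shared by the CLI and the runner.

config_keys <- c("profile", "population_size", "reps", "sample_sizes",
                 "alpha", "master_seed", "centering", "loocv",
                 "compute_generalization", "record_level", "grid")
grid_keys <- c("noise_levels", "correlations", "beta1_values",
               "beta2_values", "beta3_values", "beta0", "mu_x", "mu_z",
               "sd_x", "sd_z", "strict_calibration")

#' Load an experiment configuration from YAML or JSON
#'
#' An empty (or missing-key) file yields the full-scale default
#' configuration: the complete default grid, populations of 1e6, 1000
#' replicates, sample sizes 25–1000 (the `"full"` profile). Recognized
#' top-level keys: `profile`, `population_size`, `reps`, `sample_sizes`,
#' `alpha`, `master_seed`, `centering`, `loocv`, `compute_generalization`,
#' `record_level`, and a `grid` block with the [parameter_grid()]
#' arguments. Unknown keys are rejected with an error naming the key.
#' TOML is not supported (no TOML parser is available); use YAML or JSON.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop_config("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    toml = stop_config("TOML is not supported; use YAML or JSON"),
    stop_config("unrecognized config extension '.", ext,
                "'; use .yaml, .yml or .json"))
  raw <- raw %||% list()
  config_from_list(raw)
}

#' Build an experiment configuration from a plain list
#'
#' Programmatic equivalent of [load_config()]; used by the CLI and the
#' config round-trip.
#'
#' @param raw Named list of configuration values (may be empty).
#' @return A validated [experiment_config()].
#' @export
config_from_list <- function(raw) {
  if (length(raw) && (is.null(names(raw)) || any(names(raw) == "")))
    stop_config("config entries must all be named")
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "),
                " (allowed: ", paste(config_keys, collapse = ", "), ")")
  grid_args <- raw$grid %||% list()
  unknown_g <- setdiff(names(grid_args), grid_keys)
  if (length(unknown_g))
    stop_config("unknown grid key(s): ", paste(unknown_g, collapse = ", "))
  grid <- do.call(parameter_grid, grid_args)
  args <- raw[setdiff(names(raw), "grid")]
  args$grid <- grid
  do.call(experiment_config, args)
}

#' Serialize an experiment configuration to a plain list / YAML file
#'
#' `load_config(write_config(config, path))` reproduces `config`.
#'
#' @param config An [experiment_config()].
#' @param path Optional path ending in `.yaml`/`.yml`/`.json`; when given,
#'   the config is written there.
#' @return The plain-list representation, invisibly when `path` is given.
#' @export
write_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  g <- config$grid
  lst <- list(profile = config$profile,
              population_size = config$population_size,
              reps = config$reps,
              sample_sizes = config$sample_sizes,
              alpha = config$alpha,
              master_seed = config$master_seed,
              centering = config$centering,
              loocv = config$loocv,
              compute_generalization = config$compute_generalization,
              record_level = config$record_level,
              grid = list(noise_levels = g$noise_levels,
                          correlations = g$correlations,
                          beta1_values = g$beta1_values,
                          beta2_values = g$beta2_values,
                          beta3_values = g$beta3_values,
                          beta0 = g$beta0, mu_x = g$mu_x, mu_z = g$mu_z,
                          sd_x = g$sd_x, sd_z = g$sd_z))
  if (is.null(path)) return(lst)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = , yml = yaml::write_yaml(lst, path),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
    stop_config("unrecognized config extension '.", ext, "'"))
  invisible(lst)
}

# one-line column descriptions for the emitted data dictionary
column_dictionary <- c(
  cell_id = "stable condition identifier within the enumerated grid",
  shape = "interaction shape: none / synergistic / buffering / antagonistic",
  lambda = "noise level (multiplier of sd(Y*))",
  r = "correlation between predictors X and Z",
  n = "sample size drawn from the finite population",
  replicate = "replicate index within (cell, n)",
  beta0 = "true intercept", beta1 = "true weight of X",
  beta2 = "true weight of Z", beta3 = "true weight of the product XZ",
  delta_r2_s = "R2(s) interaction minus simple (sample)",
  delta_r2_p = "R2(p) interaction minus simple (population)",
  delta_overfit = "overfit R2(s,p) interaction minus simple",
  k = "number of analyses aggregated in the row",
  f2 = "population-level Cohen f-squared of the interaction",
  pct_significant = "percent of replicates with p < alpha",
  pct_above_0.5 = "percent of conditions with f-squared above 0.5")

#' Write a named list of tables as CSV files plus a data dictionary
#'
#' Column order is preserved exactly as given; re-running with identical
#' inputs produces byte-identical files. Values are written at full
#' precision unless `digits` is set (the presentation layer for the
#' printed-table layouts uses 2 decimals).
#'
#' @param tables Named list of data.frames.
#' @param out_dir Output directory, created if needed.
#' @param digits Optional rounding applied to numeric columns.
#' @return Named character vector of file paths (invisibly), with md5
#'   checksums as attribute `md5`.
#' @export
write_tables <- function(tables, out_dir, digits = NULL) {
  if (!is.list(tables) || length(tables) == 0L || is.null(names(tables)))
    stop_domain("tables must be a non-empty named list of data.frames")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  dict_lines <- c("# Data dictionary", "")
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (!is.null(digits)) {
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], round, digits = digits)
    }
    path <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(tab, path, row.names = FALSE)
    paths[nm] <- path
    known <- intersect(names(tab), names(column_dictionary))
    dict_lines <- c(dict_lines, paste0("## ", nm, ".csv"),
                    paste0("- `", known, "`: ", column_dictionary[known]), "")
  }
  writeLines(dict_lines, file.path(out_dir, "data_dictionary.md"))
  attr(paths, "md5") <- unname(tools::md5sum(paths))
  invisible(paths)
}
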