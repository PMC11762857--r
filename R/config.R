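# Run configuration: structured-text (YAML/JSON) loading, validation,
# resolved snapshots and run manifests.

run_config_defaults <- function() {
  list(n_individuals = 10000L, discount_rate = 0.03, psa_draws = 1000L,
       allow_recurrence = FALSE, common_random_numbers = TRUE,
       output_dir = "results", dsa_parameters = character())
}

known_config_keys <- c("n_individuals", "seed", "discount_rate", "psa_draws",
                       "allow_recurrence", "common_random_numbers",
                       "output_dir", "dsa_parameters", "population",
                       "cohort_file", "strategies", "coefficients_file")

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, rejects unknown keys, fills
#' defaults (`n_individuals` = 10,000, 3% discounting, 1,000 PSA draws, the
#' four preset strategies), and requires a `seed` and exactly one cohort
#' source — an inline `population:` block (passed to [population_config()])
#' or a `cohort_file:` CSV path.
#'
#' @param path configuration file (`.yaml`, `.yml` or `.json`).
#' @return an object of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), known_config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(run_config_defaults(), raw)
  if (is.null(cfg$seed)) stop("config: 'seed' is required", call. = FALSE)
  if (!is.numeric(cfg$n_individuals) || cfg$n_individuals < 1) {
    stop("config: 'n_individuals' must be >= 1", call. = FALSE)
  }
  if (cfg$discount_rate < 0) {
    stop("config: 'discount_rate' must be >= 0", call. = FALSE)
  }
  if (cfg$psa_draws < 1) {
    stop("config: 'psa_draws' must be >= 1", call. = FALSE)
  }
  has_pop <- !is.null(cfg$population)
  has_file <- !is.null(cfg$cohort_file)
  if (has_pop && has_file) {
    stop("config: give exactly one of 'population' or 'cohort_file'",
         call. = FALSE)
  }
  if (!has_pop && !has_file) cfg$population <- list()  # defaults
  if (is.null(cfg$strategies)) {
    cfg$strategies <- lapply(preset_strategies(), function(s)
      list(name = s$name, threshold = s$threshold,
           discontinuation = s$discontinuation))
  }
  cfg$n_individuals <- as.integer(cfg$n_individuals)
  cfg$seed <- as.integer(cfg$seed)
  cfg$psa_draws <- as.integer(cfg$psa_draws)
  structure(cfg, class = "run_config")
}

#' Materialise the strategies declared in a run configuration
#'
#' @param config a `run_config`.
#' @return named list of [strategy()] objects.
#' @export
config_strategies <- function(config) {
  out <- lapply(config$strategies, function(s) {
    strategy(name = s$name, threshold = s$threshold,
             discontinuation = if (is.null(s$discontinuation)) 0.40
                               else s$discontinuation)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Materialise the baseline cohort declared in a run configuration
#'
#' @param config a `run_config`.
#' @return a `cohort` data frame.
#' @export
config_cohort <- function(config) {
  if (!is.null(config$cohort_file)) {
    return(read_cohort(config$cohort_file))
  }
  pop <- do.call(population_config, config$population)
  generate_cohort(config$n_individuals, pop, seed = config$seed)
}

#' Write a resolved-configuration snapshot
#'
#' Serialises the fully resolved configuration (all defaults filled) as
#' JSON next to the run outputs; reloading the snapshot yields an identical
#' configuration.
#'
#' @param config a `run_config`.
#' @param dir output directory (created if needed).
#' @return the snapshot path, invisibly.
#' @export
write_config_snapshot <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "resolved_config.json")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the resolved
#' configuration's MD5 hash, the master seed, package version and R version.
#'
#' @param config a `run_config`.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_run_manifest <- function(config, dir) {
  snap <- write_config_snapshot(config, dir)
  manifest <- list(
    config_file = basename(snap),
    config_md5 = unname(tools::md5sum(snap)),
    seed = config$seed,
    package = "statinsim",
    package_version = as.character(utils::packageVersion("statinsim")),
    r_version = as.character(getRversion())
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
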