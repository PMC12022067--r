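#' Cohort data dictionary
#'
#' The versioned data dictionary backing [read_cohort()] validation:
#' explicit rows for the core schema (identifiers, demographics, history
#' flags, questionnaire totals, MoCA scores) plus prefix rules for
#' item-level columns (`u1_`/`u2_`/`u3_` items 0-4, `scopa_` items 0-3,
#' `stai1_`/`stai2_` items 1-4, `rbdsq_` items 0-1, `moca_` items at their
#' per-item maxima).
#'
#' @return A tibble: `column`, `type`, `lower`, `upper`, `required`.
#' @export
cohort_dictionary <- function() {
  path <- system.file("extdata", "data_dictionary.csv", package = "cognilr")
  readr::read_csv(path, show_col_types = FALSE)
}

prefix_rules <- function() {
  tibble(
    pattern = c("^u[123]_", "^scopa_[0-9]", "^stai[12]_[0-9]", "^rbdsq_"),
    lower = c(0, 0, 1, 0),
    upper = c(4, 3, 4, 1)
  )
}

#' Read and write cohort tables
#'
#' Cohorts travel as plain CSV: booleans as 0/1, missing values as empty
#' cells, UTF-8.  On read, every known column is range-checked against the
#' data dictionary (violations are schema errors naming the offending cell),
#' `subject_id` must be unique, and unknown columns are retained with a
#' warning so that write-then-read is an identity for any cohort.
#'
#' @param path CSV file path.
#' @param dictionary Data dictionary tibble (default [cohort_dictionary()]).
#' @return `read_cohort()`: a validated tibble.  `write_cohort()`: `path`,
#'   invisibly.
#' @export
read_cohort <- function(path, dictionary = cohort_dictionary()) {
  if (!file.exists(path)) abort(sprintf("Cohort file not found: %s", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(data, dictionary = dictionary)
}

#' @rdname read_cohort
#' @param data Cohort tibble to validate or write.
#' @export
validate_cohort <- function(data, dictionary = cohort_dictionary()) {
  data <- as_tibble(data)
  moca_max <- moca_item_maxima()
  known <- union(dictionary$column, names(moca_max))
  rules <- prefix_rules()
  is_known <- names(data) %in% known
  for (i in seq_len(nrow(rules))) {
    is_known <- is_known | grepl(rules$pattern[i], names(data))
  }
  if (any(!is_known)) {
    warn(sprintf("Unknown column(s) retained without validation: %s",
                 paste(names(data)[!is_known], collapse = ", ")))
  }
  if ("subject_id" %in% names(data) && anyDuplicated(data$subject_id)) {
    abort(sprintf("Duplicate subject_id: %s",
                  data$subject_id[duplicated(data$subject_id)][1]))
  }
  check_cell <- function(col, lo, hi) {
    v <- data[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) {
      abort(sprintf("Schema error: `%s` = %g at row %d outside [%g, %g].",
                    col, v[bad[1]], bad[1], lo, hi),
            class = "cognilr_schema_error")
    }
  }
  for (i in seq_len(nrow(dictionary))) {
    col <- dictionary$column[i]
    if (!col %in% names(data) || dictionary$type[i] %in% c("id", "categorical")) next
    check_cell(col, dictionary$lower[i], dictionary$upper[i])
  }
  for (col in intersect(names(moca_max), names(data))) {
    check_cell(col, 0, moca_max[[col]])
  }
  for (i in seq_len(nrow(rules))) {
    for (col in setdiff(grep(rules$pattern[i], names(data), value = TRUE),
                        c(dictionary$column, names(moca_max)))) {
      check_cell(col, rules$lower[i], rules$upper[i])
    }
  }
  if ("sex" %in% names(data)) {
    bad <- which(!is.na(data$sex) & !data$sex %in% c("male", "female"))
    if (length(bad)) {
      abort(sprintf("Schema error: `sex` = '%s' at row %d (must be male/female).",
                    data$sex[bad[1]], bad[1]),
            class = "cognilr_schema_error")
    }
  }
  data
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path) {
  out <- as_tibble(data)
  for (col in names(out)) {
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Read and write generator configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_synth_config()`: a validated [synth_config()].
#'   `write_synth_config()`: `path`, invisibly.
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  br <- bind_rows(purrr::map(raw$bracket_rates, as_tibble))
  fs <- if (length(raw$feature_specs)) {
    bind_rows(purrr::map(raw$feature_specs, as_tibble))
  } else default_feature_specs()
  synth_config(
    n_subjects = raw$n_subjects,
    bracket_rates = br,
    age_weights = raw$age_weights %||% NULL,
    feature_specs = fs,
    trajectory_mix = unlist(raw$trajectory_mix %||%
                              list(early = 0.37, late = 0.33, fluctuation = 0.30)),
    moca_baseline_mean = raw$moca_baseline_mean %||% 27,
    moca_baseline_sd = raw$moca_baseline_sd %||% 2.2,
    p_male = raw$p_male %||% 0.64,
    missing_rate = raw$missing_rate %||% 0,
    seed = raw$seed %||% NULL
  )
}

#' @rdname read_synth_config
#' @param config A `synth_config`.
#' @export
write_synth_config <- function(config, path) {
  validate_synth_config(config)
  payload <- list(
    n_subjects = config$n_subjects,
    bracket_rates = purrr::map(seq_len(nrow(config$bracket_rates)), function(i) {
      as.list(config$bracket_rates[i, ])
    }),
    age_weights = config$age_weights,
    feature_specs = purrr::map(seq_len(nrow(config$feature_specs)), function(i) {
      as.list(config$feature_specs[i, ])
    }),
    trajectory_mix = as.list(config$trajectory_mix),
    moca_baseline_mean = config$moca_baseline_mean,
    moca_baseline_sd = config$moca_baseline_sd,
    p_male = config$p_male,
    missing_rate = config$missing_rate,
    seed = config$seed
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' Write a provenance sidecar for a generated artifact
#'
#' Records package version, seed, configuration hash and input hashes next
#' to an output file so any run can be reproduced exactly.
#'
#' @param path Path of the JSON sidecar to write.
#' @param seed Seed used.
#' @param config_path Optional configuration file to hash.
#' @param inputs Optional character vector of input files to hash.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, seed = NULL, config_path = NULL, inputs = character()) {
  payload <- list(
    package = "cognilr",
    version = as.character(utils::packageVersion("cognilr")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = if (!is.null(config_path)) unname(tools::md5sum(config_path)) else NULL,
    input_hashes = if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
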