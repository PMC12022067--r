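# item-column vocabularies for the derived motor and cognitive scores

updrs3_items <- function() {
  list(
    rigidity = list(
      right = c("u3_rigidity_rue", "u3_rigidity_rle"),
      left = c("u3_rigidity_lue", "u3_rigidity_lle")
    ),
    akinesia = list(
      right = c("u3_fingertap_r", "u3_handmov_r", "u3_pronsup_r",
                "u3_toetap_r", "u3_legagility_r"),
      left = c("u3_fingertap_l", "u3_handmov_l", "u3_pronsup_l",
               "u3_toetap_l", "u3_legagility_l")
    ),
    tremor = list(
      right = c("u3_posturaltremor_r", "u3_kinetictremor_r",
                "u3_resttremor_rue", "u3_resttremor_rle"),
      left = c("u3_posturaltremor_l", "u3_kinetictremor_l",
               "u3_resttremor_lue", "u3_resttremor_lle")
    ),
    pigd = c("u3_arising", "u3_gait", "u3_freezing",
             "u3_posturalstability", "u3_posture"),
    tremor_score = c("u3_posturaltremor_r", "u3_posturaltremor_l",
                     "u3_kinetictremor_r", "u3_kinetictremor_l",
                     "u3_resttremor_rue", "u3_resttremor_lue",
                     "u3_resttremor_rle", "u3_resttremor_lle",
                     "u3_resttremor_lipjaw")
  )
}

moca_item_maxima <- function() {
  c(
    moca_trail = 1, moca_cube = 1, moca_clock_contour = 1,
    moca_clock_numbers = 1, moca_clock_hands = 1,
    moca_lion = 1, moca_rhino = 1, moca_camel = 1,
    moca_digits = 2, moca_letter = 1, moca_serial7 = 3,
    moca_repeat = 2, moca_fluency = 1,
    moca_abstraction = 2, moca_recall = 5, moca_orientation = 6
  )
}

moca_domains <- function() {
  list(
    visuospatial_executive = c("moca_trail", "moca_cube", "moca_clock_contour",
                               "moca_clock_numbers", "moca_clock_hands"),
    naming = c("moca_lion", "moca_rhino", "moca_camel"),
    attention = c("moca_digits", "moca_letter", "moca_serial7"),
    language = c("moca_repeat", "moca_fluency"),
    abstraction = "moca_abstraction",
    delayed_recall = "moca_recall",
    orientation = "moca_orientation"
  )
}

# row sums that go missing as soon as any constituent is missing: partial
# sums would silently shift the cutoff semantics downstream
strict_row_sum <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("Missing item column(s): %s", paste(missing, collapse = ", ")))
  }
  rowSums(as.data.frame(data[cols]))
}

check_item_range <- function(data, cols, lo, hi) {
  for (cl in intersect(cols, names(data))) {
    bad <- which(!is.na(data[[cl]]) & (data[[cl]] < lo | data[[cl]] > hi))
    if (length(bad)) {
      abort(sprintf("Item `%s` out of range [%g, %g] at row %d.",
                    cl, lo, hi, bad[1]))
    }
  }
}

#' Lateralized MDS-UPDRS III sub-scores
#'
#' Derives the six lateralized motor sub-scores plus their unilateral means.
#' Per side, rigidity sums the upper and lower limb rigidity items; akinesia
#' sums finger tapping, hand movements, pronation-supination, toe tapping
#' and leg agility; tremor sums the postural, kinetic and rest tremor
#' amplitude items of the hand and leg.  The unilateral score is the mean of
#' the left and right sums.  Any missing constituent item makes the derived
#' score missing (it then binarizes to an absent symptom) -- partial sums are
#' never formed.
#'
#' @param data Cohort with 0-4 scored item columns `u3_rigidity_rue`,
#'   `u3_fingertap_r`, ... (see [updrs3_items()] internals for the full
#'   vocabulary).
#' @return `data` with columns `rigidity_right/left/unilateral`,
#'   `akinesia_right/left/unilateral`, `tremor_right/left/unilateral`.
#'   Per-side ranges: rigidity 0-8, akinesia 0-20, tremor 0-16.
#' @export
lateralized_subscores <- function(data) {
  items <- updrs3_items()
  all_items <- unlist(items[c("rigidity", "akinesia", "tremor")], use.names = FALSE)
  check_item_range(data, all_items, 0, 4)
  data <- as_tibble(data)
  for (score in c("rigidity", "akinesia", "tremor")) {
    r <- strict_row_sum(data, items[[score]]$right)
    l <- strict_row_sum(data, items[[score]]$left)
    data[[paste0(score, "_right")]] <- r
    data[[paste0(score, "_left")]] <- l
    data[[paste0(score, "_unilateral")]] <- (r + l) / 2
  }
  data
}

#' PIGD and tremor scores with motor phenotype
#'
#' The postural instability/gait difficulty (PIGD) score is the mean of the
#' arising-from-chair, gait, freezing-of-gait, postural-stability and
#' posture items; the tremor score is the mean of the postural, kinetic and
#' rest tremor amplitude items.  Subjects are PIGD-dominant when the
#' tremor/PIGD ratio is <= 1.0 and tremor-dominant when it is >= 1.5; ratios
#' strictly between are indeterminate.  A zero PIGD score with positive
#' tremor gives an infinite ratio (tremor-dominant); both scores zero is
#' indeterminate by convention.
#'
#' @inheritParams lateralized_subscores
#' @return `data` with columns `pigd_score`, `tremor_score`, `phenotype`.
#' @export
pigd_tremor_phenotype <- function(data) {
  items <- updrs3_items()
  check_item_range(data, c(items$pigd, items$tremor_score), 0, 4)
  data <- as_tibble(data)
  pigd <- strict_row_sum(data, items$pigd) / length(items$pigd)
  trem <- strict_row_sum(data, items$tremor_score) / length(items$tremor_score)
  ratio <- ifelse(pigd == 0, ifelse(trem > 0, Inf, NaN), trem / pigd)
  data$pigd_score <- pigd
  data$tremor_score <- trem
  data$phenotype <- dplyr::case_when(
    is.nan(ratio) ~ "indeterminate", # both scores zero
    is.na(ratio) ~ NA_character_,
    ratio <= 1.0 ~ "PIGD",
    ratio >= 1.5 ~ "tremor_dominant",
    TRUE ~ "indeterminate"
  )
  data
}

#' MoCA domain sub-scores
#'
#' Sums item points within the seven standard MoCA (v1.0) domains:
#' visuospatial/executive, naming, attention, language, abstraction, delayed
#' recall and orientation.  Item values are validated against the per-item
#' maxima; an unknown `moca_`-prefixed item column is a schema error.
#'
#' @param data Cohort with MoCA item columns (`moca_trail`, `moca_cube`,
#'   `moca_clock_*`, `moca_lion`, `moca_rhino`, `moca_camel`, `moca_digits`,
#'   `moca_letter`, `moca_serial7`, `moca_repeat`, `moca_fluency`,
#'   `moca_abstraction`, `moca_recall`, `moca_orientation`).
#' @return `data` with one `moca_<domain>` column per domain (e.g.
#'   `moca_visuospatial_executive`, range 0-5).
#' @export
moca_domain_subscores <- function(data) {
  maxima <- moca_item_maxima()
  known_nonitem <- c("moca_baseline", "moca_y2", "moca_y4", "moca_total", "moca_z")
  item_cols <- setdiff(grep("^moca_", names(data), value = TRUE), known_nonitem)
  unknown <- setdiff(item_cols, c(names(maxima),
                                  paste0("moca_", names(moca_domains()))))
  if (length(unknown)) {
    abort(sprintf("Unknown MoCA item column(s): %s", paste(unknown, collapse = ", ")))
  }
  for (cl in intersect(names(maxima), names(data))) {
    bad <- which(!is.na(data[[cl]]) & (data[[cl]] < 0 | data[[cl]] > maxima[[cl]]))
    if (length(bad)) {
      abort(sprintf("MoCA item `%s` exceeds its maximum %d at row %d.",
                    cl, maxima[[cl]], bad[1]))
    }
  }
  data <- as_tibble(data)
  for (dom in names(moca_domains())) {
    data[[paste0("moca_", dom)]] <- strict_row_sum(data, moca_domains()[[dom]])
  }
  data
}

#' Pluggable MoCA normalization to z-scores
#'
#' `moca_zscore()` converts raw MoCA totals to z-scores with a pluggable
#' norm function `norm(age, education_years)` returning `list(mean, sd)`.
#' The packaged [linear_moca_norm()] is a synthetic linear toy norm (real
#' normative tables are external data); supply your own for real cohorts.
#'
#' @param data Cohort with `moca_baseline`, `age_of_onset`,
#'   `education_years`.
#' @param norm Norm function; default [linear_moca_norm].
#' @return `data` with a `moca_z` column.
#' @export
moca_zscore <- function(data, norm = linear_moca_norm) {
  nm <- norm(data$age_of_onset, data$education_years)
  data <- as_tibble(data)
  data$moca_z <- (data$moca_baseline - nm$mean) / nm$sd
  data
}

#' @rdname moca_zscore
#' @param age,education_years Numeric vectors.
#' @export
linear_moca_norm <- function(age, education_years) {
  list(mean = 27 + 0.1 * (education_years - 15) - 0.05 * (age - 60), sd = 2.4)
}

#' Binarize cohort variables into presence/absence features
#'
#' Applies a table of feature definitions to a cohort: each definition names
#' a source variable (raw or derived), a comparator and a cutoff, and yields
#' one boolean per subject.  Comparators are strict (`gt`: value > cutoff,
#' `lt`: value < cutoff; equality at the cutoff means absent), `eq` tests
#' equality, and `flag` treats the source as an already-binary indicator.
#' Sex-specific cutoffs (`cutoff_female` / `cutoff_male`) are resolved from
#' the record's `sex`.  A missing source value is an absent symptom; a
#' definition referencing a variable absent from the table is a
#' configuration error.
#'
#' @param data Cohort table (derived scores must already be computed, e.g.
#'   via [lateralized_subscores()] / [moca_domain_subscores()]).
#' @param defs Feature definition tibble (see [feature_definitions()]):
#'   columns `name`, `source`, `comparator`, `cutoff`, optional
#'   `cutoff_female` / `cutoff_male`, `hypothesis_sign`, `hypothesis`.
#' @return A tibble of logical columns, one per definition, with `defs`
#'   attached as attribute `"definitions"`.
#' @examples
#' defs <- tibble::tibble(name = "hyposmia", source = "upsit_total",
#'                        comparator = "lt", cutoff = NA_real_,
#'                        cutoff_female = 31, cutoff_male = 30)
#' binarize(tibble::tibble(sex = c("female", "male"), upsit_total = c(30, 30)), defs)
#' @export
binarize <- function(data, defs) {
  defs <- as_tibble(defs)
  if (!all(c("name", "source", "comparator") %in% names(defs))) {
    abort("`defs` needs columns name, source, comparator.")
  }
  bad <- setdiff(defs$comparator, c("gt", "lt", "eq", "flag"))
  if (length(bad)) abort(sprintf("Unknown comparator(s): %s", paste(bad, collapse = ", ")))
  out <- purrr::map(seq_len(nrow(defs)), function(i) {
    def <- defs[i, ]
    if (!def$source %in% names(data)) {
      abort(sprintf(
        "Feature `%s` references variable `%s`, absent from the cohort schema.",
        def$name, def$source
      ))
    }
    v <- data[[def$source]]
    cutoff <- rep(def$cutoff %||% NA_real_, nrow(data))
    has_sex_cutoffs <- all(c("cutoff_female", "cutoff_male") %in% names(def)) &&
      (!is.na(def$cutoff_female) || !is.na(def$cutoff_male))
    if (has_sex_cutoffs) {
      if (!"sex" %in% names(data)) {
        abort(sprintf("Feature `%s` has sex-specific cutoffs but the cohort has no `sex` column.",
                      def$name))
      }
      cutoff <- ifelse(data$sex == "female", def$cutoff_female, def$cutoff_male)
    }
    if (def$comparator != "flag" && all(is.na(cutoff))) {
      abort(sprintf("Feature `%s` needs a finite cutoff for comparator `%s`.",
                    def$name, def$comparator))
    }
    present <- switch(def$comparator,
      gt = v > cutoff,
      lt = v < cutoff,
      eq = v == cutoff,
      flag = as.logical(v)
    )
    present[is.na(present)] <- FALSE # missing value = absent symptom
    present
  })
  names(out) <- defs$name
  out <- as_tibble(out)
  attr(out, "definitions") <- defs
  out
}

#' Packaged feature definitions
#'
#' Reads the versioned YAML fixture shipping the 22 binarized baseline
#' features of the prognostic analysis (questionnaire items, derived motor
#' and cognitive sub-scores, history flags) with their cutoffs, comparators,
#' hypothesis signs and hypothesis groups.  Users may point `path` at their
#' own YAML with the same fields.
#'
#' @param path YAML file (default: the packaged fixture).
#' @return A feature definition tibble suitable for [binarize()].
#' @export
feature_definitions <- function(path = system.file("extdata", "feature_definitions.yaml",
                                                   package = "cognilr")) {
  raw <- yaml::read_yaml(path)
  purrr::map(raw$features, function(f) {
    tibble(
      name = f$name,
      source = f$source,
      comparator = f$comparator,
      cutoff = as.numeric(f$cutoff %||% NA),
      cutoff_female = as.numeric(f$cutoff_female %||% NA),
      cutoff_male = as.numeric(f$cutoff_male %||% NA),
      hypothesis_sign = as.numeric(f$hypothesis_sign %||% 1),
      hypothesis = f$hypothesis %||% NA_character_,
      description = f$description %||% NA_character_
    )
  }) %>% bind_rows()
}
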