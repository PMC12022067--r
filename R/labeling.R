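#' Label cognitive decline from longitudinal MoCA totals
#'
#' Cognitive decline is a decrease of three or more MoCA points from
#' baseline to the 2-year and/or the 4-year follow-up, evaluated only on the
#' follow-ups that are present.  On integer MoCA scores this is identical to
#' "a decrease by more than 2 points".
#'
#' @param baseline,y2,y4 Numeric vectors of MoCA totals (0-30); `y2`/`y4`
#'   may contain `NA`.
#' @return Logical vector.  Subjects with both follow-ups missing raise an
#'   error (they must be excluded upstream).
#' @examples
#' decline_label(27, 24, 26)  # TRUE: 3-point drop at year 2
#' decline_label(27, 26, 25)  # FALSE: largest drop is 2
#' decline_label(30, NA, 27)  # TRUE: rule applied to the available follow-up
#' @export
decline_label <- function(baseline, y2, y4) {
  if (any(is.na(baseline))) abort("Baseline MoCA must be present for every subject.")
  if (any(is.na(y2) & is.na(y4))) {
    abort("Both follow-ups missing for at least one subject: cannot label decline.")
  }
  d2 <- baseline - y2
  d4 <- baseline - y4
  (!is.na(d2) & d2 >= 3) | (!is.na(d4) & d4 >= 3)
}

#' Classify a longitudinal MoCA trajectory
#'
#' Four mutually exclusive categories over complete follow-ups:
#' * `stable`: no baseline-to-follow-up drop exceeds 2 points;
#' * `early_decline`: drop > 2 at year 2 without recovery (year-4 deficit
#'   also > 2);
#' * `late_decline`: drop > 2 only at year 4;
#' * `fluctuation`: drop > 2 at year 2 followed by recovery to within 2
#'   points of baseline at year 4 (a year-4 deficit of exactly 2 counts as
#'   recovered).
#'
#' Every decline-labelled subject (see [decline_label()]) falls in one of
#' `early_decline`, `late_decline` or `fluctuation`; stable subjects are
#' exactly the non-decliners.
#'
#' @param baseline,y2,y4 Numeric vectors of MoCA totals; all three must be
#'   present.
#' @return Character vector of categories.
#' @examples
#' classify_trajectory(28, 28, 28)  # stable
#' classify_trajectory(28, 24, 24)  # early_decline
#' classify_trajectory(28, 24, 27)  # fluctuation
#' @export
classify_trajectory <- function(baseline, y2, y4) {
  if (any(is.na(baseline) | is.na(y2) | is.na(y4))) {
    abort("Trajectory classification needs all three MoCA scores.")
  }
  d2 <- baseline - y2
  d4 <- baseline - y4
  dplyr::case_when(
    d2 > 2 & d4 > 2 ~ "early_decline",
    d2 <= 2 & d4 > 2 ~ "late_decline",
    d2 > 2 & d4 <= 2 ~ "fluctuation",
    TRUE ~ "stable"
  )
}

#' Add decline and trajectory labels to a cohort
#'
#' Appends a 0/1 `decline` column (and, where all three MoCA scores are
#' present, a `trajectory` column) to a cohort table.
#'
#' @param data Cohort with columns `moca_baseline`, `moca_y2`, `moca_y4`.
#' @return `data` with `decline` (integer 0/1) and `trajectory` (character,
#'   `NA` for incomplete follow-ups) columns.
#' @export
label_cohort <- function(data) {
  needed <- c("moca_baseline", "moca_y2", "moca_y4")
  if (!all(needed %in% names(data))) {
    abort(sprintf("Cohort must contain columns %s.", paste(needed, collapse = ", ")))
  }
  data <- as_tibble(data)
  data$decline <- as.integer(
    decline_label(data$moca_baseline, data$moca_y2, data$moca_y4)
  )
  complete <- !is.na(data$moca_y2) & !is.na(data$moca_y4)
  traj <- rep(NA_character_, nrow(data))
  if (any(complete)) {
    traj[complete] <- classify_trajectory(
      data$moca_baseline[complete], data$moca_y2[complete], data$moca_y4[complete]
    )
  }
  data$trajectory <- traj
  data
}

#' Trajectory category frequency table
#'
#' Counts and proportions of the four trajectory categories among subjects
#' with complete follow-ups, in the style of a cohort pie-chart summary.
#'
#' @param data A labelled cohort (see [label_cohort()]).
#' @return A tibble: `trajectory`, `n`, `proportion`.
#' @export
trajectory_table <- function(data) {
  if (!"trajectory" %in% names(data)) data <- label_cohort(data)
  tab <- data[!is.na(data$trajectory), , drop = FALSE]
  levels <- c("stable", "early_decline", "late_decline", "fluctuation")
  counts <- purrr::map_int(levels, ~ sum(tab$trajectory == .x))
  tibble(
    trajectory = levels, n = counts,
    proportion = if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 4)
  )
}

#' Bin a normalized MoCA z-score
#'
#' `above_average` for z-scores above 0, `below_average` for scores between
#' -1 and 0 (both bounds inclusive), `abnormal` below -1.
#'
#' @param z Finite numeric vector.
#' @return Character vector of bins.
#' @examples
#' zscore_bins(c(0.5, 0, -1, -1.5))
#' @export
zscore_bins <- function(z) {
  if (any(!is.finite(z))) abort("`z` must be finite.")
  dplyr::case_when(
    z > 0 ~ "above_average",
    z >= -1 ~ "below_average",
    TRUE ~ "abnormal"
  )
}

#' Categorize a MoCA change score
#'
#' Decline for a drop of more than 2 points, improvement for a rise of more
#' than 2 points, stable otherwise.
#'
#' @param delta Integer change (follow-up minus baseline).
#' @return Character vector.
#' @export
change_category <- function(delta) {
  dplyr::case_when(
    delta < -2 ~ "decline",
    delta > 2 ~ "improvement",
    TRUE ~ "stable"
  )
}
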