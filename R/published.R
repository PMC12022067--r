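#' Published age-of-onset brackets and bracket priors
#'
#' The published four-question model estimates the prior probability of
#' cognitive decline within half-open age-of-onset brackets: `[30, 40)`,
#' then 5-year intervals up to `[75, 100)`.  `published_brackets()` returns
#' the bracket grid; `published_priors()` returns the per-bracket subject and
#' decliner counts for the development cohort (PPMI), the validation cohort
#' (BIO-PD), or both pooled, together with the implied prior `decliners / n`.
#'
#' Pooling across cohorts is simply summing decliner and subject counts per
#' bracket, which smooths the sparse extreme brackets.
#'
#' @param cohort One of `"combined"`, `"ppmi"`, `"biopd"`.
#' @return `published_brackets()`: a tibble with columns `bracket_lo`,
#'   `bracket_hi`.  `published_priors()`: a [cognilr_priors] tibble with
#'   columns `bracket_lo`, `bracket_hi`, `n`, `decliners`, `prior`, carrying
#'   the overall prior as an attribute.
#' @examples
#' published_priors()
#' published_priors("ppmi")
#' @export
published_brackets <- function() {
  tibble(
    bracket_lo = c(30, 40, 45, 50, 55, 60, 65, 70, 75),
    bracket_hi = c(40, 45, 50, 55, 60, 65, 70, 75, 100)
  )
}

# per-bracket counts for the two study cohorts (decliners reconstructed as
# round(n * printed prior); overall totals 49/186 and 9/48 check out)
published_bracket_counts <- function() {
  br <- published_brackets()
  tibble(
    bracket_lo = br$bracket_lo,
    bracket_hi = br$bracket_hi,
    n_ppmi = c(4L, 6L, 25L, 24L, 31L, 37L, 34L, 13L, 8L),
    dec_ppmi = c(2L, 2L, 3L, 3L, 5L, 10L, 15L, 4L, 5L),
    n_biopd = c(5L, 1L, 6L, 3L, 10L, 6L, 6L, 6L, 3L),
    dec_biopd = c(1L, 0L, 0L, 0L, 3L, 0L, 1L, 2L, 2L)
  )
}

#' @rdname published_brackets
#' @export
published_priors <- function(cohort = c("combined", "ppmi", "biopd")) {
  cohort <- match.arg(cohort)
  counts <- published_bracket_counts()
  tab <- switch(cohort,
    ppmi = tibble(
      bracket_lo = counts$bracket_lo, bracket_hi = counts$bracket_hi,
      n = counts$n_ppmi, decliners = counts$dec_ppmi
    ),
    biopd = tibble(
      bracket_lo = counts$bracket_lo, bracket_hi = counts$bracket_hi,
      n = counts$n_biopd, decliners = counts$dec_biopd
    ),
    combined = tibble(
      bracket_lo = counts$bracket_lo, bracket_hi = counts$bracket_hi,
      n = counts$n_ppmi + counts$n_biopd,
      decliners = counts$dec_ppmi + counts$dec_biopd
    )
  )
  # overall totals include subjects with missing age of onset
  totals <- switch(cohort,
    ppmi = c(n = 186L, decliners = 49L),
    biopd = c(n = 48L, decliners = 9L),
    combined = c(n = 234L, decliners = 58L)
  )
  new_priors(tab, n_overall = totals[["n"]], decliners_overall = totals[["decliners"]])
}

#' The published four-question prognostic model
#'
#' Loads the packaged fixture encoding the final published model: pooled
#' age-bracket priors plus three risk features -- history of stroke
#' (infinite positive likelihood ratio: every affected subject declined),
#' fainting in the past six months (LR+ 2.80), and vocalization during
#' dreams (LR+ 2.70).  None of the three qualifies on the protective side
#' (all LR- >= 0.5), so an absent feature contributes no evidence and the
#' model only "rules in" decline.
#'
#' @return A [prognostic_model] object.
#' @examples
#' m <- published_model()
#' tidy(m)
#' predict(m, tibble::tibble(
#'   age_of_onset = 62, stroke = 0, fainting = 1, vocalization = 1
#' ))
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_model.json", package = "cognilr")
  read_model(path)
}
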