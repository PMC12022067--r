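#' Diagnostic likelihood ratios from a 2x2 table
#'
#' Computes the positive and negative likelihood ratio of a binary feature
#' against a binary outcome from the four cell counts: `tp` decliners with
#' the feature, `fn` decliners without it, `fp` non-decliners with it and
#' `tn` non-decliners without it.  `LR+ = sensitivity / (1 - specificity)`
#' and `LR- = (1 - sensitivity) / specificity`.  When no non-decliner shows
#' the feature but some decliners do, `LR+` is reported as `Inf` (every
#' subject with the symptom was correctly identified); no continuity
#' correction is applied by default.
#'
#' @param tp,fn,fp,tn Nonnegative integer cell counts.
#' @param correction Haldane-Anscombe continuity correction: add 0.5 to
#'   every cell before computing the ratios (default `FALSE`).
#' @return A one-row tibble: counts, `sensitivity`, `specificity`, `lr_pos`,
#'   `lr_neg`, `presence_proportion`, `presence_odds`, `fisher_p`.
#' @examples
#' likelihood_ratios(tp = 1, fn = 48, fp = 1, tn = 136) # LR+ = 137/49 = 2.80
#' likelihood_ratios(tp = 46, fn = 3, fp = 106, tn = 31) # LR- = 0.27
#' @export
likelihood_ratios <- function(tp, fn, fp, tn, correction = FALSE) {
  cells <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be nonnegative integers.")
  }
  if (tp + fn == 0L || fp + tn == 0L) {
    abort("Both outcome classes must contain at least one subject.")
  }
  fisher_p <- fisher_exact(tp, fn, fp, tn)
  if (correction) {
    tp <- tp + 0.5; fn <- fn + 0.5; fp <- fp + 0.5; tn <- tn + 0.5
  }
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  lr_pos <- if (spec == 1) {
    if (sens > 0) Inf else NaN
  } else sens / (1 - spec)
  lr_neg <- if (spec == 0) {
    if (sens < 1) Inf else NaN
  } else (1 - sens) / spec
  total <- tp + fn + fp + tn
  npos <- tp + fp
  tibble(
    tp = cells[["tp"]], fn = cells[["fn"]], fp = cells[["fp"]], tn = cells[["tn"]],
    sensitivity = sens, specificity = spec,
    lr_pos = lr_pos, lr_neg = lr_neg,
    presence_proportion = npos / total,
    presence_odds = if (npos == total) Inf else npos / (total - npos),
    fisher_p = fisher_p
  )
}

#' Per-feature diagnostic statistics for a labelled cohort
#'
#' Applies [likelihood_ratios()] to every feature column and assigns each
#' feature its qualification role via [qualify_feature()].  Missing feature
#' values are treated as absent symptoms.
#'
#' @param features A data frame of logical or 0/1 feature columns.
#' @param outcome Logical (or 0/1) outcome vector, one element per row.
#' @return A tibble with one row per feature: `feature` plus every column of
#'   [likelihood_ratios()] and `role`.
#' @export
feature_stats <- function(features, outcome) {
  features <- as.data.frame(features)
  outcome <- as.logical(outcome)
  if (nrow(features) != length(outcome)) {
    abort("`features` and `outcome` must have the same number of subjects.")
  }
  if (!any(outcome) || all(outcome)) {
    abort("Both outcome classes must contain at least one subject.")
  }
  out <- purrr::imap(features, function(col, nm) {
    x <- as.logical(col)
    x[is.na(x)] <- FALSE
    st <- likelihood_ratios(
      tp = sum(x & outcome), fn = sum(!x & outcome),
      fp = sum(x & !outcome), tn = sum(!x & !outcome)
    )
    dplyr::bind_cols(tibble(feature = nm), st)
  }) %>% bind_rows()
  out$role <- qualify_feature(out$lr_pos, out$lr_neg, out$presence_proportion)
  out
}

#' Feature qualification rule
#'
#' A feature qualifies as a risk factor ("ruling in" decline) when its
#' positive likelihood ratio exceeds 2 and the odds of symptom presence
#' exceed 0.01; it qualifies as protective ("ruling out") when its negative
#' likelihood ratio is below 0.5 and the odds of symptom absence are below
#' 0.99 (the protective evidence is the absent symptom, so its odds bound is
#' the mirror of the presence bound).  A feature may qualify on both sides,
#' or on neither (`rejected`).
#'
#' @param lr_pos,lr_neg Likelihood ratios (vectors).
#' @param presence_proportion Fraction of subjects feature-positive.
#' @return Character vector: `"risk"`, `"protective"`, `"both"`, `"rejected"`.
#' @examples
#' qualify_feature(2.80, 0.97, 0.02)  # risk
#' qualify_feature(1.21, 0.27, 0.82)  # protective
#' qualify_feature(2.70, 0.56, 0.30)  # risk (0.56 is not < 0.5)
#' @export
qualify_feature <- function(lr_pos, lr_neg, presence_proportion) {
  presence_odds <- ifelse(presence_proportion == 1, Inf,
                          presence_proportion / (1 - presence_proportion))
  absence_odds <- ifelse(presence_proportion == 0, Inf,
                         (1 - presence_proportion) / presence_proportion)
  risk <- !is.na(lr_pos) & lr_pos > 2 & presence_odds > 0.01
  protective <- !is.na(lr_neg) & lr_neg < 0.5 & absence_odds < 0.99
  dplyr::case_when(
    risk & protective ~ "both",
    risk ~ "risk",
    protective ~ "protective",
    TRUE ~ "rejected"
  )
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Thin wrapper over [stats::fisher.test()] on the cell counts.
#'
#' @inheritParams likelihood_ratios
#' @return The two-sided p-value.
#' @export
fisher_exact <- function(tp, fn, fp, tn) {
  stats::fisher.test(matrix(c(tp, fn, fp, tn), nrow = 2))$p.value
}

#' Spearman rank correlation with p-value
#'
#' @param x,y Numeric vectors.
#' @return A one-row tibble: `rho`, `p_value`.
#' @export
spearman_rho <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Normality-gated two-group comparison
#'
#' Compares a variable between two groups the way clinical baseline tables
#' are built: Shapiro-Wilk normality testing per group, then a two-sided
#' t-test when both groups look normal, otherwise a Wilcoxon rank-sum test.
#' Discrete variables (all whole numbers) are assumed non-normal.  Constant
#' input skips the normality gate and falls back to the rank test; a
#' variable constant overall is reported as not applicable.
#'
#' @param values Numeric vector (missing values dropped).
#' @param groups Two-level grouping vector aligned with `values`.
#' @param discrete Force the discreteness assumption; default `NULL`
#'   auto-detects whole-number input.
#' @return A one-row tibble: `test` ("t", "wilcoxon" or "none"),
#'   `statistic`, `p_value`, `reason`.
#' @export
group_compare <- function(values, groups, discrete = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- groups[keep]
  lev <- unique(groups)
  if (length(lev) != 2L || !all(table(groups) > 0L)) {
    abort("`groups` must define exactly two nonempty groups.")
  }
  g1 <- values[groups == lev[1]]
  g2 <- values[groups == lev[2]]
  if (length(unique(values)) == 1L) {
    return(tibble(test = "none", statistic = NA_real_, p_value = NA_real_,
                  reason = "constant variable"))
  }
  if (is.null(discrete)) discrete <- all(values == round(values))
  normal <- FALSE
  reason <- NULL
  if (discrete) {
    reason <- "discrete variable assumed non-normal"
  } else if (length(unique(g1)) == 1L || length(unique(g2)) == 1L ||
             length(g1) < 3L || length(g2) < 3L) {
    reason <- "group constant or too small for a normality test"
  } else {
    p1 <- shapiro.test(g1)$p.value
    p2 <- shapiro.test(g2)$p.value
    normal <- p1 > 0.05 && p2 > 0.05
    reason <- sprintf("Shapiro-Wilk p = %.3g / %.3g", p1, p2)
  }
  if (normal) {
    tt <- t.test(g1, g2)
    tibble(test = "t", statistic = unname(tt$statistic), p_value = tt$p.value,
           reason = reason)
  } else {
    wt <- suppressWarnings(wilcox.test(g1, g2))
    tibble(test = "wilcoxon", statistic = unname(wt$statistic),
           p_value = wt$p.value, reason = reason)
  }
}

#' Hypothesis-consistent cutoff search for a continuous predictor
#'
#' Iterates over the grid of distinct observed values as candidate cutoffs.
#' At each candidate the variable is binarized in the direction of its
#' hypothesis sign (`+1`: higher values are riskier, feature present when
#' `value > cutoff`; `-1`: feature present when `value < cutoff`), and the
#' positive likelihood ratio of the induced feature is computed.  The cutoff
#' maximizing LR+ among candidates with presence odds above `min_odds` is
#' returned, together with the Spearman correlation between candidate cutoff
#' and induced LR+ across the grid.  The cutoff is accepted only when the
#' sign of that correlation matches the hypothesis sign and its magnitude
#' reaches `consistency_floor` -- a guard against overfitting the threshold.
#'
#' @param values Numeric predictor (at least two distinct values).
#' @param outcomes Logical or 0/1 outcome vector.
#' @param hypothesis_sign `+1` or `-1`.
#' @param min_odds Minimum presence odds for an admissible cutoff.
#' @param consistency_floor Minimum `|rho|` for acceptance (default 0.7).
#' @return A list: `cutoff`, `lr_pos`, `rho`, `accepted`, `rejected_reason`
#'   (NA when accepted) and `grid` (per-candidate tibble).
#' @export
optimize_cutoff <- function(values, outcomes, hypothesis_sign,
                            min_odds = 0.01, consistency_floor = 0.7) {
  keep <- !is.na(values) & !is.na(outcomes)
  values <- values[keep]
  outcomes <- as.logical(outcomes[keep])
  if (length(unique(values)) < 2L) abort("Need at least two distinct values.")
  if (!hypothesis_sign %in% c(-1, 1)) abort("`hypothesis_sign` must be +1 or -1.")
  candidates <- sort(unique(values))
  grid <- purrr::map(candidates, function(cand) {
    x <- if (hypothesis_sign > 0) values > cand else values < cand
    npos <- sum(x)
    odds <- if (npos == length(x)) Inf else npos / (length(x) - npos)
    lr <- if (npos == 0L || npos == length(x)) NA_real_ else {
      sens <- sum(x & outcomes) / sum(outcomes)
      spec <- sum(!x & !outcomes) / sum(!outcomes)
      if (spec == 1) {
        if (sens > 0) Inf else NA_real_
      } else sens / (1 - spec)
    }
    tibble(cutoff = cand, lr_pos = lr, presence_odds = odds)
  }) %>% bind_rows()
  usable <- grid[!is.na(grid$lr_pos), , drop = FALSE]
  admissible <- usable[usable$presence_odds > min_odds, , drop = FALSE]
  if (nrow(admissible) == 0L) {
    return(list(cutoff = NA_real_, lr_pos = NA_real_, rho = NA_real_,
                accepted = FALSE, rejected_reason = "no admissible cutoff",
                grid = grid))
  }
  best <- admissible[which.max(admissible$lr_pos), ]
  finite <- usable[is.finite(usable$lr_pos), , drop = FALSE]
  rho <- if (nrow(finite) >= 3L) {
    suppressWarnings(cor(finite$cutoff, finite$lr_pos, method = "spearman"))
  } else NA_real_
  consistent <- !is.na(rho) && sign(rho) == hypothesis_sign &&
    abs(rho) >= consistency_floor
  list(
    cutoff = best$cutoff,
    lr_pos = best$lr_pos,
    rho = rho,
    accepted = consistent,
    rejected_reason = if (consistent) NA_character_ else
      "threshold-performance trend inconsistent with the hypothesis",
    grid = grid
  )
}
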