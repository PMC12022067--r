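#' ROC curve and AUC of a posterior score
#'
#' `roc_points()` sweeps every distinct score as a decision threshold
#' (predict positive when `score >= threshold`) and returns the resulting
#' (1 - specificity, sensitivity) points, anchored at (0, 0) and (1, 1).
#' `auc()` is the trapezoidal area under that curve, which equals the
#' Mann-Whitney statistic with ties counted 1/2 -- the tie convention
#' matters because posteriors from a small feature set are heavily tied.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Logical or 0/1 outcome labels; both classes must be
#'   present.
#' @return `roc_points()`: a `cognilr_roc` tibble with columns `threshold`,
#'   `fpr`, `tpr`.  `auc()`: a single probability.
#' @examples
#' auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)) # 1: perfect separation
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (!any(labels) || all(labels)) {
    abort("Both outcome classes must be present to build a ROC curve.")
  }
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels); n0 <- sum(!labels)
  tpr <- purrr::map_dbl(thresholds, ~ sum(scores >= .x & labels) / n1)
  fpr <- purrr::map_dbl(thresholds, ~ sum(scores >= .x & !labels) / n0)
  out <- tibble(
    threshold = c(Inf, thresholds, -Inf),
    fpr = c(0, fpr, 1),
    tpr = c(0, tpr, 1)
  )
  class(out) <- c("cognilr_roc", class(out))
  out
}

#' @rdname roc_points
#' @export
auc <- function(scores, labels) {
  roc <- roc_points(scores, labels)
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Confusion-matrix metrics of predicted labels
#'
#' @param predicted,labels Aligned logical (or 0/1) vectors.
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`
#'   (NA where a class is absent).
#' @export
confusion_metrics <- function(predicted, labels) {
  predicted <- as.logical(predicted)
  labels <- as.logical(labels)
  if (length(predicted) != length(labels) || length(labels) == 0L) {
    abort("`predicted` and `labels` must be nonempty aligned vectors.")
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  tibble(
    sensitivity = if (n1 > 0) sum(predicted & labels) / n1 else NA_real_,
    specificity = if (n0 > 0) sum(!predicted & !labels) / n0 else NA_real_,
    accuracy = mean(predicted == labels)
  )
}

#' Repeated random subsampling cross-validation
#'
#' Per repetition, a uniform random split assigns `floor(train_fraction * n)`
#' subjects to training and the remainder to test.  The full fitting
#' pipeline -- age-bracket priors and per-feature likelihood ratios, with the
#' feature set fixed by `feature_cols` -- is refit on the training part, and
#' the AUC of the refit model's posteriors is measured on the test part.
#' Splits whose training or test part lacks one of the outcome classes are
#' redrawn (the count is recorded).  Results are reproducible from `seed`.
#'
#' @inheritParams fit_prognostic_model
#' @param train_fraction Fraction of subjects used for training.
#' @param reps Number of random splits.
#' @param seed Integer seed.
#' @param max_redraws Redraw budget for degenerate splits across the run.
#' @return A `cognilr_cv` object: list with `auc` (per-repetition tibble),
#'   `cv_mean_auc`, `cv_sd_auc`, `n_repetitions`, `redraws`, `seed`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 300, seed = 3))
#' cv <- repeated_cv(cohort, c("fainting", "vocalization"), reps = 5, seed = 3)
#' glance(cv)
#' @export
repeated_cv <- function(data, feature_cols, brackets = published_brackets(),
                        age = "age_of_onset", outcome = "decline",
                        train_fraction = 0.8, reps = 300, seed = NULL,
                        qualify = TRUE, role = NULL, max_redraws = 1000L) {
  if (reps < 1) abort("`reps` must be at least 1.")
  n <- nrow(data)
  n_train <- floor(train_fraction * n)
  if (n_train < 2L || n - n_train < 2L) {
    abort("Cohort too small for the requested split.")
  }
  y <- as.logical(data[[outcome]])
  if (sum(y) < 2L || sum(!y) < 2L) {
    abort("Cohort cannot form a two-class train/test split.")
  }
  with_seed(seed, {
    redraws <- 0L
    aucs <- numeric(reps)
    for (r in seq_len(reps)) {
      repeat {
        idx <- sample.int(n, n_train)
        train_y <- y[idx]; test_y <- y[-idx]
        ok <- any(train_y) && !all(train_y) && any(test_y) && !all(test_y)
        if (ok) break
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          abort("Redraw budget exhausted: splits keep losing an outcome class.")
        }
      }
      fit <- fit_prognostic_model(
        data[idx, , drop = FALSE], feature_cols, brackets = brackets,
        age = age, outcome = outcome, qualify = qualify, role = role
      )
      post <- posterior_probability(
        fit, data[[age]][-idx], data[-idx, , drop = FALSE]
      )
      aucs[r] <- auc(post, test_y)
    }
    structure(
      list(
        auc = tibble(repetition = seq_len(reps), auc = aucs),
        cv_mean_auc = mean(aucs),
        cv_sd_auc = if (reps > 1) sd(aucs) else 0,
        n_repetitions = reps,
        redraws = redraws,
        seed = seed
      ),
      class = "cognilr_cv"
    )
  })
}

#' @export
print.cognilr_cv <- function(x, ...) {
  cat(sprintf("<cognilr_cv> %d repetitions: mean AUC %.3f +/- %.3f sd (%d redraws)\n",
              x$n_repetitions, x$cv_mean_auc, x$cv_sd_auc, x$redraws))
  invisible(x)
}

#' @export
tidy.cognilr_cv <- function(x, ...) x$auc

#' @export
glance.cognilr_cv <- function(x, ...) {
  tibble(
    cv_mean_auc = x$cv_mean_auc, cv_sd_auc = x$cv_sd_auc,
    n_repetitions = x$n_repetitions, redraws = x$redraws
  )
}

#' Baseline characteristics table by outcome group
#'
#' Summarises cohort variables per outcome group the way clinical baseline
#' tables are printed: `mean +/- sd (min-max)` with the normality-gated
#' two-group test of [group_compare()] for numeric variables, and
#' `positives/total (percent)` with Fisher's exact test for binary ones.
#' Missing values are dropped per comparison.  Constant variables are
#' reported with no test.
#'
#' @param data Labelled cohort.
#' @param vars Character vector of variable names to summarise.
#' @param by Outcome column (default `"decline"`).
#' @return A tibble: `variable`, `type`, one formatted column per group,
#'   `test`, `p_value`.
#' @export
cohort_report <- function(data, vars, by = "decline") {
  y <- as.logical(data[[by]])
  groups <- list(`FALSE` = which(!y), `TRUE` = which(y))
  rows <- purrr::map(vars, function(v) {
    x <- data[[v]]
    if (is.null(x)) abort(sprintf("Variable `%s` not in cohort.", v))
    is_binary <- is.logical(x) ||
      all(stats::na.omit(unique(as.numeric(x))) %in% c(0, 1))
    if (is_binary) {
      xl <- as.logical(x)
      fmt <- purrr::map_chr(groups, function(i) {
        xi <- xl[i]; xi <- xi[!is.na(xi)]
        sprintf("%d/%d (%.2f%%)", sum(xi), length(xi),
                if (length(xi)) 100 * mean(xi) else NA_real_)
      })
      tp <- sum(xl & y, na.rm = TRUE); fn_ <- sum(!xl & y, na.rm = TRUE)
      fp <- sum(xl & !y, na.rm = TRUE); tn <- sum(!xl & !y, na.rm = TRUE)
      p <- if ((tp + fn_) > 0 && (fp + tn) > 0) fisher_exact(tp, fn_, fp, tn) else NA_real_
      tibble(variable = v, type = "binary",
             no_decline = fmt[["FALSE"]], decline = fmt[["TRUE"]],
             test = "fisher", p_value = p)
    } else {
      xn <- as.numeric(x)
      fmt <- purrr::map_chr(groups, function(i) {
        xi <- xn[i]; xi <- xi[!is.na(xi)]
        if (!length(xi)) return(NA_character_)
        sprintf("%.2f ± %.2f (%.2f-%.2f)", mean(xi), sd(xi), min(xi), max(xi))
      })
      keep <- !is.na(xn)
      cmp <- group_compare(xn[keep], y[keep])
      tibble(variable = v, type = "numeric",
             no_decline = fmt[["FALSE"]], decline = fmt[["TRUE"]],
             test = if (cmp$test == "none") "not applicable" else cmp$test,
             p_value = cmp$p_value)
    }
  })
  bind_rows(rows)
}
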