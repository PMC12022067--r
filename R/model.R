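#' Age-bracket prior probabilities of cognitive decline
#'
#' Estimates the prior probability of cognitive decline within half-open
#' age-of-onset brackets as the pooled proportion of decliners per bracket.
#' Several labelled cohorts may be supplied; pooling sums decliner and
#' subject counts across them bracket by bracket.  Subjects with a missing
#' age of onset contribute to the overall (fallback) prior only.
#'
#' @param data A labelled cohort: a data frame with an age column and a 0/1
#'   (or logical) outcome column.
#' @param ... Further labelled cohorts to pool with `data`.
#' @param brackets A data frame with columns `bracket_lo`, `bracket_hi`
#'   defining ordered half-open intervals (default [published_brackets()]).
#' @param age,outcome Column names (strings) of age of onset and the decline
#'   label.
#' @return A `cognilr_priors` tibble: `bracket_lo`, `bracket_hi`, `n`,
#'   `decliners`, `prior` (`NA` for empty brackets; lookups fall back to the
#'   overall prior), with attributes `n_overall` and `decliners_overall`.
#' @examples
#' cohort <- tibble::tibble(age_of_onset = c(77, 76, 80), decline = c(1, 1, 0))
#' estimate_priors(cohort, brackets = tibble::tibble(bracket_lo = 75, bracket_hi = 100))
#' @export
estimate_priors <- function(data, ..., brackets = published_brackets(),
                            age = "age_of_onset", outcome = "decline") {
  cohorts <- c(list(data), list(...))
  rows <- purrr::map(cohorts, function(d) {
    if (!is.data.frame(d)) abort("Each cohort must be a data frame.")
    if (!all(c(age, outcome) %in% names(d))) {
      abort(sprintf("Cohort lacks required columns `%s` and/or `%s`.", age, outcome))
    }
    tibble(age = as.numeric(d[[age]]), y = as.integer(as.logical(d[[outcome]])))
  })
  pooled <- bind_rows(rows)
  pooled <- pooled[!is.na(pooled$y), , drop = FALSE]
  if (nrow(pooled) == 0L) abort("No labelled subjects: cannot estimate priors.")
  check_brackets(brackets)
  idx <- assign_bracket(pooled$age, brackets$bracket_lo, brackets$bracket_hi)
  tab <- tibble(
    bracket_lo = brackets$bracket_lo,
    bracket_hi = brackets$bracket_hi,
    n = purrr::map_int(seq_len(nrow(brackets)), ~ sum(idx == .x, na.rm = TRUE)),
    decliners = purrr::map_int(
      seq_len(nrow(brackets)),
      ~ sum(pooled$y[!is.na(idx) & idx == .x])
    )
  )
  if (any(tab$n == 0L)) {
    inform(sprintf(
      "Empty age bracket(s) %s: prior undefined there, lookups fall back to the overall prior.",
      paste(sprintf("[%g,%g)", tab$bracket_lo[tab$n == 0], tab$bracket_hi[tab$n == 0]),
            collapse = ", ")
    ))
  }
  new_priors(tab, n_overall = nrow(pooled), decliners_overall = sum(pooled$y))
}

check_brackets <- function(brackets) {
  if (!is.data.frame(brackets) ||
      !all(c("bracket_lo", "bracket_hi") %in% names(brackets))) {
    abort("`brackets` must be a data frame with columns bracket_lo, bracket_hi.")
  }
  lo <- brackets$bracket_lo
  hi <- brackets$bracket_hi
  if (any(hi <= lo) || is.unsorted(lo, strictly = TRUE) ||
      any(utils::head(hi, -1) > lo[-1])) {
    abort("Brackets must be ordered, non-overlapping half-open intervals.")
  }
  invisible(brackets)
}

new_priors <- function(tab, n_overall, decliners_overall) {
  tab$prior <- ifelse(tab$n > 0L, tab$decliners / tab$n, NA_real_)
  out <- as_tibble(tab)
  attr(out, "n_overall") <- as.integer(n_overall)
  attr(out, "decliners_overall") <- as.integer(decliners_overall)
  class(out) <- c("cognilr_priors", class(out))
  out
}

#' @rdname estimate_priors
#' @param priors A `cognilr_priors` object.
#' @return `overall_prior()`: the pooled decliner proportion over all
#'   labelled subjects (the fallback when age is missing or falls in an
#'   empty or out-of-range bracket).
#' @export
overall_prior <- function(priors) {
  attr(priors, "decliners_overall") / attr(priors, "n_overall")
}

#' @rdname estimate_priors
#' @return `lookup_prior()`: the bracket prior for each age, falling back to
#'   the overall prior for missing/out-of-range ages and empty brackets.
#' @export
lookup_prior <- function(priors, age) {
  idx <- assign_bracket(age, priors$bracket_lo, priors$bracket_hi)
  p <- priors$prior[idx]
  fallback <- is.na(p)
  p[fallback] <- overall_prior(priors)
  p
}

#' Construct a likelihood-ratio naive Bayes prognostic model
#'
#' A prognostic model is an age-bracket prior table plus a set of qualified
#' binary features, each carrying its positive and negative likelihood ratio
#' and a role.  Prediction multiplies the subject's prior odds by `lr_pos`
#' for every present feature whose role is `"risk"` or `"both"`, and by
#' `lr_neg` for every absent feature whose role is `"protective"` or
#' `"both"`; a feature therefore contributes nothing on its unqualified
#' side.  The posterior probability is `odds / (1 + odds)`.
#'
#' @param priors A `cognilr_priors` object (see [estimate_priors()]).
#' @param features A data frame with columns `name`, `lr_pos`, `lr_neg`,
#'   `role` (one of risk/protective/both); `lr_pos` may be `Inf`.
#' @param decision_cutoff Posterior probability at or above which a subject
#'   is labelled positive (default 0.5, inclusive).
#' @return An object of class `prognostic_model`.
#' @seealso [fit_prognostic_model()], [published_model()]
#' @export
prognostic_model <- function(priors, features, decision_cutoff = 0.5) {
  if (!inherits(priors, "cognilr_priors")) abort("`priors` must be a cognilr_priors object.")
  features <- as_tibble(features)
  required <- c("name", "lr_pos", "lr_neg", "role")
  if (!all(required %in% names(features))) {
    abort("`features` needs columns name, lr_pos, lr_neg, role.")
  }
  if (nrow(features) && !all(features$role %in% c("risk", "protective", "both"))) {
    abort("Feature roles must be one of 'risk', 'protective', 'both'.")
  }
  if (nrow(features) && (any(features$lr_pos < 0, na.rm = TRUE) ||
                         any(features$lr_neg < 0, na.rm = TRUE))) {
    abort("Likelihood ratios must be nonnegative.")
  }
  stopifnot_scalar_number(decision_cutoff, "decision_cutoff")
  structure(
    list(priors = priors, features = features, decision_cutoff = decision_cutoff),
    class = "prognostic_model"
  )
}

#' Fit a prognostic model from a labelled cohort
#'
#' Runs the estimation pipeline on binarized features: age-bracket priors by
#' [estimate_priors()], per-feature likelihood ratios by [feature_stats()],
#' and (optionally) the qualification rule of [qualify_feature()].
#' Unqualified (`rejected`) features are dropped when `qualify = TRUE`.
#'
#' @param data Labelled cohort containing the age column, outcome column and
#'   one 0/1 (or logical) column per feature.
#' @param feature_cols Character vector of feature column names.
#' @param brackets Bracket grid for the priors.
#' @param age,outcome Column names of age of onset and the decline label.
#' @param qualify If `TRUE` (default) keep only features passing the
#'   likelihood-ratio qualification rule; if `FALSE`, keep every feature.
#' @param role Optional fixed role assigned to every feature when
#'   `qualify = FALSE` (e.g. `"both"` to apply both likelihood-ratio sides).
#' @param decision_cutoff Decision threshold for predicted labels.
#' @return A `prognostic_model`; the full per-feature statistics table is
#'   attached as attribute `"stats"`.
#' @examples
#' cfg <- synth_config(n_subjects = 500, seed = 7)
#' cohort <- generate_cohort(cfg)
#' fit_prognostic_model(cohort, feature_cols = c("stroke", "fainting", "vocalization"))
#' @export
fit_prognostic_model <- function(data, feature_cols,
                                 brackets = published_brackets(),
                                 age = "age_of_onset", outcome = "decline",
                                 qualify = TRUE, role = NULL,
                                 decision_cutoff = 0.5) {
  missing_cols <- setdiff(feature_cols, names(data))
  if (length(missing_cols)) {
    abort(sprintf("Feature column(s) not in data: %s", paste(missing_cols, collapse = ", ")))
  }
  priors <- estimate_priors(data, brackets = brackets, age = age, outcome = outcome)
  if (length(feature_cols) == 0L) {
    empty <- tibble(name = character(), lr_pos = numeric(),
                    lr_neg = numeric(), role = character())
    return(prognostic_model(priors, empty, decision_cutoff = decision_cutoff))
  }
  stats <- feature_stats(data[feature_cols], outcome = as.logical(data[[outcome]]))
  feats <- stats[, c("feature", "lr_pos", "lr_neg", "role")]
  names(feats)[1] <- "name"
  if (!is.null(role)) {
    feats$role <- role
  } else if (qualify) {
    feats <- feats[feats$role != "rejected", , drop = FALSE]
  } else {
    feats$role[feats$role == "rejected"] <- "risk"
  }
  model <- prognostic_model(priors, feats, decision_cutoff = decision_cutoff)
  attr(model, "stats") <- stats
  model
}

#' Posterior probability of cognitive decline
#'
#' Sequential Bayes updating on the odds scale: starting from the prior odds
#' of the subject's age-of-onset bracket (overall prior if age is missing),
#' each present feature with a risk-qualified side multiplies the odds by
#' its `lr_pos`, and each absent feature with a protective-qualified side
#' multiplies by its `lr_neg`.  A present feature with infinite `lr_pos`
#' forces a posterior of exactly 1 (for any prior in (0, 1)).  A missing
#' feature value is treated as an absent symptom.
#'
#' @param model A `prognostic_model`.
#' @param age_of_onset Numeric vector of ages (NA allowed).
#' @param features A data frame (or matrix) of 0/1 or logical feature values
#'   whose column names cover every model feature.
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @examples
#' m <- published_model()
#' posterior_probability(m, 62, tibble::tibble(stroke = 0, fainting = 1, vocalization = 1))
#' @export
posterior_probability <- function(model, age_of_onset, features) {
  stopifnot(inherits(model, "prognostic_model"))
  feats <- model$features
  n <- length(age_of_onset)
  if (nrow(feats)) {
    features <- as.data.frame(features)
    missing_cols <- setdiff(feats$name, names(features))
    if (length(missing_cols)) {
      abort(sprintf("Feature vector not aligned to the model: missing %s",
                    paste(missing_cols, collapse = ", ")))
    }
    if (nrow(features) != n) {
      abort("`features` must have one row per element of `age_of_onset`.")
    }
  }
  prior <- lookup_prior(model$priors, age_of_onset)
  log_odds <- log(prior) - log1p(-prior) # +-Inf at prior 0/1 handled below
  force_one <- rep(FALSE, n)
  force_zero <- rep(FALSE, n)
  if (nrow(feats)) {
    for (j in seq_len(nrow(feats))) {
      x <- as.logical(features[[feats$name[j]]])
      x[is.na(x)] <- FALSE # missing item = absent symptom
      role <- feats$role[j]
      if (role %in% c("risk", "both")) {
        lrp <- feats$lr_pos[j]
        if (is.infinite(lrp)) {
          force_one <- force_one | x
        } else if (lrp == 0) {
          force_zero <- force_zero | x
        } else {
          log_odds <- log_odds + ifelse(x, log(lrp), 0)
        }
      }
      if (role %in% c("protective", "both")) {
        lrn <- feats$lr_neg[j]
        if (lrn == 0) {
          force_zero <- force_zero | !x
        } else if (is.infinite(lrn)) {
          force_one <- force_one | !x
        } else {
          log_odds <- log_odds + ifelse(x, 0, log(lrn))
        }
      }
    }
  }
  if (any(force_one & prior == 0)) {
    abort("Indeterminate evidence: infinite likelihood ratio applied on a prior of exactly 0.")
  }
  if (any(force_one & force_zero)) {
    abort("Indeterminate evidence: conflicting infinite and zero likelihood ratios.")
  }
  post <- stats::plogis(log_odds)
  post[prior == 0] <- 0
  post[prior == 1] <- 1
  post[force_one] <- 1
  post[force_zero & prior < 1] <- 0
  post
}

#' @rdname posterior_probability
#' @param posterior Posterior probabilities in `[0, 1]`.
#' @param cutoff Decision threshold; the label is positive when
#'   `posterior >= cutoff` (inclusive, matching a ">= 50%" decision rule).
#' @return `predict_label()`: a logical vector.
#' @export
predict_label <- function(posterior, cutoff = 0.5) {
  if (any(posterior < 0 | posterior > 1, na.rm = TRUE)) {
    abort("`posterior` must lie in [0, 1].")
  }
  posterior >= cutoff
}

#' @export
predict.prognostic_model <- function(object, newdata,
                                     age = "age_of_onset", ...) {
  if (!is.data.frame(newdata)) abort("`newdata` must be a data frame.")
  age_vals <- if (age %in% names(newdata)) newdata[[age]] else rep(NA_real_, nrow(newdata))
  post <- posterior_probability(object, age_vals, newdata)
  tibble(
    .posterior = post,
    .pred = predict_label(post, object$decision_cutoff)
  )
}

#' Bernoulli log-likelihood of a labelled cohort under a model
#'
#' `sum(y * log(p) + (1 - y) * log(1 - p))` with posteriors clipped to
#' `[eps, 1 - eps]` so that infinite-likelihood features cannot produce
#' `-Inf` terms on a mislabelled subject.
#'
#' @inheritParams posterior_probability
#' @param data Labelled cohort with age, outcome and feature columns.
#' @param outcome Outcome column name.
#' @param age Age column name.
#' @param eps Clipping constant (default 1e-12).
#' @return A single number.
#' @export
model_log_likelihood <- function(model, data, outcome = "decline",
                                 age = "age_of_onset", eps = 1e-12) {
  y <- as.integer(as.logical(data[[outcome]]))
  age_vals <- if (age %in% names(data)) data[[age]] else rep(NA_real_, nrow(data))
  p <- posterior_probability(model, age_vals, data)
  p <- clip(p, eps, 1 - eps)
  sum(y * log(p) + (1 - y) * log1p(-p))
}

#' Sequential backward elimination by likelihood-ratio test
#'
#' Compares the Bernoulli likelihood of the full model with that of the
#' model excluding each remaining feature.  The statistic
#' `LRTS = 2 * (LL_full - LL_without)` is referred to a chi-squared
#' distribution with 1 degree of freedom; per pass the single feature with
#' the smallest LRTS is removed if its LRTS falls below the `1 - alpha`
#' quantile (3.841 at `alpha = 0.05`), and the procedure repeats until every
#' remaining feature is significant.  Per-feature likelihood ratios are held
#' fixed (they are marginal quantities under the naive Bayes assumption);
#' set `re_estimate = TRUE` to refit them from `data` after each removal.
#'
#' @inheritParams model_log_likelihood
#' @param alpha Significance level of the per-feature test.
#' @param re_estimate Refit likelihood ratios after each removal?
#' @return The reduced `prognostic_model` with the elimination trace (a
#'   tibble: `step`, `feature`, `lrts`, `removed`) as attribute `"trace"`.
#'   A model reduced to zero features is returned as a prior-only model with
#'   a warning.
#' @export
lrts_backward_elimination <- function(model, data, alpha = 0.05,
                                      outcome = "decline", age = "age_of_onset",
                                      re_estimate = FALSE) {
  stopifnot(inherits(model, "prognostic_model"))
  if (nrow(model$features) < 1L) abort("Model has no features to eliminate.")
  crit <- qchisq(1 - alpha, df = 1)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    feats <- model$features
    if (nrow(feats) == 0L) break
    ll_full <- model_log_likelihood(model, data, outcome = outcome, age = age)
    lrts <- purrr::map_dbl(seq_len(nrow(feats)), function(j) {
      reduced <- prognostic_model(model$priors, feats[-j, , drop = FALSE],
                                  model$decision_cutoff)
      2 * (ll_full - model_log_likelihood(reduced, data, outcome = outcome, age = age))
    })
    worst <- which.min(lrts)
    drop_it <- lrts[worst] < crit
    trace[[step]] <- tibble(
      step = step, feature = feats$name, lrts = lrts,
      removed = seq_along(lrts) == worst & drop_it
    )
    if (!drop_it) break
    kept <- feats[-worst, , drop = FALSE]
    if (re_estimate && nrow(kept)) {
      refit <- feature_stats(data[kept$name], outcome = as.logical(data[[outcome]]))
      kept$lr_pos <- refit$lr_pos[match(kept$name, refit$feature)]
      kept$lr_neg <- refit$lr_neg[match(kept$name, refit$feature)]
    }
    model <- prognostic_model(model$priors, kept, model$decision_cutoff)
    if (nrow(kept) == 0L) {
      warn("All features eliminated: returning a prior-only model.")
      break
    }
  }
  attr(model, "trace") <- bind_rows(trace)
  model
}

#' Jaccard similarity of two binary presence vectors
#'
#' Proportion of subjects showing both symptoms among those showing at least
#' one.  If neither symptom is ever present the index is defined as 0.
#'
#' @param f1,f2 Logical (or 0/1) vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(f1, f2) {
  f1 <- as.logical(f1)
  f2 <- as.logical(f2)
  f1[is.na(f1)] <- FALSE
  f2[is.na(f2)] <- FALSE
  union <- sum(f1 | f2)
  if (union == 0L) return(0)
  sum(f1 & f2) / union
}

#' Remove redundant same-hypothesis features by Jaccard similarity
#'
#' For every pair of model features linked to the same named hypothesis
#' whose presence patterns share a Jaccard index strictly greater than
#' `threshold`, the member with the smaller single-feature LRTS contribution
#' (2 * (LL(prior + feature) - LL(prior-only))) is dropped; ties are broken
#' by smaller `|log(lr_pos)|`, then by name.  Pairs in different hypothesis
#' groups are never dropped.
#'
#' @inheritParams model_log_likelihood
#' @param hypotheses Named character vector mapping feature names to
#'   hypothesis labels.
#' @param threshold Similarity above which (strictly) a pair is redundant.
#' @return The filtered `prognostic_model`, with a tibble of dropped
#'   features (`feature`, `kept`, `jaccard`) as attribute `"dropped"`.
#' @export
redundancy_filter <- function(model, data, hypotheses, threshold = 0.5,
                              outcome = "decline", age = "age_of_onset") {
  stopifnot(inherits(model, "prognostic_model"))
  feats <- model$features
  if (nrow(feats) < 2L) {
    attr(model, "dropped") <- tibble(feature = character(), kept = character(),
                                     jaccard = numeric())
    return(model)
  }
  prior_only <- prognostic_model(model$priors, feats[0, , drop = FALSE],
                                 model$decision_cutoff)
  ll0 <- model_log_likelihood(prior_only, data, outcome = outcome, age = age)
  single_lrts <- purrr::map_dbl(seq_len(nrow(feats)), function(j) {
    m1 <- prognostic_model(model$priors, feats[j, , drop = FALSE], model$decision_cutoff)
    2 * (model_log_likelihood(m1, data, outcome = outcome, age = age) - ll0)
  })
  names(single_lrts) <- feats$name
  dropped <- character()
  drop_log <- list()
  nm <- feats$name
  for (a in seq_len(nrow(feats) - 1L)) {
    for (b in seq((a + 1L), nrow(feats))) {
      fa <- nm[a]; fb <- nm[b]
      if (fa %in% dropped || fb %in% dropped) next
      ha <- hypotheses[[fa]] %||% NA_character_
      hb <- hypotheses[[fb]] %||% NA_character_
      if (is.na(ha) || is.na(hb) || ha != hb) next
      jac <- jaccard_index(data[[fa]], data[[fb]])
      if (jac <= threshold) next
      # keep the stronger contributor
      loser <- if (single_lrts[fa] < single_lrts[fb]) fa
      else if (single_lrts[fa] > single_lrts[fb]) fb
      else {
        la <- abs(log(feats$lr_pos[a])); lb <- abs(log(feats$lr_pos[b]))
        if (la < lb) fa else if (lb < la) fb else min(fa, fb)
      }
      dropped <- c(dropped, loser)
      drop_log[[length(drop_log) + 1L]] <- tibble(
        feature = loser, kept = setdiff(c(fa, fb), loser), jaccard = jac
      )
    }
  }
  out <- prognostic_model(model$priors,
                          feats[!feats$name %in% dropped, , drop = FALSE],
                          model$decision_cutoff)
  attr(out, "dropped") <- if (length(drop_log)) bind_rows(drop_log) else
    tibble(feature = character(), kept = character(), jaccard = numeric())
  out
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat("<prognostic_model>\n")
  cat(sprintf("  %d feature(s), decision cutoff %.2f, overall prior %.3f\n",
              nrow(x$features), x$decision_cutoff, overall_prior(x$priors)))
  if (nrow(x$features)) {
    print(as.data.frame(x$features), row.names = FALSE)
  }
  invisible(x)
}

#' @export
tidy.prognostic_model <- function(x, ...) {
  x$features
}

#' @export
glance.prognostic_model <- function(x, ...) {
  tibble(
    n_features = nrow(x$features),
    n_brackets = nrow(x$priors),
    overall_prior = overall_prior(x$priors),
    decision_cutoff = x$decision_cutoff
  )
}

#' Serialize a prognostic model to JSON (and back)
#'
#' Models round-trip through a plain JSON file (priors with counts, features
#' with likelihood ratios and roles, decision cutoff, provenance).  Infinite
#' likelihood ratios are stored as the string `"Inf"`.
#'
#' @param model A `prognostic_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "prognostic_model"))
  feats <- model$features
  payload <- list(
    decision_cutoff = model$decision_cutoff,
    priors = list(
      n_overall = attr(model$priors, "n_overall"),
      decliners_overall = attr(model$priors, "decliners_overall"),
      brackets = purrr::map(seq_len(nrow(model$priors)), function(i) {
        list(lo = model$priors$bracket_lo[i], hi = model$priors$bracket_hi[i],
             n = model$priors$n[i], decliners = model$priors$decliners[i])
      })
    ),
    features = purrr::map(seq_len(nrow(feats)), function(j) {
      entry <- list(
        name = feats$name[j],
        lr_pos = if (is.infinite(feats$lr_pos[j])) "Inf" else feats$lr_pos[j],
        lr_neg = if (is.infinite(feats$lr_neg[j])) "Inf" else feats$lr_neg[j],
        role = feats$role[j]
      )
      if ("description" %in% names(feats) && !is.na(feats$description[j])) {
        entry$description <- feats$description[j]
      }
      entry
    }),
    provenance = list(
      package = "cognilr",
      version = as.character(utils::packageVersion("cognilr")),
      hash = md5_of(paste(feats$name, feats$lr_pos, feats$lr_neg, collapse = ";"))
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("Model file not found: %s", path))
  payload <- jsonlite::read_json(path)
  br <- purrr::map(payload$priors$brackets, as_tibble) %>% bind_rows()
  tab <- tibble(
    bracket_lo = as.numeric(br$lo), bracket_hi = as.numeric(br$hi),
    n = as.integer(br$n), decliners = as.integer(br$decliners)
  )
  priors <- new_priors(tab,
    n_overall = payload$priors$n_overall,
    decliners_overall = payload$priors$decliners_overall
  )
  feats <- purrr::map(payload$features, function(f) {
    desc <- f$description
    if (is.null(desc) || length(desc) == 0L) desc <- NA_character_
    tibble(
      name = f$name,
      description = as.character(desc),
      lr_pos = as.numeric(f$lr_pos),
      lr_neg = as.numeric(f$lr_neg),
      role = f$role
    )
  }) %>% bind_rows()
  prognostic_model(priors, feats, decision_cutoff = payload$decision_cutoff)
}
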