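#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the prognostic analysis
#' assumes: age of onset drawn from bracket weights, decline status from the
#' bracket prior, binary baseline features conditionally independent given
#' decline with per-feature sensitivity/specificity, and integer MoCA
#' trajectories whose labels reproduce the assigned decline status exactly.
#' Defaults mirror the published study conditions: the pooled age-bracket
#' priors and counts, and the (sensitivity, specificity) pairs implied by
#' the published 2x2 reconstructions of the three four-question-model
#' features (stroke 3/49 vs 0/137, fainting 2/49 vs 2/137, vocalization
#' 27/49 vs 28/137).
#'
#' @param n_subjects Number of subjects.
#' @param bracket_rates Data frame `bracket_lo`, `bracket_hi`, `rate` giving
#'   the decline probability per half-open age bracket.
#' @param age_weights Sampling weight per bracket (recycled to the bracket
#'   table; default the pooled subject counts).
#' @param feature_specs Data frame `name`, `sens`, `spec` of binary feature
#'   generators.
#' @param trajectory_mix Named probabilities of `early`, `late` and
#'   `fluctuation` MoCA patterns among decliners (must sum to 1).
#'   Non-decliners are always stable.  Defaults are the development-cohort
#'   shares among decliners.
#' @param moca_baseline_mean,moca_baseline_sd Baseline MoCA distribution
#'   (normal, rounded, clipped to `[3, 30]` so a 3-point drop always exists).
#' @param p_male Probability of male sex.
#' @param missing_rate MCAR probability that a baseline feature item is
#'   masked to missing (never age of onset or MoCA follow-ups).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A validated `synth_config` object (a list).
#' @examples
#' cfg <- synth_config(n_subjects = 100, seed = 1)
#' cohort <- generate_cohort(cfg)
#' @export
synth_config <- function(n_subjects = 234,
                         bracket_rates = default_bracket_rates(),
                         age_weights = NULL,
                         feature_specs = default_feature_specs(),
                         trajectory_mix = c(early = 0.37, late = 0.33, fluctuation = 0.30),
                         moca_baseline_mean = 27,
                         moca_baseline_sd = 2.2,
                         p_male = 0.64,
                         missing_rate = 0,
                         seed = NULL) {
  bracket_rates <- as_tibble(bracket_rates)
  if (is.null(age_weights)) {
    age_weights <- if ("weight" %in% names(bracket_rates)) bracket_rates$weight
    else rep(1, nrow(bracket_rates))
  }
  cfg <- structure(
    list(
      n_subjects = n_subjects,
      bracket_rates = bracket_rates,
      age_weights = age_weights,
      feature_specs = as_tibble(feature_specs),
      trajectory_mix = trajectory_mix,
      moca_baseline_mean = moca_baseline_mean,
      moca_baseline_sd = moca_baseline_sd,
      p_male = p_male,
      missing_rate = missing_rate,
      seed = seed
    ),
    class = "synth_config"
  )
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @export
default_bracket_rates <- function() {
  pri <- published_priors("combined")
  tibble(
    bracket_lo = pri$bracket_lo, bracket_hi = pri$bracket_hi,
    rate = pri$prior, weight = pri$n
  )
}

#' @rdname synth_config
#' @export
default_feature_specs <- function() {
  tibble(
    name = c("stroke", "fainting", "vocalization"),
    sens = c(3 / 49, 2 / 49, 27 / 49),
    spec = c(1, 135 / 137, 109 / 137)
  )
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1L ||
      is.na(cfg$n_subjects) || cfg$n_subjects < 0 ||
      cfg$n_subjects != round(cfg$n_subjects)) {
    abort("`n_subjects` must be a nonnegative integer.", class = "cognilr_config_error")
  }
  br <- cfg$bracket_rates
  if (!all(c("bracket_lo", "bracket_hi", "rate") %in% names(br))) {
    abort("`bracket_rates` needs columns bracket_lo, bracket_hi, rate.",
          class = "cognilr_config_error")
  }
  check_brackets(tibble(bracket_lo = br$bracket_lo, bracket_hi = br$bracket_hi))
  if (!is_prob(br$rate)) {
    abort("Bracket decline rates must be probabilities in [0, 1].",
          class = "cognilr_config_error")
  }
  if (length(cfg$age_weights) != nrow(br) || any(cfg$age_weights < 0) ||
      sum(cfg$age_weights) <= 0) {
    abort("`age_weights` must be nonnegative with positive sum, one per bracket.",
          class = "cognilr_config_error")
  }
  fs <- cfg$feature_specs
  if (nrow(fs)) {
    if (!all(c("name", "sens", "spec") %in% names(fs)) ||
        !is_prob(fs$sens) || !is_prob(fs$spec)) {
      abort("`feature_specs` needs name plus sens/spec probabilities in [0, 1].",
            class = "cognilr_config_error")
    }
    if (anyDuplicated(fs$name)) {
      abort("Feature names must be unique.", class = "cognilr_config_error")
    }
  }
  mix <- cfg$trajectory_mix
  if (!all(c("early", "late", "fluctuation") %in% names(mix)) ||
      !is_prob(unname(mix)) || abs(sum(mix) - 1) > 1e-8) {
    abort("`trajectory_mix` must give early/late/fluctuation probabilities summing to 1.",
          class = "cognilr_config_error")
  }
  if (!is_prob(cfg$missing_rate) || !is_prob(cfg$p_male)) {
    abort("`missing_rate` and `p_male` must be probabilities.",
          class = "cognilr_config_error")
  }
  cfg
}

#' Generate a synthetic baseline cohort with follow-up MoCA scores
#'
#' Draws `n_subjects` records under the generative model described in
#' [synth_config()].  Decliners receive an early, late or fluctuating MoCA
#' trajectory (drop of at least 3 points at year 2 and/or year 4; a
#' fluctuating pattern drops at year 2 and recovers to within 2 points of
#' baseline); stable subjects never drop more than 2 points.  Applying
#' [decline_label()] to the generated trajectories therefore reproduces the
#' assigned decline status for every subject with complete follow-ups.
#' Feature items are masked to `NA` at `missing_rate` (MCAR).
#'
#' @param config A `synth_config`.
#' @param seed Overrides `config$seed`.
#' @return A tibble with columns `subject_id`, `sex`, `education_years`,
#'   `age_of_onset`, one 0/1 column per feature, `moca_baseline`, `moca_y2`,
#'   `moca_y4`, `decline`, `trajectory`; the configuration and seed are
#'   attached as attribute `"provenance"`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_synth_config(config)
  n <- as.integer(config$n_subjects)
  br <- config$bracket_rates
  fs <- config$feature_specs
  with_seed(seed, {
    if (n == 0L) {
      feat_cols <- setNames(
        rep(list(integer(0)), nrow(fs)), fs$name
      )
      out <- tibble(
        subject_id = character(0), sex = character(0),
        education_years = numeric(0), age_of_onset = numeric(0),
        !!!feat_cols,
        moca_baseline = integer(0), moca_y2 = integer(0), moca_y4 = integer(0),
        decline = integer(0), trajectory = character(0)
      )
    } else {
      bracket <- sample.int(nrow(br), n, replace = TRUE,
                            prob = config$age_weights / sum(config$age_weights))
      age <- runif(n, br$bracket_lo[bracket], br$bracket_hi[bracket])
      decline <- rbinom(n, 1L, br$rate[bracket])
      sex <- ifelse(runif(n) < config$p_male, "male", "female")
      education <- clip(round(rnorm(n, 15.4, 3)), 5, 24)
      features <- purrr::map(seq_len(nrow(fs)), function(j) {
        p <- ifelse(decline == 1L, fs$sens[j], 1 - fs$spec[j])
        x <- rbinom(n, 1L, p)
        if (config$missing_rate > 0) {
          x[runif(n) < config$missing_rate] <- NA_integer_
        }
        x
      })
      names(features) <- fs$name
      traj <- rep("stable", n)
      idx_dec <- which(decline == 1L)
      if (length(idx_dec)) {
        traj[idx_dec] <- sample(
          c("early_decline", "late_decline", "fluctuation"),
          length(idx_dec), replace = TRUE,
          prob = config$trajectory_mix[c("early", "late", "fluctuation")]
        )
      }
      baseline <- clip(round(rnorm(n, config$moca_baseline_mean,
                                   config$moca_baseline_sd)), 3, 30)
      drop_big <- function(k, b) pmin(3L + rgeom(k, 0.5), b) # >= 3, never below 0
      drop_small <- function(k) sample(-2:2, k, replace = TRUE)
      d2 <- integer(n); d4 <- integer(n)
      for (cat in unique(traj)) {
        i <- which(traj == cat)
        d2[i] <- switch(cat,
          early_decline = drop_big(length(i), baseline[i]),
          fluctuation = drop_big(length(i), baseline[i]),
          drop_small(length(i))
        )
        d4[i] <- switch(cat,
          early_decline = drop_big(length(i), baseline[i]),
          late_decline = drop_big(length(i), baseline[i]),
          drop_small(length(i))
        )
      }
      out <- tibble(
        subject_id = sprintf("S%05d", seq_len(n)),
        sex = sex,
        education_years = as.numeric(education),
        age_of_onset = age,
        !!!features,
        moca_baseline = as.integer(baseline),
        moca_y2 = as.integer(pmin(baseline - d2, 30L)),
        moca_y4 = as.integer(pmin(baseline - d4, 30L)),
        decline = decline,
        trajectory = traj
      )
    }
    attr(out, "provenance") <- list(config = config, seed = seed)
    out
  })
}

#' Analytic feature statistics implied by a generator configuration
#'
#' Closed-form oracle for recovery tests: for each feature,
#' `LR+ = sens / (1 - spec)` (infinite at perfect specificity with positive
#' sensitivity), `LR- = (1 - sens) / spec`, and the expected presence
#' proportion `prevalence * sens + (1 - prevalence) * (1 - spec)` where the
#' prevalence is the weight-averaged bracket decline rate.
#'
#' @param config A `synth_config`.
#' @return A tibble: `feature`, `sens`, `spec`, `lr_pos`, `lr_neg`,
#'   `presence_proportion`, plus the implied `prevalence` as an attribute.
#' @examples
#' implied_feature_stats(synth_config(n_subjects = 10))
#' @export
implied_feature_stats <- function(config) {
  validate_synth_config(config)
  w <- config$age_weights / sum(config$age_weights)
  prev <- sum(w * config$bracket_rates$rate)
  fs <- config$feature_specs
  out <- tibble(
    feature = fs$name, sens = fs$sens, spec = fs$spec,
    lr_pos = ifelse(fs$spec == 1, ifelse(fs$sens > 0, Inf, NaN),
                    fs$sens / (1 - fs$spec)),
    lr_neg = ifelse(fs$spec == 0, ifelse(fs$sens < 1, Inf, NaN),
                    (1 - fs$sens) / fs$spec),
    presence_proportion = prev * fs$sens + (1 - prev) * (1 - fs$spec)
  )
  attr(out, "prevalence") <- prev
  out
}

#' Exact AUC of a model under a generator configuration
#'
#' Enumerates every feature-pattern x age-bracket combination with its
#' class-conditional probability under the generative distribution and
#' computes the exact AUC of the model's posterior score, counting ties with
#' weight 1/2 (the Mann-Whitney convention).  Model features must be a
#' subset of the configured features; enumeration is refused above 20
#' features.
#'
#' @param config A `synth_config`.
#' @param model A `prognostic_model`.
#' @return The exact AUC (a probability).
#' @export
expected_model_auc <- function(config, model) {
  validate_synth_config(config)
  stopifnot(inherits(model, "prognostic_model"))
  feats <- model$features
  fs <- config$feature_specs
  missing_feats <- setdiff(feats$name, fs$name)
  if (length(missing_feats)) {
    abort(sprintf("Model feature(s) not generated by the config: %s",
                  paste(missing_feats, collapse = ", ")))
  }
  k <- nrow(feats)
  if (k > 20) {
    abort(sprintf("Enumeration refused: %d features imply %.3g patterns.", k, 2^k))
  }
  br <- config$bracket_rates
  w <- config$age_weights / sum(config$age_weights)
  prev <- sum(w * br$rate)
  if (prev <= 0 || prev >= 1) {
    abort("Both outcome classes must have positive probability under the config.")
  }
  patterns <- if (k > 0) {
    as.matrix(expand.grid(rep(list(c(0L, 1L)), k)))
  } else matrix(integer(0), nrow = 1, ncol = 0)
  spec_idx <- match(feats$name, fs$name)
  sens <- fs$sens[spec_idx]
  spc <- fs$spec[spec_idx]
  mid_age <- (br$bracket_lo + br$bracket_hi) / 2
  scores <- c(); p1 <- c(); p0 <- c()
  for (b in seq_len(nrow(br))) {
    pb1 <- w[b] * br$rate[b] / prev
    pb0 <- w[b] * (1 - br$rate[b]) / (1 - prev)
    for (r in seq_len(nrow(patterns))) {
      x <- patterns[r, ]
      px1 <- prod(ifelse(x == 1L, sens, 1 - sens))
      px0 <- prod(ifelse(x == 1L, 1 - spc, spc))
      fv <- as.data.frame(as.list(x))
      if (k > 0) names(fv) <- feats$name
      s <- posterior_probability(model, mid_age[b], fv)
      scores <- c(scores, s)
      p1 <- c(p1, pb1 * px1)
      p0 <- c(p0, pb0 * px0)
    }
  }
  uniq <- sort(unique(scores))
  m1 <- purrr::map_dbl(uniq, ~ sum(p1[scores == .x]))
  m0 <- purrr::map_dbl(uniq, ~ sum(p0[scores == .x]))
  gt <- outer(uniq, uniq, ">")
  sum(outer(m1, m0) * (gt + 0.5 * diag(length(uniq))))
}
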