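test_that("priors pool decliner counts within brackets and fall back when needed", {
  one_bracket <- single_bracket()
  cohort <- make_cohort(c(rep(1, 49), rep(0, 137)))
  pri <- estimate_priors(cohort, brackets = one_bracket)
  expect_equal(pri$prior, 49 / 186)
  expect_equal(round(pri$prior, 2), 0.26)

  # pooling two cohorts in the 75-100 bracket
  a <- make_cohort(c(rep(1, 5), rep(0, 3)), age = rep(80, 8))
  b <- make_cohort(c(rep(1, 2), rep(0, 1)), age = rep(80, 3))
  pooled <- estimate_priors(a, b, brackets = tibble::tibble(bracket_lo = 75, bracket_hi = 100))
  expect_equal(pooled$prior, 7 / 11)
  expect_equal(round(pooled$prior, 2), 0.64)

  expect_error(estimate_priors(make_cohort(integer(0))), "No labelled subjects")

  # missing age contributes only to the overall prior; empty brackets fall back
  two <- tibble::tibble(bracket_lo = c(30, 60), bracket_hi = c(60, 100))
  cohort2 <- tibble::tibble(age_of_onset = c(40, 40, NA, NA), decline = c(1, 0, 1, 1))
  pri2 <- suppressMessages(estimate_priors(cohort2, brackets = two))
  expect_equal(pri2$n, c(2L, 0L))
  expect_equal(overall_prior(pri2), 3 / 4)
  expect_equal(lookup_prior(pri2, c(40, 80, NA)), c(0.5, 3 / 4, 3 / 4))
})

test_that("posterior updating follows odds arithmetic and its edge cases", {
  pri <- estimate_priors(
    make_cohort(c(rep(1, 27), rep(0, 73))), brackets = single_bracket()
  )
  m <- prognostic_model(pri, tibble::tibble(
    name = c("fainting", "vocalization"),
    lr_pos = c(2.80, 2.70), lr_neg = c(0.97, 0.56), role = "risk"
  ))
  # independent odds-arithmetic oracle
  odds <- (0.27 / 0.73) * 2.80 * 2.70
  expect_equal(
    posterior_probability(m, 60, tibble::tibble(fainting = 1, vocalization = 1)),
    odds / (1 + odds)
  )
  expect_equal(round(odds / (1 + odds), 4), 0.7366)

  # no qualified evidence: posterior equals the prior
  expect_equal(
    posterior_probability(m, 60, tibble::tibble(fainting = 0, vocalization = 0)),
    0.27
  )
  # risk-only features contribute nothing when absent even with lr_neg < 1
  expect_equal(
    posterior_probability(m, 60, tibble::tibble(fainting = NA, vocalization = 0)),
    0.27
  )
  expect_error(
    posterior_probability(m, 60, tibble::tibble(fainting = 1)),
    "not aligned"
  )
})

test_that("infinite evidence forces the posterior to one for any prior in (0,1)", {
  for (p in c(0.01, 0.27, 0.9)) {
    k <- round(1000 * p)
    pri <- estimate_priors(make_cohort(c(rep(1, k), rep(0, 1000 - k))),
                           brackets = single_bracket())
    m <- prognostic_model(pri, tibble::tibble(
      name = "stroke", lr_pos = Inf, lr_neg = 0.94, role = "risk"
    ))
    expect_equal(posterior_probability(m, 60, tibble::tibble(stroke = 1)), 1)
    expect_equal(posterior_probability(m, 60, tibble::tibble(stroke = 0)), p)
  }
  # prior exactly zero: posterior zero without evidence, error with infinite evidence
  pri0 <- estimate_priors(make_cohort(c(rep(0, 10), 1), age = c(rep(40, 10), 80)),
                          brackets = tibble::tibble(bracket_lo = c(30, 60),
                                                    bracket_hi = c(60, 100)))
  m0 <- prognostic_model(pri0, tibble::tibble(
    name = "stroke", lr_pos = Inf, lr_neg = 0.94, role = "risk"
  ))
  expect_equal(posterior_probability(m0, 40, tibble::tibble(stroke = 0)), 0)
  expect_error(posterior_probability(m0, 40, tibble::tibble(stroke = 1)),
               "Indeterminate")
})

test_that("posterior is monotone in the prior and in each applied factor", {
  withr::local_seed(12)
  pri_lo <- estimate_priors(make_cohort(c(rep(1, 2), rep(0, 8))), brackets = single_bracket())
  pri_hi <- estimate_priors(make_cohort(c(rep(1, 5), rep(0, 5))), brackets = single_bracket())
  for (rep in 1:20) {
    lrs <- sort(runif(2, 1, 10))
    feats <- function(lr) tibble::tibble(name = "f", lr_pos = lr, lr_neg = 0.5, role = "risk")
    x <- tibble::tibble(f = 1)
    p_lo <- posterior_probability(prognostic_model(pri_lo, feats(lrs[1])), 60, x)
    p_hi_lr <- posterior_probability(prognostic_model(pri_lo, feats(lrs[2])), 60, x)
    p_hi_prior <- posterior_probability(prognostic_model(pri_hi, feats(lrs[1])), 60, x)
    expect_gte(p_hi_lr, p_lo)
    expect_gte(p_hi_prior, p_lo)
  }
})

test_that("decision labelling is inclusive at the cutoff", {
  expect_true(predict_label(0.50))
  expect_false(predict_label(0.4999))
  expect_true(predict_label(1.0))
  expect_error(predict_label(1.2), "0, 1")
})

test_that("naive Bayes posteriors equal the enumerated joint-Bayes oracle", {
  withr::local_seed(99)
  for (rep in 1:50) {
    k <- sample(1:4, 1)
    sens <- runif(k, 0.05, 0.95)
    spec <- runif(k, 0.05, 0.95)
    k_dec <- sample(5:95, 1)
    prior <- k_dec / 100
    pri <- estimate_priors(make_cohort(c(rep(1, k_dec), rep(0, 100 - k_dec))),
                           brackets = single_bracket())
    feats <- tibble::tibble(
      name = paste0("f", seq_len(k)),
      lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec, role = "both"
    )
    m <- prognostic_model(pri, feats)
    pattern <- stats::rbinom(k, 1, 0.5)
    x <- tibble::as_tibble(as.list(stats::setNames(pattern, feats$name)))
    expect_equal(
      posterior_probability(m, 60, x),
      oracle_joint_posterior(prior, sens, spec, pattern),
      tolerance = 1e-12
    )
  }
})

test_that("log-likelihood matches closed forms and direct summation", {
  cohort <- make_cohort(c(1, 1, 0, 0, 0, 0))
  pri <- estimate_priors(make_cohort(c(1, 0)), brackets = single_bracket())
  m_half <- prognostic_model(pri, tibble::tibble(
    name = character(), lr_pos = numeric(), lr_neg = numeric(), role = character()
  ))
  expect_equal(model_log_likelihood(m_half, cohort), -6 * log(2))

  withr::local_seed(13)
  cohort2 <- generate_cohort(synth_config(n_subjects = 80, seed = 13))
  m <- published_model()
  p <- posterior_probability(m, cohort2$age_of_onset, cohort2)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  y <- cohort2$decline
  expect_equal(
    model_log_likelihood(m, cohort2),
    sum(y * log(p) + (1 - y) * log(1 - p))
  )
})

test_that("backward elimination drops null features and keeps informative ones", {
  withr::local_seed(21)
  cohort <- generate_cohort(synth_config(
    n_subjects = 1000,
    bracket_rates = tibble::tibble(bracket_lo = 30, bracket_hi = 100, rate = 0.25),
    feature_specs = tibble::tibble(
      name = c("strong", "noise"),
      sens = c(0.4, 0.3), spec = c(0.95, 0.7) # implied LR+ 8 vs 1
    ),
    seed = 21
  ))
  model <- fit_prognostic_model(cohort, c("strong", "noise"),
                                brackets = single_bracket(),
                                qualify = FALSE, role = "both")
  reduced <- lrts_backward_elimination(model, cohort)
  expect_equal(reduced$features$name, "strong")
  trace <- attr(reduced, "trace")
  expect_true(all(c("step", "feature", "lrts", "removed") %in% names(trace)))
  expect_true(trace$removed[trace$feature == "noise" & trace$step == 1])

  # a feature with unit likelihood ratios has LRTS exactly 0 and goes first
  null_model <- prognostic_model(model$priors, tibble::tibble(
    name = c("strong", "noise"),
    lr_pos = c(8, 1), lr_neg = c(0.63, 1), role = "both"
  ))
  red2 <- lrts_backward_elimination(null_model, cohort)
  tr2 <- attr(red2, "trace")
  expect_equal(tr2$lrts[tr2$feature == "noise" & tr2$step == 1], 0)
  expect_true(tr2$removed[tr2$feature == "noise" & tr2$step == 1])

  # eliminating everything yields a prior-only model with a warning
  pure_noise <- prognostic_model(model$priors, tibble::tibble(
    name = "noise", lr_pos = 1, lr_neg = 1, role = "both"
  ))
  expect_warning(out <- lrts_backward_elimination(pure_noise, cohort),
                 "prior-only")
  expect_equal(nrow(out$features), 0L)
})

test_that("Jaccard index and redundancy filtering follow the strict threshold", {
  expect_equal(jaccard_index(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(jaccard_index(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(jaccard_index(c(0, 0), c(0, 0)), 0) # both absent: defined as 0
  x <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  y <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  expect_equal(jaccard_index(x, y), 0.5) # 3 co-present / 6 in at least one

  withr::local_seed(31)
  base <- rbinom(400, 1, 0.4)
  twin <- base
  twin[1:10] <- 1 - twin[1:10] # nearly identical: J > 0.5
  other <- rbinom(400, 1, 0.4)
  y2 <- rbinom(400, 1, stats::plogis(-1 + 1.5 * base))
  cohort <- make_cohort(y2, a = base, b = twin, c = other)
  model <- fit_prognostic_model(cohort, c("a", "b", "c"),
                                brackets = single_bracket(),
                                qualify = FALSE, role = "both")
  hyp <- c(a = "same", b = "same", c = "different")
  filtered <- redundancy_filter(model, cohort, hyp)
  dropped <- attr(filtered, "dropped")
  expect_equal(nrow(dropped), 1L)
  expect_true(dropped$feature %in% c("a", "b"))
  expect_true("c" %in% filtered$features$name) # different hypothesis: never dropped

  # J exactly at the threshold is NOT redundant (strict >)
  cohort_half <- make_cohort(rep(c(1, 0), 5), p = x, q = y)
  m2 <- fit_prognostic_model(cohort_half, c("p", "q"),
                             brackets = single_bracket(),
                             qualify = FALSE, role = "both")
  f2 <- redundancy_filter(m2, cohort_half, c(p = "h", q = "h"), threshold = 0.5)
  expect_equal(nrow(attr(f2, "dropped")), 0L)
})

test_that("models serialize to JSON and back without changing predictions", {
  cohort <- generate_cohort(synth_config(n_subjects = 300, seed = 44))
  model <- fit_prognostic_model(cohort, c("stroke", "fainting", "vocalization"),
                                qualify = FALSE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  reloaded <- read_model(path)
  expect_equal(
    posterior_probability(reloaded, cohort$age_of_onset, cohort),
    posterior_probability(model, cohort$age_of_onset, cohort)
  )
  expect_equal(reloaded$features$lr_pos, model$features$lr_pos)
  expect_equal(overall_prior(reloaded$priors), overall_prior(model$priors))
})

test_that("the packaged published model encodes the four-question predictor", {
  m <- published_model()
  expect_equal(m$features$name, c("stroke", "fainting", "vocalization"))
  expect_equal(m$features$lr_pos, c(Inf, 2.80, 2.70))
  expect_equal(m$features$role, rep("risk", 3))
  expect_equal(nrow(m$priors), 9L)
  expect_equal(round(m$priors$prior[m$priors$bracket_lo == 75], 2), 0.64)
  expect_equal(round(overall_prior(m$priors), 2), 0.25)

  # stroke forces certainty; the interview example follows odds arithmetic
  expect_equal(
    posterior_probability(m, 55, tibble::tibble(stroke = 1, fainting = 0, vocalization = 0)),
    1
  )
  pi62 <- lookup_prior(m$priors, 62)
  odds <- pi62 / (1 - pi62) * 2.80 * 2.70
  pred <- predict(m, tibble::tibble(age_of_onset = 62, stroke = 0,
                                    fainting = 1, vocalization = 1))
  expect_equal(pred$.posterior, odds / (1 + odds))
  expect_true(pred$.pred)
})

test_that("refitting on a large generated cohort recovers the generator's model", {
  cfg <- synth_config(n_subjects = 20000, seed = 17)
  cohort <- generate_cohort(cfg)
  refit <- fit_prognostic_model(cohort, c("stroke", "fainting", "vocalization"),
                                qualify = FALSE)
  refit <- lrts_backward_elimination(refit, cohort)
  truth <- published_model()
  p_true <- posterior_probability(truth, cohort$age_of_onset, cohort)
  p_refit <- posterior_probability(refit, cohort$age_of_onset, cohort)
  expect_gt(stats::cor(p_true, p_refit), 0.99)
})
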