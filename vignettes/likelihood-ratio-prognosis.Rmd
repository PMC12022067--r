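---
title: "Likelihood-ratio prognosis of cognitive decline in de novo Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood-ratio prognosis of cognitive decline in de novo Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cognilr)
library(tibble)
```

## The problem and the model

Cognitive decline is common in Parkinson's disease and hard to anticipate at
diagnosis. `cognilr` implements a deliberately transparent prognostic model
for the 2--4 year horizon in newly diagnosed (de novo) patients: a naive
Bayes classifier expressed entirely in diagnostic likelihood ratios, so that
a clinician can reproduce any prediction with a pocket calculator.

The outcome is binary: a subject declines if their Montreal Cognitive
Assessment (MoCA, 0--30 points) drops by **3 or more points** from baseline
to the 2-year and/or the 4-year follow-up. On integer scores this is
identical to "more than 2 points", and the test suite asserts that identity
over the full `[0,30]^3` grid of score triples.

Prediction proceeds on the odds scale:

1. **Prior.** The prior probability of decline is the observed decliner
   proportion within the subject's age-of-onset bracket (`[30,40)`, then
   5-year intervals to `[75,100)`). Sparse extreme brackets are smoothed by
   pooling cohorts -- pooling is literally summing decliner and subject
   counts per bracket. Missing age of onset falls back to the overall
   decliner proportion.
2. **Evidence.** Each binarized baseline feature carries a positive
   likelihood ratio `LR+ = sens / (1 - spec)` and a negative one
   `LR- = (1 - sens) / spec`, estimated from its 2x2 table against the
   outcome. A present feature whose risk side qualifies multiplies the
   prior odds by `LR+`; an absent feature whose protective side qualifies
   multiplies by `LR-`; otherwise the factor is 1.
3. **Decision.** The posterior is `odds / (1 + odds)`; a subject is labelled
   positive when the posterior is at or above 0.5 (inclusive).

Under class-conditional independence of the features this sequential
updating is exactly the joint Bayes posterior; the suite verifies agreement
with an enumeration oracle to `1e-12` over a thousand random
configurations.

### Feature qualification

A feature enters the model as a **risk** factor when `LR+ > 2` and the odds
of symptom presence exceed 0.01, and as **protective** when `LR- < 0.5` and
the odds of symptom *absence* are below 0.99. The protective bound is
applied to the absence odds -- the mirror of the presence bound -- because
the protective evidence is the absent symptom; a literal presence-odds
reading would disqualify abnormal olfaction (present in over 80% of
subjects), which the published feature table lists as the canonical
protective factor. `qualify_feature()` documents this convention.

A present feature with infinite `LR+` (no feature-positive non-decliner was
observed; the canonical example is a history of stroke) forces the
posterior to exactly 1 for any prior in (0, 1). No zero-cell continuity
correction is applied by default, preserving that behaviour; a
Haldane--Anscombe option exists on `likelihood_ratios()`. Because such a
feature was always followed by decline in the data but is rare, a user can
neutralize it simply by answering "not present".

### Feature pruning

Two pruning stages keep the model parsimonious:

* **Sequential likelihood-ratio-test elimination.** The model likelihood is
  the Bernoulli likelihood of the observed labels under the model
  posteriors (clipped to `[1e-12, 1 - 1e-12]`); the statistic
  `2 * (LL_full - LL_without_feature)` is referred to `qchisq(0.95, 1) =
  3.841`. Per pass the single least significant feature is removed
  (removing all at once risks order effects), and the procedure repeats
  until every remaining feature is significant. The likelihood functional
  is a design choice -- the source procedure names the test but not the
  likelihood -- and it is the only likelihood available to a classifier of
  this form. Per-feature likelihood ratios are held fixed during
  elimination by default (they are marginal quantities under the naive
  Bayes assumption); `re_estimate = TRUE` refits them after each removal.
  The conventional reading -- *retain* features whose removal significantly
  hurts the likelihood -- is implemented; the alternative reading (prefer
  the reduced model when the statistic is large) contradicts the stated
  goal of keeping only features with significant effect and is not offered.
* **Jaccard redundancy filtering.** For two features tied to the same named
  hypothesis whose presence patterns overlap with Jaccard index strictly
  above 0.5, the member with the smaller single-feature likelihood-ratio
  statistic is dropped (ties: smaller `|log LR+|`, then name). Features
  under different hypotheses are never dropped, however similar.

### Cutoff search

Continuous variables without an accepted clinical threshold are binarized
by `optimize_cutoff()`: every distinct observed value is a candidate
cutoff, the candidate maximizing `LR+` among those with presence odds above
0.01 is selected, and the selection is accepted only when the Spearman
correlation between candidate cutoff and induced `LR+` has the hypothesized
sign and magnitude at least 0.7. The consistency floor is configurable --
the source states the check but no threshold -- and the maximized criterion
(`LR+` rather than Fisher significance or posterior performance) is a
design choice isolated behind this one function.

## The synthetic cohort generator

The study cohorts are access-controlled, so the package ships a generator
(`synth_config()`, `generate_cohort()`) whose defaults *are* the study
conditions:

* age-of-onset brackets with the pooled published subject counts as
  sampling weights and the pooled decliner proportions as decline rates;
* the three four-question features with sensitivity/specificity implied by
  the published 2x2 reconstructions (stroke 3/49 vs 0/137, fainting 2/49 vs
  2/137, vocalization during dreams 27/49 vs 28/137). The fainting
  reconstruction follows the printed presence proportion (0.02) and `LR-`
  (0.97), which imply 2/49 and 2/137 rather than the 1/49 and 1/137 that
  the rounded `LR+` alone would allow;
* baseline MoCA drawn from a rounded normal (mean 27, sd 2.2, clipped to
  `[3, 30]` so a 3-point drop always exists), male share 0.64 and education
  mean 15.4 years, matching the published baseline table;
* decliner trajectories split early / late / fluctuating at 0.37 / 0.33 /
  0.30. The published shares among development-cohort decliners give the
  first two; the fluctuation share is the remainder and is illustrative --
  the source describes fluctuations only narratively. A fluctuating
  trajectory drops at least 3 points at year 2 and recovers to within 2
  points of baseline at year 4; it therefore *satisfies* the decline
  definition ("and/or"), so fluctuators are drawn among decliners and
  stable subjects are exactly the non-decliners. Relabelling a generated
  cohort from its MoCA scores reproduces the generator's assigned status
  for 100% of subjects, and the suite asserts it.

Age is uniform within its bracket (the prior table's resolution makes finer
structure unidentifiable), decline drops are `3 + Geometric(0.5)` and
stable noise is uniform on `{-2, ..., +2}` -- only the 3-point threshold
semantics matter downstream. Missingness is MCAR on feature items only,
never on age of onset or follow-up totals unless configured.

What the generator does **not** emulate: item-level questionnaire
psychometrics (features are generated at the binarized level), correlated
features (class-conditional independence is the naive Bayes assumption; the
redundancy filter is exercised with explicitly constructed near-duplicate
columns in the tests), informative missingness, and cohort drift between
development and validation sites. Passing recovery tests therefore shows
the estimation machinery is correct under the model's own assumptions, not
that the assumptions hold in real cohorts.

Two analytic oracles accompany the generator: `implied_feature_stats()`
(closed-form likelihood ratios and presence proportions) and
`expected_model_auc()` (exact AUC of a model's posterior score by
enumerating all feature-pattern x bracket combinations, ties at 1/2,
refused above 20 features).

## Evaluation

`repeated_cv()` performs repeated random subsampling cross-validation:
uniform 80/20 splits (training size rounded down), the full pipeline
(priors and likelihood ratios, fixed feature set) refit on each training
part, AUC measured on the test part, mean and sd reported across
repetitions. Splits are simple random, not stratified; a split missing an
outcome class in either part is redrawn and the redraw count reported.
`auc()` is the trapezoid over all distinct-score thresholds and equals the
tie-corrected Mann--Whitney statistic (verified against a brute-force
pairwise oracle and against pROC). The reported sd is across repetitions.

Group comparisons in `cohort_report()` gate on Shapiro--Wilk per group
(discrete variables are assumed non-normal; constant groups skip the gate
and fall back to the rank test), matching how clinical baseline tables are
built. No family-wise error control is applied anywhere: the feature
screen deliberately favours type-I over type-II error, since consistency
across two independent cohorts is the real filter.

## Numerical and boundary conventions

* Comparators are strict ("higher than 5" means `> 5`); equality at a
  cutoff is absence. Missing values are absent symptoms at binarization,
  but a missing constituent item makes a *derived* score missing rather
  than a partial sum.
* "Moderate or severe" item features use response `>= 3` (item anchors
  label 3 = moderate, 4 = severe); the maximum response category encodes
  the "very much so" / "almost always" anxiety cutoffs. Both are flagged in
  the shipped YAML as interpretations.
* The decision rule is inclusive at 0.5; z-score bins place 0 and -1 in
  `below_average`; a year-4 deficit of exactly 2 points counts as
  recovered (fluctuation rather than early decline).
* A tremor/PIGD ratio of 0/0 is indeterminate by documented convention;
  0-denominator with positive tremor is tremor-dominant.
* MoCA norms for z-scores are external normative data; the package exposes
  a pluggable norm function and ships only a synthetic linear toy norm
  (`linear_moca_norm()`), clearly labelled as such.
* Unknown CSV columns are retained with a warning rather than dropped, so
  write-then-read is an identity for cohorts with user-defined features.

## Problem sizes in the shipped suite

The test suite exercises recovery at `n = 20000` (relative error of
re-estimated `LR+` within 10% for features with presence at least 2%),
Monte-Carlo agreement of empirical AUC with the enumerated value within
0.02 at the same size, elimination behaviour over 100 replicates of
`n = 1000`, null calibration of the elimination over 400 replicates and of
cross-validation over 100 repetitions of an `n = 1000` label-permuted
cohort, and exhaustive trajectory-taxonomy checks over the 29,791-point
integer grid. These sizes were chosen so the sampling error of each check
sits well inside its stated tolerance.

## A worked example

```{r example}
model <- published_model()
tidy(model)

# the four interview answers: age of onset 62, no stroke, fainting in the
# past six months, vocalization during dreams
predict(model, tibble(age_of_onset = 62, stroke = 0, fainting = 1, vocalization = 1))

# under the study-conditions generator, the exact AUC of this model
cfg <- synth_config(n_subjects = 20000, seed = 1)
expected_model_auc(cfg, model)
```

## Known limitations

The model is built for de novo patients over a 4-year horizon and says
nothing about later disease stages, clinical MCI/dementia criteria, or
probability calibration (no Platt/isotonic step; the posterior is used only
through its ordering and the 0.5 decision rule). The published headline
cross-validated and blind-validation AUCs depend on the access-controlled
study data and are not reproducible from this package alone; what the
package reproduces are the printed worked values (prevalences, likelihood
ratios, pooled priors, the infinite-evidence posterior) and the statistical
properties of the machinery under its own generative model.
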