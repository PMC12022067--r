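# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: posteriors by enumerating the exact joint
# distribution, AUC by brute-force pairwise comparison, Fisher p-values by
# hypergeometric summation.

# exact P(decline | pattern, bracket) by enumerating the joint distribution
# of (class, all feature patterns) for class-conditionally independent
# binary features
oracle_joint_posterior <- function(prior, sens, spec, pattern) {
  k <- length(sens)
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  p_joint <- function(y) {
    p_class <- if (y == 1) prior else 1 - prior
    p_feat <- apply(grid, 1, function(x) {
      prod(ifelse(x == 1,
                  if (y == 1) sens else 1 - spec,
                  if (y == 1) 1 - sens else spec))
    })
    p_class * p_feat
  }
  joint1 <- p_joint(1)
  joint0 <- p_joint(0)
  row <- which(apply(grid, 1, function(x) all(x == pattern)))
  joint1[row] / (joint1[row] + joint0[row])
}

# Mann-Whitney AUC by explicit pairwise comparison, ties weighted 1/2
oracle_pairwise_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  cases <- scores[labels]
  ctrls <- scores[!labels]
  cmp <- outer(cases, ctrls, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# two-sided Fisher p-value by summing hypergeometric probabilities of all
# tables with the observed margins that are no more probable than the
# observed one (with the customary relative tolerance)
oracle_fisher_p <- function(tp, fn, fp, tn) {
  m <- tp + fn
  n <- fp + tn
  k <- tp + fp
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tp, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small labelled cohort with hand-settable feature columns
make_cohort <- function(decline, ..., age = NULL) {
  n <- length(decline)
  tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    age_of_onset = age %||% rep(60, n),
    decline = as.integer(decline),
    ...
  )
}

single_bracket <- function(lo = 30, hi = 100) {
  tibble::tibble(bracket_lo = lo, bracket_hi = hi)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
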