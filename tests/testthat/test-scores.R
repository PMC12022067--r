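# builds a one-row tibble with every MDS-UPDRS III item used by the derived
# scores, defaulting to 0
updrs3_row <- function(...) {
  cols <- c(
    "u3_rigidity_rue", "u3_rigidity_lue", "u3_rigidity_rle", "u3_rigidity_lle",
    "u3_fingertap_r", "u3_fingertap_l", "u3_handmov_r", "u3_handmov_l",
    "u3_pronsup_r", "u3_pronsup_l", "u3_toetap_r", "u3_toetap_l",
    "u3_legagility_r", "u3_legagility_l",
    "u3_posturaltremor_r", "u3_posturaltremor_l",
    "u3_kinetictremor_r", "u3_kinetictremor_l",
    "u3_resttremor_rue", "u3_resttremor_lue",
    "u3_resttremor_rle", "u3_resttremor_lle", "u3_resttremor_lipjaw",
    "u3_arising", "u3_gait", "u3_freezing", "u3_posturalstability", "u3_posture"
  )
  row <- as.list(stats::setNames(rep(0, length(cols)), cols))
  row <- utils::modifyList(row, list(...))
  tibble::as_tibble(row)
}

moca_items_row <- function(...) {
  maxima <- c(
    moca_trail = 1, moca_cube = 1, moca_clock_contour = 1,
    moca_clock_numbers = 1, moca_clock_hands = 1, moca_lion = 1,
    moca_rhino = 1, moca_camel = 1, moca_digits = 2, moca_letter = 1,
    moca_serial7 = 3, moca_repeat = 2, moca_fluency = 1,
    moca_abstraction = 2, moca_recall = 5, moca_orientation = 6
  )
  row <- as.list(maxima)
  row <- utils::modifyList(row, list(...))
  tibble::as_tibble(row)
}

test_that("lateralized sub-scores sum the right items and feed the rigidity cutoff", {
  d <- lateralized_subscores(updrs3_row(u3_rigidity_rue = 3, u3_rigidity_rle = 3))
  expect_equal(d$rigidity_right, 6)
  expect_equal(d$rigidity_left, 0)
  expect_equal(d$rigidity_unilateral, 3)

  defs <- tibble::tibble(name = "right_rigidity", source = "rigidity_right",
                         comparator = "gt", cutoff = 5)
  expect_true(binarize(d, defs)$right_rigidity) # 6 > 5: feature present
  at_cutoff <- lateralized_subscores(updrs3_row(u3_rigidity_rue = 3, u3_rigidity_rle = 2))
  expect_false(binarize(at_cutoff, defs)$right_rigidity) # strict comparator

  zeros <- lateralized_subscores(updrs3_row())
  expect_true(all(unlist(zeros[c(
    "rigidity_right", "rigidity_left", "akinesia_right",
    "akinesia_left", "tremor_right", "tremor_left"
  )]) == 0))
})

test_that("lateralized sums agree with a brute-force re-summation on random items", {
  withr::local_seed(101)
  for (rep in 1:20) {
    vals <- as.list(stats::setNames(sample(0:4, 28, replace = TRUE), names(updrs3_row())))
    d <- lateralized_subscores(do.call(updrs3_row, vals))
    expect_equal(d$rigidity_right, vals$u3_rigidity_rue + vals$u3_rigidity_rle)
    expect_equal(
      d$akinesia_left,
      vals$u3_fingertap_l + vals$u3_handmov_l + vals$u3_pronsup_l +
        vals$u3_toetap_l + vals$u3_legagility_l
    )
    expect_equal(
      d$tremor_right,
      vals$u3_posturaltremor_r + vals$u3_kinetictremor_r +
        vals$u3_resttremor_rue + vals$u3_resttremor_rle
    )
    expect_equal(d$akinesia_unilateral, (d$akinesia_right + d$akinesia_left) / 2)
  }
})

test_that("a missing constituent item propagates to a missing derived score, then absence", {
  d <- updrs3_row(u3_rigidity_rue = 3, u3_rigidity_rle = 3)
  d$u3_rigidity_rle <- NA_real_
  scored <- lateralized_subscores(d)
  expect_true(is.na(scored$rigidity_right))
  defs <- tibble::tibble(name = "right_rigidity", source = "rigidity_right",
                         comparator = "gt", cutoff = 5)
  expect_false(binarize(scored, defs)$right_rigidity)
})

test_that("PIGD/tremor phenotype applies the ratio thresholds verbatim", {
  even <- pigd_tremor_phenotype(updrs3_row(
    u3_arising = 1, u3_gait = 1, u3_freezing = 1, u3_posturalstability = 1,
    u3_posture = 1,
    u3_posturaltremor_r = 1, u3_posturaltremor_l = 1, u3_kinetictremor_r = 1,
    u3_kinetictremor_l = 1, u3_resttremor_rue = 1, u3_resttremor_lue = 1,
    u3_resttremor_rle = 1, u3_resttremor_lle = 1, u3_resttremor_lipjaw = 1
  ))
  expect_equal(even$pigd_score, 1)
  expect_equal(even$tremor_score, 1)
  expect_equal(even$phenotype, "PIGD") # ratio exactly 1.0 is PIGD-dominant

  tremor <- pigd_tremor_phenotype(updrs3_row(
    u3_arising = 1, u3_gait = 1, u3_freezing = 1, u3_posturalstability = 1,
    u3_posture = 1,
    u3_posturaltremor_r = 3, u3_posturaltremor_l = 3, u3_kinetictremor_r = 3,
    u3_kinetictremor_l = 3, u3_resttremor_rue = 3, u3_resttremor_lue = 3,
    u3_resttremor_rle = 3, u3_resttremor_lle = 3, u3_resttremor_lipjaw = 3
  ))
  expect_equal(tremor$phenotype, "tremor_dominant") # ratio 3 >= 1.5

  zero_pigd <- pigd_tremor_phenotype(updrs3_row(u3_posturaltremor_r = 2))
  expect_equal(zero_pigd$phenotype, "tremor_dominant") # infinite ratio

  expect_equal(pigd_tremor_phenotype(updrs3_row())$phenotype, "indeterminate")
})

test_that("MoCA domain sums validate items and trigger the visuospatial cutoff", {
  full <- moca_domain_subscores(moca_items_row())
  expect_equal(full$moca_visuospatial_executive, 5)
  expect_equal(full$moca_orientation, 6)
  defs <- tibble::tibble(name = "vse", source = "moca_visuospatial_executive",
                         comparator = "lt", cutoff = 3)
  expect_false(binarize(full, defs)$vse)

  low <- moca_domain_subscores(moca_items_row(
    moca_trail = 0, moca_cube = 1, moca_clock_contour = 1,
    moca_clock_numbers = 0, moca_clock_hands = 0
  ))
  expect_equal(low$moca_visuospatial_executive, 2)
  expect_true(binarize(low, defs)$vse)

  expect_error(moca_domain_subscores(cbind(moca_items_row(), moca_spiral = 1)),
               "Unknown MoCA item")
  expect_error(moca_domain_subscores(moca_items_row(moca_digits = 3)), "maximum")
})

test_that("MoCA domain sums equal a brute-force regrouping on random item vectors", {
  withr::local_seed(7)
  maxima <- c(1, 1, 1, 1, 1, 1, 1, 1, 2, 1, 3, 2, 1, 2, 5, 6)
  names(maxima) <- names(moca_items_row())
  for (rep in 1:20) {
    vals <- purrr::imap(as.list(maxima), ~ sample(0:.x, 1))
    d <- moca_domain_subscores(tibble::as_tibble(vals))
    expect_equal(
      d$moca_visuospatial_executive,
      vals$moca_trail + vals$moca_cube + vals$moca_clock_contour +
        vals$moca_clock_numbers + vals$moca_clock_hands
    )
    expect_equal(d$moca_naming, vals$moca_lion + vals$moca_rhino + vals$moca_camel)
    expect_equal(d$moca_attention, vals$moca_digits + vals$moca_letter + vals$moca_serial7)
    expect_equal(d$moca_language, vals$moca_repeat + vals$moca_fluency)
  }
})

test_that("binarization resolves sex-specific cutoffs, missingness and schema errors", {
  defs <- feature_definitions()
  expect_equal(nrow(defs), 22L)
  upsit <- defs[defs$name == "hyposmia", ]
  d <- tibble::tibble(sex = c("female", "male", "female"),
                      upsit_total = c(30, 30, NA))
  out <- binarize(d, upsit)
  expect_equal(out$hyposmia, c(TRUE, FALSE, FALSE)) # 30 < 31 only for females

  expect_error(
    binarize(tibble::tibble(sex = "male"), upsit),
    "absent from the cohort schema"
  )
})

test_that("binarization is total and monotone for greater-than features", {
  withr::local_seed(42)
  defs <- tibble::tibble(name = "risk", source = "score",
                         comparator = "gt", cutoff = 10)
  for (rep in 1:10) {
    v <- sample(c(0:20, NA), 30, replace = TRUE)
    out <- binarize(tibble::tibble(score = v), defs)$risk
    expect_length(out, 30)
    expect_false(anyNA(out))
    bumped <- binarize(tibble::tibble(score = v + 5), defs)$risk
    expect_true(all(bumped[out & !is.na(v)])) # raising the value never flips present -> absent
  }
})
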