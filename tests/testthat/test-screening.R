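# mirrors the combat-PTSD review screen: a large review in which most
# records are questionnaire-based or otherwise ineligible, and only the
# clinically assessed current-prevalence records survive
combat_review_corpus <- function() {
  rec <- function(study_id, prevalence, n, method,
                  exposure_specific = "yes", prevalence_type = "point",
                  months = 6) {
    data.frame(study_id = study_id, sample_id = study_id,
               prevalence = prevalence, n = n, method = method,
               exposure_specific = exposure_specific,
               prevalence_type = prevalence_type,
               months_post_exposure = months, stringsAsFactors = FALSE)
  }
  recs <- c(
    # questionnaire, exposure-specific
    lapply(1:20, function(i) rec(sprintf("q%02d", i), 0.1 + i / 100, 100,
                                 "questionnaire")),
    # questionnaire, not exposure-specific
    lapply(1:3, function(i) rec(sprintf("qn%d", i), 0.2, 120,
                                "questionnaire", exposure_specific = "no")),
    # clinical but period prevalence
    lapply(1:3, function(i) rec(sprintf("pp%d", i), 0.15, 150, "clinical",
                                prevalence_type = "period", months = 12)),
    # clinical, point, eligible
    lapply(1:4, function(i) rec(sprintf("c%d", i), 0.05 + i / 100, 200,
                                "clinical", months = 12)))
  study_corpus(do.call(rbind, recs))
}

test_that("a mixed review screens down to the clinical point-prevalence records", {
  corp <- combat_review_corpus()
  dec <- screen_corpus(corp, screening_rules())
  expect_identical(sort(dec$study_id[dec$included]),
                   sort(grep("^c", corp$study_id, value = TRUE)))
  # every questionnaire record was evicted by the preference rule
  qdec <- dec[startsWith(dec$study_id, "q"), ]
  expect_true(all(vapply(qdec$reasons, function(r)
    "QUESTIONNAIRE_WHEN_CLINICAL_AVAILABLE" %in% r, logical(1))))
  # non-specific questionnaires additionally carry their own code
  qn <- dec[startsWith(dec$study_id, "qn"), ]
  expect_true(all(vapply(qn$reasons, function(r)
    "NOT_EXPOSURE_SPECIFIC" %in% r, logical(1))))
  expect_true(all(vapply(dec$reasons[!dec$included], length,
                         integer(1)) > 0))
  expect_true(all(lengths(dec$reasons[dec$included]) == 0))
})

test_that("an all-clinical clean corpus passes untouched", {
  corp <- study_corpus(data.frame(
    study_id = sprintf("s%d", 1:6), events = 5 * (1:6), n = 100,
    method = "clinical", months_post_exposure = 3))
  dec <- screen_corpus(corp)
  expect_true(all(dec$included))
})

test_that("screening equals the brute-force per-rule set oracle", {
  for (seed in c(501, 502, 503)) {
    corp <- rand_corpus(50, seed = seed)
    dec <- screen_corpus(corp, screening_rules())
    expect_identical(dec$included, oracle_screen(corp),
                     label = paste("seed", seed))
  }
})

test_that("screening is idempotent and order-independent", {
  corp <- rand_corpus(50, seed = 504)
  dec <- screen_corpus(corp)
  # idempotence: re-screening the surviving set keeps everything
  kept <- corp[dec$included, , drop = FALSE]
  expect_true(all(screen_corpus(kept)$included))
  # order independence under several permutations
  for (seed in 1:3) {
    set.seed(seed)
    perm <- sample(nrow(corp))
    dec2 <- screen_corpus(corp[perm, , drop = FALSE])
    dec2 <- dec2[match(dec$study_id, dec2$study_id), ]
    expect_identical(dec2$included, dec$included)
    expect_identical(lapply(dec2$reasons, sort), lapply(dec$reasons, sort))
  }
})

test_that("relaxing per-record rules never shrinks the included set", {
  # the corpus-wide clinical preference can legitimately interact with
  # relaxation, so monotonicity is asserted for the per-record rules
  base <- screening_rules(prefer_clinical = FALSE)
  relaxed <- list(
    screening_rules(prefer_clinical = FALSE, min_months_post_exposure = 0),
    screening_rules(prefer_clinical = FALSE, require_point_prevalence = FALSE),
    screening_rules(prefer_clinical = FALSE, exclude_help_seeking = FALSE),
    screening_rules(prefer_clinical = FALSE,
                    require_exposure_specific_for_questionnaires = FALSE),
    screening_rules(prefer_clinical = FALSE, exclude_reanalyses = FALSE))
  for (seed in c(505, 506)) {
    corp <- rand_corpus(40, seed = seed)
    inc0 <- screen_corpus(corp, base)$included
    for (r in relaxed) {
      inc1 <- screen_corpus(corp, r)$included
      expect_true(all(inc1[inc0]), label = paste("seed", seed))
    }
  }
})

test_that("wave selection takes the highest eligible prevalence", {
  waves <- study_corpus(data.frame(
    study_id = "L", sample_id = "L", n = 100,
    prevalence = c(0.30, 0.22, 0.18),
    months_post_exposure = c(1, 6, 12), wave = 1:3))
  expect_equal(select_wave(waves)$prevalence, 0.30)

  waves2 <- study_corpus(data.frame(
    study_id = "M", sample_id = "M", n = 100,
    prevalence = c(0.40, 0.25),
    months_post_exposure = c(0.5, 6), wave = 1:2))
  expect_equal(select_wave(waves2)$prevalence, 0.25)

  none <- study_corpus(data.frame(
    study_id = "N", sample_id = "N", n = 50, prevalence = 0.4,
    months_post_exposure = 0.25))
  expect_error(select_wave(none), class = "metaburden_empty_selection")

  # randomized wave sets against the brute-force argmax
  for (i in 1:20) {
    set.seed(600 + i)
    nw <- sample(2:6, 1)
    x <- study_corpus(data.frame(
      study_id = "W", sample_id = "W", n = 100,
      prevalence = round(runif(nw, 0.05, 0.5), 2),
      months_post_exposure = round(runif(nw, 0, 18), 1), wave = 1:nw))
    if (all(is.na(x$months_post_exposure) | x$months_post_exposure < 1)) next
    expect_equal(select_wave(x)$wave, x$wave[oracle_wave(x)])
  }
})

test_that("superseded waves are flagged in corpus screening", {
  corp <- study_corpus(data.frame(
    study_id = c("a", "a", "b"), sample_id = c("sa", "sa", "sb"),
    n = 100, prevalence = c(0.30, 0.20, 0.10),
    months_post_exposure = c(2, 8, 3), wave = c(1, 2, 1),
    method = "clinical"))
  dec <- screen_corpus(corp)
  expect_identical(dec$included, c(TRUE, FALSE, TRUE))
  expect_identical(dec$reasons[[2]], "SUPERSEDED_WAVE")
})

test_that("the questionnaire correction multiplies once and only once", {
  expect_equal(apply_correction(0.21), 0.1491)
  expect_equal(round_half_up(apply_correction(0.21), 2), 0.15)
  expect_equal(apply_correction(0), 0)
  expect_equal(apply_correction(1), 0.71)
  expect_error(apply_correction(1.2), class = "metaburden_validation_error")
  expect_error(apply_correction(0.5, rules = 1.5),
               class = "metaburden_validation_error")

  corp <- study_corpus(data.frame(
    study_id = c("q1", "c1"), n = 100, prevalence = c(0.20, 0.30),
    method = c("questionnaire", "clinical"), months_post_exposure = 6))
  once <- correct_corpus(corp)
  expect_equal(once$prevalence, c(0.142, 0.30))  # clinical untouched
  expect_identical(correct_corpus(once), once)   # no-op on corrected rows
})
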