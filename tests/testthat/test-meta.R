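test_that("effect sizes follow the binomial variance formulas", {
  e <- compute_effects(study_corpus(
    data.frame(study_id = "a", events = 32, n = 100)), "raw")
  expect_equal(e$y, 0.32)
  expect_equal(e$v, 0.32 * 0.68 / 100)

  # zero events: continuity correction adds 0.5 events / 1 subject
  e0 <- compute_effects(study_corpus(
    data.frame(study_id = "z", events = 0, n = 50)), "raw")
  expect_equal(e0$y, 0.5 / 51)

  el <- compute_effects(study_corpus(
    data.frame(study_id = "l", events = 25, n = 50)), "logit")
  expect_equal(el$y, 0)
  expect_equal(el$v, 1 / 25 + 1 / 25)

  expect_error(compute_effects(study_corpus(
    data.frame(study_id = "tiny", events = 1, n = 1))),
    "n must be >= 2", class = "metaburden_validation_error")
})

test_that("DL estimate matches its closed form to 1e-10", {
  # hand-checkable three-study fixture
  e3 <- data.frame(y = c(0.10, 0.20, 0.30),
                   v = c(0.0009, 0.0016, 0.0021))
  expect_equal(as.numeric(estimate_tau2(e3, "DL")),
               oracle_dl(e3$y, e3$v), tolerance = 1e-10)

  for (seed in 701:720) {
    e <- rand_effects(sample(3:12, 1), seed)
    expect_lt(abs(as.numeric(estimate_tau2(e, "DL")) -
                    oracle_dl(e$y, e$v)), 1e-10)
  }
})

test_that("identical effects give zero heterogeneity under both estimators", {
  e <- data.frame(y = rep(0.2, 5), v = runif(5, 1e-4, 1e-3))
  expect_equal(as.numeric(estimate_tau2(e, "DL")), 0)
  expect_equal(as.numeric(estimate_tau2(e, "REML")), 0)
  het <- heterogeneity(e)
  expect_equal(het$Q, 0)
  expect_equal(het$I2, 0)
})

test_that("REML matches a grid search of the restricted likelihood", {
  for (seed in 801:820) {
    set.seed(seed)
    k <- sample(4:10, 1)
    tau_true <- runif(1, 0, 0.15)
    y <- pmin(0.95, pmax(0.01, rnorm(k, 0.25, sqrt(tau_true^2 + 0.001))))
    v <- runif(k, 5e-4, 5e-3)
    e <- data.frame(y = y, v = v)
    t2 <- estimate_tau2(e, "REML")
    expect_true(isTRUE(attr(t2, "converged")))
    # absolute agreement: the grid has 1e-5 resolution
    expect_lt(abs(as.numeric(t2) - oracle_reml_grid(y, v)), 1e-4)
  }
})

test_that("pooling reduces to fixed-effect when tau2 = 0 and matches formulas", {
  e <- rand_effects(6, 901)
  p0 <- pool_effects(e, 0)
  w <- 1 / e$v
  expect_equal(p0$mu_hat, sum(w * e$y) / sum(w))
  expect_equal(p0$se, sqrt(1 / sum(w)))

  # symmetric two-study case
  e2 <- data.frame(y = c(0.1, 0.3), v = c(0.01, 0.01))
  attr(e2, "scale") <- "raw"
  expect_equal(pool_effects(e2, 0)$mu_hat, 0.2)

  # random instances against direct re-evaluation of the weighted mean
  for (seed in 902:921) {
    e <- rand_effects(sample(3:10, 1), seed)
    t2 <- runif(1, 0, 0.02)
    p <- pool_effects(e, t2)
    w <- 1 / (e$v + t2)
    expect_equal(p$mu_hat, min(1, max(0, sum(w * e$y) / sum(w))))
    expect_equal(p$se, sqrt(1 / sum(w)))
    expect_equal(p$ci_low, max(0, sum(w * e$y) / sum(w) - qnorm(.975) * p$se))
  }
})

test_that("heterogeneity matches the two-term hand computation", {
  e2 <- data.frame(y = c(0.1, 0.3), v = c(0.01, 0.01))
  het <- heterogeneity(e2)
  # w = 100 each, mu_FE = 0.2, Q = 100*0.01 + 100*0.01 = 2
  expect_equal(het$Q, 2)
  expect_equal(het$df, 1)
  expect_equal(het$I2, 50)
  expect_equal(het$p_Q, pchisq(2, 1, lower.tail = FALSE))
})

test_that("prediction intervals follow the t formula and contain the CI", {
  # fixture: k = 5, mu = 0.10, se = 0.03, tau = 0.09
  pi <- prediction_interval(0.10, 0.03, 0.09^2, k = 5, scale = "raw")
  half <- qt(0.975, 3) * sqrt(0.09^2 + 0.03^2)
  expect_equal(pi$pi_low, max(0, 0.10 - half))
  expect_equal(pi$pi_high, min(1, 0.10 + half))
  expect_true(pi$available)

  # unavailable, never fabricated, below k = 3
  pi2 <- prediction_interval(0.2, 0.05, 0.01, k = 2)
  expect_false(pi2$available)
  expect_true(is.na(pi2$pi_low))

  # converges to the CI as k grows with tau2 = 0
  pi3 <- prediction_interval(0.3, 0.02, 0, k = 1e4)
  expect_lt(abs(pi3$pi_low - (0.3 - qnorm(.975) * 0.02)), 1e-3)
  expect_lt(abs(pi3$pi_high - (0.3 + qnorm(.975) * 0.02)), 1e-3)
})

test_that("run_meta composes the pipeline end to end", {
  # identical studies: pooled value is the shared proportion
  same <- study_corpus(data.frame(
    study_id = sprintf("s%d", 1:4), events = 30, n = 100,
    method = "clinical", months_post_exposure = 6))
  res <- run_meta(same)
  expect_equal(res$mu_hat, 0.30, tolerance = 1e-12)
  expect_equal(res$tau2, 0)
  expect_equal(res$I2, 0)
  expect_equal(res$k, 4)

  # questionnaire-only corpus: the 0.71 factor propagates through pooling
  qcorp <- study_corpus(data.frame(
    study_id = sprintf("q%d", 1:3), n = 200, prevalence = 0.10,
    method = "questionnaire", months_post_exposure = 6))
  resq <- run_meta(qcorp)
  expect_true(resq$adjusted)
  expect_equal(resq$mu_hat, 0.071, tolerance = 1e-12)

  # a mixed corpus must NOT be adjusted (clinical preference already
  # removed the questionnaires)
  mixed <- study_corpus(data.frame(
    study_id = c("c1", "c2", "q1"), n = 100,
    prevalence = c(0.2, 0.3, 0.4),
    method = c("clinical", "clinical", "questionnaire"),
    months_post_exposure = 6))
  resm <- run_meta(mixed)
  expect_false(resm$adjusted)
  expect_equal(resm$k, 2)

  # too few survivors: directed toward derivation by borrowing
  two <- study_corpus(data.frame(
    study_id = c("a", "b"), n = 100, prevalence = c(0.1, 0.2),
    months_post_exposure = c(0.5, 6), method = "clinical"))
  expect_error(run_meta(two), "borrow",
               class = "metaburden_too_few_studies")
})

test_that("run_meta recovers known truth in a single seeded replicate", {
  cfg <- synthetic_meta_config(k = 9, true_mu = 0.32, true_tau = 0.15,
                               seed = 1234)
  res <- run_meta(generate_meta_corpus(cfg))
  expect_lt(abs(res$mu_hat - 0.32), 0.08)
  expect_equal(res$k, 9)
})
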