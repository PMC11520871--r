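#' Per-study effect sizes for prevalence pooling
#'
#' Converts screened study records into effect sizes on the analysis
#' scale. On the raw scale the effect is the proportion itself,
#' `y = p`, with binomial within-study variance `v = p(1-p)/n`. On the
#' logit scale `y = log(p/(1-p))` with `v = 1/(np) + 1/(n(1-p))`. When a
#' study observed 0 or all cases the usual variance degenerates; a
#' continuity correction adds 0.5 to the event count and 1 to the sample
#' size before computing `p`.
#'
#' @param studies A [study_corpus()] of screened records (each row must
#'   carry `n` plus `events` or `prevalence`).
#' @param scale `"raw"` (default) or `"logit"`.
#' @return A data frame of class `effect_sizes` with columns `study_id`,
#'   `sample_id`, `y`, `v`, `n` and attribute `scale`.
#' @export
#' @examples
#' compute_effects(study_corpus(data.frame(study_id = "s", events = 32, n = 100)))
compute_effects <- function(studies, scale = c("raw", "logit")) {
  scale <- match.arg(scale)
  studies <- study_corpus(studies)
  if (any(studies$n < 2)) {
    i <- which(studies$n < 2)[1]
    mb_stop(sprintf("record %s: n must be >= 2 to compute a variance",
                    studies$study_id[i]), "metaburden_validation_error")
  }
  p <- studies$prevalence
  n <- studies$n
  ev <- ifelse(is.na(studies$events), p * n, studies$events)
  degenerate <- p <= 0 | p >= 1
  p[degenerate] <- (ev[degenerate] + 0.5) / (n[degenerate] + 1)
  if (scale == "raw") {
    y <- p
    v <- p * (1 - p) / n
  } else {
    y <- qlogis(p)
    v <- 1 / (n * p) + 1 / (n * (1 - p))
  }
  out <- data.frame(study_id = studies$study_id, sample_id = studies$sample_id,
                    y = y, v = v, n = n, stringsAsFactors = FALSE)
  attr(out, "scale") <- scale
  class(out) <- c("effect_sizes", "data.frame")
  out
}

# DerSimonian-Laird moment estimator. Q is the fixed-effect heterogeneity
# statistic; the denominator is sum(w) - sum(w^2)/sum(w) with w = 1/v.
tau2_dl <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  denom <- sum(w) - sum(w^2) / sum(w)
  if (denom <= 0) return(0)
  max(0, (Q - (k - 1)) / denom)
}

# REML via the standard fixed-point iteration
#   tau2 <- sum(w^2 ((y - mu)^2 - v)) / sum(w^2) + 1 / sum(w),
# with w = 1/(v + tau2); this is the stationarity condition of the
# restricted log-likelihood. Floored at 0 each step.
tau2_reml <- function(y, v, tol = 1e-8, max_iter = 200L) {
  tau2 <- max(0, var(y) - mean(v))
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    mu <- sum(w * y) / sum(w)
    new <- sum(w^2 * ((y - mu)^2 - v)) / sum(w^2) + 1 / sum(w)
    new <- max(0, new)
    if (abs(new - tau2) < tol) {
      tau2 <- new
      converged <- TRUE
      break
    }
    tau2 <- new
  }
  list(tau2 = tau2, converged = converged, iterations = i)
}

# restricted log-likelihood of tau2 (profile over mu); used by the
# convergence check and, in the test suite, by the grid-search oracle.
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' Between-study variance of a random-effects meta-analysis
#'
#' Estimates the variance of true effects across studies. `"DL"` is the
#' closed-form DerSimonian-Laird moment estimator; `"REML"` (default)
#' maximises the restricted log-likelihood by fixed-point iteration
#' (tolerance 1e-8, at most 200 iterations), falling back to DL with a
#' warning if the iteration does not converge. Both are floored at zero.
#'
#' @param effects An [compute_effects()] data frame (or any data frame
#'   with columns `y` and `v`).
#' @param method `"REML"` or `"DL"`.
#' @return The tau-squared estimate, with attributes `method` and (for
#'   REML) `converged`.
#' @export
estimate_tau2 <- function(effects, method = c("REML", "DL")) {
  method <- match.arg(method)
  y <- effects$y
  v <- effects$v
  if (length(y) < 2) mb_stop("need at least 2 effects to estimate tau2",
                             "metaburden_validation_error")
  if (any(v <= 0)) mb_stop("within-study variances must be positive",
                           "metaburden_validation_error")
  if (method == "DL") {
    t2 <- tau2_dl(y, v)
    attr(t2, "method") <- "DL"
    return(t2)
  }
  fit <- tau2_reml(y, v)
  if (!fit$converged) {
    warning("REML iteration did not converge in 200 steps; falling back to DL")
    t2 <- tau2_dl(y, v)
    attr(t2, "method") <- "DL"
    attr(t2, "converged") <- FALSE
    return(t2)
  }
  t2 <- fit$tau2
  attr(t2, "method") <- "REML"
  attr(t2, "converged") <- TRUE
  t2
}

#' Pool effect sizes under a random-effects model
#'
#' Inverse-variance pooling with weights `1/(v + tau2)`. The pooled
#' effect, its standard error, and a normal-theory confidence interval
#' are computed on the analysis scale; logit-scale results are
#' back-transformed to proportions and raw-scale bounds are truncated to
#' \[0, 1\].
#'
#' @param effects An [compute_effects()] data frame.
#' @param tau2 Between-study variance (>= 0).
#' @param level Confidence level (default 0.95).
#' @return A list: `mu_hat` (pooled prevalence), `se` (on the analysis
#'   scale), `ci_low`, `ci_high`, `mu_scale` (pooled effect on the
#'   analysis scale), `weights`, `scale`.
#' @export
pool_effects <- function(effects, tau2, level = 0.95) {
  y <- effects$y
  v <- effects$v
  if (length(y) < 2) mb_stop("need k >= 2 to pool", "metaburden_validation_error")
  if (tau2 < 0) mb_stop("tau2 must be >= 0", "metaburden_validation_error")
  scale <- attr(effects, "scale") %||% "raw"
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- qnorm(1 - (1 - level) / 2)
  lo <- mu - z * se
  hi <- mu + z * se
  if (scale == "logit") {
    point <- plogis(mu)
    lo <- plogis(lo)
    hi <- plogis(hi)
  } else {
    point <- min(1, max(0, mu))
    lo <- min(1, max(0, lo))
    hi <- min(1, max(0, hi))
  }
  list(mu_hat = point, se = se, ci_low = lo, ci_high = hi,
       mu_scale = mu, weights = w / sum(w), scale = scale, level = level)
}

#' Heterogeneity statistics
#'
#' Cochran's Q with fixed-effect weights around the fixed-effect pooled
#' value, its chi-squared p-value on `k - 1` degrees of freedom, and the
#' I-squared share of total variability attributable to true
#' heterogeneity, `max(0, (Q - df)/Q) * 100`.
#'
#' @param effects An [compute_effects()] data frame.
#' @return A list with `Q`, `df`, `p_Q`, `I2`.
#' @export
heterogeneity <- function(effects) {
  y <- effects$y
  v <- effects$v
  if (length(y) < 2) mb_stop("need k >= 2 for heterogeneity",
                             "metaburden_validation_error")
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  df <- length(y) - 1L
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  list(Q = Q, df = df, p_Q = pchisq(Q, df, lower.tail = FALSE), I2 = I2)
}

#' Prediction interval for the true prevalence of a new setting
#'
#' Bounds the true effect of a new study rather than the pooled mean:
#' `mu +/- t_{k-2} * sqrt(tau2 + se^2)`, following the convention of
#' using a t quantile on `k - 2` degrees of freedom. Wider than the
#' confidence interval whenever `tau2 > 0`; requires `k >= 3`. Computed
#' on the analysis scale and back-transformed/truncated like the CI.
#'
#' @param mu_scale Pooled effect on the analysis scale.
#' @param se Standard error of the pooled effect (analysis scale).
#' @param tau2 Between-study variance.
#' @param k Number of pooled samples.
#' @param scale `"raw"` or `"logit"`.
#' @param level Coverage level (default 0.95).
#' @return A list `pi_low`, `pi_high`, `available`; bounds are `NA` with
#'   `available = FALSE` when `k <= 2` (never fabricated).
#' @export
prediction_interval <- function(mu_scale, se, tau2, k, scale = "raw",
                                level = 0.95) {
  if (k < 3) {
    return(list(pi_low = NA_real_, pi_high = NA_real_, available = FALSE))
  }
  tq <- qt(1 - (1 - level) / 2, df = k - 2)
  half <- tq * sqrt(tau2 + se^2)
  lo <- mu_scale - half
  hi <- mu_scale + half
  if (scale == "logit") {
    lo <- plogis(lo)
    hi <- plogis(hi)
  } else {
    lo <- min(1, max(0, lo))
    hi <- min(1, max(0, hi))
  }
  list(pi_low = lo, pi_high = hi, available = TRUE)
}

#' Random-effects meta-analysis of a screened prevalence corpus
#'
#' End-to-end pooling of one exposure group's literature: screens the
#' corpus ([screen_corpus()], including wave selection), applies the
#' questionnaire correction factor at study level when the surviving
#' corpus is questionnaire-only, computes effect sizes, estimates the
#' between-study variance, pools, and attaches heterogeneity statistics
#' and (for `k >= 3`) a prediction interval.
#'
#' @param corpus A [study_corpus()].
#' @param rules A [screening_rules()].
#' @param scale Analysis scale, `"raw"` (default) or `"logit"`.
#' @param estimator `"REML"` (default) or `"DL"`.
#' @param level Confidence level.
#' @return An object of class `meta_result`: `mu_hat`, `se`, `ci_low`,
#'   `ci_high`, `tau2`, `tau`, `Q`, `df`, `p_Q`, `I2`, `k`, `pi_low`,
#'   `pi_high`, `pi_available`, `estimator`, `scale`, `adjusted` (was the
#'   0.71 correction applied), `decisions` (screening audit), `studies`
#'   (per-study forest-plot table: y, bounds, weight).
#' @export
run_meta <- function(corpus, rules = screening_rules(),
                     scale = c("raw", "logit"),
                     estimator = c("REML", "DL"), level = 0.95) {
  scale <- match.arg(scale)
  estimator <- match.arg(estimator)
  corpus <- study_corpus(corpus)
  decisions <- screen_corpus(corpus, rules)
  keep <- corpus[decisions$included, , drop = FALSE]
  if (nrow(keep) < 2) {
    mb_stop(paste0(
      "fewer than 2 samples survive screening (k = ", nrow(keep), "); ",
      "a meta-analysis is not possible - derive this group's estimate by ",
      "borrowing or averaging other groups instead (see derive_groups())"),
      "metaburden_too_few_studies")
  }
  adjusted <- FALSE
  if (all(keep$method == "questionnaire")) {
    keep <- correct_corpus(keep, rules)
    adjusted <- TRUE
  }
  effects <- compute_effects(keep, scale)
  tau2 <- estimate_tau2(effects, estimator)
  pooled <- pool_effects(effects, as.numeric(tau2), level)
  het <- heterogeneity(effects)
  k <- nrow(effects)
  pi <- prediction_interval(pooled$mu_scale, pooled$se, as.numeric(tau2),
                            k, scale, level)
  z <- qnorm(1 - (1 - level) / 2)
  studies <- data.frame(
    study_id = effects$study_id, sample_id = effects$sample_id,
    y = effects$y,
    ci_low = effects$y - z * sqrt(effects$v),
    ci_high = effects$y + z * sqrt(effects$v),
    weight = pooled$weights,
    stringsAsFactors = FALSE
  )
  structure(list(
    mu_hat = pooled$mu_hat, se = pooled$se,
    ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    tau2 = as.numeric(tau2), tau = sqrt(as.numeric(tau2)),
    Q = het$Q, df = het$df, p_Q = het$p_Q, I2 = het$I2, k = k,
    pi_low = pi$pi_low, pi_high = pi$pi_high, pi_available = pi$available,
    estimator = attr(tau2, "method") %||% estimator, scale = scale,
    level = level, adjusted = adjusted, mu_scale = pooled$mu_scale,
    decisions = decisions, studies = studies
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (%s, %s scale), k = %d%s\n",
    x$estimator, x$scale, x$k,
    if (x$adjusted) ", questionnaire-adjusted (x0.71)" else ""))
  cat(sprintf("  pooled prevalence = %.2f (95%% CI %.2f-%.2f)\n",
              x$mu_hat, x$ci_low, x$ci_high))
  cat(sprintf("  Q(%d) = %.2f, p %s, I2 = %.2f%%, tau = %.2f\n",
              x$df, x$Q,
              if (x$p_Q < 0.001) "< 0.001" else sprintf("= %.3f", x$p_Q),
              x$I2, x$tau))
  if (isTRUE(x$pi_available)) {
    cat(sprintf("  95%% prediction interval %.2f-%.2f\n", x$pi_low, x$pi_high))
  }
  invisible(x)
}
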