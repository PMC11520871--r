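# Independent oracles. These deliberately re-derive each quantity from
# first principles (set operations, closed forms, grid search) rather
# than calling package internals, so agreement is evidence, not
# tautology.

# closed-form DerSimonian-Laird estimate, written out directly
oracle_dl <- function(y, v) {
  w <- 1 / v
  q <- sum(w * (y - sum(w * y) / sum(w))^2)
  c1 <- sum(w) - sum(w^2) / sum(w)
  max(0, (q - (length(y) - 1)) / c1)
}

# grid-search maximizer of the restricted log-likelihood over tau2
oracle_reml_grid <- function(y, v, upper = 1, step = 1e-5) {
  grid <- seq(0, upper, by = step)
  vp <- outer(v, grid, "+")          # k x G
  w <- 1 / vp
  sw <- colSums(w)
  mu <- colSums(w * y) / sw
  ll <- -0.5 * (colSums(log(vp)) + log(sw) +
                  colSums(w * outer(y, mu, "-")^2))
  grid[which.max(ll)]
}

# brute-force screening: each rule as an index-set operation, unioned;
# then the corpus-wide clinical preference; then per-sample argmax wave
oracle_screen <- function(corpus, rules = screening_rules()) {
  n <- nrow(corpus)
  idx <- seq_len(n)
  excl <- list(
    timing = idx[is.na(corpus$months_post_exposure) |
                   corpus$months_post_exposure < rules$min_months_post_exposure],
    period = if (rules$require_point_prevalence)
      idx[corpus$prevalence_type != "point"] else integer(),
    help = if (rules$exclude_help_seeking)
      idx[corpus$population != "general"] else integer(),
    nonspec = if (rules$require_exposure_specific_for_questionnaires)
      idx[corpus$method == "questionnaire" &
            corpus$exposure_specific != "yes"] else integer(),
    reanal = if (rules$exclude_reanalyses)
      idx[!is.na(corpus$reanalysis_of)] else integer()
  )
  out <- setdiff(idx, Reduce(union, excl))
  if (rules$prefer_clinical &&
      length(intersect(out, idx[corpus$method == "clinical"])) > 0) {
    out <- setdiff(out, idx[corpus$method == "questionnaire"])
  }
  # wave: keep per-sample maximum prevalence (tie: lowest wave, then
  # earliest months)
  keep <- integer()
  for (sid in unique(corpus$sample_id[out])) {
    cand <- out[corpus$sample_id[out] == sid]
    ord <- order(-corpus$prevalence[cand], corpus$wave[cand],
                 corpus$months_post_exposure[cand])
    keep <- c(keep, cand[ord][1])
  }
  included <- logical(n)
  included[keep] <- TRUE
  included
}

# brute-force wave selection: argmax prevalence over the timing-eligible
# subset, ties to the earliest wave
oracle_wave <- function(x, min_months = 1) {
  ok <- which(!is.na(x$months_post_exposure) &
                x$months_post_exposure >= min_months)
  ok[order(-x$prevalence[ok], x$wave[ok], x$months_post_exposure[ok])][1]
}

# randomized corpus with fully randomized screening metadata
rand_corpus <- function(n, seed) {
  set.seed(seed)
  study_corpus(data.frame(
    study_id = sprintf("r%03d", seq_len(n)),
    sample_id = sprintf("r%03d", seq_len(n)),
    events = NA_real_,
    n = sample(30:400, n, replace = TRUE),
    prevalence = round(runif(n, 0.01, 0.6), 3),
    method = sample(c("clinical", "questionnaire"), n, replace = TRUE),
    months_post_exposure = ifelse(runif(n) < 0.1, NA_real_,
                                  round(runif(n, 0, 24), 1)),
    prevalence_type = sample(c("point", "period", "unknown"), n,
                             replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    population = sample(c("general", "help_seeking", "clinical_setting"),
                        n, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
    exposure_specific = sample(c("yes", "no", "unknown"), n,
                               replace = TRUE, prob = c(0.7, 0.2, 0.1)),
    wave = 1L,
    reanalysis_of = ifelse(runif(n) < 0.1, "some_study", NA_character_),
    stringsAsFactors = FALSE))
}

# random well-conditioned effect sets for meta-engine oracle checks
rand_effects <- function(k, seed) {
  set.seed(seed)
  y <- runif(k, 0.05, 0.5)
  v <- runif(k, 5e-4, 5e-3)
  e <- data.frame(study_id = sprintf("e%d", seq_len(k)),
                  sample_id = sprintf("e%d", seq_len(k)),
                  y = y, v = v, n = round(y * (1 - y) / v))
  attr(e, "scale") <- "raw"
  class(e) <- c("effect_sizes", "data.frame")
  e
}

# mean of a logit-normal distribution by numerical integration
logitnorm_mean <- function(mu, tau) {
  if (tau == 0) return(mu)
  integrate(function(x) plogis(x) * dnorm(x, qlogis(mu), tau),
            -15, 15, rel.tol = 1e-10)$value
}
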