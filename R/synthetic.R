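# run code with a locally seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Configuration for a synthetic meta-analysis corpus
#'
#' Describes the generative world the pipeline is validated against:
#' each of `k` studies has a true prevalence drawn around `true_mu` with
#' heterogeneity `true_tau` on the chosen random-effects scale
#' (`logit_normal`: the logit of the study prevalence is normal with SD
#' `true_tau`, keeping prevalences inside (0, 1) naturally;
#' `additive_truncated`: the prevalence itself is normal, truncated to
#' (0, 1)); observed cases are binomial. A share of studies is flagged
#' as questionnaire-based, and `contamination` plants records that
#' violate individual screening rules (measured under one month,
#' help-seeking samples, period prevalence, questionnaire without
#' exposure-specific assessment), each carrying its ground-truth label.
#'
#' @param k Number of studies (>= 1).
#' @param true_mu Population mean prevalence, in (0, 1).
#' @param true_tau Heterogeneity SD on the random-effects scale (>= 0).
#' @param effects_scale `"logit_normal"` or `"additive_truncated"`.
#' @param n_range Integer range of study sample sizes (min >= 10).
#' @param questionnaire_fraction Share of clean studies flagged
#'   questionnaire-based.
#' @param contamination Named counts:
#'   `timing`, `help_seeking`, `period`, `non_specific`. Their sum may
#'   not exceed `k`.
#' @param seed Mandatory integer seed; generation never touches the
#'   wall clock.
#' @return A `synthetic_meta_config` list.
#' @export
synthetic_meta_config <- function(k, true_mu, true_tau,
                                  effects_scale = c("logit_normal",
                                                    "additive_truncated"),
                                  n_range = c(50, 500),
                                  questionnaire_fraction = 0,
                                  contamination = list(),
                                  seed) {
  effects_scale <- match.arg(effects_scale)
  if (missing(seed) || !is.numeric(seed)) {
    mb_stop("a numeric seed is mandatory", "metaburden_validation_error")
  }
  if (true_mu <= 0 || true_mu >= 1) {
    mb_stop("true_mu must be in (0, 1)", "metaburden_validation_error")
  }
  if (true_tau < 0) mb_stop("true_tau must be >= 0",
                            "metaburden_validation_error")
  if (n_range[1] < 10) mb_stop("n_range minimum must be >= 10",
                               "metaburden_validation_error")
  cont <- modifyList(list(timing = 0L, help_seeking = 0L, period = 0L,
                          non_specific = 0L), as.list(contamination))
  if (sum(unlist(cont)) > k) {
    mb_stop(sprintf("infeasible contamination: %d contaminated records > k = %d",
                    sum(unlist(cont)), k), "metaburden_validation_error")
  }
  structure(list(k = as.integer(k), true_mu = true_mu, true_tau = true_tau,
                 effects_scale = effects_scale,
                 n_range = as.integer(n_range),
                 questionnaire_fraction = questionnaire_fraction,
                 contamination = cont, seed = as.integer(seed)),
            class = "synthetic_meta_config")
}

# draw k true study prevalences under the configured random-effects law
draw_theta <- function(cfg) {
  if (cfg$effects_scale == "logit_normal") {
    plogis(rnorm(cfg$k, qlogis(cfg$true_mu), cfg$true_tau))
  } else {
    th <- rnorm(cfg$k, cfg$true_mu, cfg$true_tau)
    while (any(bad <- th <= 0 | th >= 1)) {
      th[bad] <- rnorm(sum(bad), cfg$true_mu, cfg$true_tau)
    }
    th
  }
}

#' Generate a synthetic study corpus with ground-truth screening labels
#'
#' Draws study-level true prevalences under the configured
#' random-effects distribution, binomial case counts, and screening
#' metadata. Contaminated records get exactly one planted rule
#' violation each; the returned corpus carries `truth_included` and
#' `truth_reasons` columns holding the label a correct screen must
#' reproduce (including the corpus-wide clinical-preference rule).
#' Fully reproducible: the same config (same seed) yields a
#' byte-identical corpus.
#'
#' @param cfg A [synthetic_meta_config()].
#' @return A [study_corpus()] with extra columns `theta` (true
#'   prevalence), `truth_included`, `truth_reasons` (list column).
#' @export
generate_meta_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_meta_config"))
  with_seed(cfg$seed, {
    k <- cfg$k
    theta <- draw_theta(cfg)
    n <- sample(seq(cfg$n_range[1], cfg$n_range[2]), k, replace = TRUE)
    events <- rbinom(k, n, theta)

    method <- ifelse(runif(k) < cfg$questionnaire_fraction,
                     "questionnaire", "clinical")
    months <- sample(1:24, k, replace = TRUE)
    ptype <- rep("point", k)
    popn <- rep("general", k)
    espec <- rep("yes", k)

    cont <- cfg$contamination
    n_cont <- sum(unlist(cont))
    idx <- if (n_cont > 0) sample(k, n_cont) else integer()
    kinds <- rep(names(cont), times = unlist(cont))
    planted <- setNames(rep(NA_character_, k), NULL)
    for (j in seq_along(idx)) {
      i <- idx[j]
      planted[i] <- kinds[j]
      switch(kinds[j],
        timing = { months[i] <- round(runif(1, 0, 0.9), 2) },
        help_seeking = { popn[i] <- "help_seeking" },
        period = { ptype[i] <- "period" },
        non_specific = { method[i] <- "questionnaire"; espec[i] <- "no" })
    }

    corpus <- study_corpus(data.frame(
      study_id = sprintf("syn%02d", seq_len(k)),
      events = events, n = n,
      method = method, months_post_exposure = months,
      prevalence_type = ptype, population = popn,
      exposure_specific = espec, wave = 1L,
      stringsAsFactors = FALSE))
    corpus$theta <- theta

    # ground-truth labels by construction: planted per-record violations,
    # then the corpus-wide clinical-preference rule
    reasons <- lapply(seq_len(k), function(i) {
      switch(planted[i],
        timing = "TIMING_LT_1MO",
        help_seeking = "HELP_SEEKING",
        period = "PERIOD_PREVALENCE",
        non_specific = "NOT_EXPOSURE_SPECIFIC",
        character())
    })
    clean <- lengths(reasons) == 0L
    if (any(clean & method == "clinical") && any(method == "questionnaire")) {
      q <- method == "questionnaire"
      reasons[q] <- lapply(reasons[q], c, "QUESTIONNAIRE_WHEN_CLINICAL_AVAILABLE")
    }
    corpus$truth_reasons <- reasons
    corpus$truth_included <- lengths(reasons) == 0L
    corpus
  })
}

#' Generate a full multi-group national scenario with known truth
#'
#' Builds a scenario shaped like the published six-stratum model: most
#' strata get synthetic study corpora pooled by meta-analysis, one
#' stratum borrows another's estimate, one averages two others, and the
#' last stratum is the residual absorbing the rest of the national
#' population. True prevalences and sizes are recorded so end-to-end
#' runs can be compared against ground-truth expected caseloads
#' (`size x true prevalence`).
#'
#' @param n_groups Number of strata (>= 4 so borrow/average/residual
#'   roles exist; default 6).
#' @param size_profile Optional vector of stratum sizes (persons); the
#'   default draws increasing sizes and a dominant residual, echoing a
#'   population where heavy exposure is rare.
#' @param prevalence_profile Optional vector of true prevalences;
#'   default decreases from 0.32 toward 0.02 across strata.
#' @param seed Mandatory integer seed.
#' @param dir Optional directory: when given, the scenario YAML and one
#'   corpus CSV per meta stratum are written there, readable by
#'   [run_model()].
#' @param k_per_group Studies per synthetic corpus (default 10).
#' @param n_range Study sample-size range (default 100–500).
#' @param true_tau Logit-scale heterogeneity of each corpus (default 0.15).
#' @return A list: `scenario` (list, with attribute `dir` when written),
#'   `truth` (data frame of true prevalence and expected counts per
#'   stratum, plus totals), `configs` (per-stratum generator configs).
#' @export
generate_scenario <- function(n_groups = 6, size_profile = NULL,
                              prevalence_profile = NULL, seed,
                              dir = NULL, k_per_group = 10,
                              n_range = c(100, 500), true_tau = 0.15) {
  if (missing(seed)) mb_stop("a numeric seed is mandatory",
                             "metaburden_validation_error")
  if (n_groups < 4) mb_stop("need at least 4 groups", "metaburden_validation_error")

  with_seed(seed, {
    if (is.null(prevalence_profile)) {
      prevalence_profile <- exp(seq(log(0.32), log(0.02),
                                    length.out = n_groups))
    }
    if (is.null(size_profile)) {
      base <- sort(round(runif(n_groups - 1, 3e4, 2e6)))
      size_profile <- c(base, round(3.5e6 + runif(1, 0, 1e6)))
    }
    national <- sum(size_profile)
    ids <- sprintf("g%d", seq_len(n_groups))

    # roles: group 2 borrows from group 4's analogue; the second-to-last
    # group averages its neighbours; the last is the residual
    borrow_id <- ids[2]
    borrow_src <- ids[min(4, n_groups - 2)]
    avg_id <- ids[n_groups - 1]
    avg_src <- c(ids[min(4, n_groups - 2)], ids[n_groups])
    meta_ids <- setdiff(ids, c(borrow_id, avg_id))

    sub_seeds <- sample.int(2^31 - 1, n_groups)
    configs <- list()
    groups <- list()
    for (i in seq_len(n_groups)) {
      id <- ids[i]
      g <- list(id = id, name = paste("Synthetic stratum", i),
                raw_size = size_profile[i])
      if (i == n_groups) {
        g$raw_size <- NULL
        g$residual <- TRUE
      }
      if (id == borrow_id) {
        g$estimate <- list(mode = "borrow", sources = list(borrow_src))
      } else if (id == avg_id) {
        g$estimate <- list(mode = "average", sources = as.list(avg_src))
      } else {
        cfg <- synthetic_meta_config(
          k = k_per_group, true_mu = prevalence_profile[i],
          true_tau = true_tau, n_range = n_range, seed = sub_seeds[i])
        configs[[id]] <- cfg
        g$estimate <- list(mode = "meta",
                           corpus = paste0("corpus_", id, ".csv"))
      }
      groups[[i]] <- g
    }

    scenario <- list(name = sprintf("synthetic_scenario_seed%d", seed),
                     national_population = national, interval_kind = "ci",
                     groups = groups)

    # ground truth: borrow/average strata inherit/combine true rates
    true_p <- setNames(prevalence_profile, ids)
    true_p[borrow_id] <- true_p[borrow_src]
    true_p[avg_id] <- mean(true_p[avg_src])
    truth <- data.frame(group_id = ids, size = size_profile,
                        true_prevalence = as.numeric(true_p),
                        expected = size_profile * as.numeric(true_p),
                        stringsAsFactors = FALSE)

    corpora <- lapply(configs, function(cfg) {
      corpus <- generate_meta_corpus(cfg)
      corpus$theta <- NULL
      corpus$truth_reasons <- NULL
      corpus$truth_included <- NULL
      corpus
    })
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (id in names(corpora)) {
        write_corpus(corpora[[id]], file.path(dir, paste0("corpus_", id, ".csv")))
      }
      yaml::write_yaml(scenario, file.path(dir, "scenario.yaml"))
      attr(scenario, "dir") <- normalizePath(dir)
    } else {
      # no files on disk: embed the generated corpora directly
      for (i in seq_along(scenario$groups)) {
        id <- scenario$groups[[i]]$id
        if (!is.null(corpora[[id]])) {
          scenario$groups[[i]]$estimate$corpus <- corpora[[id]]
        }
      }
    }
    list(scenario = scenario, truth = truth, configs = configs,
         total_expected = sum(truth$expected))
  })
}
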