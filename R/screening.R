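#' Screening rule set
#'
#' Bundles the eligibility and adjustment rules applied to a study corpus
#' before pooling. Defaults encode the conservative screening protocol:
#' measurements taken less than one month after traumatic exposure reflect
#' acute stress rather than PTSD and are dropped; only point prevalence is
#' retained; help-seeking and clinical-setting samples are excluded; a
#' questionnaire record must have assessed PTSD specifically in relation
#' to the war/terror exposure; re-analyses of an already-included sample
#' are dropped; and when any clinically assessed record survives, all
#' questionnaire records in the corpus are discarded in its favour
#' (`prefer_clinical`). `correction_factor` (0.71) deflates
#' questionnaire-based prevalences when a corpus contains no clinical
#' assessments at all, offsetting the documented ~41% overestimation of
#' self-report instruments relative to clinical interview.
#'
#' @param min_months_post_exposure Minimum months since exposure (default 1).
#' @param require_point_prevalence Drop period/unknown prevalence types.
#' @param exclude_help_seeking Drop help-seeking and clinical-setting samples.
#' @param require_exposure_specific_for_questionnaires Drop questionnaire
#'   records not tied to the specific exposure.
#' @param exclude_reanalyses Drop records flagged as re-analyses.
#' @param prefer_clinical Corpus-wide preference for clinical assessments.
#' @param correction_factor Multiplier in (0, 1] for questionnaire-only
#'   corpora.
#' @return An object of class `screening_rules`.
#' @export
screening_rules <- function(min_months_post_exposure = 1,
                            require_point_prevalence = TRUE,
                            exclude_help_seeking = TRUE,
                            require_exposure_specific_for_questionnaires = TRUE,
                            exclude_reanalyses = TRUE,
                            prefer_clinical = TRUE,
                            correction_factor = 0.71) {
  if (!is.numeric(correction_factor) || length(correction_factor) != 1 ||
      correction_factor <= 0 || correction_factor > 1) {
    mb_stop("correction_factor must be a single number in (0, 1]",
            "metaburden_validation_error")
  }
  if (!is.numeric(min_months_post_exposure) || min_months_post_exposure < 0) {
    mb_stop("min_months_post_exposure must be >= 0",
            "metaburden_validation_error")
  }
  structure(list(
    min_months_post_exposure = min_months_post_exposure,
    require_point_prevalence = isTRUE(require_point_prevalence),
    exclude_help_seeking = isTRUE(exclude_help_seeking),
    require_exposure_specific_for_questionnaires =
      isTRUE(require_exposure_specific_for_questionnaires),
    exclude_reanalyses = isTRUE(exclude_reanalyses),
    prefer_clinical = isTRUE(prefer_clinical),
    correction_factor = correction_factor
  ), class = "screening_rules")
}

# Per-record eligibility reasons, before corpus-wide rules. Unknown timing
# is treated as ineligible under the timing rule (conservative), and
# unknown prevalence type as ineligible under the point-prevalence rule.
base_reasons <- function(corpus, rules) {
  lapply(seq_len(nrow(corpus)), function(i) {
    r <- corpus[i, ]
    reasons <- character()
    if (is.na(r$months_post_exposure)) {
      if (rules$min_months_post_exposure > 0) reasons <- c(reasons, "TIMING_UNKNOWN")
    } else if (r$months_post_exposure < rules$min_months_post_exposure) {
      reasons <- c(reasons, "TIMING_LT_1MO")
    }
    if (rules$require_point_prevalence && r$prevalence_type != "point") {
      reasons <- c(reasons, "PERIOD_PREVALENCE")
    }
    if (rules$exclude_help_seeking && r$population != "general") {
      reasons <- c(reasons,
                   if (r$population == "help_seeking") "HELP_SEEKING" else "CLINICAL_SETTING")
    }
    if (rules$require_exposure_specific_for_questionnaires &&
        r$method == "questionnaire" && r$exposure_specific != "yes") {
      reasons <- c(reasons, "NOT_EXPOSURE_SPECIFIC")
    }
    if (rules$exclude_reanalyses && !is.na(r$reanalysis_of)) {
      reasons <- c(reasons, "REANALYSIS")
    }
    reasons
  })
}

#' Screen a study corpus
#'
#' Applies the per-record eligibility rules, then the corpus-wide
#' clinical-preference rule (if any clinically assessed record survives
#' the other filters, every questionnaire record is excluded), then wave
#' selection within each sample (only the highest eligible prevalence
#' measurement of a longitudinal sample is retained; later/other waves
#' are marked `SUPERSEDED_WAVE`). Decisions are order-independent: the
#' same corpus in any row order yields the same per-record decisions.
#'
#' @param corpus A [study_corpus()] (or coercible data frame).
#' @param rules A [screening_rules()] object.
#' @return A `screening_decisions` data frame with columns `study_id`,
#'   `sample_id`, `wave`, `included`, and the list-column `reasons`
#'   (machine-readable exclusion codes; empty iff included).
#' @export
#' @examples
#' corp <- study_corpus(data.frame(
#'   study_id = c("a", "b"), events = c(10, 20), n = c(100, 100),
#'   method = c("clinical", "questionnaire")))
#' screen_corpus(corp, screening_rules())
screen_corpus <- function(corpus, rules = screening_rules()) {
  corpus <- study_corpus(corpus)
  stopifnot(inherits(rules, "screening_rules"))

  reasons <- base_reasons(corpus, rules)
  alive <- lengths(reasons) == 0L

  if (rules$prefer_clinical &&
      any(alive & corpus$method == "clinical") &&
      any(corpus$method == "questionnaire")) {
    q <- corpus$method == "questionnaire"
    reasons[q] <- lapply(reasons[q], c, "QUESTIONNAIRE_WHEN_CLINICAL_AVAILABLE")
    alive <- lengths(reasons) == 0L
  }

  # wave selection: per sample, keep the maximum-prevalence surviving
  # record; ties broken by earliest wave then earliest measurement time
  # (deterministic, order-independent).
  for (sid in unique(corpus$sample_id)) {
    idx <- which(corpus$sample_id == sid & alive)
    if (length(idx) <= 1L) next
    ord <- order(-corpus$prevalence[idx], corpus$wave[idx],
                 corpus$months_post_exposure[idx])
    drop <- idx[ord][-1L]
    reasons[drop] <- lapply(reasons[drop], c, "SUPERSEDED_WAVE")
  }

  out <- data.frame(
    study_id = corpus$study_id,
    sample_id = corpus$sample_id,
    wave = corpus$wave,
    included = lengths(reasons) == 0L,
    stringsAsFactors = FALSE
  )
  out$reasons <- reasons
  class(out) <- c("screening_decisions", "data.frame")
  out
}

#' Select the reporting wave of a longitudinal sample
#'
#' Among repeated measurements of one sample, returns the record with the
#' highest prevalence among those taken at least `min_months` after the
#' exposure. Ties go to the earliest eligible wave. Prevalences generally
#' decline over follow-up, so this captures the peak of diagnosable PTSD.
#'
#' @param records_of_one_sample A [study_corpus()] whose rows share one
#'   `sample_id`.
#' @param min_months Minimum eligible months since exposure (default 1).
#' @return The selected single-row `study_corpus`.
#' @export
select_wave <- function(records_of_one_sample, min_months = 1) {
  x <- study_corpus(records_of_one_sample)
  if (length(unique(x$sample_id)) != 1L) {
    mb_stop("select_wave expects records of a single sample",
            "metaburden_validation_error")
  }
  eligible <- !is.na(x$months_post_exposure) &
    x$months_post_exposure >= min_months
  if (!any(eligible)) {
    mb_stop(sprintf("sample %s has no wave measured >= %g month(s) post exposure",
                    x$sample_id[1], min_months),
            "metaburden_empty_selection")
  }
  e <- x[eligible, , drop = FALSE]
  e[order(-e$prevalence, e$wave, e$months_post_exposure)[1L], , drop = FALSE]
}

#' Apply the questionnaire correction factor to a prevalence
#'
#' Deflates a questionnaire-derived prevalence by the configured factor
#' (default 0.71), used when an entire review rests on self-report
#' instruments, which overestimate PTSD prevalence relative to clinical
#' interview.
#'
#' @param prevalence Proportion(s) in \[0, 1\].
#' @param rules A [screening_rules()] (its `correction_factor` is used),
#'   or a bare numeric factor in (0, 1\].
#' @return The corrected prevalence(s).
#' @export
#' @examples
#' apply_correction(0.21)  # 0.1491, i.e. 0.15 at two decimals
apply_correction <- function(prevalence, rules = screening_rules()) {
  factor <- if (inherits(rules, "screening_rules")) rules$correction_factor
            else rules
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1) {
    mb_stop("correction factor must be in (0, 1]", "metaburden_validation_error")
  }
  if (any(is.na(prevalence)) || any(prevalence < 0) || any(prevalence > 1)) {
    mb_stop("prevalence outside [0, 1]", "metaburden_validation_error")
  }
  prevalence * factor
}

#' Apply the correction factor to every questionnaire record of a corpus
#'
#' Study-level adjustment used before pooling a questionnaire-only corpus.
#' The `corrected` provenance column guards against double application:
#' records already marked corrected are left untouched (the call is a
#' no-op for them). Adjusted prevalences no longer equal `events / n`, so
#' `events` is dropped and within-study variances are recomputed from the
#' adjusted proportion downstream.
#'
#' @param corpus A [study_corpus()].
#' @param rules A [screening_rules()].
#' @return The corpus with questionnaire prevalences multiplied by the
#'   correction factor and `corrected = TRUE`.
#' @export
correct_corpus <- function(corpus, rules = screening_rules()) {
  corpus <- study_corpus(corpus)
  todo <- corpus$method == "questionnaire" & !corpus$corrected
  if (!any(todo)) return(corpus)
  corpus$prevalence[todo] <- apply_correction(corpus$prevalence[todo], rules)
  corpus$events[todo] <- NA_real_
  corpus$corrected[todo] <- TRUE
  corpus
}

#' @export
print.screening_decisions <- function(x, ...) {
  cat(sprintf("Screening decisions: %d records, %d included\n",
              nrow(x), sum(x$included)))
  excl <- x[!x$included, , drop = FALSE]
  if (nrow(excl)) {
    codes <- sort(table(unlist(excl$reasons)), decreasing = TRUE)
    for (nm in names(codes)) cat(sprintf("  %-40s %d\n", nm, codes[[nm]]))
  }
  invisible(x)
}
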