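#' A stratum's prevalence estimate with provenance
#'
#' Holds one exposure group's prevalence point estimate and range,
#' together with how it was derived: pooled from a review (`meta`),
#' pooled from a questionnaire-only review with the 0.71 correction
#' applied upstream (`meta_adjusted`), inherited from another group
#' (`borrow`), averaged from two groups (`average`), or injected as
#' given constants (`fixed`, used for packaged printed values).
#'
#' Displayed values (`point`, `low`, `high`) carry the reporting
#' precision; `rates` keeps full-precision companions used when sizes
#' are multiplied through, so that counts derived from another group
#' propagate that group's unrounded rate rather than its two-decimal
#' display value.
#'
#' @param group_id Stratum identifier.
#' @param point,low,high Prevalence point estimate and range, in \[0, 1\]
#'   with `low <= point <= high`.
#' @param mode One of `"meta"`, `"meta_adjusted"`, `"borrow"`,
#'   `"average"`, `"fixed"`.
#' @param sources Character vector of source group/corpus ids (exactly 1
#'   for `borrow`, exactly 2 for `average`).
#' @param k Pooled-study count for meta modes.
#' @param rates Optional full-precision `c(point, low, high)`; defaults
#'   to the displayed values.
#' @return An object of class `group_estimate`.
#' @export
group_estimate <- function(group_id, point, low, high,
                           mode = c("meta", "meta_adjusted", "borrow",
                                    "average", "fixed"),
                           sources = character(), k = NA_integer_,
                           rates = NULL) {
  mode <- match.arg(mode)
  vals <- c(point = point, low = low, high = high)
  if (any(is.na(vals)) || any(vals < 0) || any(vals > 1)) {
    mb_stop(sprintf("group %s: estimate values must lie in [0, 1]", group_id),
            "metaburden_validation_error")
  }
  if (!(low <= point && point <= high)) {
    mb_stop(sprintf("group %s: need low <= point <= high (got %.4g/%.4g/%.4g)",
                    group_id, low, point, high),
            "metaburden_validation_error")
  }
  if (mode == "borrow" && length(sources) != 1L) {
    mb_stop(sprintf("group %s: borrow mode needs exactly 1 source", group_id),
            "metaburden_validation_error")
  }
  if (mode == "average" && length(sources) != 2L) {
    mb_stop(sprintf("group %s: average mode needs exactly 2 sources", group_id),
            "metaburden_validation_error")
  }
  rates <- rates %||% c(point, low, high)
  if (length(rates) != 3L || any(rates < 0) || any(rates > 1)) {
    mb_stop(sprintf("group %s: rates must be 3 proportions", group_id),
            "metaburden_validation_error")
  }
  structure(list(group_id = group_id, point = point, low = low, high = high,
                 mode = mode, sources = as.character(sources),
                 k = as.integer(k),
                 rates = setNames(as.numeric(rates), c("point", "low", "high"))),
            class = "group_estimate")
}

#' Borrow another group's estimate
#'
#' Used for strata with no usable literature of their own whose exposure
#' most resembles another stratum: the target inherits the source's
#' point, range, and full-precision rates unchanged.
#'
#' @param target_group Target group id.
#' @param source A [group_estimate()].
#' @return A `group_estimate` for the target with `mode = "borrow"`.
#' @export
derive_borrow <- function(target_group, source) {
  if (!inherits(source, "group_estimate")) {
    mb_stop(sprintf("group %s: missing or invalid borrow source", target_group),
            "metaburden_validation_error")
  }
  group_estimate(target_group, source$point, source$low, source$high,
                 mode = "borrow", sources = source$group_id,
                 rates = source$rates)
}

#' Average two groups' estimates
#'
#' For a stratum whose exposure is intermediate between two others: the
#' point estimate is the arithmetic mean of the two points, and the
#' range bounds are the means of the respective bounds. The result is a
#' heuristic range, not a confidence interval — endpoint averaging does
#' not propagate variances; it mirrors the intermediate-exposure
#' reasoning exactly. Full-precision rates are averaged likewise.
#'
#' @param target_group Target group id.
#' @param a,b [group_estimate()] objects.
#' @return A `group_estimate` with `mode = "average"`.
#' @export
#' @examples
#' g4 <- group_estimate("g4", 0.10, 0.03, 0.17, "fixed")
#' g6 <- group_estimate("g6", 0.02, 0.01, 0.03, "fixed")
#' derive_average("g5", g4, g6)  # 0.06, range 0.02-0.10
derive_average <- function(target_group, a, b) {
  if (!inherits(a, "group_estimate") || !inherits(b, "group_estimate")) {
    mb_stop(sprintf("group %s: missing or invalid average sources", target_group),
            "metaburden_validation_error")
  }
  group_estimate(target_group,
                 point = (a$point + b$point) / 2,
                 low = (a$low + b$low) / 2,
                 high = (a$high + b$high) / 2,
                 mode = "average", sources = c(a$group_id, b$group_id),
                 rates = (a$rates + b$rates) / 2)
}

#' Derive all group estimates over a borrow/average DAG
#'
#' Resolves a list of per-group derivation specs in dependency order.
#' Each spec is a list with `id`, `mode`, and, depending on the mode:
#' `corpus` (a [study_corpus()], for `meta`/`meta_adjusted`), `sources`
#' (group ids, for `borrow`/`average`), or `point`/`low`/`high` and
#' optional `rates` (for `fixed`). Borrow/average dependencies must form
#' a DAG; a cycle is reported by name. Resolution is topological, so the
#' listing order of the specs never changes the result.
#'
#' @param specs List of derivation specs.
#' @param rules A [screening_rules()] for meta modes.
#' @param scale,estimator,level Passed to [run_meta()].
#' @return Named list of [group_estimate()] objects (one per spec), in
#'   spec order. Meta results are attached as attribute `meta_results`.
#' @export
derive_groups <- function(specs, rules = screening_rules(), scale = "raw",
                          estimator = "REML", level = 0.95) {
  ids <- vapply(specs, function(s) as.character(s$id), character(1))
  if (anyDuplicated(ids)) {
    mb_stop(paste("duplicate group id:", ids[duplicated(ids)][1]),
            "metaburden_validation_error")
  }
  names(specs) <- ids
  estimates <- list()
  meta_results <- list()

  resolve_one <- function(s) {
    mode <- s$mode
    if (mode %in% c("meta", "meta_adjusted")) {
      res <- run_meta(study_corpus(s$corpus), rules, scale, estimator, level)
      meta_results[[s$id]] <<- res
      if (mode == "meta_adjusted" && !res$adjusted) {
        mb_stop(sprintf(
          "group %s: declared meta_adjusted but corpus is not questionnaire-only",
          s$id), "metaburden_validation_error")
      }
      group_estimate(s$id, round(res$mu_hat, 2), round(res$ci_low, 2),
                     round(res$ci_high, 2),
                     mode = if (res$adjusted) "meta_adjusted" else "meta",
                     sources = s$corpus_id %||% character(), k = res$k,
                     rates = c(res$mu_hat, res$ci_low, res$ci_high))
    } else if (mode == "borrow") {
      derive_borrow(s$id, estimates[[s$sources[[1]]]])
    } else if (mode == "average") {
      derive_average(s$id, estimates[[s$sources[[1]]]],
                     estimates[[s$sources[[2]]]])
    } else if (mode == "fixed") {
      group_estimate(s$id, s$point, s$low, s$high, mode = "fixed",
                     sources = as.character(s$sources %||% character()),
                     rates = s$rates %||% NULL)
    } else {
      mb_stop(paste("unknown derivation mode:", mode),
              "metaburden_validation_error")
    }
  }

  pending <- ids
  while (length(pending)) {
    progressed <- FALSE
    for (id in pending) {
      s <- specs[[id]]
      deps <- if (s$mode %in% c("borrow", "average"))
        as.character(unlist(s$sources)) else character()
      missing_dep <- setdiff(deps, c(names(estimates), ids))
      if (length(missing_dep)) {
        mb_stop(sprintf("group %s: unknown source group '%s'", id,
                        missing_dep[1]), "metaburden_validation_error")
      }
      if (all(deps %in% names(estimates))) {
        s$sources <- deps
        estimates[[id]] <- resolve_one(s)
        pending <- setdiff(pending, id)
        progressed <- TRUE
      }
    }
    if (!progressed) {
      mb_stop(paste("dependency cycle among groups:",
                    paste(sort(pending), collapse = ", ")),
              "metaburden_cycle_error")
    }
  }
  out <- estimates[ids]
  attr(out, "meta_results") <- meta_results
  out
}
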