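#' Read an exposure scenario from YAML or JSON
#'
#' A scenario describes a national projection: `national_population`,
#' optional `interval_kind`, and a list of `groups`. Each group carries
#' `id`, `name`, `raw_size` (omitted for the residual group, which takes
#' whatever remains of the population), optional `reassignments`
#' (`to`, `n`, `already_counted`) moving multifaceted-exposure
#' individuals to their highest-prevalence group, and an `estimate`
#' block naming the derivation mode:
#'
#' * `mode: meta` / `meta_adjusted` — `corpus:` a CSV/JSONL path
#'   (relative to the scenario file) pooled with [run_meta()];
#' * `mode: borrow` — `sources: [id]`;
#' * `mode: average` — `sources: [id, id]`;
#' * `mode: fixed` — `point`, `low`, `high` and either `rates` or
#'   `counts` (`expected`, `lower`, `upper`), from which full-precision
#'   rates are reconstructed as count / resolved size.
#'
#' @param path Scenario file (`.yaml`/`.yml` or `.json`).
#' @return The scenario list, with attribute `dir` for resolving
#'   relative corpus paths.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) mb_stop(paste("scenario file not found:", path))
  scn <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  attr(scn, "dir") <- dirname(normalizePath(path))
  scn
}

#' Path to the packaged Israel October 7th / war scenario
#'
#' The packaged fixture encodes the published six-stratum projection:
#' stratum sizes after exclusions, printed prevalence estimates and
#' ranges, printed expected counts for the review-derived strata, the
#' soldiers' 20,773-person reassignment to higher-prevalence strata, a
#' residual stratum for the indirectly affected, a borrow-derived
#' stratum (close proximity to the attacks inherits the intense rocket
#' exposure estimate) and an averaging note for the moderate rocket
#' exposure stratum.
#'
#' @return Path to the scenario YAML inside the installed package.
#' @export
israel_ptsd_scenario <- function() {
  system.file("extdata", "israel_ptsd_scenario.yaml", package = "metaburden",
              mustWork = TRUE)
}

validate_scenario <- function(scn) {
  if (is.null(scn$groups) || length(scn$groups) == 0L) {
    mb_stop("scenario has no groups", "metaburden_validation_error")
  }
  if (is.null(scn$national_population) || scn$national_population <= 0) {
    mb_stop("scenario needs a positive national_population",
            "metaburden_validation_error")
  }
  for (g in scn$groups) {
    if (is.null(g$id)) mb_stop("every group needs an id",
                               "metaburden_validation_error")
    if (is.null(g$estimate$mode)) {
      mb_stop(sprintf("group %s: estimate block with a mode is required", g$id),
              "metaburden_validation_error")
    }
  }
  invisible(scn)
}

#' Run the full burden-projection model on a scenario
#'
#' Pipeline: resolve mutually exclusive stratum sizes, derive each
#' stratum's prevalence estimate (pooling screened corpora, borrowing,
#' averaging, or injecting fixed values), multiply sizes by
#' full-precision rates, and aggregate national totals. Identical inputs
#' produce identical outputs; when `out_dir` is given, a Table-1-style
#' CSV, a JSON twin with full-precision provenance, per-group
#' meta-analysis JSONs with forest-plot tables, and a screening audit
#' log are written.
#'
#' @param scenario A scenario list or a path readable by
#'   [read_scenario()].
#' @param rules A [screening_rules()].
#' @param scale,estimator Meta-analysis options (see [run_meta()]).
#' @param interval_kind `"ci"` or `"pi"`: which interval the per-group
#'   ranges of meta-derived strata report. Fixed/borrow/average strata
#'   always carry the ranges of their sources.
#' @param out_dir Optional output directory for artifacts.
#' @return A [aggregate_projection()] `model_report` with the per-group
#'   estimates attached as `estimates` and meta results as
#'   `meta_results`.
#' @export
run_model <- function(scenario, rules = screening_rules(),
                      scale = "raw", estimator = "REML",
                      interval_kind = c("ci", "pi"), out_dir = NULL) {
  interval_kind <- match.arg(interval_kind)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  validate_scenario(scenario)
  base_dir <- attr(scenario, "dir") %||% "."

  sizes <- resolve_sizes(scenario$groups, scenario$national_population)
  size_of <- setNames(sizes$resolved_size, sizes$group_id)

  specs <- lapply(scenario$groups, function(g) {
    e <- g$estimate
    s <- list(id = as.character(g$id), mode = e$mode)
    if (e$mode %in% c("meta", "meta_adjusted")) {
      cpath <- e$corpus
      if (!is.null(cpath) && is.character(cpath)) {
        if (!file.exists(cpath)) cpath <- file.path(base_dir, cpath)
        s$corpus <- read_corpus(cpath)
      } else {
        s$corpus <- study_corpus(as.data.frame(e$corpus))
      }
    } else if (e$mode %in% c("borrow", "average")) {
      s$sources <- as.character(unlist(e$sources))
    } else if (e$mode == "fixed") {
      s$point <- e$point
      s$low <- e$low
      s$high <- e$high
      if (!is.null(e$counts)) {
        sz <- size_of[[s$id]]
        if (is.null(sz) || sz <= 0) mb_stop(
          sprintf("group %s: counts-based rates need a positive size", s$id),
          "metaburden_validation_error")
        s$rates <- c(e$counts$expected, e$counts$lower, e$counts$upper) / sz
      } else if (!is.null(e$rates)) {
        s$rates <- as.numeric(unlist(e$rates))
      }
    }
    s
  })

  estimates <- derive_groups(specs, rules, scale, estimator)
  meta_results <- attr(estimates, "meta_results")

  # pi ranges: swap meta-derived groups' rates/bounds for their
  # prediction intervals (points unchanged, ranges wider)
  if (interval_kind == "pi") {
    for (id in names(meta_results)) {
      mr <- meta_results[[id]]
      if (!isTRUE(mr$pi_available)) {
        mb_stop(sprintf(
          "group %s: prediction interval unavailable (k = %d < 3)", id, mr$k),
          "metaburden_validation_error")
      }
      estimates[[id]] <- group_estimate(
        id, estimates[[id]]$point, round(mr$pi_low, 2), round(mr$pi_high, 2),
        mode = estimates[[id]]$mode, sources = estimates[[id]]$sources,
        k = mr$k, rates = c(mr$mu_hat, mr$pi_low, mr$pi_high))
    }
    # re-run borrow/average propagation over the widened sources
    for (s in specs) {
      if (s$mode == "borrow") {
        estimates[[s$id]] <- derive_borrow(s$id, estimates[[s$sources[1]]])
      } else if (s$mode == "average") {
        estimates[[s$id]] <- derive_average(s$id, estimates[[s$sources[1]]],
                                            estimates[[s$sources[2]]])
      }
    }
  }

  names_of <- setNames(
    vapply(scenario$groups, function(g) as.character(g$name %||% g$id),
           character(1)),
    vapply(scenario$groups, function(g) as.character(g$id), character(1)))
  rows <- do.call(rbind, lapply(sizes$group_id, function(id) {
    project_group(size_of[[id]], estimates[[id]], names_of[[id]])
  }))
  report <- aggregate_projection(rows, scenario$national_population,
                                 interval_kind)
  report$estimates <- estimates
  report$meta_results <- meta_results
  report$scenario_name <- scenario$name %||% "scenario"

  if (!is.null(out_dir)) write_model_report(report, out_dir)
  report
}

#' Write a model report's artifacts
#'
#' Emits `report.csv` (Table-1-style columns plus a totals row),
#' `report.json` (full-precision twin with provenance), one
#' `meta_<group>.json` per pooled stratum including the forest-plot
#' table, and `screening_audit.json` with every screening decision.
#' Output is deterministic: ordered keys, fixed number formatting.
#'
#' @param report A `model_report` from [run_model()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- report$rows
  csv <- data.frame(
    group = rows$name, size = rows$size,
    prevalence_range = sprintf("%.2f-%.2f", rows$low, rows$high),
    prevalence_estimate = sprintf("%.2f", rows$point),
    expected_n = rows$expected_n, lower_n = rows$lower_n,
    upper_n = rows$upper_n, stringsAsFactors = FALSE)
  csv <- rbind(csv, data.frame(
    group = "Total", size = sum(rows$size), prevalence_range = "",
    prevalence_estimate = "",
    expected_n = report$total_expected, lower_n = report$total_lower,
    upper_n = report$total_upper))
  write.csv(csv, file.path(dir, "report.csv"), row.names = FALSE)

  js <- list(
    scenario = report$scenario_name,
    interval_kind = report$interval_kind,
    national_population = report$national_population,
    total_expected = report$total_expected,
    total_lower = report$total_lower,
    total_upper = report$total_upper,
    national_pct = report$national_pct,
    pct_low = report$pct_low, pct_high = report$pct_high,
    rows = rows[, c("group_id", "name", "size", "point", "low", "high",
                    "expected_n", "lower_n", "upper_n", "mode")],
    provenance = list(
      pct_unrounded = as.list(report$provenance$pct_unrounded),
      rows_unrounded = rows[, c("group_id", "expected_raw", "lower_raw",
                                "upper_raw")],
      estimates = lapply(report$estimates, function(e) {
        list(group_id = e$group_id, point = e$point, low = e$low,
             high = e$high, mode = e$mode, sources = e$sources,
             k = e$k, rates = as.list(e$rates))
      })
    )
  )
  writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = 10,
                              na = "null", pretty = TRUE),
             file.path(dir, "report.json"))

  for (id in names(report$meta_results %||% list())) {
    mr <- report$meta_results[[id]]
    out <- mr[c("mu_hat", "se", "ci_low", "ci_high", "tau2", "tau", "Q",
                "df", "p_Q", "I2", "k", "pi_low", "pi_high", "pi_available",
                "estimator", "scale", "adjusted")]
    out$forest <- mr$studies
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10,
                                na = "null", pretty = TRUE),
               file.path(dir, paste0("meta_", id, ".json")))
    dec <- mr$decisions
    dec$reasons <- vapply(dec$reasons, paste, character(1), collapse = ";")
    write.csv(mr$studies, file.path(dir, paste0("forest_", id, ".csv")),
              row.names = FALSE)
  }

  audits <- lapply(names(report$meta_results %||% list()), function(id) {
    d <- report$meta_results[[id]]$decisions
    list(group = id, decisions = lapply(seq_len(nrow(d)), function(i) {
      list(study_id = d$study_id[i], sample_id = d$sample_id[i],
           included = d$included[i], reasons = as.list(d$reasons[[i]]))
    }))
  })
  writeLines(jsonlite::toJSON(audits, auto_unbox = TRUE, pretty = TRUE),
             file.path(dir, "screening_audit.json"))
  invisible(dir)
}
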