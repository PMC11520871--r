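#' Round half away from zero
#'
#' Commercial rounding used for person counts and printed percentages;
#' base R's `round()` rounds half to even, which does not reproduce
#' published tables of counts.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Resolve mutually exclusive exposure-group sizes
#'
#' Individuals with multifaceted exposure are counted once, in their
#' highest-prevalence group. Each group starts from a raw head count and
#' may list reassignments moving people out to named higher-prevalence
#' groups; a reassignment marked `already_counted = TRUE` is subtracted
#' from the source but not re-added (the destination's raw size already
#' includes those people — the bookkeeping of independently sourced
#' census figures). One group may be designated `residual`: its size is
#' whatever remains of the national population after all other groups,
#' making the partition exhaustive by construction.
#'
#' @param groups A list; each element has `id`, `raw_size` (may be `NA`
#'   for the residual group), optional `reassignments` (list of
#'   `list(to=, count=, already_counted=)`; `to` may be omitted when the
#'   destination sizes already count the moved people), optional
#'   `residual = TRUE`.
#' @param national_population Total population size.
#' @param estimates Optional named list of [group_estimate()] used to
#'   validate that reassignments point to strictly higher-prevalence
#'   groups.
#' @param strict If `TRUE` a reassignment toward a lower-prevalence
#'   group is an error; otherwise a warning.
#' @return A data frame with `group_id`, `raw_size`, `resolved_size`;
#'   sizes sum exactly to `national_population`.
#' @export
resolve_sizes <- function(groups, national_population, estimates = NULL,
                          strict = FALSE) {
  ids <- vapply(groups, function(g) as.character(g$id), character(1))
  if (anyDuplicated(ids)) {
    mb_stop(paste("duplicate group id:", ids[duplicated(ids)][1]),
            "metaburden_validation_error")
  }
  raw <- vapply(groups, function(g) as.numeric(g$raw_size %||% NA_real_),
                numeric(1))
  residual <- vapply(groups, function(g) isTRUE(g$residual), logical(1))
  if (sum(residual) > 1) mb_stop("at most one residual group allowed",
                                 "metaburden_validation_error")
  out_flow <- setNames(numeric(length(ids)), ids)
  in_flow <- setNames(numeric(length(ids)), ids)
  for (g in groups) {
    for (r in g$reassignments %||% list()) {
      # "count" preferred; "n" accepted from R-built lists (YAML 1.1
      # parses a bare n: key as boolean FALSE, so files must use count)
      n <- as.numeric(r$count %||% r$n %||% NA_real_)
      if (is.na(n) || n < 0) mb_stop(
        sprintf("group %s: invalid reassignment count", g$id),
        "metaburden_validation_error")
      dest <- as.character(r$to %||% NA_character_)
      if (!is.na(dest) && !dest %in% ids) mb_stop(
        sprintf("group %s: reassignment destination '%s' does not exist",
                g$id, dest), "metaburden_validation_error")
      out_flow[[as.character(g$id)]] <- out_flow[[as.character(g$id)]] + n
      if (!is.na(dest) && !isTRUE(r$already_counted)) {
        in_flow[[dest]] <- in_flow[[dest]] + n
      }
      if (!is.null(estimates) && !is.na(dest) &&
          !is.null(estimates[[dest]]) &&
          !is.null(estimates[[as.character(g$id)]])) {
        if (estimates[[dest]]$point <= estimates[[as.character(g$id)]]$point) {
          msg <- sprintf(
            "group %s: reassignment to '%s' does not move people to a higher-prevalence group",
            g$id, dest)
          if (strict) mb_stop(msg, "metaburden_validation_error") else warning(msg)
        }
      }
    }
  }
  resolved <- raw - out_flow + in_flow
  if (any(residual)) {
    resolved[residual] <- national_population - sum(resolved[!residual])
  } else if (!isTRUE(all.equal(sum(resolved), national_population))) {
    mb_stop(sprintf(
      "resolved sizes sum to %.0f, not the national population %.0f, and no residual group is designated",
      sum(resolved), national_population), "metaburden_validation_error")
  }
  if (any(resolved < 0)) {
    i <- which(resolved < 0)[1]
    mb_stop(sprintf("group %s: resolved size is negative (%.0f)",
                    ids[i], resolved[i]), "metaburden_validation_error")
  }
  data.frame(group_id = ids, raw_size = raw, resolved_size = resolved,
             stringsAsFactors = FALSE)
}

#' Project one stratum's expected caseload
#'
#' Multiplies the resolved stratum size by the prevalence estimate's
#' full-precision rates and rounds half-up to whole persons. Unrounded
#' values are kept alongside for aggregation provenance.
#'
#' @param size Resolved stratum size in persons.
#' @param est A [group_estimate()].
#' @param name Optional display name.
#' @return A one-row data frame of class `projection_row`: `group_id`,
#'   `name`, `size`, `point`, `low`, `high`, `expected_n`, `lower_n`,
#'   `upper_n` plus unrounded `expected_raw`, `lower_raw`, `upper_raw`.
#' @export
project_group <- function(size, est, name = est$group_id) {
  if (!inherits(est, "group_estimate")) {
    mb_stop("project_group needs a group_estimate", "metaburden_validation_error")
  }
  if (is.na(size) || size < 0) {
    mb_stop(sprintf("group %s: size must be >= 0", est$group_id),
            "metaburden_validation_error")
  }
  raw <- size * est$rates
  row <- data.frame(
    group_id = est$group_id, name = name, size = size,
    point = est$point, low = est$low, high = est$high,
    expected_n = round_half_up(raw[["point"]]),
    lower_n = round_half_up(raw[["low"]]),
    upper_n = round_half_up(raw[["high"]]),
    expected_raw = raw[["point"]], lower_raw = raw[["low"]],
    upper_raw = raw[["high"]],
    mode = est$mode, stringsAsFactors = FALSE
  )
  class(row) <- c("projection_row", "data.frame")
  row
}

#' Aggregate stratum projections into a national report
#'
#' Totals are the sums of the per-stratum rounded counts (this is how
#' published tables add up), and the national share is the total divided
#' by the national population, presented at one decimal. Rows must cover
#' each group exactly once.
#'
#' @param rows A data frame of [project_group()] rows (rbind-ed).
#' @param national_population National population size.
#' @param interval_kind `"ci"` (confidence-interval ranges) or `"pi"`
#'   (prediction-interval ranges) — recorded provenance of what the
#'   per-group ranges mean.
#' @return An object of class `model_report`: `rows`, `total_expected`,
#'   `total_lower`, `total_upper`, `national_population`, `national_pct`
#'   (1-decimal), `pct_low`, `pct_high`, unrounded percentages in
#'   `provenance`.
#' @export
aggregate_projection <- function(rows, national_population,
                                 interval_kind = c("ci", "pi")) {
  interval_kind <- match.arg(interval_kind)
  if (anyDuplicated(rows$group_id)) {
    mb_stop(paste("duplicate group in projection rows:",
                  rows$group_id[duplicated(rows$group_id)][1]),
            "metaburden_validation_error")
  }
  total_expected <- sum(rows$expected_n)
  total_lower <- sum(rows$lower_n)
  total_upper <- sum(rows$upper_n)
  pct_raw <- 100 * c(total_expected, total_lower, total_upper) /
    national_population
  structure(list(
    rows = rows,
    total_expected = total_expected,
    total_lower = total_lower,
    total_upper = total_upper,
    national_population = national_population,
    national_pct = round_half_up(pct_raw[1], 1),
    pct_low = round_half_up(pct_raw[2], 1),
    pct_high = round_half_up(pct_raw[3], 1),
    interval_kind = interval_kind,
    provenance = list(pct_unrounded = setNames(
      pct_raw, c("expected", "lower", "upper")))
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Population PTSD burden projection\n")
  df <- x$rows[, c("group_id", "size", "low", "high", "point",
                   "expected_n", "lower_n", "upper_n")]
  df$range <- sprintf("%.2f-%.2f", df$low, df$high)
  df$point <- sprintf("%.2f", df$point)
  print(df[, c("group_id", "size", "range", "point",
               "expected_n", "lower_n", "upper_n")], row.names = FALSE)
  cat(sprintf("Total expected %s (range %s-%s) = %.1f%% of %s (%.1f-%.1f%%), %s ranges\n",
              format(x$total_expected, big.mark = ","),
              format(x$total_lower, big.mark = ","),
              format(x$total_upper, big.mark = ","),
              x$national_pct,
              format(x$national_population, big.mark = ","),
              x$pct_low, x$pct_high, x$interval_kind))
  invisible(x)
}
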