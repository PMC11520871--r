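#' Construct and validate a study corpus
#'
#' A study corpus is a data frame in which each row is one prevalence
#' observation extracted from the literature: a study/sample identifier,
#' the number of PTSD cases (`events`) out of `n` participants (or the
#' prevalence proportion directly), and the screening metadata used by the
#' eligibility rules — measurement method, months elapsed since traumatic
#' exposure, point vs. period prevalence, sample provenance, whether PTSD
#' was assessed specifically in relation to the war/terror exposure, the
#' wave index for longitudinal studies, and an optional pointer flagging
#' re-analyses of an existing sample.
#'
#' `prevalence` is filled in as `events / n` when absent; when both are
#' given they must agree to 1e-9. Missing values are allowed for `events`,
#' `months_post_exposure` (unknown timing), and `reanalysis_of`.
#'
#' @param x A data frame with (a subset of) the corpus columns. Missing
#'   metadata columns are added with their defaults (`method`
#'   "clinical", `prevalence_type` "point", `population` "general",
#'   `exposure_specific` "yes", `wave` 1).
#' @return A validated `study_corpus` data frame.
#' @export
#' @examples
#' study_corpus(data.frame(study_id = "s1", events = 32, n = 100))
study_corpus <- function(x) {
  stopifnot(is.data.frame(x))
  if (nrow(x) == 0L) mb_stop("study corpus is empty", "metaburden_validation_error")
  x <- as.data.frame(x, stringsAsFactors = FALSE)

  if (is.null(x$study_id)) mb_stop("study corpus needs a 'study_id' column",
                                   "metaburden_validation_error")
  x$study_id <- as.character(x$study_id)
  x$sample_id <- as.character(x$sample_id %||% x$study_id)
  x$sample_id[is.na(x$sample_id)] <- x$study_id[is.na(x$sample_id)]

  defaults <- list(
    events = NA_real_, n = NA_real_, prevalence = NA_real_,
    method = "clinical", months_post_exposure = NA_real_,
    prevalence_type = "point", population = "general",
    exposure_specific = "yes", wave = 1L, reanalysis_of = NA_character_
  )
  for (col in names(defaults)) {
    if (is.null(x[[col]])) x[[col]] <- defaults[[col]]
  }
  x$events <- as.numeric(x$events)
  x$n <- as.numeric(x$n)
  x$prevalence <- as.numeric(x$prevalence)
  x$months_post_exposure <- as.numeric(x$months_post_exposure)
  x$wave <- as.integer(x$wave)
  x$wave[is.na(x$wave)] <- 1L
  x$reanalysis_of <- as.character(x$reanalysis_of)
  x$reanalysis_of[!is.na(x$reanalysis_of) & x$reanalysis_of == ""] <- NA_character_

  for (col in c("method", "prevalence_type", "population", "exposure_specific")) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][is.na(x[[col]]) | x[[col]] == ""] <-
      if (col %in% c("prevalence_type", "exposure_specific")) "unknown" else defaults[[col]]
  }
  check_enum <- function(col, levels) {
    bad <- !x[[col]] %in% levels
    if (any(bad)) mb_stop(sprintf(
      "record %s: invalid %s '%s' (allowed: %s)",
      x$study_id[bad][1], col, x[[col]][bad][1], paste(levels, collapse = ", ")),
      "metaburden_validation_error")
  }
  check_enum("method", c("clinical", "questionnaire"))
  check_enum("prevalence_type", c("point", "period", "unknown"))
  check_enum("population", c("general", "help_seeking", "clinical_setting"))
  check_enum("exposure_specific", c("yes", "no", "unknown"))

  bad_n <- is.na(x$n) | x$n < 1
  if (any(bad_n)) mb_stop(
    sprintf("record %s/%s: sample size n must be >= 1",
            x$study_id[bad_n][1], x$sample_id[bad_n][1]),
    "metaburden_validation_error")

  fill <- is.na(x$prevalence) & !is.na(x$events)
  x$prevalence[fill] <- x$events[fill] / x$n[fill]
  if (any(is.na(x$prevalence))) {
    i <- which(is.na(x$prevalence))[1]
    mb_stop(sprintf("record %s/%s: needs events or prevalence",
                    x$study_id[i], x$sample_id[i]),
            "metaburden_validation_error")
  }
  bad_p <- x$prevalence < 0 | x$prevalence > 1
  if (any(bad_p)) mb_stop(
    sprintf("record %s/%s: prevalence %.4g outside [0, 1]",
            x$study_id[bad_p][1], x$sample_id[bad_p][1], x$prevalence[bad_p][1]),
    "metaburden_validation_error")
  both <- !is.na(x$events)
  mism <- both & abs(x$prevalence - x$events / x$n) > 1e-9
  if (any(mism)) mb_stop(
    sprintf("record %s/%s: prevalence (%.6g) != events/n (%.6g)",
            x$study_id[mism][1], x$sample_id[mism][1],
            x$prevalence[mism][1], (x$events / x$n)[mism][1]),
    "metaburden_validation_error")
  neg_ev <- both & x$events < 0
  if (any(neg_ev)) mb_stop(
    sprintf("record %s/%s: events must be >= 0", x$study_id[neg_ev][1],
            x$sample_id[neg_ev][1]), "metaburden_validation_error")

  if (is.null(x$corrected)) x$corrected <- FALSE
  x$corrected <- as.logical(x$corrected)
  x$corrected[is.na(x$corrected)] <- FALSE

  rownames(x) <- NULL
  class(x) <- c("study_corpus", "data.frame")
  x
}

corpus_columns <- c(
  "study_id", "sample_id", "events", "n", "prevalence", "method",
  "months_post_exposure", "prevalence_type", "population",
  "exposure_specific", "wave", "reanalysis_of"
)

#' Read a study corpus from CSV or JSON-lines
#'
#' CSV files must carry a header row with the corpus columns; missing
#' values are empty fields. JSON-lines files hold one JSON object per
#' line with `null` for missing values. The format is inferred from the
#' file extension (`.csv` vs `.json`/`.jsonl`/`.ndjson`) unless given.
#'
#' @param path File path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"`.
#' @return A validated [study_corpus()].
#' @export
read_corpus <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(json|jsonl|ndjson)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  if (!file.exists(path)) mb_stop(paste("corpus file not found:", path))
  x <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      rec[vapply(rec, is.null, logical(1))] <- NA
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    all_cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    })
    do.call(rbind, rows)
  }
  study_corpus(x)
}

#' Write a study corpus to CSV or JSON-lines
#'
#' @param corpus A [study_corpus()].
#' @param path Output file path.
#' @param format `"csv"`, `"jsonl"`, or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, format = c("auto", "csv", "jsonl")) {
  corpus <- study_corpus(corpus)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(json|jsonl|ndjson)$", path, ignore.case = TRUE))
      "jsonl" else "csv"
  }
  out <- corpus[intersect(c(corpus_columns, "corrected"), names(corpus))]
  if (format == "csv") {
    write.csv(out, path, row.names = FALSE, na = "")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(out))) {
      rec <- as.list(out[i, ])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
  }
  invisible(path)
}
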