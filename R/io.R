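#' Read a long-format subject table
#'
#' The canonical input is a tidy CSV with header
#' `subject_id,session,test_name,z_score`, one row per administered test;
#' tests a subject skipped are simply absent, so incomplete batteries need
#' no sentinel values. Decimal commas ("-1,48") are accepted and normalised
#' with a warning, matching the continental-European number dialect common
#' in clinical source tables. Implausible z-scores (|z| > 5) trigger a
#' warning but are kept.
#'
#' @param path CSV file path.
#' @param battery Optional [battery()] to validate test names against.
#' @param strict When a battery is given: unknown test names are an error if
#'   `TRUE` (default), a warning otherwise.
#' @return A tibble with columns `subject_id`, `session`, `test_name`,
#'   `z_score`.
#' @export
#' @examples
#' path <- system.file("extdata", "table3_pre.csv", package = "etamu")
#' read_subject_table(path)
read_subject_table <- function(path, battery = NULL, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(c("subject_id", "session", "test_name", "z_score"),
                          names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) abort(paste0(path, ": no data rows"))
  z_chr <- raw$z_score
  comma <- grepl(",", z_chr, fixed = TRUE)
  if (any(comma)) {
    warn(paste0(path, ": normalised ", sum(comma),
                " decimal-comma value(s) (e.g. \"", z_chr[comma][1], "\")"))
    z_chr <- gsub(",", ".", z_chr, fixed = TRUE)
  }
  z <- suppressWarnings(as.numeric(z_chr))
  if (anyNA(z)) {
    bad <- raw$z_score[is.na(z)][1]
    abort(paste0(path, ": malformed z_score value \"", bad, "\""))
  }
  out <- tibble(
    subject_id = raw$subject_id,
    session = raw$session,
    test_name = raw$test_name,
    z_score = z
  )
  out <- .check_subject_table(out)
  if (any(abs(out$z_score) > 5)) {
    flagged <- out[abs(out$z_score) > 5, ]
    warn(paste0(path, ": implausible z-score(s) (|z| > 5): ",
                paste0(flagged$subject_id, "/", flagged$session, "/",
                       flagged$test_name, "=", flagged$z_score,
                       collapse = ", ")))
  }
  if (!is.null(battery)) {
    unknown <- setdiff(unique(out$test_name), battery$name)
    if (length(unknown) > 0) {
      msg <- paste0(path, ": test name(s) not in battery: ",
                    paste(unknown, collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
  }
  out
}

#' @rdname read_subject_table
#' @param data A subject table (long format).
#' @export
write_subject_table <- function(data, path) {
  data <- .check_subject_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a wide-format subject table
#'
#' Convenience reader for sheets with one column per test: columns
#' `subject_id`, `session`, then one numeric column per test name. Converted
#' internally to the long layout; empty cells mean the test was not
#' administered.
#'
#' @inheritParams read_subject_table
#' @return A long-format tibble, as [read_subject_table()].
#' @export
read_wide_subject_table <- function(path, battery = NULL, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("subject_id", "session") %in% names(raw))) {
    abort(paste0(path, ": wide table needs subject_id and session columns"))
  }
  long <- tidyr::pivot_longer(raw, -c("subject_id", "session"),
                              names_to = "test_name", values_to = "z_score")
  long <- long[!is.na(long$z_score) & nzchar(long$z_score), ]
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(long, tmp, progress = FALSE)
  read_subject_table(tmp, battery = battery, strict = strict)
}

#' Build a full analysis report
#'
#' Runs the whole pipeline on a subject table: per-session scores, a cohort
#' summary (when at least two sessions are present), pre/post comparisons
#' (when both session labels are present), the balanced-model reference
#' lines for plotting, and provenance (battery label, tolerance, package
#' version, warnings emitted along the way).
#'
#' @param data Long subject table.
#' @param battery An [battery()] object.
#' @param tolerance Balanced-band half-width.
#' @param pre,post Session labels to compare when both are present.
#' @return A list of class `etamu_report` with elements `scores`, `cohort`,
#'   `comparisons`, `model_lines`, `provenance`.
#' @export
etamu_report <- function(data, battery = default_battery(), tolerance = 2,
                         pre = "pre", post = "post") {
  warnings_seen <- character()
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  data <- .check_subject_table(data)
  scores <- collect(score_sessions(data, battery, tolerance))
  cohort <- if (nrow(scores) >= 2) cohort_summary(scores) else NULL
  comparisons <- NULL
  if (all(c(pre, post) %in% unique(data$session))) {
    comparisons <- collect(
      compare_sessions(data, battery, pre = pre, post = post,
                       tolerance = tolerance)
    )
  }
  lines <- model_lines(seq(min(c(scores$avg_z, 0)) - 0.5, 0, by = 0.1),
                       battery)
  structure(
    list(
      scores = scores,
      cohort = cohort,
      comparisons = comparisons,
      model_lines = lines,
      provenance = list(
        battery_label = attr(battery, "label") %||% "unnamed",
        tolerance = tolerance,
        package_version = as.character(packageVersion("etamu")),
        warnings = warnings_seen
      )
    ),
    class = "etamu_report"
  )
}

#' Write a report to disk
#'
#' Emits the machine-readable JSON and a human-readable markdown rendering
#' side by side; numbers in the markdown are printed at 2 decimals.
#'
#' @param report An [etamu_report()] object.
#' @param stem Output path stem; `<stem>.json` and `<stem>.md` are written.
#' @return The two paths, invisibly.
#' @export
write_report <- function(report, stem) {
  stopifnot(inherits(report, "etamu_report"))
  json_path <- paste0(stem, ".json")
  md_path <- paste0(stem, ".md")
  payload <- list(
    scores = report$scores,
    cohort = report$cohort,
    comparisons = report$comparisons,
    model_lines = report$model_lines,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null", pretty = TRUE)
  writeLines(.report_markdown(report), md_path)
  invisible(c(json = json_path, md = md_path))
}

.fmt <- function(x) ifelse(is.na(x), "-", sprintf("%.2f", x))

.md_table <- function(df) {
  cells <- vapply(df, function(col) {
    if (is.numeric(col)) .fmt(col) else as.character(col)
  }, character(nrow(df)))
  cells <- matrix(cells, nrow = nrow(df))
  c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
}

.report_markdown <- function(report) {
  pv <- report$provenance
  out <- c(
    "# Eta-Mu analysis report",
    "",
    paste0("Battery: ", pv$battery_label,
           "; tolerance: ", pv$tolerance,
           "; etamu ", pv$package_version),
    "",
    "## Session scores",
    "",
    .md_table(report$scores[, c("subject_id", "session", "n_tests", "avg_z",
                                "eta", "mu", "eta_exp", "mu_exp",
                                "delta_eta", "delta_mu", "classification")])
  )
  if (!is.null(report$cohort)) {
    out <- c(out, "", "## Cohort summary", "", .md_table(report$cohort))
  }
  if (!is.null(report$comparisons)) {
    out <- c(out, "", "## Pre/post comparison", "",
             .md_table(report$comparisons[, c("subject_id", "n_paired",
                                              "avg_z_change",
                                              "eta_improvement",
                                              "mu_improvement", "paired_p")]))
  }
  if (length(pv$warnings) > 0) {
    out <- c(out, "", "## Warnings", "", paste0("- ", pv$warnings))
  }
  out
}
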