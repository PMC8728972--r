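## Canonical long-format column order. One row per subject x visit.
.biomarkers <- c("hb", "hct", "fbs", "rbc")
.cohort_cols <- c("subject_id", "visit", "group",
                  "hb", "hct", "fbs", "rbc",
                  "age", "bmi", "sbp", "dbp",
                  "parity", "education")
.numeric_cols <- c("visit", "group", .biomarkers,
                   "age", "bmi", "sbp", "dbp", "parity")

#' Biomarker names used throughout the package
#'
#' The four longitudinal biomarkers, in the canonical stacking order:
#' hemoglobin (`hb`, g/dL), hematocrit (`hct`, %), fasting blood sugar
#' (`fbs`, mg/dL) and red blood cell count (`rbc`, x10^12/L).
#'
#' @return Character vector of length four.
#' @export
biomarker_names <- function() .biomarkers

#' Construct a validated cohort table
#'
#' A cohort table is a long-format `data.frame` with one row per
#' subject x visit: columns `subject_id`, `visit` (1 = first trimester,
#' 2 = early second trimester), `group` (1 = non-GDM, 2 = GDM), the four
#' biomarkers `hb` (g/dL), `hct` (%), `fbs` (mg/dL), `rbc` (x10^12/L),
#' the covariates `age` (years), `bmi` (kg/m^2), `sbp`/`dbp` (mmHg, both
#' visit-specific), `parity` (0-3) and `education`
#' ("non-academic"/"academic").
#'
#' Rows are reordered to (subject, visit) and the invariants are checked:
#' every subject has exactly one row per visit, `group` is constant within
#' subject, and all biomarker values are strictly positive.
#'
#' @param df A data.frame holding the columns above.
#' @return The validated table, classed `"cohort_table"`, rows ordered by
#'   (subject, visit).
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df)
  missing <- setdiff(.cohort_cols, names(df))
  if (length(missing) > 0L)
    stop("cohort table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[, .cohort_cols]
  for (cl in .numeric_cols) {
    if (!is.numeric(df[[cl]])) {
      suppressWarnings(v <- as.numeric(df[[cl]]))
      bad <- which(is.na(v) & !is.na(df[[cl]]))
      if (length(bad) > 0L)
        stop("non-numeric value in column '", cl, "' at row(s) ",
             paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
      df[[cl]] <- v
    }
    df[[cl]] <- as.double(df[[cl]])  # type-stable CSV round trips
  }
  df$subject_id <- as.character(df$subject_id)
  df$education <- as.character(df$education)
  df <- df[order(df$subject_id, df$visit), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  rep <- validate_cohort(df)
  if (nrow(rep) > 0L)
    stop("invalid cohort table:\n", paste(format_validation(rep), collapse = "\n"),
         call. = FALSE)
  df
}

#' Validate a cohort table
#'
#' Checks the cohort invariants and returns a report of violations; an
#' empty report means the table is valid. Unlike [cohort_table()] this
#' never throws on rule violations, so it can be used to triage raw input.
#'
#' @param table A data.frame with the cohort columns (classed or not).
#' @return A data.frame with columns `rule`, `subject_id`, `detail`;
#'   zero rows when the table is valid.
#' @export
validate_cohort <- function(table) {
  out <- list()
  add <- function(rule, subject_id, detail)
    out[[length(out) + 1L]] <<- data.frame(rule = rule,
                                           subject_id = as.character(subject_id),
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  df <- as.data.frame(table)
  missing <- setdiff(.cohort_cols, names(df))
  if (length(missing) > 0L) {
    add("missing-column", NA_character_, paste(missing, collapse = ", "))
    return(do.call(rbind, out))
  }
  sid <- as.character(df$subject_id)
  n_v1 <- tapply(df$visit == 1, sid, sum)
  n_v2 <- tapply(df$visit == 2, sid, sum)
  incomplete <- names(n_v1)[n_v1 != 1L | n_v2 != 1L]
  for (s in incomplete)
    add("incomplete-visits", s,
        paste0("visits observed: {",
               paste(sort(df$visit[sid == s]), collapse = ","), "}"))
  g_rng <- tapply(df$group, sid, function(x) length(unique(x)))
  for (s in names(g_rng)[g_rng > 1L])
    add("group-not-constant", s,
        paste0("groups: {", paste(df$group[sid == s], collapse = ","), "}"))
  bad_group <- !df$group %in% c(1, 2)
  if (any(bad_group, na.rm = TRUE))
    add("bad-group-code", paste(unique(sid[which(bad_group)]), collapse = ","),
        "group must be 1 (non-GDM) or 2 (GDM)")
  bad_visit <- !df$visit %in% c(1, 2)
  if (any(bad_visit, na.rm = TRUE))
    add("bad-visit-code", paste(unique(sid[which(bad_visit)]), collapse = ","),
        "visit must be 1 or 2")
  for (m in .biomarkers) {
    v <- df[[m]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad) > 0L)
      add("non-positive-biomarker", paste(unique(sid[bad]), collapse = ","),
          paste0("column '", m, "' must be finite and > 0"))
  }
  if (length(out) == 0L)
    return(data.frame(rule = character(), subject_id = character(),
                      detail = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

format_validation <- function(rep) {
  sprintf("  [%s] subject(s) %s: %s", rep$rule, rep$subject_id, rep$detail)
}

#' Read a cohort CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, '.' decimal separator) into a validated
#' [cohort_table()]. Column names can be remapped through `dialect`, either
#' a named character vector `c(canonical = "file_column", ...)` or the path
#' to a YAML/JSON file holding such a map.
#'
#' @param path Path to the CSV file.
#' @param dialect Optional column-name map (named character vector or
#'   YAML/JSON file path).
#' @param incomplete How to treat subjects without both visits:
#'   `"error"` (default) fails listing the subjects, `"drop"` removes them
#'   with a message giving the count.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, dialect = NULL, incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    map <- read_dialect(dialect)
    for (canonical in names(map)) {
      src <- map[[canonical]]
      if (!src %in% names(df))
        stop("dialect maps '", canonical, "' to missing column '", src, "'",
             call. = FALSE)
      names(df)[names(df) == src] <- canonical
    }
  }
  missing <- setdiff(.cohort_cols, names(df))
  if (length(missing) > 0L)
    stop("cohort CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (incomplete == "drop") {
    tab <- table(df$subject_id)
    keep <- names(tab)[tab == 2L]
    dropped <- setdiff(names(tab), keep)
    if (length(dropped) > 0L) {
      message("dropping ", length(dropped),
              " subject(s) without both visits (complete-case policy)")
      df <- df[df$subject_id %in% keep, , drop = FALSE]
    }
  }
  cohort_table(df)
}

read_dialect <- function(dialect) {
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    if (grepl("\\.ya?ml$", dialect)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading a YAML dialect requires the 'yaml' package", call. = FALSE)
      return(unlist(yaml::read_yaml(dialect)))
    }
    return(unlist(jsonlite::read_json(dialect, simplifyVector = TRUE)))
  }
  if (is.null(names(dialect)) || any(names(dialect) == ""))
    stop("dialect must be a named character vector or a YAML/JSON file",
         call. = FALSE)
  unlist(dialect)
}

#' Write a cohort table to CSV
#'
#' Columns are written in the canonical order (subject_id, visit, group,
#' hb, hct, fbs, rbc, age, bmi, sbp, dbp, parity, education). Numeric
#' values are rendered with 17 significant digits so that
#' `read_cohort(write_cohort(x))` reproduces every double bit-exactly.
#'
#' @param table A `cohort_table` (or a data.frame accepted by
#'   [cohort_table()]; an empty table writes a header-only CSV).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  df <- as.data.frame(table)
  if (nrow(df) > 0L) df <- as.data.frame(cohort_table(df))
  else {
    for (cl in setdiff(.cohort_cols, names(df))) df[[cl]] <- character()
    df <- df[, .cohort_cols]
  }
  out <- df
  if (nrow(out) > 0L)
    for (cl in .numeric_cols) out[[cl]] <- sprintf("%.17g", df[[cl]])
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE,
                     quote = which(names(out) %in% c("subject_id", "education"))),
    error = function(e) stop("cannot write '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- length(unique(x$subject_id))
  ngdm <- length(unique(x$subject_id[x$group == 2]))
  cat(sprintf("Cohort: %d subjects (%d GDM, %d non-GDM), %d rows\n",
              n, ngdm, n - ngdm, nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
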