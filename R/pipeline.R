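classification_metrics <- function(cls, level = 0.95,
                                   ci_method = "delong", seed = 1L) {
  priors <- attr(cls, "priors")
  if (is.null(priors)) {
    pi2 <- mean(cls$group == 2)
    priors <- c(1 - pi2, pi2)
  }
  thr <- log(priors[2] / priors[1])
  bayes <- sens_spec_at(cls$score, cls$group, thr)
  yd <- youden_point(cls$score, cls$group)
  ci <- auc_ci(cls$score, cls$group, level = level, method = ci_method,
               seed = seed)
  roc <- roc_curve(cls$score, cls$group)
  list(auc = ci$auc, auc_lower = ci$lower, auc_upper = ci$upper,
       ci_level = level, ci_method = ci_method,
       sens_bayes = bayes$sens, spec_bayes = bayes$spec,
       bayes_threshold = thr,
       sens_youden = yd$sens, spec_youden = yd$spec,
       youden_threshold = yd$threshold,
       provenance = attr(cls, "provenance"),
       roc_points = roc$points)
}

#' Univariate longitudinal classification of one biomarker
#'
#' Runs the univariate strategy for a single biomarker: fits the q = 2
#' single-marker mixed model on both visits, classifies every subject
#' with the discriminant rule, and evaluates sensitivity, specificity
#' and AUC (with CI). Reported operating points: "bayes" (threshold
#' log(pi2/pi1)) and "youden".
#'
#' @param table A `cohort_table`.
#' @param marker One of `biomarker_names()`.
#' @param covariates Covariates of the mean model.
#' @param folds `NULL` for resubstitution only, or a fold count for
#'   additional stratified cross-validation.
#' @param level,ci_method,seed CI level, `"delong"`/`"bootstrap"`, seed
#'   for any resampling and for the CV fold assignment.
#' @return List with `marker`, `fit`, `resubstitution` metrics and,
#'   when requested, `cv` metrics.
#' @export
run_univariate <- function(table, marker, covariates = c("age", "bmi", "sbp", "dbp"),
                           folds = NULL, level = 0.95,
                           ci_method = "delong", seed = 1L) {
  spec <- model_spec(markers = marker, covariates = covariates)
  fit <- mlmm_fit(table, spec)
  cls <- classify_cohort(fit, table)
  out <- list(marker = marker, fit = fit,
              resubstitution = classification_metrics(cls, level, ci_method, seed))
  if (!is.null(folds)) {
    cv <- cross_validate(table, spec, folds = folds, seed = seed)
    out$cv <- classification_metrics(cv, level, ci_method, seed)
  }
  out
}

#' Multivariate longitudinal classification of the full biomarker panel
#'
#' The multivariate strategy: all four biomarkers at both visits enter a
#' single q = 8 mixed model, and each subject's stacked 8-vector is
#' scored by the discriminant rule.
#'
#' @inheritParams run_univariate
#' @param markers The biomarkers to pool (default all four).
#' @return List with `fit`, `resubstitution` metrics and optional `cv`.
#' @export
run_multivariate <- function(table, markers = biomarker_names(),
                             covariates = c("age", "bmi", "sbp", "dbp"),
                             folds = NULL, level = 0.95,
                             ci_method = "delong", seed = 1L) {
  spec <- model_spec(markers = markers, covariates = covariates)
  fit <- mlmm_fit(table, spec)
  cls <- classify_cohort(fit, table)
  out <- list(markers = markers, fit = fit,
              resubstitution = classification_metrics(cls, level, ci_method, seed))
  if (!is.null(folds)) {
    cv <- cross_validate(table, spec, folds = folds, seed = seed)
    out$cv <- classification_metrics(cv, level, ci_method, seed)
  }
  out
}

#' Assemble a study configuration
#'
#' @param params Generator parameters ([default_cohort_params()] by
#'   default); ignored when `cohort_csv` is given.
#' @param cohort_csv Optional path to a cohort CSV to analyse instead of
#'   simulating.
#' @param seed Master seed: drives the simulation, fold assignment and
#'   any bootstrap.
#' @param markers Biomarkers to analyse.
#' @param covariates Mean-model covariates.
#' @param folds `NULL` (resubstitution only) or a CV fold count.
#' @param level,ci_method AUC confidence-interval settings.
#' @return List of class `"study_config"`.
#' @export
study_config <- function(params = default_cohort_params(), cohort_csv = NULL,
                         seed = 1L, markers = biomarker_names(),
                         covariates = c("age", "bmi", "sbp", "dbp"),
                         folds = NULL, level = 0.95,
                         ci_method = c("delong", "bootstrap")) {
  structure(list(params = params, cohort_csv = cohort_csv,
                 seed = as.integer(seed), markers = markers,
                 covariates = covariates, folds = folds, level = level,
                 ci_method = match.arg(ci_method)),
            class = "study_config")
}

config_hash <- function(config) {
  canon <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                            force = TRUE, null = "null")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canon, f)
  unname(tools::md5sum(f))
}

#' Run the full study pipeline
#'
#' End-to-end analysis: obtain the cohort (simulate from `params` or
#' read `cohort_csv`), compute group descriptives, run each biomarker's
#' univariate strategy and the multivariate strategy, and assemble a
#' report with a per-marker grid of sensitivity / specificity / AUC / CI
#' for every validation mode, the ROC point sets, and a provenance block
#' (config hash, seed, package version). Fully deterministic given the
#' configuration.
#'
#' @param config A [study_config()].
#' @return List of class `"study_report"`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  table <- if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
  else generate_cohort(config$params, seed = config$seed)
  n <- length(unique(table$subject_id))
  n_gdm <- length(unique(table$subject_id[table$group == 2]))

  desc <- describe_by_group(table)

  runs <- lapply(config$markers, function(m)
    run_univariate(table, m, covariates = config$covariates,
                   folds = config$folds, level = config$level,
                   ci_method = config$ci_method, seed = config$seed))
  names(runs) <- config$markers
  multi <- run_multivariate(table, markers = config$markers,
                            covariates = config$covariates,
                            folds = config$folds, level = config$level,
                            ci_method = config$ci_method, seed = config$seed)

  grid_row <- function(name, metrics, mode) {
    data.frame(marker = name, mode = mode,
               sens_bayes = metrics$sens_bayes, spec_bayes = metrics$spec_bayes,
               sens_youden = metrics$sens_youden,
               spec_youden = metrics$spec_youden,
               auc = metrics$auc, auc_lower = metrics$auc_lower,
               auc_upper = metrics$auc_upper, stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, c(
    lapply(config$markers, function(m)
      grid_row(m, runs[[m]]$resubstitution, "resubstitution")),
    list(grid_row("multivariate", multi$resubstitution, "resubstitution")),
    if (!is.null(config$folds)) c(
      lapply(config$markers, function(m)
        grid_row(m, runs[[m]]$cv, "cross-validated")),
      list(grid_row("multivariate", multi$cv, "cross-validated")))))
  rownames(grid) <- NULL

  roc_points <- c(lapply(runs, function(r) r$resubstitution$roc_points),
                  list(multivariate = multi$resubstitution$roc_points))

  structure(list(
    provenance = list(
      package = "gdmpanel",
      version = as.character(utils::packageVersion("gdmpanel")),
      config_hash = config_hash(config),
      seed = config$seed,
      n_subjects = n, n_gdm = n_gdm,
      source = if (is.null(config$cohort_csv)) "simulated" else "csv"),
    descriptives = desc,
    performance = grid,
    roc_points = roc_points),
    class = "study_report")
}

round_half_up <- function(x) floor(x + 0.5)

#' Write a study report to disk
#'
#' Serializes the report as full-precision JSON plus a human-readable
#' Markdown summary whose percentages are rendered as integers
#' (round-half-up). Identical reports produce byte-identical files.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "study_report.json")
  md_path <- file.path(dir, "study_report.md")
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, dataframe = "columns",
                           force = TRUE, null = "null")
  writeLines(json, json_path)

  g <- report$performance
  lines <- c(
    "# Study report",
    "",
    sprintf("- package: %s %s", report$provenance$package,
            report$provenance$version),
    sprintf("- config hash: %s", report$provenance$config_hash),
    sprintf("- seed: %d", report$provenance$seed),
    sprintf("- cohort: %d subjects (%d GDM)", report$provenance$n_subjects,
            report$provenance$n_gdm),
    "",
    "## Predictive performance (percent, rounded)",
    "",
    "| Marker | Mode | Sens (Bayes) | Spec (Bayes) | Sens (Youden) | Spec (Youden) | AUC | 95% CI |",
    "|---|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %d | %d | %d | %d | %d | %d-%d |",
            g$marker, g$mode,
            round_half_up(100 * g$sens_bayes),
            round_half_up(100 * g$spec_bayes),
            round_half_up(100 * g$sens_youden),
            round_half_up(100 * g$spec_youden),
            round_half_up(100 * g$auc),
            round_half_up(100 * g$auc_lower),
            round_half_up(100 * g$auc_upper)))
  writeLines(lines, md_path)
  invisible(c(json = json_path, markdown = md_path))
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (", x$provenance$source, " cohort, n = ",
      x$provenance$n_subjects, ", GDM = ", x$provenance$n_gdm, ")\n\n",
      sep = "")
  g <- x$performance
  show <- data.frame(marker = g$marker, mode = g$mode,
                     sens = round_half_up(100 * g$sens_youden),
                     spec = round_half_up(100 * g$spec_youden),
                     auc = round_half_up(100 * g$auc),
                     ci = sprintf("%d-%d", round_half_up(100 * g$auc_lower),
                                  round_half_up(100 * g$auc_upper)))
  print(show, row.names = FALSE)
  invisible(x)
}
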