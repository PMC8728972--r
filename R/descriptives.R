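#' Independent-samples t-test from group summaries
#'
#' Two-sided t-test computed directly from per-group mean, SD and n, as
#' needed when only published summaries are available. The pooled variant
#' uses the pooled variance with `n1 + n2 - 2` degrees of freedom; the
#' Welch variant uses the Satterthwaite approximation.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (s1 <= 0 || s2 <= 0) stop("SDs must be > 0", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (m1 - m2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic without continuity correction by default (a Yates
#' correction is available for 2x2 tables), df = (r-1)(c-1).
#'
#' @param counts r x c matrix of non-negative counts (at least 2x2).
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return List with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate table: a zero row or column marginal", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Two-way mixed-design repeated-measures ANOVA
#'
#' Between factor = GDM group, within factor = visit (two levels each
#' possible for the group factor with two groups; any number of groups is
#' supported). Implemented from its sums-of-squares decomposition: the
#' between-subject stratum partitions subject means into group and
#' subject-within-group terms; the within-subject stratum partitions the
#' normalized visit difference `w_i = (y_i2 - y_i1)/sqrt(2)` into time,
#' group x time and residual terms. With only two visit levels no
#' sphericity correction is needed.
#'
#' @param table Cohort table (complete two-visit data).
#' @param marker Biomarker column to analyse.
#' @return List with the three F tests: `p_interaction`, `p_group`,
#'   `p_time`, plus `F_group`, `F_time`, `F_interaction` and their
#'   degrees of freedom.
#' @export
mixed_anova <- function(table, marker) {
  df <- as.data.frame(table)
  stopifnot(marker %in% names(df))
  df <- df[order(df$subject_id, df$visit), ]
  v1 <- df[df$visit == 1, ]; v2 <- df[df$visit == 2, ]
  if (!identical(v1$subject_id, v2$subject_id))
    stop("complete two-visit data required", call. = FALSE)
  g <- factor(v1$group)
  if (any(table(g) < 2))
    stop("each group needs at least 2 subjects", call. = FALSE)
  y1 <- v1[[marker]]; y2 <- v2[[marker]]
  n <- length(y1); G <- nlevels(g)
  grand <- mean(c(y1, y2))

  ## between-subject stratum (subject means, weight t = 2)
  m_i <- (y1 + y2) / 2
  m_g <- tapply(m_i, g, mean)
  n_g <- as.vector(table(g))
  ss_group <- 2 * sum(n_g * (m_g - grand)^2)
  ss_subj <- 2 * sum((m_i - m_g[g])^2)
  df_group <- G - 1; df_subj <- n - G
  F_group <- (ss_group / df_group) / (ss_subj / df_subj)

  ## within-subject stratum (normalized visit contrast)
  w <- (y2 - y1) / sqrt(2)
  w_g <- tapply(w, g, mean)
  ss_time <- n * mean(w)^2
  ss_int <- sum(n_g * (w_g - mean(w))^2)
  ss_err <- sum((w - w_g[g])^2)
  df_err <- n - G
  F_time <- ss_time / (ss_err / df_err)
  F_int <- (ss_int / df_group) / (ss_err / df_err)

  list(F_group = F_group, df_group = c(df_group, df_subj),
       p_group = stats::pf(F_group, df_group, df_subj, lower.tail = FALSE),
       F_time = F_time, df_time = c(1, df_err),
       p_time = stats::pf(F_time, 1, df_err, lower.tail = FALSE),
       F_interaction = F_int, df_interaction = c(df_group, df_err),
       p_interaction = stats::pf(F_int, df_group, df_err, lower.tail = FALSE),
       ss = c(group = ss_group, subject = ss_subj, time = ss_time,
              interaction = ss_int, error_within = ss_err))
}

#' Group-comparison summary of a cohort
#'
#' Builds the familiar two-table summary of a two-group cohort:
#' demographics/covariates with per-group mean (SD) or counts and the
#' matching test (pooled t for continuous, Pearson chi-square for
#' categorical), and biomarker trends with per group x visit mean (SD)
#' and the mixed-ANOVA group and interaction p-values. With a single
#' group all tests are `NA`.
#'
#' @param table A `cohort_table`.
#' @return List of class `"group_summary"` with data.frames
#'   `covariates`, `categorical` and `biomarkers`.
#' @export
describe_by_group <- function(table) {
  df <- as.data.frame(table)
  v1 <- df[df$visit == 1, ]; v2 <- df[df$visit == 2, ]
  two_groups <- length(unique(df$group)) == 2
  grp <- function(d, col, g) d[[col]][d$group == g]

  cont_row <- function(name, d, col) {
    x1 <- grp(d, col, 1); x2 <- grp(d, col, 2)
    p <- if (two_groups && length(x1) >= 2 && length(x2) >= 2)
      t_test_summary(mean(x1), stats::sd(x1), length(x1),
                     mean(x2), stats::sd(x2), length(x2))$p else NA_real_
    data.frame(variable = name,
               non_gdm_mean = mean(x1), non_gdm_sd = stats::sd(x1),
               gdm_mean = if (length(x2)) mean(x2) else NA_real_,
               gdm_sd = if (length(x2) >= 2) stats::sd(x2) else NA_real_,
               p = p, stringsAsFactors = FALSE)
  }
  covariates <- rbind(
    cont_row("age", v1, "age"),
    cont_row("bmi.visit1", v1, "bmi"), cont_row("bmi.visit2", v2, "bmi"),
    cont_row("sbp.visit1", v1, "sbp"), cont_row("sbp.visit2", v2, "sbp"),
    cont_row("dbp.visit1", v1, "dbp"), cont_row("dbp.visit2", v2, "dbp"))

  cat_row <- function(name, col, levels) {
    x <- factor(v1[[col]], levels = levels)
    tab <- table(x, factor(v1$group, levels = 1:2))
    p <- if (two_groups && all(rowSums(tab) > 0))
      tryCatch(chi_square_test(tab)$p, error = function(e) NA_real_)
    else NA_real_
    data.frame(variable = name,
               category = levels,
               non_gdm_n = as.vector(tab[, 1]),
               gdm_n = as.vector(tab[, 2]),
               p = c(p, rep(NA_real_, length(levels) - 1L)),
               stringsAsFactors = FALSE)
  }
  categorical <- rbind(
    cat_row("parity", "parity", as.character(0:3)),
    cat_row("education", "education", c("non-academic", "academic")))

  bio <- do.call(rbind, lapply(.biomarkers, function(m) {
    an <- if (two_groups) mixed_anova(df, m)
    else list(p_group = NA_real_, p_interaction = NA_real_)
    data.frame(
      marker = m, visit = 1:2,
      non_gdm_mean = c(mean(grp(v1, m, 1)), mean(grp(v2, m, 1))),
      non_gdm_sd = c(stats::sd(grp(v1, m, 1)), stats::sd(grp(v2, m, 1))),
      gdm_mean = if (two_groups) c(mean(grp(v1, m, 2)), mean(grp(v2, m, 2)))
      else NA_real_,
      gdm_sd = if (two_groups) c(stats::sd(grp(v1, m, 2)),
                                 stats::sd(grp(v2, m, 2))) else NA_real_,
      p_group = c(an$p_group, NA_real_),
      p_interaction = c(an$p_interaction, NA_real_),
      stringsAsFactors = FALSE)
  }))
  structure(list(covariates = covariates, categorical = categorical,
                 biomarkers = bio),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, digits = 3, ...) {
  cat("Covariates by group:\n")
  print(format(x$covariates, digits = digits), row.names = FALSE)
  cat("\nCategorical covariates by group:\n")
  print(format(x$categorical, digits = digits), row.names = FALSE)
  cat("\nBiomarker trends by group (mixed-design repeated-measures ANOVA):\n")
  print(format(x$biomarkers, digits = digits), row.names = FALSE)
  invisible(x)
}
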