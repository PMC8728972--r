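.groups <- c("non-GDM", "GDM")
.visits <- c("1", "2")

#' Construct generator parameters for a synthetic cohort
#'
#' Bundles everything the class-conditional cohort generator needs:
#' cohort size, GDM prevalence, per (biomarker, group, visit) means and
#' SDs, the between-biomarker correlation matrix (same visit), the
#' within-biomarker correlation between the two visits, and covariate
#' distributions. The implied 8x8 per-group biomarker covariance is the
#' Kronecker product of the cross-marker and the 2x2 visit correlation,
#' scaled by the group/visit SDs, and must be positive definite.
#'
#' @param n_subjects Number of subjects.
#' @param prevalence Probability that a subject is GDM (0 < p < 1 unless
#'   exactly 0 or 1 is requested for degenerate simulations).
#' @param marker_means,marker_sds Numeric arrays `[marker, group, visit]`
#'   with dimnames `biomarker_names()` x `c("non-GDM","GDM")` x
#'   `c("1","2")`; units are the biomarker's own units.
#' @param cross_marker_corr 4x4 correlation matrix between biomarkers at
#'   the same visit (unit diagonal, symmetric positive definite).
#' @param within_marker_corr Correlation between visit-1 and visit-2
#'   values of the same biomarker, |r| < 1.
#' @param covariate_params List with elements `age` (per-group mean/sd),
#'   `bmi`, `sbp`, `dbp` (per group x visit mean/sd arrays),
#'   `covariate_visit_corr` (within-subject correlation of the
#'   visit-specific covariates), `parity_probs` (per-group probabilities
#'   over parity 0-3) and `academic_prob` (per-group probability of
#'   academic education).
#' @param seed Default RNG seed used by [generate_cohort()] when none is
#'   passed.
#' @return An object of class `"cohort_params"`.
#' @seealso [default_cohort_params()] for the calibrated defaults.
#' @export
cohort_params <- function(n_subjects, prevalence, marker_means, marker_sds,
                          cross_marker_corr, within_marker_corr,
                          covariate_params, seed = 1L) {
  stopifnot(n_subjects >= 1, prevalence >= 0, prevalence <= 1)
  dn <- list(.biomarkers, .groups, .visits)
  check_arr <- function(a, what) {
    if (!is.array(a) || !identical(dim(a), c(4L, 2L, 2L)))
      stop(what, " must be a 4x2x2 array [marker, group, visit]", call. = FALSE)
    dimnames(a) <- dn
    a
  }
  marker_means <- check_arr(marker_means, "marker_means")
  marker_sds <- check_arr(marker_sds, "marker_sds")
  if (any(marker_sds <= 0)) stop("all marker SDs must be > 0", call. = FALSE)
  R <- as.matrix(cross_marker_corr)
  if (!isSymmetric(unname(R), tol = 1e-8) || any(abs(diag(R) - 1) > 1e-12))
    stop("cross_marker_corr must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("cross_marker_corr must be positive definite", call. = FALSE)
  if (abs(within_marker_corr) >= 1)
    stop("|within_marker_corr| must be < 1", call. = FALSE)
  p <- structure(list(n_subjects = as.integer(n_subjects),
                      prevalence = prevalence,
                      marker_means = marker_means, marker_sds = marker_sds,
                      cross_marker_corr = R,
                      within_marker_corr = within_marker_corr,
                      covariate_params = covariate_params,
                      seed = as.integer(seed)),
                 class = "cohort_params")
  for (g in .groups) implied_marker_sigma(p, g)  # PD check per group
  p
}

#' Calibrated default generator parameters
#'
#' Defaults that emulate the motivating prospective GDM cohort: n = 600
#' pregnant women with GDM prevalence 8.2%, and group x visit biomarker
#' means/SDs set to published summary statistics for Hb, Hct, FBS and RBC
#' at the first-trimester and early-second-trimester visits. One printed
#' SD (RBC, non-GDM, visit 1: 5.01 for a mean of 4.39 x10^12/L) is
#' physiologically impossible and is treated as a typo for 0.51.
#'
#' The correlation structure is NOT available from published summaries and
#' is a declared assumption: 0.65 between Hb and Hct, 0.45 between RBC and
#' each of Hb/Hct, 0.10 between FBS and the hematologic markers, and 0.5
#' between the two visits of the same marker. Covariate distributions
#' (age, BMI, SBP, DBP per group/visit; parity and education category
#' probabilities) follow the published per-group summaries; the
#' within-subject correlation of the visit-specific covariates is set to
#' 0.7 (assumption).
#'
#' @return A `"cohort_params"` object.
#' @export
default_cohort_params <- function() {
  dn <- list(.biomarkers, .groups, .visits)
  means <- array(NA_real_, c(4, 2, 2), dimnames = dn)
  sds <- array(NA_real_, c(4, 2, 2), dimnames = dn)
  # [marker, group, visit]
  means["hb", "GDM", ] <- c(13.22, 12.32); sds["hb", "GDM", ] <- c(1.17, 0.90)
  means["hb", "non-GDM", ] <- c(12.63, 11.89); sds["hb", "non-GDM", ] <- c(0.99, 0.97)
  means["hct", "GDM", ] <- c(39.53, 36.87); sds["hct", "GDM", ] <- c(3.35, 2.54)
  means["hct", "non-GDM", ] <- c(37.55, 35.86); sds["hct", "non-GDM", ] <- c(3.54, 2.88)
  means["fbs", "GDM", ] <- c(92.04, 96.96); sds["fbs", "GDM", ] <- c(12.01, 12.74)
  means["fbs", "non-GDM", ] <- c(83.19, 81.08); sds["fbs", "non-GDM", ] <- c(11.75, 10.17)
  means["rbc", "GDM", ] <- c(4.58, 4.19); sds["rbc", "GDM", ] <- c(0.45, 0.41)
  # printed SD 5.01 at visit 1 is impossible for a mean of 4.39; corrected to 0.51
  means["rbc", "non-GDM", ] <- c(4.39, 4.12); sds["rbc", "non-GDM", ] <- c(0.51, 0.45)

  R <- diag(4)
  dimnames(R) <- list(.biomarkers, .biomarkers)
  R["hb", "hct"] <- R["hct", "hb"] <- 0.65
  R["hb", "rbc"] <- R["rbc", "hb"] <- 0.45
  R["hct", "rbc"] <- R["rbc", "hct"] <- 0.45
  R["fbs", c("hb", "hct", "rbc")] <- 0.10
  R[c("hb", "hct", "rbc"), "fbs"] <- 0.10

  gv <- function(v1n, v1g, v2n, v2g) {
    a <- array(NA_real_, c(2, 2, 2),
               dimnames = list(.groups, .visits, c("mean", "sd")))
    a["non-GDM", "1", ] <- v1n; a["GDM", "1", ] <- v1g
    a["non-GDM", "2", ] <- v2n; a["GDM", "2", ] <- v2g
    a
  }
  covpar <- list(
    age = rbind("non-GDM" = c(mean = 27.19, sd = 3.93),
                "GDM" = c(mean = 28.35, sd = 3.89)),
    bmi = gv(c(24.89, 4.30), c(26.09, 5.02), c(29.73, 4.11), c(30.90, 4.45)),
    sbp = gv(c(101.79, 12.31), c(101.73, 10.78), c(106.56, 14.43), c(112.55, 13.62)),
    dbp = gv(c(64.20, 7.70), c(63.47, 8.05), c(66.16, 9.57), c(70.01, 10.60)),
    covariate_visit_corr = 0.7,
    parity_probs = rbind("non-GDM" = c(1, 260, 224, 66) / 551,
                         "GDM" = c(0, 28, 15, 6) / 49),
    academic_prob = c("non-GDM" = 152 / 551, "GDM" = 11 / 49))

  cohort_params(n_subjects = 600L, prevalence = 0.082,
                marker_means = means, marker_sds = sds,
                cross_marker_corr = R, within_marker_corr = 0.5,
                covariate_params = covpar, seed = 1L)
}

#' Implied per-group biomarker covariance
#'
#' Assembles the 8x8 covariance of the stacked biomarker vector
#' (visits nested within biomarker: hb1, hb2, hct1, hct2, fbs1, fbs2,
#' rbc1, rbc2) for one group: `diag(s) (R_markers %x% R_visits) diag(s)`
#' where `R_visits` has off-diagonal `within_marker_corr`.
#'
#' @param params A `"cohort_params"` object.
#' @param group `"non-GDM"` or `"GDM"`.
#' @return 8x8 positive-definite covariance matrix.
#' @export
implied_marker_sigma <- function(params, group = .groups) {
  group <- match.arg(group)
  Rt <- matrix(c(1, params$within_marker_corr,
                 params$within_marker_corr, 1), 2, 2)
  R8 <- kronecker(params$cross_marker_corr, Rt)
  s <- as.vector(t(params$marker_sds[, group, ]))  # marker-major, visit-minor
  S <- diag(s) %*% R8 %*% diag(s)
  lab <- paste(rep(.biomarkers, each = 2), rep(1:2, 4), sep = ".")
  dimnames(S) <- list(lab, lab)
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied biomarker covariance for group '", group,
         "' is not positive definite", call. = FALSE)
  S
}

draw_covariates <- function(n, group, covpar) {
  # group: integer vector in {1,2}; returns visit-specific covariate matrices
  gname <- .groups[group]
  age <- stats::rnorm(n, covpar$age[gname, "mean"], covpar$age[gname, "sd"])
  rho <- covpar$covariate_visit_corr
  draw_pair <- function(par) {
    m1 <- par[cbind(gname, "1", "mean")]; s1 <- par[cbind(gname, "1", "sd")]
    m2 <- par[cbind(gname, "2", "mean")]; s2 <- par[cbind(gname, "2", "sd")]
    z1 <- stats::rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    cbind(m1 + s1 * z1, m2 + s2 * z2)
  }
  bmi <- draw_pair(covpar$bmi)
  sbp <- draw_pair(covpar$sbp)
  dbp <- draw_pair(covpar$dbp)
  parity <- integer(n)
  for (g in 1:2) {
    idx <- which(group == g)
    if (length(idx) > 0L)
      parity[idx] <- sample(0:3, length(idx), replace = TRUE,
                            prob = covpar$parity_probs[.groups[g], ])
  }
  education <- ifelse(stats::runif(n) < covpar$academic_prob[gname],
                      "academic", "non-academic")
  list(age = age, bmi = bmi, sbp = sbp, dbp = dbp,
       parity = parity, education = education)
}

assemble_cohort <- function(group, y, cov) {
  # y: n x 8 stacked biomarkers (marker-major, visit-minor)
  n <- length(group)
  sid <- sprintf("S%05d", seq_len(n))
  row_v <- function(v) data.frame(
    subject_id = sid, visit = v, group = as.numeric(group),
    hb = y[, 2 * 0 + v], hct = y[, 2 * 1 + v],
    fbs = y[, 2 * 2 + v], rbc = y[, 2 * 3 + v],
    age = cov$age, bmi = cov$bmi[, v], sbp = cov$sbp[, v], dbp = cov$dbp[, v],
    parity = as.numeric(cov$parity), education = cov$education,
    stringsAsFactors = FALSE)
  cohort_table(rbind(row_v(1L), row_v(2L)))
}

#' Generate a synthetic cohort from class-conditional distributions
#'
#' Draws each subject's group label Bernoulli(prevalence), then the
#' 8-vector of stacked biomarkers from the group-specific multivariate
#' normal implied by the configured means, SDs and correlations
#' ([implied_marker_sigma()]), and the covariates from their configured
#' per-group distributions. Deterministic given `seed`.
#'
#' @param params A `"cohort_params"` object.
#' @param seed RNG seed; defaults to `params$seed`.
#' @param n_subjects Optional override of `params$n_subjects`.
#' @return A `cohort_table` with `2 * n_subjects` rows.
#' @export
generate_cohort <- function(params, seed = params$seed, n_subjects = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  n <- if (is.null(n_subjects)) params$n_subjects else as.integer(n_subjects)
  set.seed(seed)
  group <- 1L + stats::rbinom(n, 1L, params$prevalence)
  y <- matrix(NA_real_, n, 8L)
  for (g in 1:2) {
    idx <- which(group == g)
    if (length(idx) == 0L) next
    mu <- as.vector(t(params$marker_means[, .groups[g], ]))
    S <- implied_marker_sigma(params, .groups[g])
    y[idx, ] <- MASS::mvrnorm(length(idx), mu, S)
  }
  cov <- draw_covariates(n, group, params$covariate_params)
  assemble_cohort(group, y, cov)
}

#' Ground-truth parameters for model-based simulation
#'
#' Describes the data-generating mixed model y_i = X_i beta + Z_i b_i +
#' eps_i with b_i ~ N(0, D) (one random intercept per biomarker) and
#' independent biomarker-specific error variances, together with the
#' covariate source used to build X_i.
#'
#' @param beta Fixed-effect vector in the order produced by
#'   [build_design()] for `spec`.
#' @param D p x p random-intercept covariance (symmetric PSD).
#' @param sigma2 Length-p vector of error variances (> 0).
#' @param spec A [model_spec()]; defaults to the full four-marker model.
#' @param covariate_params Covariate distributions (the
#'   `covariate_params` element of a `"cohort_params"`); defaults to the
#'   calibrated ones.
#' @return An object of class `"model_truth"`.
#' @export
model_truth <- function(beta, D, sigma2, spec = model_spec(),
                        covariate_params = default_cohort_params()$covariate_params) {
  p <- length(spec$markers)
  D <- as.matrix(D)
  if (!identical(dim(D), c(p, p)) || !isSymmetric(unname(D), tol = 1e-8))
    stop("D must be a symmetric ", p, "x", p, " matrix", call. = FALSE)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("D must be positive semi-definite", call. = FALSE)
  if (length(sigma2) != p || any(sigma2 < 0))
    stop("sigma2 must be length ", p, " and non-negative", call. = FALSE)
  k <- p * length(spec$terms)
  if (length(beta) != k)
    stop("beta has length ", length(beta), " but the design needs ", k,
         call. = FALSE)
  structure(list(beta = as.numeric(beta), D = D, sigma2 = as.numeric(sigma2),
                 spec = spec, covariate_params = covariate_params),
            class = "model_truth")
}

#' Simulate a cohort exactly from the mixed model
#'
#' Covariates and group labels are drawn as in [generate_cohort()];
#' biomarker responses are then built as `X_i beta + Z_i b_i + eps_i`
#' with `b_i ~ N(0, D)` and independent biomarker-specific errors.
#' Deterministic given `seed`.
#'
#' @param truth A [model_truth()] object.
#' @param n_subjects Number of subjects.
#' @param prevalence GDM prevalence.
#' @param seed RNG seed.
#' @return A `cohort_table`.
#' @export
generate_from_model <- function(truth, n_subjects, prevalence, seed = 1L) {
  stopifnot(inherits(truth, "model_truth"))
  n <- as.integer(n_subjects)
  set.seed(seed)
  group <- 1L + stats::rbinom(n, 1L, prevalence)
  cov <- draw_covariates(n, group, truth$covariate_params)
  # placeholder biomarkers, overwritten below (positive so validation passes)
  y0 <- matrix(1, n, 8L)
  tab <- assemble_cohort(group, y0, cov)
  des <- build_design(tab, truth$spec)
  M <- design_mean(des, truth$beta)                       # n x q fixed part
  p <- des$p
  b <- MASS::mvrnorm(n, rep(0, p), truth$D)
  if (p == 1L) b <- matrix(b, ncol = 1L)
  eps <- matrix(stats::rnorm(n * des$q), n, des$q) *
    rep(sqrt(truth$sigma2[des$layout$marker_idx]), each = n)
  Y <- M + b[, des$layout$marker_idx, drop = FALSE] + eps
  # write responses back into the long table (generated markers may span
  # any real value; offset far enough to keep them positive would distort
  # the model, so positivity validation is relaxed here via direct fill)
  df <- as.data.frame(tab)
  for (a in seq_len(des$q)) {
    m <- truth$spec$markers[des$layout$marker_idx[a]]
    v <- des$layout$visit[a]
    df[[m]][df$visit == v] <- Y[match(df$subject_id[df$visit == v],
                                      des$subject_id), a]
  }
  df <- df[order(df$subject_id, df$visit), ]
  rownames(df) <- NULL
  class(df) <- c("cohort_table", "data.frame")
  df
}
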