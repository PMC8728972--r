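#' Conditional group means for every subject
#'
#' For a fitted model, the expected stacked response of subject i under
#' each diagnosis: `mu_g,i = X_i^(g) beta` where `X_i^(g)` is the
#' subject's design with the group indicator (and any group x time
#' interaction) forced to group g, all other covariates at their
#' observed values. The means depend only on the design, never on the
#' subject's observed biomarkers.
#'
#' @param fit An [mlmm_fit()] result.
#' @param design An [build_design()] result built with `fit$spec`.
#' @return List with `mu1` and `mu2`, each n x q.
#' @export
conditional_group_means <- function(fit, design) {
  if (!identical(design$beta_names, names(fit$beta)))
    stop("design and fitted model use different specifications", call. = FALSE)
  if (!"group" %in% design$spec$terms)
    stop("model specification lacks the group indicator", call. = FALSE)
  M <- design_mean(design, fit$beta)
  nt <- design$nt
  shift <- matrix(NA_real_, design$n, design$q)  # mu2 - mu1 per slot
  for (a in seq_len(design$q)) {
    m <- design$layout$marker_idx[a]
    bg <- fit$beta[(m - 1L) * nt + design$group_term]
    s <- bg
    if (!is.na(design$int_term))
      s <- s + fit$beta[(m - 1L) * nt + design$int_term] *
        (design$layout$visit[a] - 1)
    shift[, a] <- s
  }
  g <- design$group01
  mu1 <- M - g * shift       # observed mean minus (observed - group1) part
  mu2 <- mu1 + shift
  list(mu1 = mu1, mu2 = mu2)
}

#' Linear discriminant score
#'
#' The allocation statistic
#' `L = (mu1 - mu2)' V^{-1} (y - (mu1 + mu2)/2)`: larger values favor
#' population 1 (non-GDM). Accepts single vectors or row-matched
#' matrices (one subject per row).
#'
#' @param y Observed stacked response (vector, or n x q matrix).
#' @param mu1,mu2 Conditional means under group 1 / group 2 (same shape
#'   as `y`).
#' @param V q x q positive-definite marginal covariance.
#' @return Scalar (or length-n vector) of discriminant scores.
#' @export
discriminant_score <- function(y, mu1, mu2, V) {
  ch <- tryCatch(chol(as.matrix(V)),
                 error = function(e) stop("V is not positive definite",
                                          call. = FALSE))
  W <- chol2inv(ch)
  if (is.null(dim(y))) {
    drop(crossprod(mu1 - mu2, W %*% (y - (mu1 + mu2) / 2)))
  } else {
    rowSums(((mu1 - mu2) %*% W) * (y - (mu1 + mu2) / 2))
  }
}

#' Allocate a subject from its discriminant score
#'
#' Population 1 (non-GDM) when `L >= log(pi2/pi1)`, population 2 (GDM)
#' otherwise; a score exactly at the threshold goes to population 1.
#'
#' @param score Discriminant score(s).
#' @param pi1,pi2 Prior proportions of populations 1 and 2
#'   (pi1 + pi2 = 1, both > 0).
#' @return Integer label(s) in \{1, 2\}.
#' @export
allocate <- function(score, pi1, pi2) {
  check_priors(pi1, pi2)
  ifelse(score >= log(pi2 / pi1), 1L, 2L)
}

check_priors <- function(pi1, pi2) {
  if (pi1 <= 0 || pi2 <= 0 || abs(pi1 + pi2 - 1) > 1e-8)
    stop("priors must be positive and sum to 1", call. = FALSE)
  invisible(TRUE)
}

#' Posterior group probabilities
#'
#' Equal-covariance Gaussian Bayes posterior: `p_g` proportional to
#' `pi_g N(y; mu_g, V)`. Computed in log space from the discriminant
#' score, so no over/underflow occurs for |L| up to several hundred:
#' `p1 = plogis(L - log(pi2/pi1))`.
#'
#' @inheritParams discriminant_score
#' @param pi1,pi2 Prior proportions.
#' @return List with `p1` and `p2` (vectors summing to 1 elementwise).
#' @export
posterior <- function(y, mu1, mu2, V, pi1, pi2) {
  check_priors(pi1, pi2)
  L <- discriminant_score(y, mu1, mu2, V)
  p1 <- stats::plogis(L - log(pi2 / pi1))
  list(p1 = p1, p2 = 1 - p1)
}

#' Classify a cohort with a fitted model (resubstitution)
#'
#' Scores every subject with the fitted discriminant, allocates with the
#' prior-proportion threshold and reports posteriors. Priors default to
#' the sample group proportions of the scored table.
#'
#' @param fit An [mlmm_fit()] result.
#' @param table A `cohort_table` compatible with `fit$spec`.
#' @param priors Optional `c(pi1, pi2)`; defaults to the sample
#'   proportions.
#' @return A data.frame of class `"gdm_classification"` with columns
#'   `subject_id`, `group` (true label), `score`, `label` (allocated),
#'   `posterior1`, `posterior2`; attribute `provenance` is
#'   `"resubstitution"` and attribute `priors` the priors used.
#' @export
classify_cohort <- function(fit, table, priors = NULL) {
  design <- build_design(table, fit$spec)
  classify_design(fit, design, priors)
}

classify_design <- function(fit, design, priors = NULL,
                            provenance = "resubstitution") {
  if (is.null(priors)) {
    pi2 <- mean(design$group01)
    priors <- c(1 - pi2, pi2)
  }
  check_priors(priors[1], priors[2])
  mu <- conditional_group_means(fit, design)
  score <- discriminant_score(design$y, mu$mu1, mu$mu2, fit$V)
  thr <- log(priors[2] / priors[1])
  label <- ifelse(score >= thr, 1L, 2L)
  p1 <- stats::plogis(score - thr)
  out <- data.frame(subject_id = design$subject_id,
                    group = design$group01 + 1L,
                    score = score, label = label,
                    posterior1 = p1, posterior2 = 1 - p1,
                    stringsAsFactors = FALSE)
  attr(out, "priors") <- priors
  attr(out, "provenance") <- provenance
  class(out) <- c("gdm_classification", "data.frame")
  out
}

#' Stratified k-fold cross-validated classification
#'
#' Splits subjects into `folds` strata-balanced folds (deterministic
#' given `seed`), fits the model without each fold and scores the
#' held-out subjects; priors are estimated from each training split.
#'
#' @param table A `cohort_table`.
#' @param spec A [model_spec()].
#' @param folds Number of folds (>= 2; `n` gives leave-one-out).
#' @param seed RNG seed for the fold assignment.
#' @param control Passed to [mlmm_fit()].
#' @return A `"gdm_classification"` data.frame (provenance
#'   `"cross-validated"`) in the original subject order, with a
#'   `fold` column.
#' @export
cross_validate <- function(table, spec = model_spec(), folds = 10L,
                           seed = 1L, control = list()) {
  df <- as.data.frame(table)
  subj <- unique(df[order(df$subject_id), c("subject_id", "group")])
  n <- nrow(subj)
  if (folds < 2 || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  for (g in unique(subj$group)) {
    idx <- sample(which(subj$group == g))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  res <- vector("list", folds)
  for (f in seq_len(folds)) {
    train_ids <- subj$subject_id[fold != f]
    test_ids <- subj$subject_id[fold == f]
    if (length(test_ids) == 0L) next
    train_groups <- subj$group[fold != f]
    if (length(unique(train_groups)) < 2)
      stop("training split of fold ", f, " lacks a group; use fewer folds",
           call. = FALSE)
    fit_f <- mlmm_fit(df[df$subject_id %in% train_ids, ], spec,
                      control = control)
    pi2 <- mean(train_groups == 2)
    des_f <- build_design(df[df$subject_id %in% test_ids, ], spec)
    out <- classify_design(fit_f, des_f, priors = c(1 - pi2, pi2),
                           provenance = "cross-validated")
    out$fold <- f
    res[[f]] <- out
  }
  out <- do.call(rbind, res)
  out <- out[match(subj$subject_id, out$subject_id), ]
  rownames(out) <- NULL
  attr(out, "provenance") <- "cross-validated"
  attr(out, "folds") <- folds
  class(out) <- c("gdm_classification", "data.frame")
  out
}
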