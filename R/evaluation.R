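## Risk orientation: the discriminant score is oriented toward non-GDM
## (larger = healthier), so the ROC risk marker is the NEGATED score.
## The positive class is GDM (label 2) throughout.

risk_from_scores <- function(scores) -scores

check_two_classes <- function(labels) {
  if (!all(labels %in% c(1, 2)))
    stop("labels must be coded 1 (non-GDM) / 2 (GDM)", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both classes must be present", call. = FALSE)
  invisible(TRUE)
}

#' Empirical ROC curve of discriminant scores
#'
#' Sweeps every distinct risk value (risk = negated discriminant score,
#' positive class = GDM) as a ">= threshold" rule and reports one
#' (1 - specificity, sensitivity) point per distinct threshold plus the
#' (0, 0) and (1, 1) endpoints. The trapezoidal area equals the
#' Mann-Whitney AUC exactly, ties included.
#'
#' @param scores Discriminant scores (larger favors non-GDM).
#' @param labels True groups, 1 = non-GDM, 2 = GDM.
#' @return Object of class `"roc_result"`: data.frame `points`
#'   (threshold on the risk scale, sens, spec, fpr) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  check_two_classes(labels)
  r <- risk_from_scores(scores)
  pos <- labels == 2
  ord <- order(r, decreasing = TRUE)
  r_s <- r[ord]; pos_s <- pos[ord]
  tp <- cumsum(pos_s); fp <- cumsum(!pos_s)
  last <- !duplicated(r_s, fromLast = TRUE)
  sens <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  thr <- c(Inf, r_s[last])
  pts <- data.frame(threshold = thr, sens = sens, spec = 1 - fpr, fpr = fpr)
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' Mann-Whitney AUC estimator
#'
#' `AUC = [#(risk_pos > risk_neg) + 0.5 #(ties)] / (n_pos n_neg)` with
#' risk = negated discriminant score and GDM the positive class;
#' equivalently the normalized rank-sum.
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc_mann_whitney <- function(scores, labels) {
  check_two_classes(labels)
  r <- risk_from_scores(scores)
  pos <- labels == 2
  n1 <- sum(pos); n0 <- sum(!pos)
  rk <- rank(r)
  (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confidence interval for the AUC
#'
#' Default: DeLong's structural-components variance with a normal
#' approximation, truncated to [0, 1]. Alternative: stratified bootstrap
#' percentile interval (2000 resamples, seeded).
#'
#' @inheritParams roc_curve
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param seed RNG seed (bootstrap only).
#' @param n_boot Bootstrap resamples (default 2000).
#' @return List with `auc`, `lower`, `upper`, `level`, `method` (and
#'   `se` for DeLong).
#' @export
auc_ci <- function(scores, labels, level = 0.95,
                   method = c("delong", "bootstrap"), seed = 1L,
                   n_boot = 2000L) {
  method <- match.arg(method)
  check_two_classes(labels)
  if (sum(labels == 2) < 2 || sum(labels == 1) < 2)
    stop("need at least 2 subjects per class for a CI", call. = FALSE)
  auc <- auc_mann_whitney(scores, labels)
  if (method == "delong") {
    r <- risk_from_scores(scores)
    x <- r[labels == 2]; yv <- r[labels == 1]
    m <- length(x); n <- length(yv)
    psi <- outer(x, yv, function(a, b) (a > b) + 0.5 * (a == b))
    v10 <- rowMeans(psi)          # placement of each positive
    v01 <- colMeans(psi)          # placement of each negative
    se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
    z <- stats::qnorm((1 + level) / 2)
    lo <- max(0, auc - z * se); hi <- min(1, auc + z * se)
    return(list(auc = auc, lower = lo, upper = hi, level = level,
                method = "delong", se = se))
  }
  set.seed(seed)
  idx_pos <- which(labels == 2); idx_neg <- which(labels == 1)
  boots <- vapply(seq_len(n_boot), function(i) {
    ip <- sample(idx_pos, replace = TRUE)
    ineg <- sample(idx_neg, replace = TRUE)
    auc_mann_whitney(c(scores[ip], scores[ineg]),
                     c(rep(2, length(ip)), rep(1, length(ineg))))
  }, numeric(1))
  qs <- stats::quantile(boots, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  list(auc = auc, lower = qs[1], upper = qs[2], level = level,
       method = "bootstrap")
}

#' Sensitivity and specificity at a score threshold
#'
#' Applies the allocation rule "non-GDM iff score >= threshold" (the
#' tie-inclusive rule of the discriminant) and tallies sensitivity
#' (fraction of GDM allocated GDM) and specificity (fraction of non-GDM
#' allocated non-GDM).
#'
#' @inheritParams roc_curve
#' @param threshold Cut-off on the discriminant-score scale.
#' @return List with `sens` and `spec`.
#' @export
sens_spec_at <- function(scores, labels, threshold) {
  check_two_classes(labels)
  pred <- ifelse(scores >= threshold, 1L, 2L)
  list(sens = mean(pred[labels == 2] == 2L),
       spec = mean(pred[labels == 1] == 1L))
}

#' Youden-optimal operating point
#'
#' Scans every observed score as a candidate threshold and returns the
#' one maximizing Youden's J = sens + spec - 1; ties go to the lower
#' threshold.
#'
#' @inheritParams roc_curve
#' @return List with `threshold`, `sens`, `spec`, `j`.
#' @export
youden_point <- function(scores, labels) {
  check_two_classes(labels)
  cand <- sort(unique(c(scores, max(scores) + 1)))
  best <- NULL
  for (thr in cand) {
    ss <- sens_spec_at(scores, labels, thr)
    j <- ss$sens + ss$spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(threshold = thr, sens = ss$sens, spec = ss$spec, j = j)
  }
  best
}

#' Closed-form binormal AUC
#'
#' AUC of a single normally distributed marker in two classes:
#' `Phi(|m1 - m2| / sqrt(s1^2 + s2^2))`.
#'
#' @param m1,s1 Mean and SD in one class.
#' @param m2,s2 Mean and SD in the other class.
#' @return AUC in [0.5, 1].
#' @export
binormal_auc <- function(m1, s1, m2, s2) {
  stopifnot(s1 > 0, s2 > 0)
  stats::pnorm(abs(m1 - m2) / sqrt(s1^2 + s2^2))
}
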