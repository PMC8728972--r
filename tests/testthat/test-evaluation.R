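# Risks below are passed as negated scores so that larger risk = GDM.

test_that("Mann-Whitney AUC equals exhaustive pair counting", {
  risk_pos <- c(0.9, 0.8); risk_neg <- c(0.1, 0.2)
  expect_equal(auc_mann_whitney(-c(risk_pos, risk_neg), c(2, 2, 1, 1)), 1)
  expect_equal(auc_mann_whitney(rep(0, 10), rep(c(1, 2), 5)), 0.5)
  expect_equal(auc_mann_whitney(-c(3, 1, 2, 0), c(2, 2, 1, 1)), 0.75)
  set.seed(12)
  for (i in 1:50) {
    n <- sample(4:50, 1)
    labels <- c(1, 2, sample(1:2, n - 2, replace = TRUE))
    scores <- round(rnorm(n), sample(0:1, 1))  # force ties sometimes
    pairs <- outer(-scores[labels == 2], -scores[labels == 1],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc_mann_whitney(scores, labels), mean(pairs),
                 tolerance = 1e-12)
  }
  expect_error(auc_mann_whitney(1:4, rep(2, 4)), "both classes")
})

test_that("the ROC curve matches a brute-force threshold sweep and its area the AUC", {
  scores <- -c(0.2, 0.8, 0.8, 0.3, 0.6, 0.1)  # risks with a tie
  labels <- c(1, 2, 1, 1, 2, 1)
  rc <- roc_curve(scores, labels)
  risks <- -scores
  for (i in seq_len(nrow(rc$points))) {
    thr <- rc$points$threshold[i]
    if (!is.finite(thr)) next
    expect_equal(rc$points$sens[i], mean(risks[labels == 2] >= thr))
    expect_equal(rc$points$spec[i], mean(risks[labels == 1] < thr))
  }
  expect_equal(rc$auc, auc_mann_whitney(scores, labels), tolerance = 1e-10)
  set.seed(8)
  for (i in 1:20) {
    s <- round(rnorm(30), 1)
    l <- c(1, 2, sample(1:2, 28, replace = TRUE))
    expect_equal(roc_curve(s, l)$auc, auc_mann_whitney(s, l),
                 tolerance = 1e-10)
  }
  # perfectly separated and fully tied scores
  expect_equal(roc_curve(-c(5, 6, 1, 2), c(2, 2, 1, 1))$auc, 1)
  flat <- roc_curve(rep(0, 8), rep(1:2, 4))
  expect_equal(flat$auc, 0.5)
})

test_that("AUC is invariant to monotone risk transforms and flips under label swap", {
  set.seed(21)
  scores <- rnorm(40)
  labels <- c(1, 2, sample(1:2, 38, replace = TRUE))
  a <- auc_mann_whitney(scores, labels)
  for (f in list(function(x) x^3, function(x) atan(x), function(x) 5 * x + 2))
    # applying f to the risk means applying -f(-s) to the score
    expect_equal(auc_mann_whitney(-f(-scores), labels), a, tolerance = 1e-12)
  expect_equal(auc_mann_whitney(scores, 3 - labels), 1 - a, tolerance = 1e-12)
})

test_that("DeLong variance equals the structural-components formula", {
  set.seed(33)
  scores <- rnorm(20)
  labels <- c(rep(2, 8), rep(1, 12))
  ci <- auc_ci(scores, labels)
  x <- -scores[labels == 2]; y <- -scores[labels == 1]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi); v01 <- colMeans(psi)
  se <- sqrt(var(v10) / 8 + var(v01) / 12)
  expect_equal(ci$se, se, tolerance = 1e-12)
  expect_equal(ci$auc, mean(psi), tolerance = 1e-12)
  expect_lte(ci$upper, 1); expect_gte(ci$lower, 0)
  expect_true(ci$lower <= ci$auc && ci$auc <= ci$upper)
})

test_that("DeLong CI agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(34)
  scores <- rnorm(60)
  labels <- c(rep(2, 20), rep(1, 40))
  scores[labels == 2] <- scores[labels == 2] - 1  # GDM risk higher
  ci <- auc_ci(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, -scores, levels = c(1, 2),
                                direction = "<", quiet = TRUE))
  expect_equal(ci$lower, as.numeric(ref)[1], tolerance = 1e-8)
  expect_equal(ci$auc, as.numeric(ref)[2], tolerance = 1e-8)
  expect_equal(ci$upper, as.numeric(ref)[3], tolerance = 1e-8)
})

test_that("bootstrap CIs are seed-reproducible and cover a null AUC", {
  set.seed(35)
  scores <- rnorm(300)
  labels <- rep(1:2, 150)
  a <- auc_ci(scores, labels, method = "bootstrap", seed = 4)
  b <- auc_ci(scores, labels, method = "bootstrap", seed = 4)
  expect_identical(a, b)
  expect_true(a$lower <= 0.5 && 0.5 <= a$upper)
  d <- auc_ci(scores, labels)
  expect_true(d$lower <= 0.5 && 0.5 <= d$upper)
  expect_error(auc_ci(c(1, 2, 3), c(2, 1, 1)), "at least 2")
})

test_that("sensitivity and specificity match a hand-tallied confusion matrix", {
  scores <- c(2.0, 1.0, 0.5, -0.5, -1.0, -2.0, 0.0, 3.0)
  labels <- c(1, 1, 1, 2, 2, 2, 2, 1)
  ss <- sens_spec_at(scores, labels, threshold = 0)
  # score >= 0 -> non-GDM: predictions 1,1,1,2,2,2,1,1
  expect_equal(ss$sens, 3 / 4)
  expect_equal(ss$spec, 4 / 4)
  ss2 <- sens_spec_at(scores, labels, threshold = -10)
  expect_equal(ss2$sens, 0)  # every score above threshold -> all non-GDM
  expect_equal(ss2$spec, 1)
  # symmetric toy data at the equal-prior Bayes threshold: sens = spec
  sym_scores <- c(1.5, 0.5, -0.5, -1.5)
  sym_labels <- c(1, 1, 2, 2)
  ssym <- sens_spec_at(sym_scores, sym_labels, 0)
  expect_equal(ssym$sens, ssym$spec)
})

test_that("the Youden point maximizes J with ties to the lower threshold", {
  scores <- c(3, 2, 1, 0, -1, -2)
  labels <- c(1, 1, 1, 2, 2, 2)
  yd <- youden_point(scores, labels)
  expect_equal(yd$j, 1)
  expect_equal(yd$sens, 1)
  expect_equal(yd$spec, 1)
  expect_equal(yd$threshold, 1)  # lowest threshold achieving J = 1
})

test_that("the binormal closed form matches its Monte-Carlo AUC", {
  expect_equal(binormal_auc(5, 1, 5, 2), 0.5)
  expect_equal(binormal_auc(92.04, 12.01, 83.19, 11.75),
               pnorm(8.85 / sqrt(12.01^2 + 11.75^2)), tolerance = 1e-12)
  set.seed(41)
  n <- 20000
  x_gdm <- rnorm(n, 92.04, 12.01)
  x_non <- rnorm(n, 83.19, 11.75)
  emp <- auc_mann_whitney(-c(x_gdm, x_non), rep(c(2, 1), each = n))
  expect_equal(emp, binormal_auc(92.04, 12.01, 83.19, 11.75),
               tolerance = 0.01)
})
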