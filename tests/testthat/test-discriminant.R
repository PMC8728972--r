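test_that("the discriminant score reproduces hand-computed cases", {
  # q = 2 worked example: mu1 = 0, mu2 = (1,1), V = I, y = (2,2)
  expect_equal(discriminant_score(c(2, 2), c(0, 0), c(1, 1), diag(2)), -3)
  # midpoint scores zero; y = mu1 scores half the Mahalanobis distance
  set.seed(3)
  V <- rand_pd(4); mu1 <- rnorm(4); mu2 <- rnorm(4)
  expect_equal(discriminant_score((mu1 + mu2) / 2, mu1, mu2, V), 0,
               tolerance = 1e-12)
  d2 <- drop(crossprod(mu1 - mu2, solve(V, mu1 - mu2)))
  expect_equal(discriminant_score(mu1, mu1, mu2, V), d2 / 2, tolerance = 1e-10)
  expect_gt(discriminant_score(mu1, mu1, mu2, V), 0)
  expect_error(discriminant_score(c(1, 1), c(0, 0), c(1, 1),
                                  matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("allocation applies the prior-odds threshold with ties to population 1", {
  expect_equal(allocate(0, 0.5, 0.5), 1L)       # L = threshold = 0
  expect_equal(allocate(-3, 0.5, 0.5), 2L)
  expect_equal(allocate(-2, 0.918, 0.082), 1L)  # threshold ~ -2.415
  expect_equal(allocate(-2.5, 0.918, 0.082), 2L)
  expect_error(allocate(0, 0.9, 0.2), "sum to 1")
  # prior monotonicity: raising pi2 never turns GDM into non-GDM
  sc <- seq(-4, 4, by = 0.25)
  prev <- c(0.05, 0.2, 0.5, 0.8)
  lab <- sapply(prev, function(p2) allocate(sc, 1 - p2, p2))
  # raising pi2 raises the threshold, so labels can only move 1 -> 2
  expect_true(all(apply(lab, 1, function(r) all(diff(r) >= 0))))
})

test_that("posteriors satisfy the score-density identity and sum to one", {
  set.seed(9)
  for (q in c(1, 3)) {
    for (i in 1:25) {
      V <- rand_pd(q); mu1 <- rnorm(q); mu2 <- rnorm(q); y <- rnorm(q)
      pi2 <- runif(1, 0.05, 0.95)
      po <- posterior(y, mu1, mu2, V, 1 - pi2, pi2)
      L <- discriminant_score(y, mu1, mu2, V)
      expect_equal(po$p1 + po$p2, 1, tolerance = 1e-12)
      expect_equal(po$p1 / po$p2, exp(L) * (1 - pi2) / pi2, tolerance = 1e-8)
      expect_equal(allocate(L, 1 - pi2, pi2),
                   if (po$p1 >= po$p2) 1L else 2L)
    }
  }
  # extreme scores stay finite in log space
  po <- posterior(700, 0, 1, 1e-6, 0.5, 0.5)
  expect_false(any(is.na(c(po$p1, po$p2))))
})

test_that("conditional group means depend on the design only", {
  tab <- small_cohort(n = 80, seed = 19)
  spec <- model_spec(markers = c("hb", "fbs"))
  fit <- mlmm_fit(tab, spec)
  des <- build_design(tab, spec)
  mu <- conditional_group_means(fit, des)
  # shifting every observed response leaves mu1/mu2 untouched
  df2 <- as.data.frame(tab)
  df2$hb <- df2$hb + 5
  des2 <- build_design(cohort_table(df2), spec)
  mu2 <- conditional_group_means(fit, des2)
  expect_identical(mu$mu1, mu2$mu1)
  # mu2 - mu1 equals the per-marker group coefficients replicated over visits
  shift <- mu$mu2 - mu$mu1
  expect_equal(unname(shift[1, ]),
               rep(unname(fit$beta[c("hb:group", "fbs:group")]), each = 2),
               tolerance = 1e-12)
  expect_equal(max(abs(sweep(shift, 2, shift[1, ]))), 0, tolerance = 1e-12)
})

test_that("cohort classification is deterministic and group-swap antisymmetric", {
  tab <- small_cohort(n = 100, seed = 37)
  spec <- model_spec(markers = c("hb", "fbs"))
  fit <- mlmm_fit(tab, spec)
  a <- classify_cohort(fit, tab)
  b <- classify_cohort(fit, tab)
  expect_identical(a, b)
  expect_equal(attr(a, "provenance"), "resubstitution")
  expect_equal(sum(attr(a, "priors")), 1)
  # relabeling groups 1 <-> 2 flips every score sign and swaps posteriors
  df <- as.data.frame(tab)
  df$group <- 3 - df$group
  fit_sw <- mlmm_fit(cohort_table(df), spec)
  b <- classify_cohort(fit_sw, cohort_table(df),
                       priors = rev(attr(a, "priors")))
  expect_equal(b$score, -a$score, tolerance = 1e-4)
  expect_equal(b$posterior1, a$posterior2, tolerance = 1e-4)
})

test_that("an uninformative score with a dominant prior allocates to population 1", {
  p <- default_cohort_params()
  # remove all group differences: both groups use the non-GDM distribution
  p$marker_means[, "GDM", ] <- p$marker_means[, "non-GDM", ]
  p$marker_sds[, "GDM", ] <- p$marker_sds[, "non-GDM", ]
  tab <- generate_cohort(p, seed = 44, n_subjects = 400)
  fit <- mlmm_fit(tab, model_spec())
  cls <- classify_cohort(fit, tab)
  expect_gt(mean(cls$label == 1L), 0.95)
})

test_that("stratified cross-validation is seed-stable with both groups per fold", {
  tab <- small_cohort(n = 60, seed = 51, prevalence = 0.3)
  spec <- model_spec(markers = "fbs", covariates = "age")
  a <- cross_validate(tab, spec, folds = 5, seed = 2)
  b <- cross_validate(tab, spec, folds = 5, seed = 2)
  expect_identical(a, b)
  expect_equal(attr(a, "provenance"), "cross-validated")
  expect_equal(sort(unique(a$fold)), 1:5)
  expect_setequal(a$subject_id, unique(tab$subject_id))
  expect_true(all(table(a$fold) >= 1))
  expect_error(cross_validate(tab, spec, folds = 1), "folds")
})

test_that("leave-one-out scores every subject exactly once", {
  tab <- small_cohort(n = 40, seed = 53, prevalence = 0.3)
  spec <- model_spec(markers = "fbs", covariates = "age")
  loo <- cross_validate(tab, spec, folds = 40, seed = 1)
  expect_equal(nrow(loo), 40L)
  expect_equal(anyDuplicated(loo$subject_id), 0L)
})
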