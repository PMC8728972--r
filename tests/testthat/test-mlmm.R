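test_that("stacked designs have the declared shape and canonical ordering", {
  tab <- cohort_table(manual_cohort_df())
  des <- build_design(tab, model_spec())
  expect_equal(des$q, 8L)
  expect_equal(des$k, 4L * 7L)
  expect_equal(dim(des$y), c(2L, 8L))
  expect_equal(des$layout$marker, rep(biomarker_names(), each = 2))
  # single-marker spec gives the univariate strategy input
  des1 <- build_design(tab, model_spec(markers = "fbs"))
  expect_equal(des1$q, 2L)
  # shuffling input rows leaves the assembled design unchanged
  shuffled <- as.data.frame(tab)[c(3, 1, 4, 2), ]
  des2 <- build_design(cohort_table(shuffled), model_spec())
  expect_identical(des$y, des2$y)
  expect_identical(des$X, des2$X)
  expect_error(build_design(tab, model_spec(covariates = c("age", "nope"))),
               "nope")
})

test_that("marginal covariance assembles Z D Z' + Omega", {
  # D = 0 collapses to the diagonal error
  V0 <- marginal_covariance(matrix(0, 2, 2) + diag(1e-12, 2), c(2, 3))
  expect_equal(V0, diag(c(2, 2, 3, 3)), tolerance = 1e-10)
  # p = 1: compound symmetry
  V1 <- marginal_covariance(matrix(1.5), 0.7)
  expect_equal(V1, matrix(c(2.2, 1.5, 1.5, 2.2), 2), tolerance = 1e-12)
  # full 4-marker case against elementwise assembly
  set.seed(1)
  D <- rand_pd(4); s2 <- runif(4, 0.5, 2)
  V <- marginal_covariance(D, s2)
  for (a in 1:8) for (b in 1:8) {
    m1 <- ceiling(a / 2); m2 <- ceiling(b / 2)
    expect_equal(V[a, b], D[m1, m2] + (a == b) * s2[m1], tolerance = 1e-12)
  }
  expect_error(marginal_covariance(matrix(-5), 1), "positive definite")
})

test_that("GLS with identity weight is OLS, and is scale-invariant in V", {
  tab <- small_cohort(n = 60, seed = 13)
  des <- build_design(tab, model_spec(markers = c("hb", "fbs"),
                                      covariates = "age"))
  b_gls <- gls_beta(des)
  # stacked OLS oracle via lm
  Xs <- do.call(rbind, des$X)
  ys <- as.vector(des$y)
  b_ols <- coef(lm(ys ~ Xs - 1))
  expect_equal(unname(b_gls), unname(b_ols), tolerance = 1e-8)
  V <- rand_pd(des$q)
  expect_equal(gls_beta(des, V), gls_beta(des, 7.3 * V), tolerance = 1e-8)
})

test_that("rank-deficient designs are refused with the collinear column named", {
  tab <- small_cohort(n = 40, seed = 14)
  df <- as.data.frame(tab)
  df$dup <- df$age
  expect_error(
    gls_beta(build_design(df, model_spec(markers = "hb",
                                         covariates = c("age", "dup")))),
    "collinear")
})

test_that("log-likelihood matches a per-subject Cholesky density oracle", {
  set.seed(17)
  tab <- small_cohort(n = 25, seed = 17)
  des <- build_design(tab, model_spec(markers = c("hb", "hct"),
                                      covariates = "age"))
  D <- rand_pd(2); s2 <- runif(2, 0.5, 2)
  beta <- rnorm(des$k)
  V <- marginal_covariance(D, s2)
  ll <- mlmm_loglik(des, beta, D, s2)
  # oracle: whiten each residual with the Cholesky factor and use dnorm
  L <- t(chol(V))
  oracle <- 0
  for (i in seq_len(des$n)) {
    Xi <- t(sapply(seq_len(des$q), function(a) des$X[[a]][i, ]))
    r <- des$y[i, ] - Xi %*% beta
    z <- forwardsolve(L, r)
    oracle <- oracle + sum(dnorm(z, log = TRUE)) - sum(log(diag(L)))
  }
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("identity covariance and zero mean reduce loglik to the standard normal", {
  des <- build_design(cohort_table(manual_cohort_df()),
                      model_spec(markers = "hb", covariates = "age"))
  ll <- mlmm_loglik(des, beta = rep(0, des$k), V = diag(2))
  expect_equal(ll, -0.5 * (des$n * 2 * log(2 * pi) + sum(des$y^2)),
               tolerance = 1e-10)
})

test_that("the univariate fit agrees with an lme random-intercept oracle", {
  skip_if_not_installed("nlme")
  tab <- small_cohort(n = 150, seed = 7)
  fit <- mlmm_fit(tab, model_spec(markers = "fbs"))
  df <- as.data.frame(tab)
  df$g01 <- df$group - 1; df$time <- df$visit - 1
  ref <- nlme::lme(fbs ~ g01 + time + age + bmi + sbp + dbp,
                   random = ~1 | subject_id, data = df, method = "ML")
  expect_true(fit$converged)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$beta["fbs:group"]), unname(nlme::fixef(ref)["g01"]),
               tolerance = 1e-3)
})

test_that("fitting data simulated without random effects drives D toward zero", {
  truth <- toy_truth()
  truth$D[] <- 0
  truth$sigma2[] <- c(1, 1)
  tab <- generate_from_model(truth, n_subjects = 2000, prevalence = 0.3,
                             seed = 23)
  fit <- mlmm_fit(tab, truth$spec)
  expect_true(fit$converged)
  se <- sqrt(diag(fit$vcov_beta))
  expect_true(all(abs(fit$beta - truth$beta) < 3.5 * se))
  expect_lt(max(eigen(fit$D, only.values = TRUE)$values),
            0.05 * max(fit$sigma2))
})

test_that("the optimum is a fixed point: refitting from it moves loglik < 1e-6", {
  tab <- small_cohort(n = 120, seed = 29)
  spec <- model_spec(markers = c("hb", "fbs"))
  des <- build_design(tab, spec)
  fit <- mlmm_fit(des)
  ll2 <- mlmm_loglik(des, fit$beta, fit$D, fit$sigma2)
  expect_lt(abs(ll2 - fit$loglik), 1e-6)
  # and the reported loglik is the ML objective at the estimates
  fit2 <- mlmm_fit(des, control = list(maxit = 1000))
  expect_lt(abs(fit2$loglik - fit$loglik), 1e-6)
})

test_that("the fit is invariant under affine rescaling of a biomarker", {
  tab <- small_cohort(n = 150, seed = 41)
  spec <- model_spec()
  fit <- mlmm_fit(tab, spec)
  scaled <- as.data.frame(tab)
  scaled$fbs <- scaled$fbs / 18.016  # mg/dL -> mmol/L
  fit2 <- mlmm_fit(cohort_table(scaled), spec)
  # loglik shifts by n * t * log(scale) (Jacobian of the rescaling)
  shift <- fit$n * 2 * log(18.016)
  expect_equal(fit2$loglik, fit$loglik + shift, tolerance = 1e-3)
  expect_equal(unname(fit2$beta["fbs:group"]),
               unname(fit$beta["fbs:group"]) / 18.016, tolerance = 1e-4)
  expect_equal(unname(fit2$beta["hb:group"]), unname(fit$beta["hb:group"]),
               tolerance = 1e-4)
})
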