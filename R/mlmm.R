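#' Specify the multivariate longitudinal mixed model
#'
#' The model stacks `p` biomarkers at `t = 2` visits into a response
#' vector of length `q = 2p` per subject (visits nested within
#' biomarker) and fits y_i = X_i beta + Z_i b_i + eps_i with one random
#' intercept per biomarker (`b_i ~ N(0, D)`, unstructured p x p `D`) and
#' independent biomarker-specific error variances. Every covariate gets
#' a biomarker-specific coefficient (seemingly-unrelated-regressions
#' layout); each biomarker block contains an intercept, the GDM group
#' indicator (0 = non-GDM, 1 = GDM), the visit indicator (0 = first,
#' 1 = early second trimester), the listed covariates, and optionally a
#' group x time interaction.
#'
#' @param markers Character vector of response biomarkers (subset of
#'   `biomarker_names()`, order defines the stacking).
#' @param covariates Covariate columns entering each biomarker block;
#'   default age, BMI, SBP, DBP.
#' @param group_time_interaction Include a group x time term per
#'   biomarker (off by default).
#' @return An object of class `"mlmm_spec"`.
#' @export
model_spec <- function(markers = biomarker_names(),
                       covariates = c("age", "bmi", "sbp", "dbp"),
                       group_time_interaction = FALSE) {
  markers <- match.arg(markers, .biomarkers, several.ok = TRUE)
  terms <- c("(Intercept)", "group", "time", covariates,
             if (group_time_interaction) "group:time")
  structure(list(markers = markers, covariates = covariates,
                 group_time_interaction = group_time_interaction,
                 terms = terms),
            class = "mlmm_spec")
}

#' Build the stacked per-subject design
#'
#' Converts a long cohort table into stacked responses and design
#' matrices: for each subject, `y_i` of length `q = 2p` (visits nested
#' within biomarker) and a `q x k` fixed-effects design with one
#' coefficient block per biomarker. The group indicator is recoded
#' 0/1 (from the 1 = non-GDM / 2 = GDM labels) and time 0/1.
#'
#' @param table A `cohort_table` (or data.frame with the same columns;
#'   must be complete two-visit data).
#' @param spec A [model_spec()].
#' @return An object of class `"mlmm_design"`: element `y` is the n x q
#'   response matrix, `X` a list of q matrices (n x k), one per response
#'   slot, plus layout metadata.
#' @export
build_design <- function(table, spec = model_spec()) {
  stopifnot(inherits(spec, "mlmm_spec"))
  df <- as.data.frame(table)
  need <- c("subject_id", "visit", "group", spec$markers, spec$covariates)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("design needs missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- df[order(df$subject_id, df$visit), , drop = FALSE]
  v1 <- df[df$visit == 1, , drop = FALSE]
  v2 <- df[df$visit == 2, , drop = FALSE]
  if (!identical(v1$subject_id, v2$subject_id))
    stop("complete two-visit data required", call. = FALSE)
  n <- nrow(v1)
  p <- length(spec$markers)
  t <- 2L
  q <- p * t
  nt <- length(spec$terms)
  k <- p * nt
  group01 <- as.numeric(v1$group) - 1
  layout <- data.frame(slot = seq_len(q),
                       marker_idx = rep(seq_len(p), each = t),
                       marker = rep(spec$markers, each = t),
                       visit = rep(seq_len(t), p))
  y <- matrix(NA_real_, n, q)
  X <- vector("list", q)
  visit_df <- list(v1, v2)
  for (a in seq_len(q)) {
    m <- layout$marker[a]
    v <- layout$visit[a]
    dv <- visit_df[[v]]
    y[, a] <- dv[[m]]
    block <- cbind(1, group01, v - 1,
                   as.matrix(dv[, spec$covariates, drop = FALSE]))
    if (spec$group_time_interaction) block <- cbind(block, group01 * (v - 1))
    Xa <- matrix(0, n, k)
    cols <- (layout$marker_idx[a] - 1L) * nt + seq_len(nt)
    Xa[, cols] <- block
    X[[a]] <- Xa
  }
  beta_names <- as.vector(t(outer(spec$markers, spec$terms, paste, sep = ":")))
  structure(list(y = y, X = X, group01 = group01,
                 subject_id = v1$subject_id, layout = layout,
                 spec = spec, n = n, p = p, t = t, q = q, k = k,
                 nt = nt, beta_names = beta_names,
                 group_term = which(spec$terms == "group"),
                 int_term = if (spec$group_time_interaction)
                   which(spec$terms == "group:time") else NA_integer_),
            class = "mlmm_design")
}

## n x q matrix of fixed-effect means X_i beta
design_mean <- function(design, beta) {
  M <- matrix(NA_real_, design$n, design$q)
  for (a in seq_len(design$q)) M[, a] <- design$X[[a]] %*% beta
  M
}

#' Marginal covariance of a subject's stacked response
#'
#' Assembles `V = Z D Z' + Omega` for the random-intercept model with
#' visits nested within biomarker: `V = D %x% J_t + diag(rep(sigma2,
#' each = t))` where `J_t` is the t x t all-ones matrix. With `p = 1`,
#' `t = 2` this is the familiar compound-symmetry matrix
#' `[[d + s2, d], [d, d + s2]]`.
#'
#' @param D p x p random-intercept covariance.
#' @param sigma2 Length-p error variances.
#' @param t Number of visits (default 2).
#' @return The q x q symmetric positive-definite marginal covariance.
#' @export
marginal_covariance <- function(D, sigma2, t = 2L) {
  D <- as.matrix(D)
  p <- nrow(D)
  stopifnot(length(sigma2) == p)
  V <- kronecker(D, matrix(1, t, t)) + diag(rep(sigma2, each = t),
                                            nrow = p * t)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    stop("marginal covariance is not positive definite; D = ",
         paste(signif(D, 4), collapse = ","), "; sigma2 = ",
         paste(signif(sigma2, 4), collapse = ","), call. = FALSE)
  V
}

## Sufficient statistics that make each likelihood evaluation O(q^2 k^2):
## SXX[(a-1)q + b... ] row ab holds vec(t(X_a) %*% X_b); SXY row ab holds
## t(X_a) %*% y[, b]; Syy = t(y) %*% y. For a symmetric weight W = V^{-1},
##   A = sum_ab W[a,b] Sxx_ab,  c = sum_ab W[a,b] Sxy_ab,
##   sum_i r_i' W r_i = sum(W * Syy) - 2 c'beta + beta' A beta.
design_suffstats <- function(design) {
  q <- design$q; k <- design$k
  SXX <- matrix(NA_real_, q * q, k * k)
  SXY <- matrix(NA_real_, q * q, k)
  for (b in seq_len(q)) {
    for (a in seq_len(q)) {
      ab <- a + (b - 1L) * q
      SXX[ab, ] <- as.vector(crossprod(design$X[[a]], design$X[[b]]))
      SXY[ab, ] <- crossprod(design$X[[a]], design$y[, b])
    }
  }
  list(SXX = SXX, SXY = SXY, Syy = crossprod(design$y))
}

gls_components <- function(suff, W, k) {
  w <- as.vector(W)
  A <- matrix(crossprod(suff$SXX, w), k, k)
  cvec <- as.vector(crossprod(suff$SXY, w))
  list(A = A, c = cvec)
}

#' Generalized least squares for the fixed effects
#'
#' Computes `beta = (sum_i X_i' W X_i)^{-1} sum_i X_i' W y_i` with
#' `W = V^{-1}` for a marginal covariance `V` shared across subjects.
#'
#' @param design An [build_design()] result.
#' @param V q x q marginal covariance (defaults to the identity, in which
#'   case the estimate is ordinary least squares on the stacked data).
#' @return Named fixed-effect vector.
#' @export
gls_beta <- function(design, V = diag(design$q)) {
  W <- chol2inv(chol(V))
  comp <- gls_components(design_suffstats(design), W, design$k)
  qrA <- qr(comp$A)
  if (qrA$rank < design$k) {
    bad <- design$beta_names[qrA$pivot[(qrA$rank + 1L):design$k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- solve(comp$A, comp$c)
  names(beta) <- design$beta_names
  beta
}

#' Gaussian log-likelihood of the stacked model
#'
#' Evaluates sum_i -0.5 [ q log(2 pi) + log|V| + (y_i - X_i beta)'
#' V^{-1} (y_i - X_i beta) ] for a shared marginal covariance `V`.
#'
#' @param design An [build_design()] result.
#' @param beta Fixed-effect vector.
#' @param D,sigma2 Random-intercept covariance and error variances, used
#'   to assemble `V` via [marginal_covariance()] when `V` is not given.
#' @param V Optional explicit q x q covariance.
#' @return Scalar log-likelihood.
#' @export
mlmm_loglik <- function(design, beta, D = NULL, sigma2 = NULL, V = NULL) {
  if (is.null(V)) V <- marginal_covariance(D, sigma2, design$t)
  ch <- chol(V)
  W <- chol2inv(ch)
  suff <- design_suffstats(design)
  comp <- gls_components(suff, W, design$k)
  quad <- sum(W * suff$Syy) - 2 * sum(comp$c * beta) +
    sum(beta * (comp$A %*% beta))
  -0.5 * (design$n * design$q * log(2 * pi) +
            design$n * 2 * sum(log(diag(ch))) + quad)
}

## --- unconstrained parameterization: log-Cholesky for D, log for sigma2 ---
theta_dim <- function(p) p * (p + 1L) / 2L + p

theta_to_cov <- function(theta, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- theta[seq_len(p * (p + 1L) / 2L)]
  diag(L) <- exp(diag(L))
  list(D = L %*% t(L),
       sigma2 = exp(theta[p * (p + 1L) / 2L + seq_len(p)]))
}

cov_to_theta <- function(D, sigma2, p) {
  ev <- eigen(D, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-6 * max(mean(diag(D)), sigma2, 1e-8))
  Dp <- ev$vectors %*% (lam * t(ev$vectors))
  L <- t(chol(Dp))
  diag(L) <- log(diag(L))
  c(L[lower.tri(L, diag = TRUE)], log(pmax(sigma2, 1e-8)))
}

## moment starting values from OLS residuals
start_theta <- function(design) {
  beta0 <- gls_beta(design)
  E <- design$y - design_mean(design, beta0)
  p <- design$p
  S <- stats::cov(E)
  D0 <- matrix(0, p, p)
  s20 <- numeric(p)
  for (m in seq_len(p)) {
    a1 <- 2L * m - 1L; a2 <- 2L * m
    D0[m, m] <- S[a1, a2]
    s20[m] <- max(mean(c(S[a1, a1], S[a2, a2])) - D0[m, m],
                  0.05 * mean(c(S[a1, a1], S[a2, a2])))
    if (m > 1L) for (mm in seq_len(m - 1L)) {
      b1 <- 2L * mm - 1L; b2 <- 2L * mm
      D0[m, mm] <- D0[mm, m] <- mean(c(S[a1, b1], S[a1, b2],
                                       S[a2, b1], S[a2, b2]))
    }
  }
  diag(D0) <- pmax(diag(D0), 0.05 * diag(S)[seq(1, 2 * p, by = 2)])
  cov_to_theta(D0, s20, p)
}

#' Fit the multivariate longitudinal mixed model by maximum likelihood
#'
#' Maximizes the profiled Gaussian log-likelihood over an unconstrained
#' parameterization of the covariance parameters (log-Cholesky factor of
#' `D`, log error variances); the fixed effects are profiled out by GLS
#' at each covariance evaluation. Quasi-Newton (BFGS) from
#' moment-estimator starting values, with a Nelder-Mead polish if BFGS
#' reports non-convergence. Estimation is plain ML (not REML) because the
#' discriminant rule uses the ML objective.
#'
#' @param design An [build_design()] result (or a `cohort_table`, in
#'   which case `spec` is used to build the design).
#' @param spec A [model_spec()], used only when `design` is a table.
#' @param control List of optimizer options: `maxit` (default 500),
#'   `reltol` (1e-10).
#' @return An object of class `"mlmm_fit"`: `beta` (named), `D`,
#'   `sigma2`, `V` (fitted marginal covariance), `loglik`, `vcov_beta`,
#'   `converged`, `n_iter`, plus the spec and layout. Non-convergence is
#'   reported through `converged = FALSE`, never silently.
#' @export
mlmm_fit <- function(design, spec = model_spec(), control = list()) {
  if (!inherits(design, "mlmm_design")) design <- build_design(design, spec)
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)
  p <- design$p
  suff <- design_suffstats(design)
  const <- design$n * design$q * log(2 * pi)

  negll <- function(theta) {
    cv <- theta_to_cov(theta, p)
    V <- kronecker(cv$D, matrix(1, design$t, design$t)) +
      diag(rep(cv$sigma2, each = design$t), nrow = design$q)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    W <- chol2inv(ch)
    comp <- gls_components(suff, W, design$k)
    beta <- tryCatch(solve(comp$A, comp$c), error = function(e) NULL)
    if (is.null(beta)) return(1e10)
    quad <- sum(W * suff$Syy) - sum(comp$c * beta)
    0.5 * (const + design$n * 2 * sum(log(diag(ch))) + quad)
  }

  th0 <- start_theta(design)
  opt <- stats::optim(th0, negll, method = "BFGS",
                      control = list(maxit = ctrl$maxit,
                                     reltol = ctrl$reltol))
  n_iter <- opt$counts[["function"]]
  converged <- opt$convergence == 0L
  if (!converged) {
    opt2 <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = 5000L,
                                        reltol = ctrl$reltol))
    n_iter <- n_iter + opt2$counts[["function"]]
    if (opt2$value <= opt$value) opt <- opt2
    converged <- opt$convergence == 0L
  }

  cv <- theta_to_cov(opt$par, p)
  V <- marginal_covariance(cv$D, cv$sigma2, design$t)
  W <- chol2inv(chol(V))
  comp <- gls_components(suff, W, design$k)
  beta <- solve(comp$A, comp$c)
  names(beta) <- design$beta_names
  dimnames(cv$D) <- list(design$spec$markers, design$spec$markers)
  names(cv$sigma2) <- design$spec$markers
  structure(list(beta = beta, D = cv$D, sigma2 = cv$sigma2, V = V,
                 loglik = -opt$value, vcov_beta = solve(comp$A),
                 converged = converged, n_iter = n_iter,
                 spec = design$spec, layout = design$layout,
                 n = design$n, q = design$q, k = design$k, nt = design$nt,
                 theta = opt$par),
            class = "mlmm_fit")
}

#' @export
print.mlmm_fit <- function(x, ...) {
  cat(sprintf("Multivariate longitudinal mixed model: %d markers, n = %d, logLik = %.3f (%s)\n",
              length(x$spec$markers), x$n, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  cat("Random-intercept covariance D:\n")
  print(round(x$D, 4))
  cat("Error variances:\n")
  print(round(x$sigma2, 4))
  invisible(x)
}
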