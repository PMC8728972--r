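# Shared fixtures: everything is generated in code, no stored data.

# A tiny deterministic two-subject cohort (hand-written values).
manual_cohort_df <- function() {
  data.frame(
    subject_id = rep(c("A", "B"), each = 2),
    visit = c(1, 2, 1, 2),
    group = c(1, 1, 2, 2),
    hb = c(12.5, 11.9, 13.4, 12.6),
    hct = c(37.0, 35.5, 40.1, 37.2),
    fbs = c(84.0, 80.5, 93.2, 97.8),
    rbc = c(4.4, 4.1, 4.6, 4.2),
    age = c(27, 27, 31, 31),
    bmi = c(24.5, 29.1, 26.2, 31.0),
    sbp = c(101, 106, 103, 113),
    dbp = c(64, 66, 63, 70),
    parity = c(1, 1, 2, 2),
    education = rep(c("academic", "non-academic"), each = 2),
    stringsAsFactors = FALSE)
}

# Random symmetric positive-definite matrix.
rand_pd <- function(q) {
  A <- matrix(rnorm(q * q), q, q)
  crossprod(A) + diag(q) * 0.5
}

# Small calibrated cohort for fit-based tests.
small_cohort <- function(n = 200, seed = 11, prevalence = 0.25) {
  p <- default_cohort_params()
  p$prevalence <- prevalence   # richer minority class at small n
  generate_cohort(p, seed = seed, n_subjects = n)
}

# Ground truth with moderate effects for model-based simulation.
toy_truth <- function(markers = c("hb", "fbs")) {
  spec <- model_spec(markers = markers, covariates = c("age", "bmi"))
  nt <- length(spec$terms)  # intercept, group, time, age, bmi
  p <- length(markers)
  beta <- rep(c(10, 0.8, -0.5, 0.02, 0.01), p) *
    rep(seq_len(p), each = nt)
  D <- diag(0.4, p) + 0.1
  model_truth(beta, D, sigma2 = rep(0.5, p), spec = spec)
}
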