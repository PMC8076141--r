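# Shared fixtures: small one-factor toys and scaled-down cohort configs,
# all generated in code under fixed seeds.

# one factor, three indicators, one covariate; optionally a residual
# correlation between y1 and y2
toy_spec <- function(resid_cor = FALSE) {
  mimic_spec(
    indicators = c("y1", "y2", "y3"),
    factors = list(f = c("y1", "y2", "y3")),
    covariates = "x",
    structural = list(f = "x"),
    residual_correlations = if (resid_cor) list(c("y1", "y2")))
}

# data generated from the toy model; true parameters returned as attribute
gen_toy_data <- function(n, seed, lambda = c(0.8, 0.6, 1.0), gamma = 0.5,
                         theta = c(0.5, 0.7, 0.4), nu = c(0, -1, 2),
                         theta12 = 0, miss = c(0, 0, 0)) {
  set.seed(seed)
  x <- stats::rnorm(n)
  f <- gamma * x + stats::rnorm(n)
  Th <- diag(theta)
  Th[1, 2] <- Th[2, 1] <- theta12
  E <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(Th)
  Y <- sweep(outer(f, lambda) + E, 2L, nu, "+")
  colnames(Y) <- c("y1", "y2", "y3")
  for (j in 1:3)
    if (miss[j] > 0) Y[sample.int(n, miss[j]), j] <- NA
  out <- data.frame(Y, x = x)
  attr(out, "truth") <- list(lambda = lambda, gamma = gamma, theta = theta,
                             nu = nu, theta12 = theta12)
  out
}

# scaled-down cohort config with no missingness or artifacts (complete data)
complete_config <- function(n) {
  cfg <- scale_cohort_config(cohort_config(), n)
  cohort_config(
    n_total = cfg$n_total, stratum_counts = cfg$stratum_counts,
    zero_dose_count = cfg$zero_dose_count,
    expansion_counts = cfg$expansion_counts,
    missing_counts = stats::setNames(rep(0L, 14), indicator_names()),
    abi_high_counts = c(l = 0L, r = 0L), abi_low_counts = c(l = 0L, r = 0L),
    surgery_counts = c(carotid = 0L, peripheral = 0L, aorta = 0L))
}

# simulate, clean and rescale an analysis-ready cohort in one step
analysis_cohort <- function(seed, config = cohort_config(),
                            params = default_generating_parameters()) {
  coh <- simulate_cohort(config, params, seed = seed)
  rescale_indicators(apply_validity_filters(coh))
}

# closed-form multivariate normal log density (oracle; independent of the
# package's likelihood code)
dmvnorm_log <- function(y, mu, S) {
  p <- length(y)
  L <- chol(S)
  z <- backsolve(L, y - mu, transpose = TRUE)
  -0.5 * (p * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}
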