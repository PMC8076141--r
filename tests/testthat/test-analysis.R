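# Study-specific pipeline: final model structure, indirect effects,
# comparator, sensitivity switches.

test_that("the final model has the published structure", {
  sp <- atherosclerosis_spec()
  expect_equal(unname(colSums(sp$lambda_free)), c(4L, 2L, 8L))
  pairs <- apply(sp$theta_pairs, 1L, paste, collapse = ":")
  expect_setequal(pairs, c("ai:csbp", "imt_cca_l:imt_cca_r",
                           "abi_l:abi_r", "ut_l:ut_r"))
  expect_equal(sum(sp$kappa_free), 1L)
  expect_true(sp$kappa_free["ai", "female"])
  expect_equal(sum(sp$gamma_free), 21L)
})

test_that("indirect effects equal the derivative of the implied means", {
  coh <- analysis_cohort(seed = 81, config = complete_config(800))
  dat <- prepare_analysis_data(coh)
  fit <- fit_mimic(atherosclerosis_spec(), dat, se = FALSE)
  ie <- indirect_effects(fit)
  # finite-difference oracle on the implied means
  h <- 1e-6
  d1 <- dat[1, , drop = FALSE]
  d2 <- d1; d2$dose <- d2$dose + h
  num <- (predict(fit, d2) - predict(fit, d1)) / h
  sc <- vapply(fit$spec$indicators, mimicsem:::.natural_scale_factor,
               numeric(1))
  expect_equal(ie$effect_per_gy, unname(num[1, ] * sc), tolerance = 1e-6)
  # mediating factor bookkeeping
  expect_equal(ie$factor[ie$indicator == "abdominal_calc"], "calcification")
  # zero dose paths give zero indirect effects
  fit0 <- fit
  fit0$matrices$Gamma[, "dose"] <- 0
  expect_equal(indirect_effects(fit0)$effect_per_gy, rep(0, 14))
})

test_that("the comparator factorizes into per-indicator regressions and its
           joint likelihood matches the FIML engine", {
  coh <- analysis_cohort(seed = 82, config = scale_cohort_config(
    cohort_config(), 900))
  comp <- ordinary_regression(coh)
  expect_equal(nrow(comp), 14L)
  # dual route: rebuild the joint diagonal-covariance likelihood from the
  # per-indicator lm fits and evaluate it with the package's FIML kernel
  dat <- prepare_analysis_data(coh)
  Y <- as.matrix(dat[, indicator_names()])
  X <- as.matrix(dat[, setdiff(names(dat), indicator_names())])
  pats <- mimicsem:::prep_patterns(Y, X)
  C <- matrix(0, ncol(Y), ncol(X) + 1)
  rownames(C) <- colnames(Y)
  colnames(C) <- c("(Intercept)", colnames(X))
  v <- numeric(ncol(Y))
  covsets <- list(
    stiffness = c("dose", "age_c", "city", "distal", "city_distal"),
    calcification = c("dose", "age_c", "age_c2", "female", "city",
                      "distal", "city_distal", "smk_current", "smk_past"),
    plaque = c("dose", "age_c", "city", "distal", "city_distal",
               "smk_current", "smk_past"))
  spec <- atherosclerosis_spec()
  fac <- apply(spec$lambda_free, 1L, function(r) spec$factors[which(r)[1]])
  for (j in seq_len(ncol(Y))) {
    indn <- colnames(Y)[j]
    cs <- covsets[[fac[[indn]]]]
    if (indn == "ai") cs <- union(cs, "female")
    df <- dat[!is.na(dat[[indn]]), c(indn, cs)]
    m <- stats::lm(stats::reformulate(cs, indn), df)
    C[indn, c("(Intercept)", cs)] <- stats::coef(m)
    v[j] <- mean(stats::residuals(m)^2)
  }
  ll_engine <- mimicsem:::loglik_moments(pats, C, diag(v))
  expect_equal(ll_engine, attr(comp, "loglik"), tolerance = 1e-6)
})

test_that("sensitivity switches subset and transform as labeled", {
  coh <- analysis_cohort(seed = 83, config = scale_cohort_config(
    cohort_config(), 1200))
  n2 <- sum(coh$dose_weighted <= 2)
  expect_equal(n2, sum(scale_cohort_config(cohort_config(),
                                           1200)$stratum_counts[1:4]))
  sens <- sensitivity_analysis(coh, c("dose_le_2", "drop_expansion"))
  expect_equal(sens$dose_le_2$fit$n_used, n2)
  expect_equal(sens$drop_expansion$fit$n_used,
               sum(coh$subcohort != "expansion"))
  sq <- sensitivity_analysis(coh, "quadratic_dose")$quadratic_dose
  expect_true("gamma.calcification.dose2" %in% sq$std$name)
})

test_that("a quadratic dose term generated as zero is estimated near zero", {
  ests <- vapply(1:6, function(r) {
    coh <- analysis_cohort(seed = 900 + r,
                           config = complete_config(1000))
    sq <- sensitivity_analysis(coh, "quadratic_dose")$quadratic_dose
    sq$std$std[sq$std$name == "gamma.calcification.dose2"]
  }, numeric(1))
  expect_lt(abs(mean(ests)), 3 * stats::sd(ests) / sqrt(6) + 0.01)
})

test_that("log-scale generation analyzed on the log scale matches the
           linear analysis of linear-scale data", {
  # indicators generated multiplicatively, then log-transformed for the
  # sensitivity run: dose effects should be close to the linear-scale run
  coh <- analysis_cohort(seed = 84, config = complete_config(1500))
  rep_lin <- run_primary(coh, indices = FALSE)
  rep_log <- sensitivity_analysis(coh, "log_indicators")$log_indicators
  g_lin <- rep_lin$std$std[rep_lin$std$name == "gamma.plaque.dose"]
  g_log <- rep_log$std$std[rep_log$std$name == "gamma.plaque.dose"]
  expect_lt(abs(g_lin - g_log), 0.05)
})
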