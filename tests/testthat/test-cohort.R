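# Synthetic cohort generator: calibration, determinism, mechanism checks.

test_that("stratum sizes are exact and dose strata hit configured means", {
  cfg <- cohort_config()
  cov <- gen_covariates(cfg, seed = 1)
  expect_equal(unname(table(cov$stratum)), cfg$stratum_counts,
               ignore_attr = TRUE)
  expect_equal(nrow(cov), 3274L)
  expect_equal(sum(cov$dose_weighted == 0), cfg$zero_dose_count)
  expect_true(all(cov$dose_weighted <= cfg$max_dose))
  # distal participants only in the lowest dose stratum
  expect_true(all(cov$stratum[cov$location_atb == "distal"] == 1L))
  # weighted-dose convention is preserved by the gamma/neutron split
  expect_equal(weighted_dose(cov$dose_gamma, cov$dose_neutron),
               cov$dose_weighted, tolerance = 1e-12)
})

test_that("the grand mean dose converges to its calibrated value", {
  cfg <- cohort_config()
  means <- vapply(1:10, function(s)
    mean(gen_covariates(cfg, seed = s)$dose_weighted), numeric(1))
  target <- sum(cfg$stratum_counts * cfg$stratum_mean_doses) / cfg$n_total
  mc_se <- stats::sd(means) / sqrt(10)
  expect_lt(abs(mean(means) - target), 3 * mc_se + 1e-4)
  expect_lt(abs(target - 0.30), 0.005)
})

test_that("degenerate covariate proportions propagate exactly", {
  cfg <- cohort_config(prop_female = rep(1, 5))
  cov <- gen_covariates(cfg, seed = 2)
  expect_true(all(cov$sex == "female"))
})

test_that("generation is deterministic for a fixed seed", {
  a <- simulate_cohort(seed = 5)
  b <- simulate_cohort(seed = 5)
  expect_identical(a, b)
  raw1 <- assemble_raw_population(seed = 5)
  raw2 <- assemble_raw_population(seed = 5)
  expect_identical(raw1, raw2)
})

test_that("null generating parameters produce independent noise at the
           configured scale", {
  cfg <- complete_config(1500)
  pars <- default_generating_parameters()
  pars$loadings[] <- 0
  for (f in names(pars$structural)) pars$structural[[f]][] <- 0
  pars$residual_correlations <- lapply(pars$residual_correlations,
                                       function(rc) { rc$value <- 0; rc })
  pars$direct_effects <- list()
  cov <- gen_covariates(cfg, seed = 3)
  tab <- gen_outcomes(cov, pars, cfg, seed = 4)
  Y <- as.matrix(tab[, setdiff(indicator_names(),
                               c("thoracic_calc", "abdominal_calc"))])
  expect_equal(unname(colMeans(Y)),
               unname(cfg$indicator_means[colnames(Y)]), tolerance = 0.01)
  expect_equal(unname(apply(Y, 2, stats::sd)),
               unname(cfg$indicator_sds[colnames(Y)]), tolerance = 0.06)
  cors <- stats::cor(Y)
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(nrow(Y)) + 0.03)
})

test_that("left/right upstroke-time correlation matches the model-implied
           value", {
  cfg <- complete_config(3000)
  pars <- default_generating_parameters()
  cov <- gen_covariates(cfg, seed = 6)
  tab <- gen_outcomes(cov, pars, cfg, seed = 7)
  G <- attr(tab, "generating")
  A <- G$Lambda %*% G$Gamma + G$Kappa
  implied <- A %*% G$Sx %*% t(A) + G$Lambda %*% G$Psi %*% t(G$Lambda) +
    G$Theta
  r_implied <- implied["ut_l", "ut_r"] /
    sqrt(implied["ut_l", "ut_l"] * implied["ut_r", "ut_r"])
  r_sample <- stats::cor(tab$ut_l, tab$ut_r)
  expect_lt(abs(r_sample - r_implied), 3 / sqrt(nrow(tab)) + 0.01)
  # and the whole continuous block is model-faithful element-wise
  cont <- setdiff(indicator_names(), c("thoracic_calc", "abdominal_calc"))
  Yz <- scale(as.matrix(tab[, cont]))
  Rs <- stats::cor(as.matrix(tab[, cont]))
  Ri <- stats::cov2cor(implied[cont, cont])
  expect_lt(max(abs(Rs - Ri)), 3 / sqrt(nrow(tab)) + 0.04)
})

test_that("calcification discretization is monotone with a floor at zero", {
  x <- seq(-30, 40, by = 0.25)
  g3 <- pmin(pmax(round(x), 0), 3)
  g24 <- pmin(pmax(round(x), 0), 24)
  expect_true(all(diff(g3) >= 0))
  expect_true(all(diff(g24) >= 0))
  expect_equal(g24[x < -0.5], rep(0, sum(x < -0.5)))
  cfg <- cohort_config()
  tab <- gen_outcomes(gen_covariates(cfg, seed = 8), seed = 9)
  expect_true(all(tab$thoracic_calc %in% 0:3))
  expect_true(all(tab$abdominal_calc %in% 0:24))
})

test_that("missingness is imposed at exactly the configured counts", {
  cfg <- cohort_config()
  tab <- gen_outcomes(gen_covariates(cfg, seed = 10), seed = 11)
  raw <- impose_missingness_and_artifacts(tab, cfg, seed = 12)
  expect_equal(unname(colSums(is.na(raw[, indicator_names()]))),
               unname(cfg$missing_counts[indicator_names()]))
  # zero missingness leaves the table untouched
  cfg0 <- cohort_config(
    missing_counts = stats::setNames(rep(0L, 14), indicator_names()),
    abi_high_counts = c(l = 0L, r = 0L), abi_low_counts = c(l = 0L, r = 0L),
    surgery_counts = c(carotid = 0L, peripheral = 0L, aorta = 0L))
  raw0 <- impose_missingness_and_artifacts(tab, cfg0, seed = 12)
  expect_equal(raw0[, indicator_names()], tab[, indicator_names()])
  expect_error(
    impose_missingness_and_artifacts(
      tab[1:100, ], cohort_config(missing_counts = stats::setNames(
        c(5000L, rep(0L, 13)), indicator_names())), seed = 1),
    "exceed")
})

test_that("missingness depends on age under the MAR mechanism and not when
           the age slope is zero", {
  cfg <- cohort_config()
  tab <- gen_outcomes(gen_covariates(cfg, seed = 13), seed = 14)
  raw <- impose_missingness_and_artifacts(tab, cfg, seed = 15)
  expect_gt(mean(raw$age_exam[is.na(raw$bapwv_l)]),
            mean(raw$age_exam[!is.na(raw$bapwv_l)]))
  # null mechanism: chi-square association of missingness with an age split
  cfg0 <- cohort_config(mar_age_slope = 0)
  p <- vapply(1:8, function(r) {
    raw0 <- impose_missingness_and_artifacts(tab, cfg0, seed = 100 + r)
    old <- raw0$age_exam > stats::median(raw0$age_exam)
    suppressWarnings(stats::chisq.test(
      table(old, is.na(raw0$bapwv_l)))$p.value)
  }, numeric(1))
  expect_lte(sum(p < 0.05), 3)      # ~0.4 expected rejections out of 8
})

test_that("the invited population reproduces the exclusion arithmetic", {
  raw <- assemble_raw_population(seed = 16)
  expect_equal(nrow(raw), 4123L)
  el <- apply_eligibility(raw)
  log <- el$log
  expect_equal(log$excluded[log$reason == "refuser"], 247L)
  expect_equal(log$excluded[log$reason == "in_utero"], 321L)
  expect_equal(log$remaining[log$reason == "in_utero"], 3555L)
  expect_equal(log$excluded[log$reason == "missing_dose"], 273L)
  expect_equal(log$excluded[log$reason == "missing_smoking"], 8L)
  expect_equal(nrow(el$cohort), 3274L)
  # the invited minus excluded arithmetic reconciles line by line
  expect_equal(log$remaining[1] - sum(log$excluded), nrow(el$cohort))
})
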