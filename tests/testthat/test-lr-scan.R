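test_that("freeing a parameter never decreases the log-likelihood and a
           truly nonzero residual correlation ranks first", {
  dat <- gen_toy_data(800, seed = 61, theta12 = 0.35)
  fit <- fit_mimic(toy_spec(), dat, se = FALSE)
  cands <- list(
    list(type = "residual_correlation", indicator1 = "y1",
         indicator2 = "y2"),
    list(type = "residual_correlation", indicator1 = "y1",
         indicator2 = "y3"),
    list(type = "residual_correlation", indicator1 = "y2",
         indicator2 = "y3"))
  scan <- lr_scan(fit, cands)
  expect_true(all(scan$delta_chi2 >= -1e-6))
  expect_equal(scan$candidate[1], "y1:y2")
  expect_lt(scan$p[1], 1e-4)
})

test_that("null candidates give chi-square(1)-scale improvements", {
  sp <- toy_spec()
  d2 <- vapply(1:25, function(r) {
    dat <- gen_toy_data(400, seed = 800 + r)  # theta12 = 0 truth
    fit <- fit_mimic(sp, dat, se = FALSE)
    lr_scan(fit, list(list(type = "residual_correlation",
                           indicator1 = "y1",
                           indicator2 = "y2")))$delta_chi2
  }, numeric(1))
  # mean of a chi-square(1) is 1; loose 3-sigma band for 25 draws
  expect_lt(abs(mean(d2) - 1), 3 * sqrt(2 / 25) + 0.3)
})

test_that("already-free candidates are skipped with a note", {
  dat <- gen_toy_data(200, seed = 62, theta12 = 0.2)
  fit <- fit_mimic(toy_spec(resid_cor = TRUE), dat, se = FALSE)
  scan <- lr_scan(fit, list(
    list(type = "residual_correlation", indicator1 = "y1",
         indicator2 = "y2"),
    list(type = "residual_correlation", indicator1 = "y2",
         indicator2 = "y3")))
  expect_equal(attr(scan, "skipped"), "y1:y2")
  expect_equal(nrow(scan), 1L)
})

test_that("the wald option reports an estimate and its asymptotic test", {
  dat <- gen_toy_data(600, seed = 63, theta12 = 0.3)
  fit <- fit_mimic(toy_spec(), dat, se = FALSE)
  scan <- lr_scan(fit, list(list(type = "residual_correlation",
                                 indicator1 = "y1", indicator2 = "y2")),
                  wald = TRUE)
  expect_true(is.finite(scan$estimate) && is.finite(scan$se))
  # LR and Wald p-values agree to an order of magnitude on strong effects
  expect_lt(scan$p_wald, 0.01)
  expect_gt(scan$estimate, 0.1)
})
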