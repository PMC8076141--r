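# Methods-section derivations, exclusions, validity filters, rescaling.

test_that("weighted dose is gamma plus ten times neutron", {
  expect_equal(weighted_dose(1.0, 0.1), 2.0)
  expect_equal(weighted_dose(0, 0), 0)
  expect_equal(weighted_dose(0.5, 0), 0.5)
  expect_equal(weighted_dose(c(1, 0.5), c(0.1, 0)), c(2.0, 0.5))
  expect_error(weighted_dose(-0.1, 0), "non-negative")
})

test_that("smoking classification honors the examination window", {
  h <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(year = m[, 1], smoking = as.logical(m[, 2]))
  }
  expect_equal(classify_smoking(h(2012, 1)), "current")
  expect_equal(classify_smoking(h(1970, 1, 2011, 0)), "past")
  expect_equal(classify_smoking(h(1970, 1, 2012, 1)), "current")
  expect_equal(classify_smoking(h(1980, 0, 2013, 0)), "never")
  expect_equal(classify_smoking(data.frame(year = numeric(0),
                                           smoking = logical(0))), "never")
  expect_equal(classify_smoking(NULL), "never")
  expect_error(classify_smoking(h(1950, 1)), "1963-2014")
})

test_that("abdominal score sums eight region grades", {
  expect_equal(abdominal_score(rep(3, 8)), 24L)
  expect_equal(abdominal_score(rep(0, 8)), 0L)
  expect_equal(abdominal_score(c(1, 0, 2, 0, 0, 3, 0, 0)), 6L)
  expect_error(abdominal_score(c(1, 0, 2, 0, 0, 4, 0, 0)), "0-3")
  expect_error(abdominal_score(rep(1, 7)), "eight")
})

test_that("validity filters mask side-specifically and idempotently", {
  coh <- simulate_cohort(seed = 71)
  coh$abi_l[1] <- 1.45
  coh$abi_l[2] <- 0.85; coh$bapwv_l[2] <- 17
  coh$abi_r[2] <- 1.10; coh$bapwv_r[2] <- 18
  out <- apply_validity_filters(coh)
  expect_true(is.na(out$abi_l[1]))
  expect_false(is.na(out$abi_r[1]))
  expect_true(is.na(out$bapwv_l[2]))
  expect_equal(out$abi_l[2], 0.85)   # low ABI retained, baPWV masked
  expect_equal(out$bapwv_r[2], 18)
  expect_equal(nrow(out), nrow(coh))
  # idempotent: reapplication changes nothing
  expect_identical(apply_validity_filters(out)[, indicator_names()],
                   out[, indicator_names()])
})

test_that("surgery masks exactly the measurements the site can affect", {
  coh <- simulate_cohort(seed = 72)
  i_car <- which(coh$surgery_carotid)[1]
  i_per <- which(coh$surgery_peripheral)[1]
  i_aor <- which(coh$surgery_aorta)[1]
  out <- apply_validity_filters(coh)
  imt <- c("imt_cca_l", "imt_cca_r", "imt_ica_l", "imt_ica_r")
  hemo <- c("abi_l", "abi_r", "ut_l", "ut_r", "bapwv_l", "bapwv_r",
            "ai", "csbp")
  expect_true(all(is.na(out[i_car, imt])))
  expect_true(all(is.na(out[i_per, hemo])))
  expect_true(all(is.na(out[i_aor, c(hemo, "thoracic_calc",
                                     "abdominal_calc")])))
  # carotid surgery leaves the hemodynamic block as it was
  expect_equal(unlist(out[i_car, hemo]), unlist(coh[i_car, hemo]))
})

test_that("rescaling multiplies ABI by 10, round-trips, and flags double
           application", {
  coh <- simulate_cohort(seed = 73)
  coh$abi_l[5] <- 1.13
  coh$abi_r[6] <- NA
  out <- rescale_indicators(coh)
  expect_equal(out$abi_l[5], 11.3)
  expect_true(is.na(out$abi_r[6]))
  expect_equal(out$bapwv_l, coh$bapwv_l)  # m/s input is already the
                                          # fitting scale
  expect_error(rescale_indicators(out), "already")
  back <- inverse_rescale(out)
  expect_equal(back$abi_l, coh$abi_l, tolerance = 1e-12)
  # cm/s ingestion divides baPWV by 100
  coh_cm <- coh
  coh_cm$bapwv_l <- coh$bapwv_l * 100
  coh_cm$bapwv_r <- coh$bapwv_r * 100
  out_cm <- rescale_indicators(coh_cm, bapwv_unit = "cm_s")
  expect_equal(out_cm$bapwv_l, coh$bapwv_l, tolerance = 1e-12)
})

test_that("eligibility on an unflagged cohort is the identity with an
           empty log", {
  coh <- simulate_cohort(seed = 74)
  el <- apply_eligibility(coh)
  expect_equal(nrow(el$cohort), nrow(coh))
  expect_equal(sum(el$log$excluded), 0L)
})

test_that("filtering order is stable: eligibility, validity, rescale", {
  raw <- assemble_raw_population(seed = 75)
  a <- rescale_indicators(apply_validity_filters(apply_eligibility(raw)$cohort))
  # validity before eligibility gives the same analyzed table because the
  # two touch disjoint records/conditions
  b0 <- apply_validity_filters(raw)
  b <- rescale_indicators(apply_eligibility(b0)$cohort)
  expect_equal(a[, indicator_names()], b[, indicator_names()])
})
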