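#' Build the structural-model covariate matrix from a cohort table
#'
#' Coding conventions: \code{female} = 1 for women; \code{city} = 1 for
#' Nagasaki (Hiroshima reference); \code{distal} = 1 for location > 3 km at
#' the time of the bombing; \code{city_distal} their product; smoking enters
#' as two dummies with never-smoker as reference.  Age is centered at the
#' sample mean (or a supplied center) and the quadratic term is computed
#' after centering, so the centering choice affects only intercepts.
#'
#' @param cohort data frame with columns \code{dose_weighted},
#'   \code{age_exam}, \code{sex}, \code{city}, \code{location_atb},
#'   \code{smoking}.
#' @param age_center optional centering constant for age; defaults to the
#'   sample mean of \code{age_exam}.
#' @return data frame of numeric covariate columns \code{dose},
#'   \code{age_c}, \code{age_c2}, \code{female}, \code{city}, \code{distal},
#'   \code{city_distal}, \code{smk_current}, \code{smk_past}; the centering
#'   constant is attached as attribute \code{age_center}.
#' @export
build_covariates <- function(cohort, age_center = NULL) {
  if (is.null(age_center)) age_center <- mean(cohort$age_exam)
  age_c <- cohort$age_exam - age_center
  city <- as.numeric(cohort$city == "nagasaki")
  distal <- as.numeric(cohort$location_atb == "distal")
  out <- data.frame(
    dose = cohort$dose_weighted,
    age_c = age_c,
    age_c2 = age_c^2,
    female = as.numeric(cohort$sex == "female"),
    city = city,
    distal = distal,
    city_distal = city * distal,
    smk_current = as.numeric(cohort$smoking == "current"),
    smk_past = as.numeric(cohort$smoking == "past"))
  attr(out, "age_center") <- age_center
  out
}

#' Names of the 14 atherosclerosis indicators
#'
#' Column order used throughout: left/right brachial-ankle pulse wave
#' velocity, augmentation index, central systolic blood pressure, thoracic
#' and abdominal aortic calcification scores, left/right common and internal
#' carotid intima-media thickness, left/right ankle-brachial index,
#' left/right upstroke time.
#' @return character vector of length 14.
#' @export
indicator_names <- function() c(
  "bapwv_l", "bapwv_r", "ai", "csbp",
  "thoracic_calc", "abdominal_calc",
  "imt_cca_l", "imt_cca_r", "imt_ica_l", "imt_ica_r",
  "abi_l", "abi_r", "ut_l", "ut_r")
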