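# Cohort preparation: derivations, eligibility exclusions, validity
# filters, surgery masking and indicator rescaling.

#' Weighted radiation dose
#'
#' Combines gamma and neutron skin-dose components into the weighted dose
#' used throughout: gamma plus ten times the (smaller) neutron dose.
#'
#' @param gamma gamma-ray dose in Gy (non-negative).
#' @param neutron neutron dose in Gy (non-negative).
#' @return weighted dose in Gy (vectorized).
#' @export
weighted_dose <- function(gamma, neutron) {
  if (any(gamma < 0, na.rm = TRUE) || any(neutron < 0, na.rm = TRUE))
    stop("dose components must be non-negative")
  gamma + 10 * neutron
}

#' Classify smoking status from an interview history
#'
#' \code{current}: any positive report during the examination window
#' (2010-2014); \code{past}: any positive report in 1963-2010 but none in
#' the examination window; \code{never} otherwise.  An empty history is
#' classified as \code{never}.
#'
#' @param history data frame with columns \code{year} (1963-2014) and
#'   \code{smoking} (logical: smoking reported at that contact).
#' @return one of \code{"never"}, \code{"current"}, \code{"past"}.
#' @export
classify_smoking <- function(history) {
  if (is.null(history) || nrow(history) == 0L) return("never")
  stopifnot(all(c("year", "smoking") %in% names(history)))
  if (any(history$year < 1963 | history$year > 2014))
    stop("history years must lie in 1963-2014")
  pos <- history$year[history$smoking]
  if (any(pos >= 2010)) "current"
  else if (length(pos) > 0) "past"
  else "never"
}

#' Total abdominal aortic calcification score
#'
#' Sum of the eight per-region grades (anterior and posterior walls at
#' vertebral levels L1-L4), each graded 0-3.
#'
#' @param grades numeric vector of 8 grades, each in \{0, 1, 2, 3\}.
#' @return integer score in 0-24.
#' @export
abdominal_score <- function(grades) {
  if (length(grades) != 8L) stop("eight region grades are required")
  if (!all(grades %in% 0:3)) stop("grades must be integers in 0-3")
  as.integer(sum(grades))
}

#' Apply eligibility exclusions
#'
#' Removes, in order: known hemodialysis (pre-invitation), refusers,
#' in-utero exposed, then records with missing radiation dose and records
#' with missing smoking information.  The returned log reconciles the
#' invited count with the analyzed count.
#'
#' @param raw invited-population table
#'   (\code{\link{assemble_raw_population}}).
#' @return list with \code{cohort} (analyzed table) and \code{log}
#'   (data frame of exclusion reasons, counts, and remaining sizes; excluded
#'   ids attached as attribute \code{ids}).
#' @export
apply_eligibility <- function(raw) {
  steps <- list(
    hemodialysis = function(d) isTRUE_v(d$hemodialysis, nrow(d)),
    refuser = function(d) isTRUE_v(d$refuser, nrow(d)),
    in_utero = function(d) isTRUE_v(d$in_utero, nrow(d)),
    missing_dose = function(d) is.na(d$dose_weighted),
    missing_smoking = function(d) is.na(d$smoking))
  log <- data.frame(reason = character(0), excluded = integer(0),
                    remaining = integer(0), stringsAsFactors = FALSE)
  ids <- list()
  d <- raw
  for (nm in names(steps)) {
    drop <- steps[[nm]](d)
    ids[[nm]] <- d$id[drop]
    d <- d[!drop, , drop = FALSE]
    log <- rbind(log, data.frame(reason = nm, excluded = sum(drop),
                                 remaining = nrow(d)))
  }
  log <- rbind(data.frame(reason = "invited", excluded = 0L,
                          remaining = nrow(raw)), log)
  attr(log, "ids") <- ids
  rownames(d) <- NULL
  list(cohort = d, log = log)
}

isTRUE_v <- function(x, n) if (is.null(x)) rep(FALSE, n) else x %in% TRUE

#' Apply measurement validity filters and surgery masking
#'
#' Side-specific masking to missing, in place: an ankle-brachial index above
#' 1.4 is considered invalid and masked; a measured same-side ABI below 0.9
#' invalidates that side's pulse wave velocity (the ABI itself is retained).
#' The baPWV rule keys on the measured, pre-mask ABI value; the two ABI
#' rules act on opposite tails so they never conflict.  Prior vascular
#' surgery masks the measurements the surgery could affect: carotid surgery
#' masks the four intima-media thickness values; peripheral-artery surgery
#' masks ABI, upstroke time, baPWV, augmentation index and central systolic
#' pressure; aortic surgery masks those plus both calcification scores.
#' Masking never un-masks and is idempotent.
#'
#' @param cohort analyzed cohort table.
#' @return the cohort with invalid entries set to missing; per-rule masking
#'   counts attached as attribute \code{validity_log}.
#' @export
apply_validity_filters <- function(cohort) {
  log <- c()
  for (side in c("l", "r")) {
    abi <- cohort[[paste0("abi_", side)]]
    hi <- !is.na(abi) & abi > 1.4
    lo <- !is.na(abi) & abi < 0.9
    cohort[[paste0("abi_", side)]][hi] <- NA_real_
    cohort[[paste0("bapwv_", side)]][lo] <- NA_real_
    log[paste0("abi_high_", side)] <- sum(hi)
    log[paste0("bapwv_low_abi_", side)] <- sum(lo)
  }
  mask <- function(rows, cols) {
    for (j in cols) cohort[rows, j] <<- NA_real_
  }
  imt <- c("imt_cca_l", "imt_cca_r", "imt_ica_l", "imt_ica_r")
  hemo <- c("abi_l", "abi_r", "ut_l", "ut_r", "bapwv_l", "bapwv_r",
            "ai", "csbp")
  if (!is.null(cohort$surgery_carotid)) {
    mask(which(cohort$surgery_carotid), imt)
    mask(which(cohort$surgery_peripheral), hemo)
    mask(which(cohort$surgery_aorta),
         c(hemo, "thoracic_calc", "abdominal_calc"))
    log["surgery_carotid"] <- sum(cohort$surgery_carotid)
    log["surgery_peripheral"] <- sum(cohort$surgery_peripheral)
    log["surgery_aorta"] <- sum(cohort$surgery_aorta)
  }
  attr(cohort, "validity_log") <- log
  cohort
}

#' Rescale indicators to the model-fitting scale
#'
#' The ankle-brachial index is multiplied by 10 and brachial-ankle pulse
#' wave velocity is put on its fitting scale (values recorded in cm/s are
#' divided by 100; values already in m/s are numerically unchanged), so all
#' indicator variances are of comparable magnitude for the optimizer.
#' Missing values stay missing.  A scale flag guards against double
#' application; \code{inverse_rescale} restores the natural scale.
#'
#' @param cohort analyzed cohort table.
#' @param bapwv_unit unit in which baPWV columns are recorded.
#' @return rescaled cohort with attribute \code{rescaled = TRUE}.
#' @export
rescale_indicators <- function(cohort, bapwv_unit = c("m_s", "cm_s")) {
  bapwv_unit <- match.arg(bapwv_unit)
  if (isTRUE(attr(cohort, "rescaled")))
    stop("indicators are already on the fitting scale")
  cohort$abi_l <- cohort$abi_l * 10
  cohort$abi_r <- cohort$abi_r * 10
  if (bapwv_unit == "cm_s") {
    cohort$bapwv_l <- cohort$bapwv_l / 100
    cohort$bapwv_r <- cohort$bapwv_r / 100
  }
  attr(cohort, "rescaled") <- TRUE
  cohort
}

#' @rdname rescale_indicators
#' @export
inverse_rescale <- function(cohort, bapwv_unit = c("m_s", "cm_s")) {
  bapwv_unit <- match.arg(bapwv_unit)
  if (!isTRUE(attr(cohort, "rescaled")))
    stop("cohort is not on the fitting scale")
  cohort$abi_l <- cohort$abi_l / 10
  cohort$abi_r <- cohort$abi_r / 10
  if (bapwv_unit == "cm_s") {
    cohort$bapwv_l <- cohort$bapwv_l * 100
    cohort$bapwv_r <- cohort$bapwv_r * 100
  }
  attr(cohort, "rescaled") <- NULL
  cohort
}

# multiplicative factor taking a fitting-scale indicator effect back to
# natural units
.natural_scale_factor <- function(indicator) {
  if (indicator %in% c("abi_l", "abi_r")) 1 / 10 else 1
}
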