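# Synthetic cohort generator calibrated to the study's descriptive moments
# and fitted model structure.

#' Default synthetic-cohort configuration
#'
#' Encodes the cohort composition the generator reproduces: five radiation
#' dose strata with their sizes and mean doses (point mass at zero dose in
#' the lowest stratum), per-stratum sex/city/location/smoking proportions,
#' the two-sub-cohort age/dose mixture (a younger expansion sub-cohort with
#' low doses and an older primary sub-cohort), per-indicator natural-scale
#' means and SDs, per-indicator missing-value counts, data-entry artifact
#' counts (out-of-range ankle-brachial index values), vascular-surgery
#' counts by site, and the pre-analysis exclusion categories (refusers,
#' in-utero exposed, missing dose, missing smoking).
#'
#' @param n_total analyzed cohort size.
#' @param ... replacement values for any top-level element (see
#'   \code{str(cohort_config())}).
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_total = 3274L, ...) {
  cfg <- list(
    n_total = as.integer(n_total),
    # dose strata: lower bounds (Gy), exact sizes, within-stratum mean dose
    stratum_lower = c(0, 0.005, 0.5, 1, 2),
    stratum_upper = c(0.005, 0.5, 1, 2, 4.84),
    stratum_counts = c(1163L, 1529L, 251L, 229L, 102L),
    stratum_mean_doses = c(0.001, 0.116, 0.720, 1.36, 3.09),
    zero_dose_count = 381L,   # exact-zero doses within the lowest stratum
    max_dose = 4.84,
    # per-stratum covariate proportions
    prop_female = c(0.600, 0.561, 0.649, 0.581, 0.569),
    prop_hiroshima = c(0.494, 0.751, 0.558, 0.524, 0.696),
    prop_distal = c(894 / 1163, 0, 0, 0, 0),
    prop_smoking = rbind(
      never   = c(0.591, 0.570, 0.625, 0.568, 0.549),
      current = c(0.083, 0.098, 0.080, 0.083, 0.020),
      past    = c(0.326, 0.332, 0.295, 0.349, 0.431)),
    # sub-cohort mixture inducing age-dose confounding
    expansion_counts = c(710L, 943L, 32L, 15L, 3L), # per stratum
    age_mean_expansion = 70.8,
    age_mean_primary = 78.3,
    age_sd_within = 4.94,     # solved so the pooled age SD is 6.2
    age_range = c(60, 95),
    age_exposure_offset = 67, # age at exam minus age at exposure
    # indicator marginals on the natural scale.  For the two calcification
    # scores these are the moments of the continuous latent score that is
    # rounded and clamped to the grade range.  The thoracic pair (grades
    # 0-3) was solved once so the discretized grades reproduce the target
    # grade-scale moments 1.12/0.81 exactly.  For the abdominal score
    # (0-24) no continuous normal both reproduces the zero-heavy target
    # moments 4.71/5.04 after clamping and keeps the score's covariance
    # with the other indicators linear (matching the target SD forces a
    # large continuous mass below zero, whose clamping distorts the
    # covariance structure the estimator consumes); the generator keeps
    # the target mean and shrinks the continuous SD to 3.3, a frozen
    # compromise that leaves ~6% of mass clamped at zero and keeps the
    # measurement model covariance-faithful.
    indicator_means = c(
      bapwv_l = 18.4, bapwv_r = 18.3, ai = 87.5, csbp = 140.6,
      thoracic_calc = 1.095641, abdominal_calc = 4.71,
      imt_cca_l = 1.11, imt_cca_r = 1.08, imt_ica_l = 1.71,
      imt_ica_r = 1.77, abi_l = 1.13, abi_r = 1.14,
      ut_l = 145.0, ut_r = 144.9),
    indicator_sds = c(
      bapwv_l = 3.8, bapwv_r = 3.9, ai = 11.4, csbp = 20.1,
      thoracic_calc = 0.815822, abdominal_calc = 3.3,
      imt_cca_l = 0.43, imt_cca_r = 0.36, imt_ica_l = 0.90,
      imt_ica_r = 0.97, abi_l = 0.080, abi_r = 0.084,
      ut_l = 25.1, ut_r = 24.7),
    missing_counts = c(
      bapwv_l = 370L, bapwv_r = 365L, ai = 191L, csbp = 236L,
      thoracic_calc = 109L, abdominal_calc = 76L,
      imt_cca_l = 53L, imt_cca_r = 46L, imt_ica_l = 160L,
      imt_ica_r = 109L, abi_l = 311L, abi_r = 315L,
      ut_l = 331L, ut_r = 334L),
    mar_age_slope = 0.08,     # log-odds of missingness per year of age
    # measurement artifacts and surgery flags among analyzed participants
    abi_high_counts = c(l = 4L, r = 6L),   # ABI > 1.4 (invalid)
    abi_low_counts = c(l = 39L, r = 31L),  # ABI < 0.9 (invalidates baPWV)
    surgery_counts = c(carotid = 5L, peripheral = 16L, aorta = 21L),
    # pre-analysis exclusion categories
    exclusions = c(hemodialysis = 0L, refuser = 247L, in_utero = 321L,
                   missing_dose = 273L, missing_smoking = 8L))
  cfg <- utils::modifyList(cfg, list(...))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with(config, {
    if (sum(stratum_counts) != n_total)
      stop("stratum counts must sum to n_total")
    if (any(indicator_sds <= 0)) stop("indicator SDs must be positive")
    if (any(missing_counts > n_total)) stop("missing counts exceed n_total")
    props <- c(prop_female, prop_hiroshima, prop_distal, prop_smoking)
    if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
    if (any(abs(colSums(prop_smoking) - 1) > 1e-8))
      stop("smoking proportions must sum to 1 per stratum")
    if (any(expansion_counts > stratum_counts))
      stop("expansion counts exceed stratum counts")
    if (zero_dose_count > stratum_counts[1])
      stop("zero-dose count exceeds the lowest stratum")
    # uniform-with-matched-mean dose law must stay inside stratum bounds
    upper_implied <- 2 * stratum_mean_doses[-1] - stratum_lower[-1]
    if (any(upper_implied <= stratum_lower[-1]) ||
        any(upper_implied > pmin(stratum_upper[-1], max_dose) + 1e-12))
      stop("stratum mean incompatible with stratum bounds")
  })
  invisible(config)
}

#' Scale a cohort configuration to a different size
#'
#' Rescales all count-valued configuration entries (stratum sizes, zero-dose
#' point mass, sub-cohort allocation, missing counts, artifact, surgery and
#' exclusion counts) proportionally to a new analyzed-cohort size, keeping
#' proportions and distributional settings unchanged.  Used for scaled-down
#' simulation studies.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param n_total new analyzed cohort size.
#' @return a \code{cohort_config} for the new size.
#' @export
scale_cohort_config <- function(config, n_total) {
  f <- n_total / config$n_total
  sc <- as.integer(round(config$stratum_counts * f))
  sc[which.max(sc)] <- sc[which.max(sc)] + (as.integer(n_total) - sum(sc))
  cohort_config(
    n_total = n_total,
    stratum_counts = sc,
    zero_dose_count = min(as.integer(round(config$zero_dose_count * f)),
                          sc[1]),
    expansion_counts = pmin(as.integer(round(config$expansion_counts * f)),
                            sc),
    missing_counts = vapply(config$missing_counts,
                            function(k) as.integer(round(k * f)),
                            integer(1)),
    abi_high_counts = round(config$abi_high_counts * f),
    abi_low_counts = round(config$abi_low_counts * f),
    surgery_counts = round(config$surgery_counts * f),
    exclusions = round(config$exclusions * f))
}

#' Default generating parameters for synthetic outcomes
#'
#' Standardized-scale parameter values to which the generator is calibrated:
#' loadings of the 14 indicators on the three latent atherosclerotic factors
#' (arterial stiffness, calcification, plaque), factor residual
#' correlations, residual correlations among indicator pairs, structural
#' coefficients of the covariates on the factors (per unit covariate, in
#' factor-SD units), and the direct effect of sex on augmentation index.
#' The reference per-factor \eqn{R^2} values and dose-coefficient
#' confidence intervals reported for the emulated cohort are included for
#' use by the E-value sensitivity analysis.
#'
#' @param ... replacement values for any top-level element.
#' @return object of class \code{generating_parameters}.
#' @export
default_generating_parameters <- function(...) {
  par <- list(
    factor_map = c(
      bapwv_l = "stiffness", bapwv_r = "stiffness", ai = "stiffness",
      csbp = "stiffness",
      thoracic_calc = "calcification", abdominal_calc = "calcification",
      imt_cca_l = "plaque", imt_cca_r = "plaque", imt_ica_l = "plaque",
      imt_ica_r = "plaque", abi_l = "plaque", abi_r = "plaque",
      ut_l = "plaque", ut_r = "plaque"),
    loadings = c(
      bapwv_l = 0.98, bapwv_r = 0.97, ai = 0.11, csbp = 0.42,
      thoracic_calc = 0.48, abdominal_calc = 0.84,
      imt_cca_l = 0.39, imt_cca_r = 0.43, imt_ica_l = 0.64,
      imt_ica_r = 0.67, abi_l = -0.21, abi_r = -0.24,
      ut_l = 0.40, ut_r = 0.42),
    factor_correlations = c(stiffness.calcification = 0.24,
                            stiffness.plaque = 0.08,
                            calcification.plaque = 0.65),
    residual_correlations = list(
      list(pair = c("ai", "csbp"), value = 0.47),
      list(pair = c("imt_cca_l", "imt_cca_r"), value = 0.30),
      list(pair = c("abi_l", "abi_r"), value = 0.66),
      list(pair = c("ut_l", "ut_r"), value = 0.80)),
    structural = list(
      stiffness = c(dose = 0.036, age_c = 0.074, city = 0.017,
                    distal = -0.094, city_distal = 0.17),
      calcification = c(dose = 0.15, age_c = 0.062, age_c2 = 0.001,
                        female = 0.19, city = -0.18, distal = 0.11,
                        city_distal = -0.085, smk_current = 0.47,
                        smk_past = 0.54),
      plaque = c(dose = 0.11, age_c = 0.057, city = -0.50,
                 distal = 0.083, city_distal = -0.003,
                 smk_current = 0.48, smk_past = 0.63)),
    direct_effects = list(list(covariate = "female", indicator = "ai",
                               value = 0.78)),
    reference_r2 = c(stiffness = 0.21, calcification = 0.27, plaque = 0.28),
    reference_dose_ci = list(
      calcification = c(estimate = 0.15, lower = 0.070, upper = 0.23),
      plaque = c(estimate = 0.11, lower = 0.029, upper = 0.20),
      stiffness = c(estimate = 0.036, lower = -0.025, upper = 0.095)))
  par <- utils::modifyList(par, list(...))
  class(par) <- "generating_parameters"
  par
}

#' Generate cohort covariates
#'
#' Draws the analyzed-cohort covariate table: dose stratum sizes are exact;
#' doses within a stratum follow a uniform law rescaled to the stratum mean
#' (with a point mass of exact zeros in the lowest stratum); the weighted
#' dose is decomposed into gamma and neutron components under the
#' gamma + 10 x neutron convention; sub-cohort membership (expansion vs
#' primary) is allocated per stratum and drives the age mixture; sex, city,
#' location and smoking are drawn from per-stratum proportions; distal
#' participants occur only in the lowest dose stratum.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @param counts optional per-stratum sizes overriding the configured ones.
#' @return covariate data frame, one row per participant.
#' @export
gen_covariates <- function(config, seed = 1L,
                           counts = config$stratum_counts) {
  validate_cohort_config(config)
  set.seed(seed)
  n <- sum(counts)
  stratum <- rep(seq_along(counts), counts)
  dose <- numeric(n)
  for (s in seq_along(counts)) {
    idx <- which(stratum == s)
    ns <- length(idx)
    if (ns == 0L) next
    if (s == 1L) {
      nz <- round(config$zero_dose_count * ns / config$stratum_counts[1])
      nz <- min(nz, ns)
      mean_nonzero <- if (ns > nz)
        config$stratum_mean_doses[1] * ns / (ns - nz) else 0
      d <- c(rep(0, nz), stats::runif(ns - nz, 0, 2 * mean_nonzero))
      dose[idx] <- sample(d)
    } else {
      lo <- config$stratum_lower[s]
      hi <- 2 * config$stratum_mean_doses[s] - lo
      dose[idx] <- stats::runif(ns, lo, hi)
    }
  }
  dose <- pmin(dose, config$max_dose)

  # sub-cohort allocation (scaled if counts differ from the configured ones)
  expansion <- logical(n)
  for (s in seq_along(counts)) {
    idx <- which(stratum == s)
    ne <- round(config$expansion_counts[s] * length(idx) /
                  config$stratum_counts[s])
    expansion[sample(idx, min(ne, length(idx)))] <- TRUE
  }
  age_mean <- ifelse(expansion, config$age_mean_expansion,
                     config$age_mean_primary)
  age <- stats::rnorm(n, age_mean, config$age_sd_within)
  age <- pmin(pmax(age, config$age_range[1]), config$age_range[2])

  ps <- function(v) v[stratum]
  sex <- ifelse(stats::runif(n) < ps(config$prop_female), "female", "male")
  city <- ifelse(stats::runif(n) < ps(config$prop_hiroshima),
                 "hiroshima", "nagasaki")
  location <- ifelse(stats::runif(n) < ps(config$prop_distal),
                     "distal", "proximal")
  u <- stats::runif(n)
  p_never <- ps(config$prop_smoking["never", ])
  p_current <- ps(config$prop_smoking["current", ])
  smoking <- ifelse(u < p_never, "never",
                    ifelse(u < p_never + p_current, "current", "past"))

  data.frame(
    id = sprintf("S%05d", seq_len(n)),
    subcohort = ifelse(expansion, "expansion", "primary"),
    stratum = stratum,
    age_exam = age,
    age_exposure = pmax(age - config$age_exposure_offset, 0),
    sex = sex, city = city, location_atb = location, smoking = smoking,
    dose_gamma = 0.98 * dose,
    dose_neutron = 0.002 * dose,
    dose_weighted = dose,
    stringsAsFactors = FALSE)
}

# Solve the unstandardized generating matrices implied by standardized-scale
# parameters and a realized covariate sample (identification: factor
# residual variances 1, unit total indicator variance before scaling).
.generating_matrices <- function(params, X) {
  ind <- indicator_names()
  fac <- c("stiffness", "calcification", "plaque")
  p <- length(ind); m <- length(fac); q <- ncol(X)
  Sx <- stats::cov(X) * (nrow(X) - 1) / nrow(X)

  Gamma_std <- matrix(0, m, q, dimnames = list(fac, colnames(X)))
  for (f in fac) {
    g <- params$structural[[f]]
    Gamma_std[f, names(g)] <- g
  }
  a <- diag(Gamma_std %*% Sx %*% t(Gamma_std))  # implied factor R^2
  if (any(a >= 1))
    stop("structural coefficients imply factor R^2 >= 1")
  var_f <- 1 / (1 - a)
  sd_f <- sqrt(var_f)
  Gamma <- Gamma_std * sd_f              # row-wise scale to natural factors

  Psi <- diag(m); dimnames(Psi) <- list(fac, fac)
  fc <- params$factor_correlations
  for (nm in names(fc)) {
    pr <- strsplit(nm, ".", fixed = TRUE)[[1]]
    Psi[pr[1], pr[2]] <- Psi[pr[2], pr[1]] <- fc[[nm]]
  }

  Lambda <- matrix(0, p, m, dimnames = list(ind, fac))
  for (j in ind)
    Lambda[j, params$factor_map[[j]]] <-
      params$loadings[[j]] / sd_f[params$factor_map[[j]]]

  Kappa <- matrix(0, p, q, dimnames = list(ind, colnames(X)))
  for (de in params$direct_effects)
    Kappa[de$indicator, de$covariate] <- de$value

  A <- Lambda %*% Gamma + Kappa
  h <- diag(A %*% Sx %*% t(A) + Lambda %*% Psi %*% t(Lambda))
  theta_diag <- 1 - h
  if (any(theta_diag <= 0.005))
    stop("generating parameters leave no residual indicator variance")
  Theta <- diag(theta_diag); dimnames(Theta) <- list(ind, ind)
  for (rc in params$residual_correlations) {
    i <- rc$pair[1]; j <- rc$pair[2]
    Theta[i, j] <- Theta[j, i] <-
      rc$value * sqrt(theta_diag[i] * theta_diag[j])
  }
  list(Lambda = Lambda, Psi = Psi, Gamma = Gamma, Kappa = Kappa,
       Theta = Theta, var_f = var_f, Sx = Sx)
}

#' Generate complete indicator outcomes
#'
#' Draws latent factors from the structural model (correlated factor
#' residuals with unit variance) and indicators from the measurement model
#' (loadings, direct effects, correlated measurement residuals) on a
#' unit-variance scale, then maps each indicator to its natural units.
#' The two aortic calcification indicators are discretized by fixed
#' thresholds (round and clamp of the continuous score) to grades 0-3
#' (thoracic) and scores 0-24 (abdominal).
#'
#' @param covariates covariate table from \code{\link{gen_covariates}}.
#' @param params a \code{\link{default_generating_parameters}} object.
#' @param config a \code{\link{cohort_config}} (indicator scale map).
#' @param seed integer seed.
#' @return the covariate table with 14 complete indicator columns appended;
#'   the unstandardized generating matrices are attached as attribute
#'   \code{generating}.
#' @export
gen_outcomes <- function(covariates, params = default_generating_parameters(),
                         config = cohort_config(), seed = 1L) {
  set.seed(seed)
  X <- as.matrix(build_covariates(covariates))
  G <- .generating_matrices(params, X)
  n <- nrow(X); p <- nrow(G$Lambda); m <- ncol(G$Lambda)
  ind <- rownames(G$Lambda)

  Fmat <- X %*% t(G$Gamma) + matrix(stats::rnorm(n * m), n, m) %*% chol(G$Psi)
  Ystd <- Fmat %*% t(G$Lambda) + X %*% t(G$Kappa) +
    matrix(stats::rnorm(n * p), n, p) %*% chol(G$Theta)
  colnames(Ystd) <- ind

  mu <- config$indicator_means[ind]
  sd <- config$indicator_sds[ind]
  Y <- sweep(sweep(Ystd, 2L, colMeans(Ystd)), 2L, sd, "*")
  Y <- sweep(Y, 2L, mu, "+")
  Y[, "thoracic_calc"] <- pmin(pmax(round(Y[, "thoracic_calc"]), 0), 3)
  Y[, "abdominal_calc"] <- pmin(pmax(round(Y[, "abdominal_calc"]), 0), 24)
  # keep strictly non-negative physiological measurements
  for (j in c("imt_cca_l", "imt_cca_r", "imt_ica_l", "imt_ica_r"))
    Y[, j] <- pmax(Y[, j], 0.05)

  out <- cbind(covariates, as.data.frame(Y))
  attr(out, "generating") <- G
  out
}

#' Impose missingness and measurement artifacts
#'
#' Masks each indicator in exactly the configured number of records through
#' a missing-at-random mechanism: records are selected by weighted sampling
#' without replacement with weights logistic in age (older participants are
#' more likely to have missing measurements), so missingness depends only on
#' an always-observed covariate.  Afterwards the configured numbers of
#' out-of-range ankle-brachial index values (ABI > 1.4; ABI < 0.9) are
#' injected among observed values, and vascular-surgery flags are assigned.
#'
#' @param table complete cohort table from \code{\link{gen_outcomes}}.
#' @param config a \code{\link{cohort_config}}.
#' @param seed integer seed.
#' @return the table with missing values, artifact values, surgery flag
#'   columns (\code{surgery_carotid}, \code{surgery_peripheral},
#'   \code{surgery_aorta}) and exclusion flag columns (all \code{FALSE}).
#' @export
impose_missingness_and_artifacts <- function(table, config = cohort_config(),
                                             seed = 1L) {
  set.seed(seed)
  n <- nrow(table)
  ind <- indicator_names()
  scale_counts <- n / config$n_total
  w <- stats::plogis(config$mar_age_slope *
                       (table$age_exam - mean(table$age_exam)))
  for (j in ind) {
    k <- round(config$missing_counts[[j]] * scale_counts)
    if (k > n) stop("requested missing count exceeds cohort size for ", j)
    if (k > 0) table[sample.int(n, k, prob = w), j] <- NA_real_
  }
  for (side in c("l", "r")) {
    col <- paste0("abi_", side)
    obs <- which(!is.na(table[[col]]))
    k_hi <- round(config$abi_high_counts[[side]] * scale_counts)
    k_lo <- round(config$abi_low_counts[[side]] * scale_counts)
    pick <- sample(obs, min(k_hi + k_lo, length(obs)))
    hi <- pick[seq_len(min(k_hi, length(pick)))]
    lo <- setdiff(pick, hi)
    table[hi, col] <- stats::runif(length(hi), 1.41, 1.60)
    table[lo, col] <- stats::runif(length(lo), 0.60, 0.89)
  }
  for (site in c("carotid", "peripheral", "aorta"))
    table[[paste0("surgery_", site)]] <- FALSE
  free <- seq_len(n)
  for (site in c("carotid", "peripheral", "aorta")) {
    k <- round(config$surgery_counts[[site]] * scale_counts)
    pick <- sample(free, min(k, length(free)))
    table[[paste0("surgery_", site)]][pick] <- TRUE
    free <- setdiff(free, pick)
  }
  table$refuser <- FALSE
  table$in_utero <- FALSE
  table$hemodialysis <- FALSE
  table
}

#' Assemble the full invited population
#'
#' Builds the invited-population table: the analyzed records (with outcomes,
#' missingness and artifacts) plus the configured counts of refusers
#' (no measurements), in-utero exposed, records with missing radiation dose
#' and records with missing smoking information.  Eligibility filtering
#' (\code{\link{apply_eligibility}}) recovers the analyzed cohort.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param params generating parameters.
#' @param seed integer seed.
#' @return data frame with one row per invited participant, rows in a
#'   seed-determined shuffle.
#' @export
assemble_raw_population <- function(config = cohort_config(),
                                    params = default_generating_parameters(),
                                    seed = 1L) {
  ex <- config$exclusions
  # analyzed records plus the dose/smoking-excluded ones carry outcomes
  n_out <- config$n_total + ex[["missing_dose"]] + ex[["missing_smoking"]]
  counts <- round(config$stratum_counts * n_out / config$n_total)
  counts[1] <- counts[1] + (n_out - sum(counts))
  cov <- gen_covariates(config, seed = seed, counts = counts)
  tab <- gen_outcomes(cov, params, config, seed = seed + 1L)
  tab <- impose_missingness_and_artifacts(tab, config, seed = seed + 2L)
  set.seed(seed + 3L)
  idx <- sample.int(nrow(tab))
  i_dose <- idx[seq_len(ex[["missing_dose"]])]
  i_smk <- idx[ex[["missing_dose"]] + seq_len(ex[["missing_smoking"]])]
  tab$dose_weighted[i_dose] <- NA_real_
  tab$dose_gamma[i_dose] <- NA_real_
  tab$dose_neutron[i_dose] <- NA_real_
  tab$smoking[i_smk] <- NA_character_

  # refusers and in-utero exposed: covariates only, no measurements
  n_extra <- ex[["refuser"]] + ex[["in_utero"]] + ex[["hemodialysis"]]
  if (n_extra > 0) {
    counts_e <- pmax(round(config$stratum_counts * n_extra / config$n_total), 0L)
    counts_e[1] <- counts_e[1] + (n_extra - sum(counts_e))
    cov_e <- gen_covariates(config, seed = seed + 4L, counts = counts_e)
    for (j in indicator_names()) cov_e[[j]] <- NA_real_
    for (site in c("carotid", "peripheral", "aorta"))
      cov_e[[paste0("surgery_", site)]] <- FALSE
    cov_e$refuser <- FALSE; cov_e$in_utero <- FALSE
    cov_e$hemodialysis <- FALSE
    lab <- rep(c("refuser", "in_utero", "hemodialysis"),
               times = ex[c("refuser", "in_utero", "hemodialysis")])
    set.seed(seed + 5L)
    lab <- sample(lab)
    cov_e$refuser <- lab == "refuser"
    cov_e$in_utero <- lab == "in_utero"
    cov_e$hemodialysis <- lab == "hemodialysis"
    tab <- rbind(tab, cov_e[, names(tab)])
  }
  set.seed(seed + 6L)
  tab <- tab[sample.int(nrow(tab)), ]
  tab$id <- sprintf("P%05d", seq_len(nrow(tab)))
  rownames(tab) <- NULL
  tab
}

#' Simulate an analyzed cohort in one call
#'
#' Convenience wrapper: covariates, outcomes, missingness and artifacts for
#' the analyzed cohort only (no excluded records).
#'
#' @inheritParams assemble_raw_population
#' @return cohort data frame ready for \code{\link{apply_validity_filters}}.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            params = default_generating_parameters(),
                            seed = 1L) {
  cov <- gen_covariates(config, seed = seed)
  tab <- gen_outcomes(cov, params, config, seed = seed + 1L)
  impose_missingness_and_artifacts(tab, config, seed = seed + 2L)
}
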