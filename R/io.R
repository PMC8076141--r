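# Plain-text serialization: cohort CSV (with seed header), configuration
# and model-spec YAML, tidy estimate CSV.

#' Read and write cohort tables
#'
#' Cohorts are stored as CSV with missing values as empty fields and an
#' optional leading comment line recording the generator seed
#' (\code{# seed: <n>}).
#'
#' @param cohort cohort data frame.
#' @param path file path.
#' @param seed optional integer recorded in the header.
#' @export
write_cohort <- function(cohort, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(cohort, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @return \code{read_cohort}: the cohort data frame, with the recorded
#'   seed (if any) as attribute \code{seed}.
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1L)
  seed <- NULL
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    m <- regmatches(first, regexec("seed:\\s*(\\d+)", first))[[1]]
    if (length(m) == 2) seed <- as.integer(m[2])
  }
  out <- utils::read.csv(path, skip = skip, na.strings = "",
                         stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}

#' Serialize a model specification
#'
#' Writes the free-parameter structure (factor-indicator map, structural
#' paths, residual-correlation pairs, direct effects) as YAML; the
#' counterpart reader reconstructs an identical \code{mimic_spec}.
#'
#' @param spec a \code{mimic_spec}.
#' @param path file path.
#' @export
write_model_spec <- function(spec, path) {
  a <- spec$args
  yaml::write_yaml(list(
    indicators = a$indicators,
    factors = a$factors,
    covariates = a$covariates,
    structural = a$structural,
    residual_correlations = if (nrow(spec$theta_pairs))
      apply(spec$theta_pairs, 1L, as.list) else NULL,
    direct_effects = if (!is.null(a$direct_effects))
      lapply(.as_pairs(a$direct_effects) |>
               apply(1L, identity, simplify = FALSE), as.list) else NULL
  ), path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  y <- yaml::read_yaml(path)
  rc <- if (!is.null(y$residual_correlations))
    lapply(y$residual_correlations, unlist)
  de <- if (!is.null(y$direct_effects)) lapply(y$direct_effects, unlist)
  mimic_spec(unlist(y$indicators), lapply(y$factors, unlist),
             unlist(y$covariates), lapply(y$structural, unlist), rc, de)
}

#' Export fitted estimates as tidy CSV
#'
#' One row per free parameter with unstandardized and standardized
#' estimates and, when a bootstrap is supplied, percentile interval limits
#' for both scales.
#'
#' @param report a \code{mimic_report} (or a \code{mimic_fit}).
#' @param path file path.
#' @export
write_estimates <- function(report, path) {
  tab <- estimates_table(report)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @return \code{estimates_table}: the tidy data frame itself.
#' @export
estimates_table <- function(report) {
  if (inherits(report, "mimic_fit"))
    report <- list(std = standardized_solution(report), boot = NULL)
  std <- report$std
  tab <- data.frame(parameter = std$name, block = std$block,
                    estimate = std$estimate, std = std$std,
                    lower = NA_real_, upper = NA_real_,
                    std_lower = NA_real_, std_upper = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(report$boot)) {
    ci <- report$boot$ci
    i <- match(tab$parameter, ci$name)
    tab$lower <- ci$lower[i]; tab$upper <- ci$upper[i]
    j <- match(paste0("std.", tab$parameter), ci$name)
    tab$std_lower <- ci$lower[j]; tab$std_upper <- ci$upper[j]
  }
  tab
}

#' @rdname cohort_config
#' @param path file path for the YAML configuration.
#' @export
write_cohort_config <- function(config, path) {
  u <- unclass(config)
  u$prop_smoking <- as.list(as.data.frame(t(config$prop_smoking)))
  # named vectors must become maps, not sequences, to keep their names
  named <- vapply(u, function(v) !is.null(names(v)), logical(1))
  u[named] <- lapply(u[named], as.list)
  yaml::write_yaml(u, path)
  invisible(path)
}

#' @rdname cohort_config
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  sm <- t(vapply(y$prop_smoking, unlist, numeric(5)))
  base <- cohort_config()
  y$prop_smoking <- NULL
  y <- lapply(y, function(v) if (is.list(v)) unlist(v) else v)
  # integer-valued fields come back as plain numerics; re-coerce
  cfg <- utils::modifyList(unclass(base), y)
  cfg$prop_smoking <- base$prop_smoking
  cfg$prop_smoking[] <- sm[rownames(base$prop_smoking), ]
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}
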