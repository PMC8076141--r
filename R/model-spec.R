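#' Specify a MIMIC structural equation model
#'
#' A MIMIC (multiple indicators, multiple causes) model relates observed
#' covariates to latent factors through a linear structural model, and the
#' latent factors to observed indicators through a linear measurement model:
#' \deqn{\eta_i = \Gamma x_i + \zeta_i, \qquad
#'       y_i = \nu + \Lambda \eta_i + K x_i + \epsilon_i,}
#' with \eqn{\zeta \sim N(0, \Psi)} and \eqn{\epsilon \sim N(0, \Theta)}.
#' For identification the factor residual variances (the diagonal of
#' \eqn{\Psi}) are fixed at 1, so the free off-diagonal entries of
#' \eqn{\Psi} are factor residual correlations.
#'
#' @param indicators character vector of indicator (column) names.
#' @param factors named list; each element is a character vector naming the
#'   indicators that load on that factor (free loadings).
#' @param covariates character vector of covariate column names.
#' @param structural named list mapping each factor to the covariates with a
#'   free structural path into it; covariates not listed are fixed to zero.
#' @param residual_correlations optional 2-column character matrix (or list of
#'   length-2 vectors) of indicator pairs with a free residual covariance.
#' @param direct_effects optional 2-column character matrix (or list of
#'   length-2 vectors) of (covariate, indicator) pairs with a free direct path.
#'
#' @return An object of class \code{mimic_spec} describing the pattern of free
#'   and fixed parameters.  Free parameters are ordered: loadings, factor
#'   residual correlations, structural coefficients, direct effects,
#'   intercepts, residual variances, residual covariances.
#' @export
mimic_spec <- function(indicators, factors, covariates,
                       structural = NULL,
                       residual_correlations = NULL,
                       direct_effects = NULL) {
  stopifnot(is.character(indicators), length(indicators) >= 1,
            is.list(factors), length(factors) >= 1,
            is.character(covariates))
  p <- length(indicators)
  m <- length(factors)
  q <- length(covariates)
  fnames <- names(factors)
  if (is.null(fnames) || any(fnames == ""))
    stop("'factors' must be a fully named list")

  lambda_free <- matrix(FALSE, p, m, dimnames = list(indicators, fnames))
  for (f in fnames) {
    ind <- factors[[f]]
    if (!all(ind %in% indicators)) stop("unknown indicator in factor ", f)
    lambda_free[ind, f] <- TRUE
  }
  if (any(colSums(lambda_free) == 0))
    stop("every factor needs at least one free loading")

  gamma_free <- matrix(FALSE, m, q, dimnames = list(fnames, covariates))
  if (!is.null(structural)) {
    for (f in names(structural)) {
      if (!f %in% fnames) stop("unknown factor in structural: ", f)
      cv <- structural[[f]]
      if (!all(cv %in% covariates)) stop("unknown covariate for factor ", f)
      gamma_free[f, cv] <- TRUE
    }
  }

  kappa_free <- matrix(FALSE, p, q, dimnames = list(indicators, covariates))
  if (!is.null(direct_effects)) {
    de <- .as_pairs(direct_effects)
    for (k in seq_len(nrow(de))) {
      if (!de[k, 1] %in% covariates || !de[k, 2] %in% indicators)
        stop("direct effect must be (covariate, indicator)")
      kappa_free[de[k, 2], de[k, 1]] <- TRUE
    }
  }

  theta_pairs <- matrix(character(0), 0, 2)
  if (!is.null(residual_correlations)) {
    theta_pairs <- .as_pairs(residual_correlations)
    if (!all(theta_pairs %in% indicators))
      stop("unknown indicator in residual_correlations")
  }

  spec <- structure(list(
    indicators = indicators, factors = fnames, covariates = covariates,
    p = p, m = m, q = q,
    lambda_free = lambda_free, gamma_free = gamma_free,
    kappa_free = kappa_free, theta_pairs = theta_pairs,
    args = list(indicators = indicators, factors = factors,
                covariates = covariates, structural = structural,
                residual_correlations = residual_correlations,
                direct_effects = direct_effects)
  ), class = "mimic_spec")
  spec$par_table <- .par_table(spec)
  spec
}

.as_pairs <- function(x) {
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("pairs must have two columns")
  x
}

# Enumerate free parameters in canonical order with C++ target codes.
# targets: 0 Lambda, 1 Psi off-diag (Fisher-z), 2 Gamma, 3 Kappa, 4 nu,
#          5 log Theta diagonal, 6 Theta off-diagonal.
.par_table <- function(spec) {
  rows <- list()
  add <- function(target, i, j, name, block)
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, row = i - 1L, col = j - 1L,
      name = name, block = block, stringsAsFactors = FALSE)
  for (f in seq_len(spec$m)) for (i in seq_len(spec$p))
    if (spec$lambda_free[i, f])
      add(0L, i, f, paste0("lambda.", spec$indicators[i], ".", spec$factors[f]),
          "loading")
  if (spec$m > 1)
    for (i in seq_len(spec$m - 1)) for (j in seq(i + 1, spec$m))
      add(1L, i, j, paste0("psi.", spec$factors[i], ".", spec$factors[j]),
          "factor_correlation")
  for (f in seq_len(spec$m)) for (j in seq_len(spec$q))
    if (spec$gamma_free[f, j])
      add(2L, f, j, paste0("gamma.", spec$factors[f], ".", spec$covariates[j]),
          "structural")
  for (i in seq_len(spec$p)) for (j in seq_len(spec$q))
    if (spec$kappa_free[i, j])
      add(3L, i, j, paste0("kappa.", spec$indicators[i], ".", spec$covariates[j]),
          "direct")
  for (i in seq_len(spec$p))
    add(4L, i, 1L, paste0("nu.", spec$indicators[i]), "intercept")
  for (i in seq_len(spec$p))
    add(5L, i, i, paste0("theta.", spec$indicators[i]), "residual_variance")
  if (nrow(spec$theta_pairs) > 0)
    for (k in seq_len(nrow(spec$theta_pairs))) {
      i <- match(spec$theta_pairs[k, 1], spec$indicators)
      j <- match(spec$theta_pairs[k, 2], spec$indicators)
      ij <- sort(c(i, j))
      add(6L, ij[1], ij[2],
          paste0("theta.", spec$indicators[ij[1]], ".", spec$indicators[ij[2]]),
          "residual_covariance")
    }
  do.call(rbind, rows)
}

#' @export
print.mimic_spec <- function(x, ...) {
  cat("MIMIC model specification\n")
  cat(sprintf("  indicators: %d, factors: %d, covariates: %d\n",
              x$p, x$m, x$q))
  cat(sprintf("  free parameters: %d (%s)\n", nrow(x$par_table),
              paste(sprintf("%s %d", names(table(x$par_table$block)),
                            as.integer(table(x$par_table$block))),
                    collapse = ", ")))
  invisible(x)
}

#' Number of free parameters in a specification
#' @param spec a \code{mimic_spec}.
#' @return integer count of free parameters.
#' @export
n_free_params <- function(spec) nrow(spec$par_table)

# C++ model descriptor: fixed base matrices plus the free-parameter table.
.cpp_model <- function(spec) {
  list(p = spec$p, m = spec$m, q = spec$q,
       Lambda0 = matrix(0, spec$p, spec$m),
       Psi0 = diag(spec$m),
       Gamma0 = matrix(0, spec$m, spec$q),
       Kappa0 = matrix(0, spec$p, spec$q),
       Theta0 = diag(spec$p),
       nu0 = numeric(spec$p),
       free_tab = as.matrix(spec$par_table[, c("target", "row", "col")]))
}

# Transform natural-scale values to the unconstrained optimizer scale.
.to_unconstrained <- function(spec, values) {
  tr <- spec$par_table$target
  out <- values
  out[tr == 1L] <- atanh(values[tr == 1L])
  out[tr == 5L] <- log(values[tr == 5L])
  out
}

# Inverse transform: optimizer scale back to natural scale.
.to_natural <- function(spec, theta) {
  tr <- spec$par_table$target
  out <- theta
  out[tr == 1L] <- tanh(theta[tr == 1L])
  out[tr == 5L] <- exp(theta[tr == 5L])
  names(out) <- spec$par_table$name
  out
}

# Jacobian diagonal d(natural)/d(theta), for delta-method standard errors.
.transform_jacobian <- function(spec, theta) {
  tr <- spec$par_table$target
  j <- rep(1, length(theta))
  j[tr == 1L] <- 1 / cosh(theta[tr == 1L])^2
  j[tr == 5L] <- exp(theta[tr == 5L])
  j
}

#' Expand a parameter vector into model matrices
#'
#' @param spec a \code{mimic_spec}.
#' @param theta free-parameter vector on the unconstrained optimizer scale
#'   (log residual variances, Fisher-z factor correlations).
#' @return list with \code{Lambda}, \code{Psi}, \code{Gamma}, \code{Kappa},
#'   \code{nu}, \code{Theta} on the natural scale.
#' @export
unpack_params <- function(spec, theta) {
  M <- .cpp_model(spec)
  Lambda <- M$Lambda0; Psi <- M$Psi0; Gamma <- M$Gamma0
  Kappa <- M$Kappa0; nu <- M$nu0; Theta <- M$Theta0
  pt <- spec$par_table
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L; j <- pt$col[k] + 1L; v <- theta[k]
    switch(as.character(pt$target[k]),
      "0" = Lambda[i, j] <- v,
      "1" = Psi[i, j] <- Psi[j, i] <- tanh(v),
      "2" = Gamma[i, j] <- v,
      "3" = Kappa[i, j] <- v,
      "4" = nu[i] <- v,
      "5" = Theta[i, i] <- exp(v),
      "6" = Theta[i, j] <- Theta[j, i] <- v)
  }
  dimnames(Lambda) <- list(spec$indicators, spec$factors)
  dimnames(Psi) <- list(spec$factors, spec$factors)
  dimnames(Gamma) <- list(spec$factors, spec$covariates)
  dimnames(Kappa) <- list(spec$indicators, spec$covariates)
  names(nu) <- spec$indicators
  dimnames(Theta) <- list(spec$indicators, spec$indicators)
  list(Lambda = Lambda, Psi = Psi, Gamma = Gamma, Kappa = Kappa,
       nu = nu, Theta = Theta)
}

# Pack natural-scale matrices into a theta vector (inverse of unpack_params);
# used by the synthetic generator and for warm starts.
pack_params <- function(spec, mats) {
  pt <- spec$par_table
  vals <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L; j <- pt$col[k] + 1L
    vals[k] <- switch(as.character(pt$target[k]),
      "0" = mats$Lambda[i, j],
      "1" = mats$Psi[i, j],
      "2" = mats$Gamma[i, j],
      "3" = mats$Kappa[i, j],
      "4" = mats$nu[i],
      "5" = mats$Theta[i, i],
      "6" = mats$Theta[i, j])
  }
  .to_unconstrained(spec, vals)
}
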