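#' Fit a MIMIC model by full-information maximum likelihood
#'
#' Maximizes the observed-data Gaussian likelihood (FIML) of a MIMIC model by
#' quasi-Newton (BFGS) optimization on an unconstrained parameterization
#' (log residual variances, Fisher-z factor residual correlations).
#' Indicators are standardized internally for optimizer conditioning and
#' estimates are returned on the input scale.  Records with no observed
#' indicator are dropped (and counted); covariates must be complete.
#'
#' Latent factor residual variances are fixed at 1 for identification, so
#' factor scale is set by the covariate model, and each factor's sign is
#' normalized so that its first free loading is positive.
#'
#' @param spec a \code{\link{mimic_spec}}.
#' @param data data frame with the spec's indicator and covariate columns.
#' @param start optional warm start: a natural-scale matrix list as returned
#'   by \code{unpack_params} (e.g. \code{fitted$matrices}).
#' @param se logical; compute the observed-information covariance matrix of
#'   the estimates (numerical Hessian).  Skipping it (\code{se = FALSE})
#'   speeds up simulation studies and bootstrap replicates.
#' @param control list passed to \code{\link[stats]{optim}} (\code{maxit},
#'   \code{reltol}).
#' @return An object of class \code{mimic_fit}: estimates (natural scale),
#'   model matrices, log-likelihood, degrees of freedom, convergence report,
#'   covariance matrix of estimates (if requested), and the model frame
#'   moments needed for standardization and bootstrap.
#' @seealso \code{\link{standardized_solution}}, \code{\link{fit_indices}},
#'   \code{\link{bootstrap_ci}}
#' @export
fit_mimic <- function(spec, data, start = NULL, se = TRUE,
                      control = list()) {
  stopifnot(inherits(spec, "mimic_spec"))
  miss_cols <- setdiff(c(spec$indicators, spec$covariates), names(data))
  if (length(miss_cols))
    stop("data lacks columns: ", paste(miss_cols, collapse = ", "))
  Y <- as.matrix(data[, spec$indicators, drop = FALSE])
  X <- as.matrix(data[, spec$covariates, drop = FALSE])
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  n <- nrow(Y)

  # internal indicator standardization (observed-value moments)
  a <- colMeans(Y, na.rm = TRUE)
  s <- apply(Y, 2L, stats::sd, na.rm = TRUE)
  s[!is.finite(s) | s <= 0] <- 1
  Yz <- sweep(sweep(Y, 2L, a), 2L, s, "/")
  pats <- prep_patterns(Yz, X)
  cppm <- .cpp_model(spec)

  theta0 <- if (is.null(start)) .start_values(spec, Yz, X)
            else pack_params(spec, .rescale_mats(spec, start, a, s))

  negll <- function(th) -fiml_loglik_cpp(cppm, pats, th)
  grad <- function(th) -fiml_grad_cpp(cppm, pats, th)
  gnorm <- function(th) sqrt(sum(fiml_grad_cpp(cppm, pats, th)^2))
  tol_g <- max(1, 1e-3 * n)
  ctrl <- utils::modifyList(list(maxit = 1000L, reltol = 1e-12,
                                 restarts = 8L), control)
  restarts <- ctrl$restarts
  ctrl$restarts <- NULL
  # BFGS with restarts: a restart resets the Hessian approximation, which
  # recovers from stalls near the admissibility boundary; a stall with a
  # large gradient additionally shrinks all correlation-type parameters
  # toward zero (deterministically) before re-optimizing
  corr_idx <- spec$par_table$target %in% c(1L, 6L)
  run_opt <- function(th0) {
    opt <- stats::optim(th0, negll, grad, method = "BFGS", control = ctrl)
    for (r in seq_len(restarts)) {
      if (gnorm(opt$par) < tol_g) break
      opt2 <- stats::optim(opt$par, negll, grad, method = "BFGS",
                           control = ctrl)
      if (opt2$value >= opt$value - 1e-8 && gnorm(opt2$par) >= tol_g) {
        th <- opt2$par
        th[corr_idx] <- 0.5 * th[corr_idx]
        opt3 <- stats::optim(th, negll, grad, method = "BFGS",
                             control = ctrl)
        opt <- if (opt3$value < opt2$value) opt3 else opt2
      } else opt <- opt2
    }
    opt
  }
  opt <- run_opt(theta0)
  if (gnorm(opt$par) >= tol_g && is.null(start)) {
    alt <- run_opt(.start_values_simple(spec, Yz))
    if (alt$value < opt$value) opt <- alt
  }
  theta <- .fix_factor_signs(spec, opt$par)
  ll_int <- -negll(theta)

  # log-likelihood correction for the internal rescaling of indicators
  n_obs_j <- colSums(!is.na(Y))
  ll <- ll_int - sum(n_obs_j * log(s))

  mats_int <- unpack_params(spec, theta)
  mats <- .unscale_mats(spec, mats_int, a, s)
  est <- .to_natural(spec, pack_params(spec, mats))

  vc <- NULL
  if (se) {
    H <- fiml_hess_cpp(cppm, pats, theta)
    J <- .transform_jacobian(spec, theta) * .scale_factors(spec, s)
    vc <- tryCatch({
      vth <- solve(-H)
      vn <- diag(J) %*% vth %*% diag(J)
      dimnames(vn) <- list(spec$par_table$name, spec$par_table$name)
      vn
    }, error = function(e) {
      warning("observed information not invertible: ", conditionMessage(e))
      NULL
    })
  }

  grad_norm <- sqrt(sum(fiml_grad_cpp(cppm, pats, theta)^2))
  Sx <- stats::cov(X) * (n - 1) / n

  structure(list(
    spec = spec, estimates = est, matrices = mats, theta = theta,
    loglik = ll, n_used = n, n_dropped = sum(!keep),
    n_params = length(theta),
    df_model = .n_moments(spec) - length(theta),
    vcov = vc,
    convergence = list(
      code = if (is.finite(grad_norm) && grad_norm < tol_g)
        opt$convergence else 1L,
      counts = opt$counts, grad_norm = grad_norm),
    Sx = Sx, x_means = colMeans(X),
    y_scale = list(center = a, scale = s),
    model_frame = data.frame(Y, X, check.names = FALSE)
  ), class = "mimic_fit")
}

.n_moments <- function(spec)
  spec$p * (spec$q + 1L) + spec$p * (spec$p + 1L) / 2L

# default starting values: loadings from each factor's sum-score proxy
# (covariance of the indicator with the row mean of its factor's indicator
# block), residual variances at the complementary share, intercepts at
# sample means, all correlations/regressions at zero
.start_values <- function(spec, Yz, X) {
  pt <- spec$par_table
  v <- numeric(nrow(pt))
  mz <- colMeans(Yz, na.rm = TRUE)
  lam0 <- matrix(0, spec$p, spec$m)
  for (f in seq_len(spec$m)) {
    block <- which(spec$lambda_free[, f])
    s <- rowMeans(Yz[, block, drop = FALSE], na.rm = TRUE)
    s[!is.finite(s)] <- NA
    sdp <- stats::sd(s, na.rm = TRUE)
    for (j in block) {
      l <- stats::cov(Yz[, j], s, use = "pairwise.complete.obs") /
        max(sdp, 1e-3)
      if (!is.finite(l)) l <- 0.7
      lam0[j, f] <- max(min(l, 0.95), -0.95)
    }
  }
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L; j <- pt$col[k] + 1L
    v[k] <- switch(as.character(pt$target[k]),
      "0" = lam0[i, j],
      "4" = mz[i],
      "5" = log(max(1 - sum(lam0[i, ]^2), 0.2)),
      0)
  }
  v
}

# flip each factor's sign so its first free loading is positive
# fallback start: loadings at the indicator sample SD, residual variances
# at half the sample variance, everything else at zero
.start_values_simple <- function(spec, Yz) {
  pt <- spec$par_table
  v <- numeric(nrow(pt))
  sdz <- apply(Yz, 2L, stats::sd, na.rm = TRUE)
  mz <- colMeans(Yz, na.rm = TRUE)
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L
    v[k] <- switch(as.character(pt$target[k]),
      "0" = sdz[i],
      "4" = mz[i],
      "5" = log(0.5 * sdz[i]^2),
      0)
  }
  v
}

.fix_factor_signs <- function(spec, theta) {
  mats <- unpack_params(spec, theta)
  for (f in seq_len(spec$m)) {
    anchor <- which(spec$lambda_free[, f])[1L]
    if (mats$Lambda[anchor, f] < 0) {
      mats$Lambda[, f] <- -mats$Lambda[, f]
      mats$Gamma[f, ] <- -mats$Gamma[f, ]
      for (g in seq_len(spec$m)) if (g != f) {
        mats$Psi[f, g] <- -mats$Psi[f, g]
        mats$Psi[g, f] <- mats$Psi[f, g]
      }
    }
  }
  pack_params(spec, mats)
}

# affine maps between input-scale and internally standardized indicators
.rescale_mats <- function(spec, mats, a, s) {
  D <- 1 / s
  list(Lambda = mats$Lambda * D, Psi = mats$Psi, Gamma = mats$Gamma,
       Kappa = mats$Kappa * D, nu = (mats$nu - a) * D,
       Theta = mats$Theta * outer(D, D))
}
.unscale_mats <- function(spec, mats, a, s) {
  list(Lambda = mats$Lambda * s, Psi = mats$Psi, Gamma = mats$Gamma,
       Kappa = mats$Kappa * s, nu = a + mats$nu * s,
       Theta = mats$Theta * outer(s, s))
}
# per-parameter multiplicative factor from internal to input scale
.scale_factors <- function(spec, s) {
  pt <- spec$par_table
  f <- rep(1, nrow(pt))
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L; j <- pt$col[k] + 1L
    f[k] <- switch(as.character(pt$target[k]),
      "0" = s[i], "3" = s[i], "4" = s[i],
      "5" = s[i]^2, "6" = s[i] * s[j], 1)
  }
  f
}

#' Fit the saturated reference model
#'
#' Unrestricted multivariate regression of all indicators on all covariates
#' with unrestricted covariance, maximized over the same FIML likelihood via
#' an EM algorithm on missingness-pattern sufficient statistics.  With
#' complete data this equals closed-form multivariate regression.  Used as
#' the reference model for the likelihood-ratio chi-square.
#'
#' @param spec a \code{mimic_spec} (defines the indicator/covariate columns).
#' @param data data frame.
#' @param tol convergence tolerance on the log-likelihood change.
#' @param max_iter maximum EM iterations.
#' @return list of class \code{mimic_reffit} with \code{loglik},
#'   \code{n_params}, \code{C} (p x (q+1) mean coefficients), \code{Sigma}.
#' @export
fit_saturated <- function(spec, data, tol = 1e-8, max_iter = 2000L) {
  Y <- as.matrix(data[, spec$indicators, drop = FALSE])
  X <- as.matrix(data[, spec$covariates, drop = FALSE])
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  p <- ncol(Y); q1 <- ncol(X) + 1L; n <- nrow(Y)
  pats <- prep_patterns(Y, X)

  C <- matrix(0, p, q1)
  C[, 1] <- colMeans(Y, na.rm = TRUE)
  Sigma <- diag(apply(Y, 2L, stats::var, na.rm = TRUE) * (n - 1) / n, p)

  ll_old <- loglik_moments(pats, C, Sigma)
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    Txx <- matrix(0, q1, q1); Txy <- matrix(0, q1, p); Tyy <- matrix(0, p, p)
    for (P in pats) {
      o <- P$obs + 1L
      mi <- setdiff(seq_len(p), o)
      Txx <- Txx + P$Sxx
      if (length(mi) == 0L) {
        Txy[, o] <- Txy[, o] + P$Sxy
        Tyy[o, o] <- Tyy[o, o] + P$Syy
        next
      }
      Soo <- Sigma[o, o, drop = FALSE]
      B <- Sigma[mi, o, drop = FALSE] %*% solve(Soo)
      D <- C[mi, , drop = FALSE] - B %*% C[o, , drop = FALSE]
      V <- Sigma[mi, mi, drop = FALSE] - B %*% Sigma[o, mi, drop = FALSE]
      Sxy_m <- P$Sxx %*% t(D) + P$Sxy %*% t(B)
      Syy_om <- t(P$Sxy) %*% t(D) + P$Syy %*% t(B)
      Syy_mm <- D %*% P$Sxx %*% t(D) + D %*% P$Sxy %*% t(B) +
        B %*% t(P$Sxy) %*% t(D) + B %*% P$Syy %*% t(B) + P$n * V
      Txy[, o] <- Txy[, o] + P$Sxy
      Txy[, mi] <- Txy[, mi] + Sxy_m
      Tyy[o, o] <- Tyy[o, o] + P$Syy
      Tyy[o, mi] <- Tyy[o, mi] + Syy_om
      Tyy[mi, o] <- Tyy[mi, o] + t(Syy_om)
      Tyy[mi, mi] <- Tyy[mi, mi] + Syy_mm
    }
    C <- t(solve(Txx, Txy))
    Sigma <- (Tyy - C %*% Txy - t(Txy) %*% t(C) + C %*% Txx %*% t(C)) / n
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- loglik_moments(pats, C, Sigma)
    if (is.na(ll)) stop("saturated EM produced a singular covariance")
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) { converged <- TRUE; break }
    ll_old <- ll
  }
  structure(list(loglik = loglik_moments(pats, C, Sigma),
                 n_params = p * q1 + p * (p + 1L) / 2L,
                 C = C, Sigma = Sigma, n_used = n,
                 iterations = iter, converged = converged,
                 kind = "saturated"),
            class = "mimic_reffit")
}

#' Fit the baseline (independence) reference model
#'
#' Intercept-only means with a diagonal covariance and no covariate effects;
#' under FIML this factorizes into per-indicator univariate normal MLEs over
#' each indicator's observed values.  Used as the null reference for the CFI.
#'
#' @param spec a \code{mimic_spec}.
#' @param data data frame.
#' @return list of class \code{mimic_reffit}.
#' @export
fit_baseline <- function(spec, data) {
  Y <- as.matrix(data[, spec$indicators, drop = FALSE])
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]
  p <- ncol(Y)
  ll <- 0
  mu <- numeric(p); v <- numeric(p)
  for (j in seq_len(p)) {
    yj <- Y[, j][!is.na(Y[, j])]
    nj <- length(yj)
    mu[j] <- mean(yj)
    v[j] <- mean((yj - mu[j])^2)
    ll <- ll - 0.5 * nj * (log(2 * pi) + log(v[j]) + 1)
  }
  structure(list(loglik = ll, n_params = 2L * p,
                 mean = mu, var = v, n_used = nrow(Y),
                 converged = TRUE, kind = "baseline"),
            class = "mimic_reffit")
}

#' Likelihood-based fit indices
#'
#' Chi-square against the saturated model, CFI against the baseline model,
#' RMSEA, and AIC:
#' \deqn{\chi^2 = 2(\ell_{sat} - \ell_{model}), \quad
#'       CFI = 1 - \frac{\max(\chi^2 - df, 0)}{\max(\chi^2_b - df_b, 0)},
#'       \quad RMSEA = \sqrt{\max(\chi^2 - df, 0) / (df\,n)}.}
#'
#' @param model a \code{mimic_fit} (or any list with \code{loglik},
#'   \code{n_params}).
#' @param saturated result of \code{\link{fit_saturated}} on the same records.
#' @param baseline result of \code{\link{fit_baseline}} on the same records.
#' @param n number of records used (defaults to the model fit's).
#' @return list of class \code{fit_indices}: \code{chi2}, \code{df},
#'   \code{cfi}, \code{rmsea}, \code{aic}.
#' @export
fit_indices <- function(model, saturated, baseline, n = model$n_used) {
  chi2 <- 2 * (saturated$loglik - model$loglik)
  df <- saturated$n_params - model$n_params
  chi2_b <- 2 * (saturated$loglik - baseline$loglik)
  df_b <- saturated$n_params - baseline$n_params
  if (df < 0) {
    warning("negative model degrees of freedom; indices undefined")
    return(structure(list(chi2 = chi2, df = df, cfi = NA_real_,
                          rmsea = NA_real_,
                          aic = -2 * model$loglik + 2 * model$n_params),
                     class = "fit_indices"))
  }
  num <- max(chi2 - df, 0)
  den <- max(chi2_b - df_b, 0)
  cfi <- if (den > 0) 1 - num / den else 1
  cfi <- min(max(cfi, 0), 1)
  rmsea <- if (num <= 0) 0 else sqrt(num / (df * n))
  structure(list(chi2 = chi2, df = df, cfi = cfi, rmsea = rmsea,
                 aic = -2 * model$loglik + 2 * model$n_params),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, ...) {
  cat(sprintf("chi2 = %.3f on %d df | CFI = %.3f | RMSEA = %.3f | AIC = %.1f\n",
              x$chi2, x$df, x$cfi, x$rmsea, x$aic))
  invisible(x)
}
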