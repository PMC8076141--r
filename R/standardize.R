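#' Standardized solution of a fitted MIMIC model
#'
#' Rescales estimates to the standard deviations of the latent factors and
#' the indicators, leaving covariates on their original units.  Factor SDs
#' come from the model-implied total factor variance
#' \eqn{diag(\Gamma S_x \Gamma' + \Psi)} with \eqn{S_x} the sample covariate
#' covariance; indicator SDs from the model-implied total indicator variance.
#' Residual covariances (between indicators, and between factors) are
#' reported as residual correlations.  Because factor residual variances are
#' fixed at 1, the per-factor \eqn{R^2} is \eqn{1 - 1/Var(f)}.
#'
#' @param fit a \code{mimic_fit}.
#' @return data frame with one row per free parameter: \code{name},
#'   \code{block}, \code{estimate} (input scale) and \code{std}
#'   (standardized); per-factor \eqn{R^2} and implied SDs are attached as
#'   attributes \code{r2}, \code{factor_sd}, \code{indicator_sd}.
#' @export
standardized_solution <- function(fit) {
  stopifnot(inherits(fit, "mimic_fit"))
  spec <- fit$spec
  M <- fit$matrices
  Sx <- fit$Sx
  var_f <- diag(M$Gamma %*% Sx %*% t(M$Gamma) + M$Psi)
  A <- M$Lambda %*% M$Gamma + M$Kappa
  var_y <- diag(A %*% Sx %*% t(A) + M$Lambda %*% M$Psi %*% t(M$Lambda) +
                  M$Theta)
  if (any(var_f <= 0) || any(var_y <= 0))
    stop("non-positive implied variance; cannot standardize")
  sd_f <- sqrt(var_f); sd_y <- sqrt(var_y)
  names(sd_f) <- spec$factors; names(sd_y) <- spec$indicators

  pt <- spec$par_table
  est <- .to_natural(spec, pack_params(spec, M)) # input scale
  std <- numeric(nrow(pt))
  for (k in seq_len(nrow(pt))) {
    i <- pt$row[k] + 1L; j <- pt$col[k] + 1L
    std[k] <- switch(as.character(pt$target[k]),
      "0" = M$Lambda[i, j] * sd_f[j] / sd_y[i],
      "1" = M$Psi[i, j],
      "2" = M$Gamma[i, j] / sd_f[i],
      "3" = M$Kappa[i, j] / sd_y[i],
      "4" = NA_real_,
      "5" = M$Theta[i, i] / var_y[i],
      "6" = M$Theta[i, j] / sqrt(M$Theta[i, i] * M$Theta[j, j]))
  }
  out <- data.frame(name = pt$name, block = pt$block,
                    estimate = unname(est), std = std,
                    stringsAsFactors = FALSE)
  attr(out, "r2") <- stats::setNames(1 - 1 / var_f, spec$factors)
  attr(out, "factor_sd") <- sd_f
  attr(out, "indicator_sd") <- sd_y
  out
}
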