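# S3 methods for mimic_fit objects.

#' @export
print.mimic_fit <- function(x, ...) {
  cat("MIMIC model fit by FIML\n")
  cat(sprintf("  records used: %d (%d dropped with no observed indicator)\n",
              x$n_used, x$n_dropped))
  cat(sprintf("  free parameters: %d | logLik = %.3f | df = %d\n",
              x$n_params, x$loglik, x$df_model))
  cat(sprintf("  convergence code %d, |gradient| = %.2e\n",
              x$convergence$code, x$convergence$grad_norm))
  invisible(x)
}

#' @export
summary.mimic_fit <- function(object, ...) {
  std <- standardized_solution(object)
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, nrow(std))
  tab <- data.frame(std[, c("name", "block", "estimate")],
                    se = se, z = std$estimate / se, std = std$std,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, r2 = attr(std, "r2"),
                 loglik = object$loglik, n_used = object$n_used,
                 n_params = object$n_params,
                 convergence = object$convergence),
            class = "summary.mimic_fit")
}

#' @export
print.summary.mimic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("MIMIC model fit by FIML: n = %d, logLik = %.2f, %d parameters\n\n",
              x$n_used, x$loglik, x$n_params))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, digits)
  tab$se <- signif(tab$se, digits)
  tab$z <- signif(tab$z, digits)
  tab$std <- signif(tab$std, digits)
  print(tab, row.names = FALSE)
  cat("\nLatent factor R-squared:\n")
  print(round(x$r2, digits))
  invisible(x)
}

#' @export
coef.mimic_fit <- function(object, ...) object$estimates

#' @export
vcov.mimic_fit <- function(object, ...) object$vcov

#' @export
logLik.mimic_fit <- function(object, ...)
  structure(object$loglik, df = object$n_params, nobs = object$n_used,
            class = "logLik")

#' Model-implied indicator means
#'
#' @param object a \code{mimic_fit}.
#' @param newdata optional data frame with the covariate columns; defaults to
#'   the fitting data.
#' @param ... unused.
#' @return matrix of implied means (records x indicators),
#'   \eqn{\nu + (\Lambda\Gamma + K)x}.
#' @export
predict.mimic_fit <- function(object, newdata = NULL, ...) {
  spec <- object$spec
  df <- if (is.null(newdata)) object$model_frame else newdata
  X <- as.matrix(df[, spec$covariates, drop = FALSE])
  A <- object$matrices$Lambda %*% object$matrices$Gamma + object$matrices$Kappa
  mu <- sweep(X %*% t(A), 2L, object$matrices$nu, "+")
  colnames(mu) <- spec$indicators
  mu
}

#' @export
fitted.mimic_fit <- function(object, ...) predict.mimic_fit(object)

#' @export
residuals.mimic_fit <- function(object, ...) {
  Y <- as.matrix(object$model_frame[, object$spec$indicators, drop = FALSE])
  Y - predict.mimic_fit(object)
}

#' Simulate complete indicator data from a fitted MIMIC model
#'
#' Draws latent factors from the structural model and indicators from the
#' measurement model at the fitted parameter values, conditional on the
#' covariates (no missingness is imposed).
#'
#' @param object a \code{mimic_fit}.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param newdata optional covariate data frame; defaults to fitting data.
#' @param ... unused.
#' @return a list of \code{nsim} data frames with indicator and covariate
#'   columns.
#' @export
simulate.mimic_fit <- function(object, nsim = 1, seed = NULL,
                               newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- object$spec
  df <- if (is.null(newdata)) object$model_frame else newdata
  X <- as.matrix(df[, spec$covariates, drop = FALSE])
  M <- object$matrices
  n <- nrow(X)
  Lpsi <- chol(M$Psi)
  Lth <- chol(M$Theta)
  out <- vector("list", nsim)
  for (b in seq_len(nsim)) {
    Fmat <- X %*% t(M$Gamma) +
      matrix(stats::rnorm(n * spec$m), n, spec$m) %*% Lpsi
    Y <- sweep(Fmat %*% t(M$Lambda) + X %*% t(M$Kappa) +
                 matrix(stats::rnorm(n * spec$p), n, spec$p) %*% Lth,
               2L, M$nu, "+")
    colnames(Y) <- spec$indicators
    out[[b]] <- data.frame(Y, X, check.names = FALSE)
  }
  out
}

#' @export
plot.mimic_fit <- function(x, blocks = c("loading", "factor_correlation",
                                         "structural", "direct",
                                         "residual_covariance"), ...) {
  std <- standardized_solution(x)
  std <- std[std$block %in% blocks, ]
  graphics::dotchart(std$std, labels = std$name,
                     xlab = "standardized estimate", pch = 19, ...)
  graphics::abline(v = 0, lty = 3)
  invisible(std)
}
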