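# Pattern-grouped sufficient statistics and FIML likelihood wrappers.

# Split records by missingness pattern and accumulate, per pattern, the
# cross-products the Gaussian likelihood needs.  Covariates must be complete.
prep_patterns <- function(Y, X) {
  stopifnot(is.matrix(Y), is.matrix(X), nrow(Y) == nrow(X))
  if (anyNA(X)) stop("covariates must be complete")
  obs <- !is.na(Y)
  keep <- rowSums(obs) > 0
  n_dropped <- sum(!keep)
  Y <- Y[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  obs <- obs[keep, , drop = FALSE]
  Xt <- cbind(1, X)
  key <- apply(obs, 1L, function(r) paste0(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), key)
  pats <- lapply(groups, function(idx) {
    o <- which(obs[idx[1L], ])
    Yo <- Y[idx, o, drop = FALSE]
    Xg <- Xt[idx, , drop = FALSE]
    list(obs = o - 1L, n = length(idx),
         Sxx = crossprod(Xg), Sxy = crossprod(Xg, Yo), Syy = crossprod(Yo))
  })
  structure(pats, n_used = nrow(Y), n_dropped = n_dropped,
            p = ncol(Y), q = ncol(X))
}

#' FIML log-likelihood of a MIMIC model
#'
#' Evaluates the observed-data Gaussian log-likelihood, summing each record's
#' log-density over its observed indicator subset (full-information maximum
#' likelihood, valid under missingness at random).  Records are grouped by
#' missingness pattern; records with no observed indicator contribute nothing
#' and are dropped.
#'
#' @param spec a \code{mimic_spec}.
#' @param theta free-parameter vector on the unconstrained scale (see
#'   \code{\link{unpack_params}}), or a list of natural-scale matrices as
#'   returned by \code{unpack_params}.
#' @param data data frame containing the spec's indicator and covariate
#'   columns; covariates must be complete.
#' @return the log-likelihood (scalar).
#' @export
fiml_loglik <- function(spec, theta, data) {
  Y <- as.matrix(data[, spec$indicators, drop = FALSE])
  X <- as.matrix(data[, spec$covariates, drop = FALSE])
  pats <- prep_patterns(Y, X)
  if (is.list(theta)) theta <- pack_params(spec, theta)
  fiml_loglik_cpp(.cpp_model(spec), pats, theta)
}

# Log-likelihood directly from conditional-mean coefficients C = [nu, A]
# (p x (q+1)) and covariance Sigma; used by the saturated EM and in tests.
loglik_moments <- function(pats, C, Sigma)
  fiml_loglik_moments_cpp(pats, C, Sigma)
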