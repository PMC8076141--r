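#' Likelihood-ratio scan over candidate fixed parameters
#'
#' Refits the model once per candidate with that single parameter freed and
#' reports the likelihood-ratio improvement (\eqn{\Delta\chi^2} on 1 df).
#' This is the model-modification search used when deciding which residual
#' correlations or direct effects the data support: asymptotically
#' equivalent to a score-test modification index, but computed by an actual
#' refit, so the reported improvement is exact rather than a quadratic
#' approximation.
#'
#' @param fit a \code{mimic_fit}.
#' @param candidates list of candidate parameters; each element is a list
#'   with \code{type} in \code{"residual_correlation"}, \code{"direct"},
#'   \code{"loading"}, \code{"structural"} and the two names that identify
#'   it (indicator/indicator, covariate/indicator, indicator/factor,
#'   covariate/factor respectively), e.g.
#'   \code{list(type = "direct", covariate = "dose", indicator = "ai")}.
#' @param wald logical; also compute the freed parameter's Wald estimate,
#'   standard error and p-value from the refit's observed information.
#' @return data frame sorted by decreasing \eqn{\Delta\chi^2} with columns
#'   \code{candidate}, \code{delta_chi2}, \code{p}, and when
#'   \code{wald = TRUE} also \code{estimate}, \code{se}, \code{p_wald};
#'   candidates already free are skipped with a note attribute.
#' @export
lr_scan <- function(fit, candidates, wald = FALSE) {
  stopifnot(inherits(fit, "mimic_fit"))
  rows <- list()
  skipped <- character(0)
  for (cand in candidates) {
    sp <- tryCatch(.spec_add(fit$spec, cand), error = function(e) e)
    if (inherits(sp, "error")) { skipped <- c(skipped, .cand_name(cand)); next }
    ref <- fit_mimic(sp$spec, fit$model_frame, start = fit$matrices,
                     se = wald)
    d2 <- 2 * (ref$loglik - fit$loglik)
    row <- data.frame(candidate = .cand_name(cand),
                      delta_chi2 = d2,
                      p = stats::pchisq(max(d2, 0), df = 1,
                                        lower.tail = FALSE),
                      stringsAsFactors = FALSE)
    if (wald) {
      k <- match(sp$new_name, sp$spec$par_table$name)
      est <- .to_natural(sp$spec, pack_params(sp$spec, ref$matrices))[k]
      se_k <- if (!is.null(ref$vcov)) sqrt(max(ref$vcov[k, k], 0)) else NA_real_
      row$estimate <- unname(est)
      row$se <- se_k
      row$p_wald <- 2 * stats::pnorm(-abs(est / se_k))
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$delta_chi2), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

.cand_name <- function(cand)
  paste(unlist(cand[setdiff(names(cand), "type")]), collapse = ":")

# Rebuild a spec with one additional free parameter; errors if already free.
.spec_add <- function(spec, cand) {
  a <- spec$args
  new_name <- NULL
  if (cand$type == "residual_correlation") {
    pair <- c(cand$indicator1, cand$indicator2)
    if (nrow(spec$theta_pairs) > 0 &&
        any(apply(spec$theta_pairs, 1L,
                  function(r) setequal(r, pair))))
      stop("already free")
    a$residual_correlations <- rbind(spec$theta_pairs, pair)
    ij <- sort(match(pair, spec$indicators))
    new_name <- paste0("theta.", spec$indicators[ij[1]], ".",
                       spec$indicators[ij[2]])
  } else if (cand$type == "direct") {
    if (spec$kappa_free[cand$indicator, cand$covariate]) stop("already free")
    existing <- which(spec$kappa_free, arr.ind = TRUE)
    de <- cbind(spec$covariates[existing[, 2]],
                spec$indicators[existing[, 1]])
    a$direct_effects <- rbind(de, c(cand$covariate, cand$indicator))
    new_name <- paste0("kappa.", cand$indicator, ".", cand$covariate)
  } else if (cand$type == "loading") {
    if (spec$lambda_free[cand$indicator, cand$factor]) stop("already free")
    a$factors[[cand$factor]] <- c(a$factors[[cand$factor]], cand$indicator)
    new_name <- paste0("lambda.", cand$indicator, ".", cand$factor)
  } else if (cand$type == "structural") {
    if (spec$gamma_free[cand$factor, cand$covariate]) stop("already free")
    a$structural[[cand$factor]] <- c(a$structural[[cand$factor]],
                                     cand$covariate)
    new_name <- paste0("gamma.", cand$factor, ".", cand$covariate)
  } else stop("unknown candidate type: ", cand$type)
  sp <- mimic_spec(a$indicators, a$factors, a$covariates, a$structural,
                   a$residual_correlations, a$direct_effects)
  list(spec = sp, new_name = new_name)
}
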