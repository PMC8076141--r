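#' Percentile bootstrap confidence intervals for a fitted MIMIC model
#'
#' Resamples participants (rows) with replacement, refits the model to each
#' resample warm-started at the full-data estimates, and forms percentile
#' intervals for every unstandardized and standardized free parameter (and,
#' optionally, user-supplied derived quantities such as indirect effects).
#' Non-converged replicates are dropped and counted; a warning is raised if
#' more than 10\% fail.
#'
#' @param fit a \code{mimic_fit}.
#' @param B number of bootstrap replications (the primary analysis uses
#'   2000; smaller values are useful for exploration).
#' @param seed integer seed controlling the resampling.
#' @param level confidence level (default 0.95).
#' @param extra_fun optional \code{function(fit)} returning a named numeric
#'   vector recomputed on every replicate.
#' @return object of class \code{mimic_boot}: \code{ci} (data frame with
#'   \code{name}, \code{lower}, \code{upper}), replicate draws \code{t},
#'   \code{n_failed}, \code{B}, \code{level}.
#' @export
bootstrap_ci <- function(fit, B = 2000L, seed = 1L, level = 0.95,
                         extra_fun = NULL) {
  stopifnot(inherits(fit, "mimic_fit"), B >= 2)
  set.seed(seed)
  data <- fit$model_frame
  n <- nrow(data)
  base <- .boot_quantities(fit, extra_fun)
  draws <- matrix(NA_real_, B, length(base),
                  dimnames = list(NULL, names(base)))
  n_failed <- 0L
  ok <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_fit <- tryCatch(
      fit_mimic(fit$spec, data[idx, , drop = FALSE],
                start = fit$matrices, se = FALSE),
      error = function(e) NULL)
    if (is.null(rep_fit) || rep_fit$convergence$code != 0) {
      n_failed <- n_failed + 1L
      next
    }
    draws[b, ] <- .boot_quantities(rep_fit, extra_fun)
    ok[b] <- TRUE
  }
  if (n_failed > 0.10 * B)
    warning(sprintf("%d of %d bootstrap replicates failed to converge",
                    n_failed, B))
  alpha <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2L, function(v) {
    if (all(is.na(v))) c(NA_real_, NA_real_)
    else stats::quantile(v, probs = c(alpha, 1 - alpha), names = FALSE)
  })
  structure(list(
    ci = data.frame(name = names(base), estimate = unname(base),
                    lower = qs[1L, ], upper = qs[2L, ],
                    stringsAsFactors = FALSE),
    t = draws[ok, , drop = FALSE],
    n_failed = n_failed, B = B, level = level, seed = seed
  ), class = "mimic_boot")
}

.boot_quantities <- function(fit, extra_fun) {
  std <- standardized_solution(fit)
  out <- c(stats::setNames(std$estimate, std$name),
           stats::setNames(std$std, paste0("std.", std$name)),
           stats::setNames(attr(std, "r2"),
                           paste0("r2.", names(attr(std, "r2")))))
  if (!is.null(extra_fun)) out <- c(out, extra_fun(fit))
  out
}

#' @export
print.mimic_boot <- function(x, ...) {
  cat(sprintf("Percentile bootstrap: B = %d (%d failed), level = %.2f\n",
              x$B, x$n_failed, x$level))
  invisible(x)
}
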