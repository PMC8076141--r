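# Fitting: closed-form reductions, recovery, reference models, fit indices.

test_that("saturated fit on complete data equals closed-form regression", {
  dat <- gen_toy_data(300, seed = 21)
  sp <- toy_spec()
  sat <- fit_saturated(sp, dat)
  # closed form: per-record multivariate regression with ML covariance
  Y <- as.matrix(dat[, 1:3]); X <- cbind(1, dat$x)
  B <- solve(crossprod(X), crossprod(X, Y))
  E <- Y - X %*% B
  S <- crossprod(E) / nrow(Y)
  ll <- -0.5 * nrow(Y) * (3 * log(2 * pi) +
                            as.numeric(determinant(S)$modulus) + 3)
  expect_equal(sat$loglik, ll, tolerance = 1e-6)
  expect_equal(sat$n_params, 3 * 2 + 6)
})

test_that("saturated EM with missing data matches direct maximization", {
  dat <- gen_toy_data(150, seed = 22, miss = c(30, 20, 10))
  sp <- toy_spec()
  sat <- fit_saturated(sp, dat)
  expect_true(sat$converged)
  # independent route: numerically maximize the same observed-data
  # likelihood over (C, Sigma) via an unconstrained parameterization
  Y <- as.matrix(dat[, 1:3]); X <- as.matrix(dat[, "x", drop = FALSE])
  pats <- mimicsem:::prep_patterns(Y, X)
  negll <- function(par) {
    C <- matrix(par[1:6], 3, 2)
    L <- matrix(0, 3, 3)
    L[lower.tri(L, diag = TRUE)] <- par[7:12]
    diag(L) <- exp(diag(L))
    S <- L %*% t(L)
    v <- mimicsem:::loglik_moments(pats, C, S)
    if (is.na(v)) 1e10 else -v
  }
  opt <- stats::optim(c(sat$C, 0, 0, 0, 0, 0, 0), negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_equal(sat$loglik, -opt$value, tolerance = 1e-4)
})

test_that("restricted, baseline and saturated log-likelihoods nest", {
  dat <- gen_toy_data(250, seed = 23, miss = c(30, 0, 10))
  sp <- toy_spec()
  fit <- fit_mimic(sp, dat, se = FALSE)
  sat <- fit_saturated(sp, dat)
  base <- fit_baseline(sp, dat)
  expect_gte(sat$loglik, fit$loglik - 1e-6)
  expect_gte(fit$loglik, base$loglik - 1e-6)
  # baseline equals the per-indicator univariate normal MLE
  y1 <- dat$y1[!is.na(dat$y1)]
  v1 <- mean((y1 - mean(y1))^2)
  ll1 <- -0.5 * length(y1) * (log(2 * pi) + log(v1) + 1)
  y2 <- dat$y2; v2 <- mean((y2 - mean(y2))^2)
  ll2 <- -0.5 * length(y2) * (log(2 * pi) + log(v2) + 1)
  y3 <- dat$y3[!is.na(dat$y3)]
  v3 <- mean((y3 - mean(y3))^2)
  ll3 <- -0.5 * length(y3) * (log(2 * pi) + log(v3) + 1)
  expect_equal(base$loglik, ll1 + ll2 + ll3, tolerance = 1e-10)
})

test_that("fit indices follow their defining arithmetic", {
  # hand-computed fixture
  model <- list(loglik = -1050, n_params = 10, n_used = 200)
  sat <- list(loglik = -1000, n_params = 20)
  base <- list(loglik = -1400, n_params = 6)
  fi <- fit_indices(model, sat, base, n = 200)
  expect_equal(fi$chi2, 100)           # 2 * (1050 - 1000)
  expect_equal(fi$df, 10)
  expect_equal(fi$cfi, 1 - (100 - 10) / (800 - 14))
  expect_equal(fi$rmsea, sqrt(90 / (10 * 200)))
  expect_equal(fi$aic, 2 * 1050 + 20)
  # perfect fit: model = saturated
  fi0 <- fit_indices(list(loglik = -1000, n_params = 20, n_used = 200),
                     sat, base)
  expect_equal(fi0$chi2, 0)
  expect_equal(fi0$cfi, 1)
  expect_equal(fi0$rmsea, 0)
  # the baseline scored against itself has CFI 0
  fib <- fit_indices(list(loglik = -1400, n_params = 6, n_used = 200),
                     sat, base)
  expect_equal(fib$cfi, 0)
})

test_that("toy parameter recovery is unbiased within Monte-Carlo error", {
  sp <- toy_spec()
  R <- 12
  lam1 <- gam <- numeric(R)
  for (r in seq_len(R)) {
    dat <- gen_toy_data(1200, seed = 300 + r)
    fit <- fit_mimic(sp, dat, se = FALSE)
    lam1[r] <- fit$matrices$Lambda[1, 1]
    gam[r] <- fit$matrices$Gamma[1, 1]
  }
  expect_lt(abs(mean(lam1) - 0.8), 3 * stats::sd(lam1) / sqrt(R))
  expect_lt(abs(mean(gam) - 0.5), 3 * stats::sd(gam) / sqrt(R))
})

test_that("different admissible starts reach the same maximum", {
  dat <- gen_toy_data(400, seed = 31)
  sp <- toy_spec()
  f1 <- fit_mimic(sp, dat, se = FALSE)
  tr <- attr(dat, "truth")
  start <- list(Lambda = matrix(c(1.2, 1.2, 1.2), 3, 1),
                Psi = matrix(1, 1, 1), Gamma = matrix(0.1, 1, 1),
                Kappa = matrix(0, 3, 1), nu = c(0.5, 0.5, 0.5),
                Theta = diag(c(1, 1, 1)))
  f2 <- fit_mimic(sp, dat, start = start, se = FALSE)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-3)
})

test_that("refits are deterministic and factor signs are normalized", {
  dat <- gen_toy_data(300, seed = 32)
  sp <- toy_spec()
  f1 <- fit_mimic(sp, dat, se = FALSE)
  f2 <- fit_mimic(sp, dat, se = FALSE)
  expect_identical(f1$theta, f2$theta)
  expect_gt(f1$matrices$Lambda[1, 1], 0)
})

test_that("observed-information standard errors track sampling spread", {
  sp <- toy_spec()
  dat <- gen_toy_data(800, seed = 33)
  fit <- fit_mimic(sp, dat, se = TRUE)
  k <- match("gamma.f.x", fit$spec$par_table$name)
  se_wald <- sqrt(fit$vcov[k, k])
  reps <- vapply(1:20, function(r)
    fit_mimic(sp, gen_toy_data(800, seed = 600 + r),
              se = FALSE)$matrices$Gamma[1, 1], numeric(1))
  expect_lt(abs(se_wald / stats::sd(reps) - 1), 0.6)
})

test_that("records with no observed indicator are dropped and counted", {
  dat <- gen_toy_data(50, seed = 34)
  dat[1:3, c("y1", "y2", "y3")] <- NA
  fit <- fit_mimic(toy_spec(), dat, se = FALSE)
  expect_equal(fit$n_used, 47)
  expect_equal(fit$n_dropped, 3)
})
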