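# The FIML likelihood against independent closed-form oracles.

test_that("complete data reduces to the closed-form Gaussian likelihood", {
  dat <- gen_toy_data(200, seed = 11)
  sp <- toy_spec()
  tr <- attr(dat, "truth")
  mats <- list(
    Lambda = matrix(tr$lambda, 3, 1), Psi = matrix(1, 1, 1),
    Gamma = matrix(tr$gamma, 1, 1), Kappa = matrix(0, 3, 1),
    nu = tr$nu, Theta = diag(tr$theta))
  S <- mats$Lambda %*% t(mats$Lambda) + mats$Theta
  mu <- outer(dat$x * tr$gamma, tr$lambda)
  mu <- sweep(mu, 2L, tr$nu, "+")
  ll_oracle <- sum(vapply(seq_len(nrow(dat)), function(i)
    dmvnorm_log(unlist(dat[i, 1:3]), mu[i, ], S), numeric(1)))
  expect_equal(fiml_loglik(sp, mats, dat), ll_oracle, tolerance = 1e-8)
})

test_that("missing entries are marginalized exactly (brute-force oracle)", {
  dat <- gen_toy_data(60, seed = 12)
  sp <- toy_spec()
  tr <- attr(dat, "truth")
  mats <- list(
    Lambda = matrix(tr$lambda, 3, 1), Psi = matrix(1, 1, 1),
    Gamma = matrix(tr$gamma, 1, 1), Kappa = matrix(0, 3, 1),
    nu = tr$nu, Theta = diag(tr$theta))
  S <- mats$Lambda %*% t(mats$Lambda) + mats$Theta
  mu_of <- function(x) tr$nu + tr$lambda * tr$gamma * x

  # knock out single cells and whole pairs in a few records
  dat$y1[1] <- NA; dat$y2[2] <- NA; dat$y1[3] <- NA; dat$y3[3] <- NA
  ll_oracle <- 0
  for (i in seq_len(nrow(dat))) {
    o <- which(!is.na(dat[i, 1:3]))
    ll_oracle <- ll_oracle +
      dmvnorm_log(unlist(dat[i, o]), mu_of(dat$x[i])[o],
                  S[o, o, drop = FALSE])
  }
  expect_equal(fiml_loglik(sp, mats, dat), ll_oracle, tolerance = 1e-8)

  # and the additivity form: full-data records plus the marginal of the
  # incomplete record's observed subset
  dat2 <- gen_toy_data(5, seed = 13)
  ll_full_4 <- sum(vapply(2:5, function(i)
    dmvnorm_log(unlist(dat2[i, 1:3]), mu_of(dat2$x[i]), S), numeric(1)))
  dat2$y2[1] <- NA
  ll_marg_1 <- dmvnorm_log(unlist(dat2[1, c(1, 3)]),
                           mu_of(dat2$x[1])[c(1, 3)], S[c(1, 3), c(1, 3)])
  expect_equal(fiml_loglik(sp, mats, dat2), ll_full_4 + ll_marg_1,
               tolerance = 1e-8)
})

test_that("a single standard-normal observation gives -log(2*pi)/2", {
  sp <- mimic_spec("y1", list(f = "y1"), "x")
  mats <- list(Lambda = matrix(0, 1, 1), Psi = matrix(1, 1, 1),
               Gamma = matrix(0, 1, 1), Kappa = matrix(0, 1, 1),
               nu = 0, Theta = matrix(1, 1, 1))
  dat <- data.frame(y1 = 0, x = 0)
  expect_equal(fiml_loglik(sp, mats, dat), -0.5 * log(2 * pi),
               tolerance = 1e-12)
})

test_that("likelihood is invariant to record order", {
  dat <- gen_toy_data(150, seed = 14, miss = c(25, 10, 0))
  sp <- toy_spec()
  set.seed(1)
  perm <- sample.int(nrow(dat))
  mats <- unpack_params(sp, stats::runif(n_free_params(sp), -0.3, 0.3))
  expect_equal(fiml_loglik(sp, mats, dat),
               fiml_loglik(sp, mats, dat[perm, ]), tolerance = 1e-10)
})

test_that("analytic score matches central finite differences", {
  dat <- gen_toy_data(120, seed = 15, theta12 = 0.2, miss = c(20, 15, 5))
  sp <- toy_spec(resid_cor = TRUE)
  Y <- as.matrix(dat[, 1:3]); X <- as.matrix(dat[, "x", drop = FALSE])
  pats <- mimicsem:::prep_patterns(Y, X)
  cppm <- mimicsem:::.cpp_model(sp)
  set.seed(2)
  for (r in 1:5) {
    th <- stats::runif(n_free_params(sp), -0.4, 0.4)
    ga <- mimicsem:::fiml_grad_cpp(cppm, pats, th)
    gn <- mimicsem:::fiml_grad_num_cpp(cppm, pats, th)
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("implied moments follow the path algebra", {
  # no loadings: covariance is the residual matrix
  sp0 <- mimic_spec(c("y1", "y2"), list(f = c("y1", "y2")), "x")
  m0 <- unpack_params(sp0, pack_params(sp0, list(
    Lambda = matrix(0, 2, 1), Psi = matrix(1, 1, 1),
    Gamma = matrix(0, 1, 1), Kappa = matrix(0, 2, 1),
    nu = c(0, 0), Theta = diag(2))))
  S0 <- m0$Lambda %*% m0$Psi %*% t(m0$Lambda) + m0$Theta
  expect_equal(S0, diag(2), ignore_attr = TRUE)

  # unit loadings, unit factor variance, identity residuals
  m1 <- list(Lambda = matrix(1, 2, 1), Psi = matrix(1, 1, 1),
             Gamma = matrix(0, 1, 1), Kappa = matrix(0, 2, 1),
             nu = c(0, 0), Theta = diag(2))
  S1 <- m1$Lambda %*% m1$Psi %*% t(m1$Lambda) + m1$Theta
  expect_equal(S1, matrix(c(2, 1, 1, 2), 2), ignore_attr = TRUE)

  # chain product: gamma 0.5, lambda 2, x = 1 -> implied mean 1
  mu <- m1$nu[1] + 2 * (0.5 * 1)
  expect_equal(mu, 1)
})
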