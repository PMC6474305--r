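test_that("degenerate closed-form fits are exact", {
  X1 <- matrix(1, 4, 1, dimnames = list(NULL, "(Intercept)"))
  f <- fit_nb_glm(c(2, 2, 2, 2), X1)
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-6)
  expect_equal(f$deviance, 0, tolerance = 1e-8)

  f2 <- fit_nb_glm(1:4, X1, offset = log(1:4))
  expect_equal(unname(f2$coefficients), 0, tolerance = 1e-6)
  expect_equal(f2$deviance, 0, tolerance = 1e-8)
})

test_that("fitted (beta, theta, loglik) match the grid-search oracle", {
  for (fx in oracle_fixtures()) {
    o <- oracle_nb_grid(fx$y, fx$X)
    f <- suppressWarnings(fit_nb_glm(fx$y, fx$X))
    expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-3)
    expect_equal(f$theta, o$theta, tolerance = 1e-3)
    expect_equal(f$log_likelihood, o$log_likelihood, tolerance = 1e-3)
  }
})

test_that("equidispersed data drive theta to the Poisson boundary", {
  # near-Poisson counts: beta and loglik still match the oracle, while
  # both routes push theta to a very large value (1/theta ~ 0)
  y <- c(5, 1, 4, 2, 7, 3)
  X <- cbind(1, c(1, 0, 1, 0, 1, 0))
  o <- oracle_nb_grid(y, X, ltheta_range = c(-3, 16))
  f <- suppressWarnings(fit_nb_glm(y, X))
  expect_equal(unname(f$coefficients), o$beta, tolerance = 1e-3)
  expect_equal(f$log_likelihood, o$log_likelihood, tolerance = 1e-3)
  expect_gt(f$theta, 1e3)
  expect_gt(o$theta, 1e3)
})

test_that("NB fit agrees with MASS::glm.nb on realistic data", {
  skip_if_not_installed("MASS")
  set.seed(11)
  x <- rnorm(150)
  y <- rnbinom(150, mu = exp(1.2 + 0.6 * x), size = 1.8)
  f <- fit_nb_glm(y, cbind("(Intercept)" = 1, x = x))
  m <- MASS::glm.nb(y ~ x)
  expect_equal(unname(f$coefficients), unname(coef(m)), tolerance = 1e-5)
  expect_equal(f$theta, m$theta, tolerance = 1e-4)
  expect_equal(f$aic, AIC(m), tolerance = 1e-5)
  expect_equal(f$deviance, deviance(m), tolerance = 1e-5)
  expect_equal(f$null_deviance, m$null.deviance, tolerance = 1e-5)
})

test_that("theta fixed at 1e8 reproduces the Poisson GLM", {
  set.seed(5)
  x <- rnorm(80)
  y <- rpois(80, exp(0.8 + 0.4 * x))
  f <- fit_nb_glm(y, cbind(1, x), theta = 1e8)
  g <- glm(y ~ x, family = poisson())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-4)
  expect_equal(f$deviance, deviance(g), tolerance = 1e-4)
  expect_equal(f$null_deviance, g$null.deviance, tolerance = 1e-4)
})

test_that("nb_log_likelihood matches direct evaluation and is additive", {
  # Poisson limit at large theta
  expect_equal(nb_log_likelihood(0, 1, 1e9), dpois(0, 1, log = TRUE),
               tolerance = 1e-6)
  # gamma-function form, term by term
  expect_equal(nb_log_likelihood(3, 3, 2), oracle_nb_density_log(3, 3, 2),
               tolerance = 1e-10)
  set.seed(2)
  y <- rnbinom(20, mu = 4, size = 1.5)
  mu <- runif(20, 1, 8)
  expect_equal(nb_log_likelihood(y, mu, 1.5),
               sum(oracle_nb_density_log(y, mu, 1.5)), tolerance = 1e-8)
  # additivity over independent observations
  expect_equal(nb_log_likelihood(y[1:2], mu[1:2], 2),
               nb_log_likelihood(y[1], mu[1], 2) +
                 nb_log_likelihood(y[2], mu[2], 2))
  expect_error(nb_log_likelihood(1, -1, 2), "mu")
  expect_error(nb_log_likelihood(1, 1, 0), "theta")
})

test_that("adjusted D-squared follows the penalised-deviance formula", {
  expect_equal(adjusted_d2(deviance = 40, null_deviance = 100, n = 21, p = 5),
               0.5)
  expect_equal(adjusted_d2(deviance = 100, null_deviance = 100, n = 30, p = 1),
               0)
  # poor model can go negative; rendering shows "0 (value)"
  neg <- adjusted_d2(deviance = 95, null_deviance = 100, n = 20, p = 8)
  expect_lt(neg, 0)
  expect_equal(format_adj_d2(-0.14), "0 (-0.14)")
  expect_equal(format_adj_d2(0.54), "0.54")
  expect_error(adjusted_d2(deviance = 1, null_deviance = 2, n = 4, p = 5),
               "n <= p")
})

test_that("predict_mean honours the log link and design contract", {
  set.seed(7)
  x <- rnorm(40)
  X <- cbind("(Intercept)" = 1, x = x)
  y <- rnbinom(40, mu = exp(1 + 0.3 * x), size = 2)
  f <- fit_nb_glm(y, X)
  expect_equal(predict_mean(f, X), f$fitted_means, tolerance = 1e-10)
  # doubling the offset argument doubles predictions
  p1 <- predict_mean(f, X, new_offset = rep(log(2), 40))
  expect_equal(p1, 2 * predict_mean(f, X), tolerance = 1e-10)
  # column mismatch is refused
  X2 <- X; colnames(X2) <- c("(Intercept)", "z")
  expect_error(predict_mean(f, X2), "mismatch")
})

test_that("error paths: singular design, all-zero response", {
  X <- cbind(1, c(1, 0, 1, 0), c(2, 0, 2, 0))
  colnames(X) <- c("(Intercept)", "a", "b")
  expect_error(fit_nb_glm(c(1, 2, 3, 4), X), "collinear.*b")
  expect_error(fit_nb_glm(c(0, 0, 0, 0), matrix(1, 4, 1)), "all counts")
})

test_that("coefficients are recovered without bias at large n", {
  set.seed(31)
  n <- 2000
  x <- rnorm(n)
  beta <- c(1, 0.5)
  y <- rnbinom(n, mu = exp(beta[1] + beta[2] * x), size = 2)
  f <- fit_nb_glm(y, cbind(1, x))
  expect_lt(max(abs(f$coefficients - beta)), 0.05)
})

test_that("a pure-noise column cannot increase deviance", {
  set.seed(17)
  x <- rnorm(100)
  y <- rnbinom(100, mu = exp(1 + 0.5 * x), size = 2)
  f1 <- fit_nb_glm(y, cbind(1, x))
  f2 <- fit_nb_glm(y, cbind(1, x, rnorm(100)), theta = f1$theta)
  expect_lte(f2$deviance, f1$deviance + 1e-6)
})
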