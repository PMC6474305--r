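#' Negative-binomial (NB2) log-likelihood
#'
#' Exact log-likelihood of independent NB2 observations with means `mu` and
#' dispersion `theta` (variance \eqn{\mu + \mu^2/\theta}), evaluated in log
#' space. This is the shared kernel used by model fitting, AIC reporting and
#' the ecogroup mixture E-step.
#'
#' @param y non-negative integer vector of counts.
#' @param mu positive vector of means, recycled against `y` if scalar.
#' @param theta positive dispersion parameter.
#' @param weights optional non-negative observation weights.
#' @return the (weighted) log-likelihood, a finite scalar.
#' @export
nb_log_likelihood <- function(y, mu, theta, weights = NULL) {
  if (length(mu) == 1L) mu <- rep(mu, length(y))
  if (length(y) != length(mu)) stop("'y' and 'mu' must have equal length")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("'mu' must be positive and finite")
  if (!is.finite(theta) || theta <= 0) stop("'theta' must be positive and finite")
  ll <- stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
  if (is.null(weights)) sum(ll) else sum(weights * ll)
}

# NB2 deviance; y log(y/mu) term is 0 at y = 0
nb_deviance <- function(y, mu, theta, weights = NULL) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  t2 <- (y + theta) * log((y + theta) / (mu + theta))
  d <- 2 * (t1 - t2)
  tot <- if (is.null(weights)) sum(d) else sum(weights * d)
  max(tot, 0)  # guard float noise on saturated fits
}

# One IRLS pass for NB regression at fixed theta (log link).
# Returns beta, eta (linear predictor incl. offset), mu, ll.
nb_irls <- function(y, X, offset = NULL, weights = NULL, beta = NULL,
                    theta = 1, maxit = 30, tol = 1e-10) {
  n <- length(y)
  if (is.null(offset)) offset <- rep(0, n)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(beta)) {
    mu <- pmax(y, 0.25) + mean(y) * 0.1 + 0.05
    eta <- log(mu)
    z <- eta - offset
    fit0 <- stats::lm.wfit(X, z, weights)
    beta <- fit0$coefficients
    beta[is.na(beta)] <- 0
  }
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- exp(eta)
  ll <- nb_log_likelihood(y, mu, theta, weights)
  for (it in seq_len(maxit)) {
    w <- weights * mu * theta / (mu + theta)
    z <- (eta - offset) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, pmax(w, 1e-12))
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    # step-halve if the exact likelihood would decrease
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_c <- pmin(drop(X %*% cand) + offset, 30)
      mu_c <- exp(eta_c)
      ll_c <- nb_log_likelihood(y, mu_c, theta, weights)
      if (ll_c >= ll - 1e-12 || step < 1 / 64) break
      step <- step / 2
    }
    if (ll_c < ll) break  # no improving step found; keep current beta
    moved <- abs(ll_c - ll)
    beta <- cand; eta <- eta_c; mu <- mu_c; ll <- ll_c
    if (moved < tol * (abs(ll) + 1)) break
  }
  list(beta = beta, eta = eta, mu = mu, ll = ll)
}

# Weighted ML estimate of theta given mu, via 1-D search on log(theta)
nb_theta_ml <- function(y, mu, weights = NULL, lower = -7, upper = 16) {
  f <- function(lt) nb_log_likelihood(y, mu, exp(lt), weights)
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-9)
  exp(opt$maximum)
}

#' Fit a negative-binomial GLM with log link
#'
#' Maximum-likelihood fit of an NB2 regression: IRLS for the coefficients at
#' fixed dispersion, alternated with one-dimensional ML estimation of the
#' dispersion \eqn{\theta}, until the relative change in log-likelihood falls
#' below `tol`. An offset enters the linear predictor with coefficient fixed
#' at 1 (used for library sizes in abundance models).
#'
#' @param y non-negative integer response vector.
#' @param design numeric design matrix (including an intercept column when one
#'   is wanted); must be full column rank.
#' @param offset optional numeric vector added to the linear predictor.
#' @param weights optional non-negative prior weights (used by the mixture
#'   M-step; ordinary fits leave this `NULL`).
#' @param theta fix the dispersion at this value instead of estimating it
#'   (e.g. `1e8` for a Poisson-limit fit); `NULL` (default) estimates it.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum number of outer (beta, theta) alternations.
#' @return an object of class `nb_glm`: coefficients, `theta`,
#'   `log_likelihood`, `deviance`, `null_deviance`, `aic`, `fitted_means`,
#'   standard errors and Wald z/P-values, `n`, `p`, `design_info`,
#'   `converged`.
#' @export
fit_nb_glm <- function(y, design, offset = NULL, weights = NULL,
                       theta = NULL, tol = 1e-8, max_iter = 200) {
  y <- as.numeric(y)
  design <- as.matrix(design)
  n <- length(y)
  if (nrow(design) != n) stop("rows of 'design' must match length of 'y'")
  if (!is.null(offset) && length(offset) != n)
    stop("'offset' must match length of 'y'")
  if (any(y < 0) || any(abs(y - round(y)) > 1e-8))
    stop("'y' must contain non-negative integers")
  if (all(y == 0)) stop("degenerate response: all counts are zero")
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    bad <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    stop("singular design: collinear column(s) ", paste(bad, collapse = ", "))
  }
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(ncol(design)))

  fixed_theta <- !is.null(theta)
  th <- if (fixed_theta) theta else {
    mu0 <- pmax(mean(y), 0.1)
    v <- stats::var(y)
    if (is.finite(v) && v > mu0) max(mu0^2 / (v - mu0), 0.1) else 10
  }
  fit <- nb_irls(y, design, offset, weights, beta = NULL, theta = th)
  ll <- fit$ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (!fixed_theta) th <- nb_theta_ml(y, fit$mu, weights)
    fit <- nb_irls(y, design, offset, weights, beta = fit$beta, theta = th)
    if (abs(fit$ll - ll) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll <- fit$ll
      break
    }
    ll <- fit$ll
  }
  if (!converged)
    warning("fit_nb_glm did not converge in ", max_iter, " iterations")

  w <- if (is.null(weights)) rep(1, n) else weights
  # Fisher information for Wald SEs
  wirls <- w * fit$mu * th / (fit$mu + th)
  info <- crossprod(design * sqrt(wirls))
  vc <- tryCatch(solve(info), error = function(e) matrix(NA, ncol(design), ncol(design)))
  se <- sqrt(diag(vc))
  zval <- fit$beta / se
  pval <- 2 * stats::pnorm(-abs(zval))

  # null model: intercept only, same offset, same theta
  if (ncol(design) > 1L || any(design[, 1] != 1)) {
    nullfit <- nb_irls(y, matrix(1, n, 1), offset, weights, theta = th)
    null_dev <- nb_deviance(y, nullfit$mu, th, weights)
  } else {
    null_dev <- nb_deviance(y, fit$mu, th, weights)
  }

  p <- ncol(design) + 1L  # theta counted as an estimated parameter
  out <- list(
    coefficients = stats::setNames(fit$beta, colnames(design)),
    theta = th,
    log_likelihood = ll,
    deviance = nb_deviance(y, fit$mu, th, weights),
    null_deviance = null_dev,
    n = n, p = p,
    aic = -2 * ll + 2 * p,
    fitted_means = fit$mu,
    se = stats::setNames(se, colnames(design)),
    z = stats::setNames(zval, colnames(design)),
    p_values = stats::setNames(pval, colnames(design)),
    design_info = list(terms = colnames(design), has_offset = !is.null(offset),
                       theta_fixed = fixed_theta),
    converged = converged
  )
  class(out) <- "nb_glm"
  out
}

#' @export
print.nb_glm <- function(x, ...) {
  cat("Negative-binomial GLM (log link)\n")
  cat(sprintf("  n = %d, p = %d, theta = %.4g, AIC = %.2f\n",
              x$n, x$p, x$theta, x$aic))
  cat(sprintf("  deviance = %.3f (null %.3f), converged: %s\n",
              x$deviance, x$null_deviance, x$converged))
  tab <- cbind(estimate = x$coefficients, se = x$se, z = x$z, p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Adjusted D-squared (deviance explained, parameter-penalised)
#'
#' \eqn{D^2 = 1 - deviance/null\_deviance}; the adjusted form penalises for
#' model size: \eqn{1 - ((n-1)/(n-p)) (1 - D^2)}. May be negative for poor
#' models; see [format_adj_d2()] for the conventional "0 (value)" rendering.
#'
#' @param fit an `nb_glm` fit, or `NULL` when the four scalars are supplied.
#' @param deviance,null_deviance,n,p scalars overriding the fit's values.
#' @return adjusted D-squared (can be negative).
#' @export
adjusted_d2 <- function(fit = NULL, deviance = fit$deviance,
                        null_deviance = fit$null_deviance,
                        n = fit$n, p = fit$p) {
  if (null_deviance <= 0) stop("null deviance must be positive")
  if (n <= p) stop("adjustment undefined: n <= p")
  d2 <- 1 - deviance / null_deviance
  1 - ((n - 1) / (n - p)) * (1 - d2)
}

#' Render adjusted D-squared, showing negatives as "0 (value)"
#'
#' @param x numeric adjusted D-squared value(s).
#' @param digits decimal places.
#' @return character vector.
#' @export
format_adj_d2 <- function(x, digits = 2) {
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  ifelse(x < 0, paste0("0 (", fmt(x), ")"), fmt(x))
}

#' Predicted mean counts from a fitted NB GLM
#'
#' @param fit an `nb_glm` object.
#' @param new_design design matrix with columns matching the training design.
#' @param new_offset optional offset vector for the new data.
#' @return positive vector `exp(new_design %*% beta + new_offset)`.
#' @export
predict_mean <- function(fit, new_design, new_offset = NULL) {
  new_design <- as.matrix(new_design)
  if (!identical(colnames(new_design), fit$design_info$terms))
    stop("level/column mismatch: new design columns [",
         paste(colnames(new_design), collapse = ", "),
         "] do not match fit terms [",
         paste(fit$design_info$terms, collapse = ", "), "]")
  eta <- drop(new_design %*% fit$coefficients)
  if (!is.null(new_offset)) eta <- eta + new_offset
  exp(pmin(eta, 30))
}
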