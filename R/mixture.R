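#' @name ecogroup-mixture
#' @title Species-archetype mixture of negative-binomial regressions
#' @description
#' OTUs are clustered into "ecogroups" by the shape of their modelled
#' response to environmental covariates: a finite mixture in which every OTU
#' belongs to one of G latent groups, each group carrying a shared
#' coefficient profile \eqn{\beta_g} and dispersion \eqn{\theta_g}, while a
#' per-OTU intercept \eqn{\alpha_i} absorbs differences in overall abundance
#' so that grouping reflects response shape, not commonness. For OTU i with
#' counts \eqn{y_{ij}} over samples j and covariate rows \eqn{x_j}, the
#' mixture log-likelihood is
#' \deqn{\ell = \sum_i \log \sum_g \pi_g \prod_j NB(y_{ij};
#'   \exp(\alpha_i + x_j'\beta_g), \theta_g)}
#' maximised by EM: the E-step computes membership probabilities
#' \eqn{\tau_{ig}} in log space (log-sum-exp); the M-step updates the mixing
#' proportions, refits each group's \eqn{(\beta_g, \theta_g)} by
#' \eqn{\tau}-weighted NB regression, and updates the \eqn{\alpha_i} by a
#' safeguarded Newton step. Every block update is accepted only if it does
#' not decrease its objective, so the observed-data log-likelihood is
#' non-decreasing across iterations (generalised EM).
NULL

# log f_ig matrix: per-OTU per-group log-likelihood contributions
mix_logf <- function(Y, eta_g, alpha, theta, offmat = NULL) {
  n_otu <- nrow(Y); G <- ncol(eta_g$beta_eta)
  out <- matrix(0, n_otu, G)
  for (g in seq_len(G)) {
    lmu <- outer(alpha, eta_g$beta_eta[, g], "+")
    if (!is.null(offmat)) lmu <- lmu + offmat
    mu <- exp(pmin(lmu, 30))
    out[, g] <- rowSums(stats::dnbinom(Y, size = theta[g], mu = mu, log = TRUE))
  }
  out
}

# row-wise log-sum-exp
row_lse <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit the ecogroup (species archetype) mixture by EM
#'
#' @param counts OTU count matrix; either samples x OTUs (as stored in a
#'   `fungal_dataset`, transposed internally) when `otus_as_rows = FALSE`, or
#'   already OTUs x samples. Intended for a rarefied table (equal library
#'   sizes), in which case no offset is needed; pass `offset` (per sample,
#'   log scale) for unrarefied use.
#' @param design samples x p covariate matrix WITHOUT an intercept column
#'   (the per-OTU intercepts play that role).
#' @param G number of ecogroups (the analysis default is the number of
#'   fungal trophic groups, 6).
#' @param n_starts number of EM starts: start 1 is deterministic (k-means on
#'   per-OTU independent NB-GLM coefficient vectors), the rest draw random
#'   responsibilities.
#' @param seed integer seed controlling all starts.
#' @param tol relative log-likelihood stopping tolerance.
#' @param max_iter maximum EM iterations per start.
#' @param offset optional per-sample log offset.
#' @param otus_as_rows set `TRUE` when `counts` is already OTUs x samples.
#' @param shared_intercept fit one common intercept inside each group's
#'   coefficient vector instead of per-OTU intercepts.
#' @return object of class `ecogroup_model`: `G`, `pi`, `beta` (G x p),
#'   `alpha`, `theta`, `tau`, `log_likelihood`, `trace` (log-likelihood per
#'   EM iteration of the winning start), `converged`, and fitting metadata.
#'   Groups are relabelled in decreasing order of `pi`.
#' @export
fit_archetype_mixture <- function(counts, design, G = 6, n_starts = 3,
                                  seed = 1L, tol = 1e-6, max_iter = 500,
                                  offset = NULL, otus_as_rows = FALSE,
                                  shared_intercept = FALSE) {
  Y <- if (otus_as_rows) as.matrix(counts) else t(as.matrix(counts))
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  nz <- rowSums(Y) > 0
  if (!all(nz)) {
    message(sum(!nz), " all-zero OTU(s) dropped before mixture fitting")
    Y <- Y[nz, , drop = FALSE]
  }
  n_otu <- nrow(Y); n_samp <- ncol(Y); p <- ncol(X)
  if (G > n_otu) stop("G exceeds the number of OTUs")
  if (n_samp != nrow(X)) stop("design rows must match the number of samples")
  offmat <- if (!is.null(offset)) matrix(offset, n_otu, n_samp, byrow = TRUE)

  if (shared_intercept) {
    X <- cbind("(Intercept)" = 1, X)
    p <- p + 1L
  }

  em_run <- function(tau) {
    pi_g <- pmax(colMeans(tau), 1e-10); pi_g <- pi_g / sum(pi_g)
    alpha <- log(rowMeans(Y) + 0.1) - if (is.null(offmat)) 0 else mean(offmat)
    if (shared_intercept) alpha <- rep(0, n_otu)
    beta <- matrix(0, p, G, dimnames = list(colnames(X), NULL))
    theta <- rep(1, G)
    ovec <- if (is.null(offset)) rep(0, n_samp) else offset
    # stacked layout: observation (i, j) at index i + (j-1) * n_otu
    yv <- as.vector(Y)
    Xs <- X[rep(seq_len(n_samp), each = n_otu), , drop = FALSE]
    ovs <- rep(ovec, each = n_otu)
    ll <- -Inf; trace <- numeric(0); converged <- FALSE

    for (iter in seq_len(max_iter)) {
      ## M-step (uses current tau)
      pi_g <- pmax(colMeans(tau), 1e-10); pi_g <- pi_g / sum(pi_g)
      beta_eta <- X %*% beta
      for (g in seq_len(G)) {
        wv <- rep(tau[, g], n_samp)
        offv <- rep(alpha, n_samp) + ovs
        q_old <- nb_log_likelihood(yv, exp(pmin(Xs %*% beta[, g] + offv, 30)),
                                   theta[g], wv)
        fit <- tryCatch(
          nb_irls(yv, Xs, offv, wv, beta = beta[, g], theta = theta[g],
                  maxit = 4),
          error = function(e) NULL)
        if (!is.null(fit) && fit$ll >= q_old) {
          beta[, g] <- fit$beta
          mu_g <- fit$mu
        } else {
          mu_g <- exp(pmin(drop(Xs %*% beta[, g]) + offv, 30))
        }
        th_new <- nb_theta_ml(yv, mu_g, wv)
        if (nb_log_likelihood(yv, mu_g, th_new, wv) >=
            nb_log_likelihood(yv, mu_g, theta[g], wv))
          theta[g] <- th_new
      }
      beta_eta <- X %*% beta

      ## alpha update: safeguarded Newton, vectorised over OTUs
      if (!shared_intercept) {
        obj_alpha <- function(a) {
          q <- matrix(0, n_otu, G)
          for (g in seq_len(G)) {
            lmu <- outer(a, beta_eta[, g], "+")
            if (!is.null(offmat)) lmu <- lmu + offmat
            q[, g] <- rowSums(stats::dnbinom(Y, size = theta[g],
                                             mu = exp(pmin(lmu, 30)), log = TRUE))
          }
          rowSums(tau * q)
        }
        for (sweep in 1:2) {
          grad <- info <- rep(0, n_otu)
          for (g in seq_len(G)) {
            lmu <- outer(alpha, beta_eta[, g], "+")
            if (!is.null(offmat)) lmu <- lmu + offmat
            mu <- exp(pmin(lmu, 30))
            grad <- grad + tau[, g] *
              rowSums((Y - mu) * theta[g] / (mu + theta[g]))
            info <- info + tau[, g] *
              rowSums(mu * theta[g] / (mu + theta[g]))
          }
          step <- grad / pmax(info, 1e-8)
          step <- pmax(pmin(step, 2), -2)
          q0 <- obj_alpha(alpha)
          accepted <- rep(FALSE, n_otu)
          for (h in 0:4) {
            cand <- ifelse(accepted, alpha, alpha + step / 2^h)
            q1 <- obj_alpha(cand)
            better <- !accepted & q1 >= q0 - 1e-12
            alpha[better] <- cand[better]
            accepted <- accepted | better
            if (all(accepted)) break
          }
          if (max(abs(grad / pmax(info, 1e-8))) < 1e-6) break
        }
      }

      ## E-step and observed-data log-likelihood
      beta_eta <- X %*% beta
      logf <- mix_logf(Y, list(beta_eta = beta_eta), alpha, theta, offmat)
      a <- sweep(logf, 2, log(pi_g), "+")
      lse <- row_lse(a)
      tau <- exp(a - lse)
      ll_new <- sum(lse)
      trace <- c(trace, ll_new)
      if (is.finite(ll) && abs(ll_new - ll) < tol * (abs(ll) + 1)) {
        ll <- ll_new; converged <- TRUE; break
      }
      ll <- ll_new
    }
    list(pi = pi_g, beta = t(beta), alpha = alpha, theta = theta,
         tau = tau, ll = ll, trace = trace, converged = converged)
  }

  ## starts
  set.seed(seed)
  starts <- list()
  km_tau <- tryCatch({
    coefs <- t(vapply(seq_len(n_otu), function(i) {
      f <- suppressWarnings(
        fit_nb_glm(Y[i, ], cbind("(Intercept)" = 1, as.matrix(design)),
                   offset = offset, max_iter = 25, tol = 1e-6))
      f$coefficients[-1]
    }, numeric(ncol(design))))
    coefs_s <- scale(coefs)
    coefs_s[!is.finite(coefs_s)] <- 0
    km <- stats::kmeans(coefs_s, centers = min(G, n_otu),
                        nstart = 5, iter.max = 30)
    tau0 <- matrix(1e-3, n_otu, G)
    tau0[cbind(seq_len(n_otu), km$cluster)] <- 1
    tau0 / rowSums(tau0)
  }, error = function(e) NULL)
  if (!is.null(km_tau)) starts[[1]] <- km_tau
  while (length(starts) < n_starts) {
    r <- matrix(stats::runif(n_otu * G, 0.05, 1), n_otu, G)
    starts[[length(starts) + 1]] <- r / rowSums(r)
  }

  runs <- lapply(starts, em_run)
  best <- runs[[which.max(vapply(runs, function(r) r$ll, 0))]]

  ## canonical order: decreasing pi
  ord <- order(best$pi, decreasing = TRUE)
  out <- list(
    G = G, pi = best$pi[ord],
    beta = best$beta[ord, , drop = FALSE],
    alpha = stats::setNames(best$alpha, rownames(Y)),
    theta = best$theta[ord],
    tau = best$tau[, ord, drop = FALSE],
    log_likelihood = best$ll, trace = best$trace,
    converged = best$converged,
    n_starts = length(starts), seed = seed, tol = tol,
    terms = colnames(X), otu_ids = rownames(Y),
    shared_intercept = shared_intercept)
  rownames(out$tau) <- rownames(Y)
  rownames(out$beta) <- paste0("ecogroup", seq_len(G))
  class(out) <- "ecogroup_model"
  out
}

#' @export
print.ecogroup_model <- function(x, ...) {
  cat(sprintf(
    "Ecogroup mixture: G = %d, %d OTUs, log-likelihood %.2f (converged: %s)\n",
    x$G, length(x$otu_ids), x$log_likelihood, x$converged))
  cat("mixing proportions:", paste(round(x$pi, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Recompute membership probabilities from an ecogroup model
#'
#' @param model an `ecogroup_model`.
#' @param counts count matrix (same orientation convention as the fit).
#' @param design samples x p covariate matrix matching the model terms.
#' @param offset optional per-sample log offset.
#' @param otus_as_rows as in [fit_archetype_mixture()].
#' @return n_OTU x G matrix whose rows sum to 1.
#' @export
responsibilities <- function(model, counts, design, offset = NULL,
                             otus_as_rows = FALSE) {
  Y <- if (otus_as_rows) as.matrix(counts) else t(as.matrix(counts))
  X <- as.matrix(design)
  if (model$shared_intercept) X <- cbind("(Intercept)" = 1, X)
  offmat <- if (!is.null(offset))
    matrix(offset, nrow(Y), ncol(Y), byrow = TRUE)
  beta_eta <- X %*% t(model$beta)
  logf <- mix_logf(Y, list(beta_eta = beta_eta), model$alpha, model$theta,
                   offmat)
  a <- sweep(logf, 2, log(model$pi), "+")
  tau <- exp(a - row_lse(a))
  rownames(tau) <- rownames(Y)
  tau
}

#' Assign each OTU to its highest-probability ecogroup
#'
#' Ties are broken toward the lowest group index (and logged).
#'
#' @param model an `ecogroup_model`.
#' @return data.frame (`otu_id`, `ecogroup`, `probability`).
#' @export
assign_ecogroups <- function(model) {
  tau <- model$tau
  idx <- max.col(tau, ties.method = "first")
  ties <- rowSums(abs(tau - tau[cbind(seq_len(nrow(tau)), idx)]) < 1e-12) > 1
  if (any(ties))
    message(sum(ties), " OTU(s) with tied membership assigned to the ",
            "lowest group index")
  data.frame(otu_id = rownames(tau), ecogroup = idx,
             probability = tau[cbind(seq_len(nrow(tau)), idx)],
             stringsAsFactors = FALSE)
}

#' Long-format ecogroup coefficient profiles
#'
#' One row per (ecogroup, term) pair; coefficients near 0 indicate little
#' relationship between that covariate and member-OTU abundance. Abiotic and
#' biotic models produce independent group numberings.
#'
#' @param model an `ecogroup_model`.
#' @return data.frame (`ecogroup`, `term`, `coefficient`).
#' @export
coefficient_profiles <- function(model) {
  data.frame(
    ecogroup = rep(seq_len(model$G), each = length(model$terms)),
    term = rep(model$terms, model$G),
    coefficient = as.vector(t(model$beta)),
    stringsAsFactors = FALSE)
}
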