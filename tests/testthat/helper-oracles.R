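# Brute-force grid maximisation of the exact NB log-likelihood over
# (beta, log theta), by iterative grid refinement. Independent of the
# package's IRLS fitting path: it only evaluates the likelihood.
oracle_nb_grid <- function(y, X, rounds = 7, pts = 15,
                           beta_range = c(-4, 5), ltheta_range = c(-3, 8)) {
  p <- ncol(X)
  lo <- c(rep(beta_range[1], p), ltheta_range[1])
  hi <- c(rep(beta_range[2], p), ltheta_range[2])
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p + 1), function(k) seq(lo[k], hi[k], length.out = pts))
    combos <- as.matrix(expand.grid(grids))
    ll <- apply(combos, 1, function(par) {
      mu <- exp(drop(X %*% par[1:p]))
      sum(stats::dnbinom(y, size = exp(par[p + 1]), mu = mu, log = TRUE))
    })
    best <- combos[which.max(ll), ]
    spacing <- (hi - lo) / (pts - 1)
    lo <- best - 1.5 * spacing
    hi <- best + 1.5 * spacing
  }
  list(beta = unname(best[1:p]), theta = exp(unname(best[p + 1])),
       log_likelihood = max(ll))
}

# Term-by-term NB2 log-density via its gamma-function form (test oracle)
oracle_nb_density_log <- function(y, mu, theta) {
  lgamma(y + theta) - lgamma(theta) - lgamma(y + 1) +
    theta * log(theta / (theta + mu)) + y * log(mu / (theta + mu))
}

# Fixed tiny overdispersed fixtures for oracle-equivalence checks
oracle_fixtures <- function() {
  fx <- list(
    list(y = c(0, 1, 0, 8), x = NULL),
    list(y = c(2, 10, 1, 7, 0), x = NULL),
    list(y = c(3, 0, 0, 1, 12, 2), x = NULL),
    list(y = c(15, 0, 3, 1, 20, 2), x = c(1, 0, 1, 0, 1, 0)),
    list(y = c(0, 2, 1, 9, 4, 14, 1, 7), x = c(0, 0, 0, 0, 1, 1, 1, 1)))
  lapply(fx, function(f) {
    f$X <- if (is.null(f$x)) matrix(1, length(f$y), 1) else cbind(1, f$x)
    f
  })
}
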