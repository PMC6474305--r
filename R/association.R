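#' Observed and expected ecogroup x trophic-group contingency table
#'
#' Cross-tabulates OTUs' ecogroup assignments against their trophic (guild)
#' labels; expected counts under no association are
#' \eqn{E_{ij} = (row_i \times col_j)/N}, and
#' \eqn{X^2 = \sum (O-E)^2/E}. Levels with a zero margin are dropped with a
#' warning. OTUs with an "unassigned" guild are usually excluded by the
#' caller before testing (see [permutation_chi_squared()]).
#'
#' @param ecogroup categorical vector of ecogroup labels, one per OTU.
#' @param guild categorical vector of trophic-group labels, same length.
#' @return object of class `contingency_result` (without a P-value):
#'   `observed`, `expected`, `chi_squared`.
#' @export
contingency_expected <- function(ecogroup, guild) {
  if (length(ecogroup) != length(guild))
    stop("label vectors must have equal length")
  eco <- droplevels(factor(ecogroup))
  gld <- droplevels(factor(guild))
  O <- table(ecogroup = eco, guild = gld)
  zr <- rowSums(O) == 0; zc <- colSums(O) == 0
  if (any(zr) || any(zc)) {
    warning("zero-margin level(s) dropped: ",
            paste(c(rownames(O)[zr], colnames(O)[zc]), collapse = ", "))
    O <- O[!zr, !zc, drop = FALSE]
  }
  if (nrow(O) < 2L || ncol(O) < 2L)
    stop("need at least two levels in each classification")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  structure(list(observed = O, expected = E,
                 chi_squared = sum((O - E)^2 / E)),
            class = "contingency_result")
}

#' Permutation chi-squared test of ecogroup / guild association
#'
#' Permutes the guild labels across OTUs `n_perm` times, recomputing the
#' chi-squared statistic each time (both margins, hence the expected table,
#' are preserved by permutation). The P-value uses the add-one estimator
#' \eqn{(1 + \#\{X^2_{perm} \ge X^2_{obs}\})/(n\_perm + 1)}, so its floor is
#' \eqn{1/(n\_perm+1)}. A Monte-Carlo Fisher-style P-value
#' (`stats::fisher.test` with simulated null) is reported alongside when
#' `fisher = TRUE`.
#'
#' @param ecogroup,guild equal-length label vectors (one entry per OTU).
#' @param n_perm number of permutations (the analysis default is 10,000).
#' @param seed integer RNG seed.
#' @param exclude_unassigned drop OTUs whose guild is "unassigned" before
#'   testing (default TRUE; set FALSE to keep them as their own category).
#' @param fisher also compute the Monte-Carlo Fisher P-value.
#' @return object of class `contingency_result` with `observed`, `expected`,
#'   `chi_squared`, `p_perm`, `p_fisher`, `n_perm`, `seed`.
#' @export
permutation_chi_squared <- function(ecogroup, guild, n_perm = 10000,
                                    seed = 1L, exclude_unassigned = TRUE,
                                    fisher = FALSE) {
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  if (length(ecogroup) != length(guild))
    stop("label vectors must have equal length")
  keep <- if (exclude_unassigned) guild != "unassigned" else
    rep(TRUE, length(guild))
  base <- contingency_expected(ecogroup[keep], guild[keep])
  O <- base$observed; E <- base$expected
  Gn <- nrow(O); Fn <- ncol(O)
  ei <- as.integer(factor(as.character(ecogroup[keep]), levels = rownames(O)))
  gi <- as.integer(factor(as.character(guild[keep]), levels = colnames(O)))
  ok <- !is.na(ei) & !is.na(gi)  # entries of dropped zero-margin levels
  ei <- ei[ok]; gi <- gi[ok]
  N <- length(ei)
  chi_obs <- base$chi_squared
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    gp <- gi[sample.int(N)]
    Ob <- tabulate(ei + (gp - 1L) * Gn, nbins = Gn * Fn)
    chib <- sum((Ob - E)^2 / E)
    if (chib >= chi_obs - 1e-9) exceed <- exceed + 1L
  }
  p_fisher <- NA_real_
  if (fisher)
    p_fisher <- tryCatch(
      stats::fisher.test(O, simulate.p.value = TRUE, B = n_perm)$p.value,
      error = function(e) NA_real_)
  structure(list(observed = O, expected = E, chi_squared = chi_obs,
                 p_perm = (1 + exceed) / (n_perm + 1),
                 p_fisher = p_fisher, n_perm = n_perm, seed = seed),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("Ecogroup x trophic-group association: X^2 = %.3f\n",
              x$chi_squared))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation P = %.4g (%d permutations)\n",
                x$p_perm, x$n_perm))
  if (!is.null(x$p_fisher) && is.finite(x$p_fisher))
    cat(sprintf("  Monte-Carlo Fisher P = %.4g\n", x$p_fisher))
  cat("observed:\n"); print(x$observed)
  cat("expected (no association):\n"); print(round(x$expected, 1))
  invisible(x)
}
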