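#' Root-mean-square predictive error of a richness model on target samples
#'
#' Predictions come from [predict_mean()] on the target samples' covariates
#' and library sizes; the error is
#' \eqn{\sqrt{mean((predicted - observed)^2)}}.
#'
#' @param fit site-trained `nb_glm` richness model.
#' @param target_samples scoped sample data.frame (with `library_size`).
#' @param target_richness observed OTU richness at the target samples.
#' @param vset the [variable_set()] the model was trained with.
#' @return non-negative scalar RMSE.
#' @export
predictive_error <- function(fit, target_samples, target_richness, vset) {
  if (nrow(target_samples) == 0L) stop("empty target sample set")
  d <- build_design(target_samples, vset, scale_spec("site", "transfer"),
                    mode = "richness")
  pred <- predict_mean(fit, d$X)
  sqrt(mean((pred - target_richness)^2))
}

#' Train-site x target-site predictive-error matrix
#'
#' For every ordered pair of sites, a richness model (one variable set,
#' site-scale design, no site factor) is trained on the first site and used
#' to predict OTU richness at the second; the cell stores the RMSE. Diagonal
#' cells are in-sample errors.
#'
#' @param dataset a `fungal_dataset` with at least two sites.
#' @param vset a [variable_set()].
#' @return object of class `transfer_matrix`: `values` (train rows x target
#'   columns), `variable_set`, `site_region`.
#' @export
transfer_matrix <- function(dataset, vset) {
  sites <- sort(unique(dataset$samples$site))
  if (length(sites) < 2L) stop("need at least 2 sites")
  site_region <- vapply(sites, function(s)
    dataset$samples$region[match(s, dataset$samples$site)], "")
  scoped <- lapply(sites, function(s) scope_samples(dataset, scale_spec("site", s)))
  names(scoped) <- sites
  vals <- matrix(NA_real_, length(sites), length(sites),
                 dimnames = list(train = sites, target = sites))
  for (tr in sites) {
    fit <- tryCatch({
      d <- build_design(scoped[[tr]], vset, scale_spec("site", tr), "richness")
      fit_nb_glm(scoped[[tr]]$richness, d$X)
    }, error = function(e) {
      warning("fit failed on training site ", tr, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(fit)) next
    for (tg in sites)
      vals[tr, tg] <- predictive_error(fit, scoped[[tg]],
                                       scoped[[tg]]$richness, vset)
  }
  structure(list(values = vals, variable_set = vset$name,
                 site_region = site_region),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Predictive-error (RMSE) matrix, %s variables\n", x$variable_set))
  print(round(x$values, 2))
  invisible(x)
}

#' @export
plot.transfer_matrix <- function(x, ...) {
  v <- log(x$values)
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, ]), axes = FALSE,
                  xlab = "target site", ylab = "training site",
                  main = paste("log predictive error,", x$variable_set), ...)
  graphics::axis(1, seq_len(n), colnames(v), las = 2)
  graphics::axis(2, seq_len(n), rev(rownames(v)), las = 2)
  invisible(x)
}

#' Within/between-region ANOVA on log predictive errors
#'
#' Matrix cells are grouped into one within-region group per region (training
#' and target site in the same region, diagonal cells included) and a single
#' between-region group; a one-way ANOVA is run on log(RMSE), with Tukey HSD
#' adjusted pairwise comparisons. With 6 sites in 2 regions of 3 this gives
#' groups of 9, 9 and 18 cells and error df 33.
#'
#' @param tm a [transfer_matrix()].
#' @return object of class `transfer_anova`: `F`, `df`, `p`, `tukey`,
#'   `groups`, `data`.
#' @export
region_transfer_anova <- function(tm) {
  v <- tm$values
  if (anyNA(v)) stop("transfer matrix contains missing cells")
  reg <- tm$site_region
  grp <- outer(reg, reg, function(a, b)
    ifelse(a == b, paste0("within-", a), "between-region"))
  vals <- as.vector(v)
  if (any(vals == 0)) {
    warning("zero RMSE cell(s); replaced by half the smallest positive value")
    vals[vals == 0] <- min(vals[vals > 0]) / 2
  }
  dat <- data.frame(log_error = log(vals), group = factor(as.vector(grp)))
  fit <- stats::aov(log_error ~ group, data = dat)
  an <- summary(fit)[[1]]
  structure(list(
    F = an[1, "F value"], df = c(an[1, "Df"], an[2, "Df"]),
    p = an[1, "Pr(>F)"],
    tukey = stats::TukeyHSD(fit)$group,
    groups = table(dat$group), data = dat), class = "transfer_anova")
}

#' @export
print.transfer_anova <- function(x, ...) {
  cat(sprintf("ANOVA on log predictive errors: F(%d,%d) = %.2f, P = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  cat("group sizes:\n"); print(x$groups)
  cat("Tukey HSD adjusted pairwise P-values:\n")
  print(round(x$tukey, 4))
  invisible(x)
}
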