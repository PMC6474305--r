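ABIOTIC_TERMS <- c("season", "salinity", "ph", "moisture")
BIOTIC_TERMS <- c("plant_richness", "root_biomass", "cover_herb",
                  "cover_shrub", "cover_grass", "cover_sedge", "cover_rush")

#' Define an abiotic or biotic variable set
#'
#' The abiotic set holds season, salinity, pH and soil moisture, plus a site
#' factor when data from several sites are pooled (regional/overall scales).
#' The biotic set holds plant species richness, total root biomass and the
#' percentage cover of the five plant growth-form groups; it never includes
#' the site factor.
#'
#' @param name "abiotic" or "biotic".
#' @return list with `name` and `terms`.
#' @export
variable_set <- function(name = c("abiotic", "biotic")) {
  name <- match.arg(name)
  terms <- if (name == "abiotic") ABIOTIC_TERMS else BIOTIC_TERMS
  structure(list(name = name, terms = terms), class = "variable_set")
}

#' Define an analysis scale (site, region, or all data pooled)
#'
#' @param level "site", "region" or "overall".
#' @param unit the site or region label; ignored for "overall".
#' @export
scale_spec <- function(level = c("site", "region", "overall"), unit = "all") {
  level <- match.arg(level)
  if (level == "overall") unit <- "all"
  structure(list(level = level, unit = unit), class = "scale_spec")
}

scale_label <- function(scale) {
  if (scale$level == "overall") "overall" else scale$unit
}

#' All site, region and overall scales present in a dataset
#' @param dataset a `fungal_dataset`.
#' @return list of [scale_spec()] objects (sites, then regions, then overall).
#' @export
enumerate_scales <- function(dataset) {
  sites <- sort(unique(dataset$samples$site))
  regions <- sort(unique(dataset$samples$region))
  c(lapply(sites, function(s) scale_spec("site", s)),
    lapply(regions, function(r) scale_spec("region", r)),
    list(scale_spec("overall")))
}

#' Subset a dataset's samples to one analysis scale
#'
#' @param dataset a `fungal_dataset`.
#' @param scale a [scale_spec()].
#' @return data.frame of sample metadata with `library_size` and `richness`
#'   columns appended.
#' @export
scope_samples <- function(dataset, scale) {
  s <- dataset$samples
  s$library_size <- dataset$library_size
  s$richness <- dataset$richness
  idx <- switch(scale$level,
    site = s$site == scale$unit,
    region = s$region == scale$unit,
    overall = rep(TRUE, nrow(s)))
  if (!any(idx)) stop("no samples in scope for scale '", scale_label(scale), "'")
  s[idx, , drop = FALSE]
}

#' Build a design matrix for richness or abundance models
#'
#' Richness mode: the intercept is followed by log(library size) as the first
#' covariate (its coefficient is estimated), then the variable-set terms.
#' Abundance mode: the same covariates, but log(library size) is returned as
#' an offset with coefficient fixed at 1. The abiotic set gains site dummies
#' only when the scale pools several sites (region/overall); terms constant
#' within scope are dropped with a warning. Categorical terms use treatment
#' contrasts with the lexicographically first level as reference; season's
#' reference is summer, so positive coefficients mean higher in winter.
#'
#' @param samples scoped sample data.frame (from [scope_samples()]), must
#'   include `library_size`.
#' @param vset a [variable_set()].
#' @param scale a [scale_spec()].
#' @param mode "richness" or "abundance".
#' @return list with `X` (design matrix incl. intercept), `offset` (vector or
#'   `NULL`), and `dropped` (names of constant terms removed).
#' @export
build_design <- function(samples, vset, scale, mode = c("richness", "abundance")) {
  mode <- match.arg(mode)
  if (any(samples$library_size <= 0)) stop("zero library size in scope")
  terms <- vset$terms
  if (vset$name == "abiotic" && scale$level %in% c("region", "overall"))
    terms <- c("site", terms)

  cols <- list("(Intercept)" = rep(1, nrow(samples)))
  loglib <- log(samples$library_size)
  offset <- NULL
  if (mode == "richness") cols$log_lib <- loglib else offset <- loglib

  dropped <- character(0)
  for (tm in terms) {
    v <- samples[[tm]]
    if (length(unique(v)) < 2L) {
      dropped <- c(dropped, tm)
      next
    }
    if (tm == "season") {
      cols$seasonwinter <- as.numeric(v == "winter")
    } else if (tm == "site") {
      lev <- sort(unique(v))
      for (l in lev[-1]) cols[[paste0("site", l)]] <- as.numeric(v == l)
    } else {
      cols[[tm]] <- as.numeric(v)
    }
  }
  if (length(dropped))
    warning("term(s) constant within scope dropped: ",
            paste(dropped, collapse = ", "))
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, offset = offset, dropped = dropped)
}

#' Fit and compare abiotic vs biotic richness models at one scale
#'
#' Fits negative-binomial GLMs of OTU richness on each variable set for the
#' samples in scope and records AIC, adjusted D-squared and the lower-AIC
#' winner, together with coefficient tables (Wald z tests).
#'
#' @param dataset a `fungal_dataset`.
#' @param scale a [scale_spec()].
#' @param min_samples smallest number of in-scope samples allowed.
#' @return object of class `richness_comparison` with per-set fits, `aic`,
#'   `adj_d2` and `winner`.
#' @export
fit_scale_models <- function(dataset, scale, min_samples = 10) {
  sm <- scope_samples(dataset, scale)
  if (nrow(sm) < min_samples)
    stop("only ", nrow(sm), " samples in scope; need >= ", min_samples)
  fits <- list()
  for (vname in c("abiotic", "biotic")) {
    vs <- variable_set(vname)
    d <- build_design(sm, vs, scale, mode = "richness")
    fits[[vname]] <- fit_nb_glm(sm$richness, d$X)
  }
  aic <- vapply(fits, function(f) f$aic, 0)
  adj <- vapply(fits, adjusted_d2, 0)
  out <- list(scale = scale, fits = fits, aic = aic, adj_d2 = adj,
              n = nrow(sm),
              winner = names(aic)[which.min(aic)])
  class(out) <- "richness_comparison"
  out
}

#' @export
print.richness_comparison <- function(x, ...) {
  cat(sprintf("Richness models at scale '%s' (n = %d)\n",
              scale_label(x$scale), x$n))
  for (v in names(x$fits))
    cat(sprintf("  %-8s AIC %9.1f  adj-D2 %s\n",
                v, x$aic[[v]], format_adj_d2(x$adj_d2[[v]])))
  cat("  winner (lower AIC):", x$winner, "\n")
  invisible(x)
}

#' AIC / adjusted D-squared comparison table across all scales
#'
#' One row per site, per region, and overall, with the AIC and adjusted
#' D-squared of the abiotic and biotic richness models (negative adjusted
#' values are rendered as "0 (value)" in the formatted columns).
#'
#' @param dataset a `fungal_dataset`.
#' @param scales list of [scale_spec()]; default every scale in the dataset.
#' @return data.frame with numeric and formatted comparison columns.
#' @export
richness_table <- function(dataset, scales = enumerate_scales(dataset)) {
  rows <- lapply(scales, function(sc) {
    cmp <- fit_scale_models(dataset, sc)
    data.frame(
      scale = scale_label(sc), level = sc$level, n = cmp$n,
      aic_abiotic = cmp$aic[["abiotic"]],
      adj_d2_abiotic = cmp$adj_d2[["abiotic"]],
      aic_biotic = cmp$aic[["biotic"]],
      adj_d2_biotic = cmp$adj_d2[["biotic"]],
      winner = cmp$winner, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_d2_abiotic_fmt <- format_adj_d2(out$adj_d2_abiotic)
  out$adj_d2_biotic_fmt <- format_adj_d2(out$adj_d2_biotic)
  out
}

#' Coefficient table for one fitted richness comparison
#'
#' @param cmp a `richness_comparison`.
#' @return long data.frame (scale, variable_set, term, estimate, se, z, p).
#' @export
coefficient_table <- function(cmp) {
  do.call(rbind, lapply(names(cmp$fits), function(v) {
    f <- cmp$fits[[v]]
    data.frame(scale = scale_label(cmp$scale), variable_set = v,
               term = names(f$coefficients),
               estimate = unname(f$coefficients), se = unname(f$se),
               z = unname(f$z), p = unname(f$p_values),
               stringsAsFactors = FALSE)
  }))
}
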