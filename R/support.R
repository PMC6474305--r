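#' Filter OTUs by prevalence and total abundance within a scope
#'
#' @param counts samples x OTUs matrix.
#' @param min_prevalence keep OTUs present (count > 0) in at least this many
#'   samples.
#' @param min_total keep OTUs with at least this total count.
#' @return the filtered matrix.
#' @export
filter_otus <- function(counts, min_prevalence = 5, min_total = 0) {
  if (min_prevalence < 0 || min_total < 0) stop("thresholds must be >= 0")
  keep <- colSums(counts > 0) >= min_prevalence & colSums(counts) >= min_total
  if (!any(keep)) stop("all OTUs removed by the filter")
  counts[, keep, drop = FALSE]
}

#' Classify an OTU's variable-set support from a pair of AICs
#'
#' An OTU supports the biotic set when the abiotic model's AIC exceeds the
#' biotic one by more than `threshold` (default 2), the abiotic set in the
#' mirror case, and neither ("no_support") when the gap is `<= threshold`
#' (a gap of exactly 2 is no_support).
#'
#' @param aic_abiotic,aic_biotic finite AIC values (vectorised).
#' @param threshold AIC-gap required for support.
#' @return character vector in {"abiotic", "biotic", "no_support"}.
#' @export
classify_support <- function(aic_abiotic, aic_biotic, threshold = 2) {
  if (any(!is.finite(aic_abiotic)) || any(!is.finite(aic_biotic)))
    stop("AIC values must be finite")
  delta <- aic_abiotic - aic_biotic
  ifelse(delta > threshold, "biotic",
         ifelse(delta < -threshold, "abiotic", "no_support"))
}

#' Per-OTU abiotic vs biotic abundance models at one scale
#'
#' Each OTU passing the prevalence/total filter is modelled twice with
#' negative-binomial GLMs of its counts (log link, log library size as an
#' offset with coefficient fixed at 1): once on the abiotic design, once on
#' the biotic design. The AIC pair classifies the OTU's support via
#' [classify_support()]. Fit failures are recorded per OTU without aborting
#' the scan.
#'
#' @param dataset a `fungal_dataset`.
#' @param scale a [scale_spec()].
#' @param min_prevalence,min_total OTU filter thresholds (applied in scope).
#' @param threshold AIC-gap for support classification.
#' @return object of class `support_result`: per-OTU data.frame
#'   (`otu_id`, `aic_abiotic`, `aic_biotic`, `delta`, `label`), `scale`,
#'   `n_failed`.
#' @export
fit_per_otu_models <- function(dataset, scale, min_prevalence = 5,
                               min_total = 0, threshold = 2) {
  sm <- scope_samples(dataset, scale)
  counts <- dataset$counts[sm$sample_id, , drop = FALSE]
  counts <- filter_otus(counts, min_prevalence, min_total)
  designs <- lapply(c(abiotic = "abiotic", biotic = "biotic"), function(v)
    build_design(sm, variable_set(v), scale, mode = "abundance"))
  res <- lapply(colnames(counts), function(otu) {
    aics <- vapply(designs, function(d) {
      tryCatch(
        suppressWarnings(fit_nb_glm(counts[, otu], d$X, offset = d$offset)$aic),
        error = function(e) NA_real_)
    }, 0)
    data.frame(otu_id = otu, aic_abiotic = aics[["abiotic"]],
               aic_biotic = aics[["biotic"]], stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  failed <- !is.finite(tab$aic_abiotic) | !is.finite(tab$aic_biotic)
  if (any(failed))
    message(sum(failed), " OTU(s) unfit at scale '", scale_label(scale),
            "'; excluded from summaries")
  tab <- tab[!failed, , drop = FALSE]
  if (!nrow(tab)) stop("no OTU could be fitted in scope")
  tab$delta <- tab$aic_abiotic - tab$aic_biotic
  tab$label <- classify_support(tab$aic_abiotic, tab$aic_biotic, threshold)
  structure(list(table = tab, scale = scale, n_failed = sum(failed),
                 threshold = threshold), class = "support_result")
}

#' Community-level summary of per-OTU support
#'
#' Label proportions over the analysed OTUs plus the community-level total
#' AIC (sum of per-OTU AICs) under each variable set.
#'
#' @param support a `support_result`, or a data.frame with columns
#'   `aic_abiotic`, `aic_biotic`, `label`.
#' @return object of class `support_summary` with `n_otus`, `proportions`,
#'   `sigma_aic_abiotic`, `sigma_aic_biotic`.
#' @export
support_summary <- function(support) {
  tab <- if (inherits(support, "support_result")) support$table else support
  if (!nrow(tab)) stop("no classified OTUs")
  lab <- factor(tab$label, levels = c("abiotic", "biotic", "no_support"))
  props <- as.vector(table(lab)) / nrow(tab)
  names(props) <- levels(lab)
  structure(list(
    n_otus = nrow(tab), proportions = props,
    sigma_aic_abiotic = sum(tab$aic_abiotic),
    sigma_aic_biotic = sum(tab$aic_biotic)), class = "support_summary")
}

#' @export
print.support_summary <- function(x, ...) {
  cat(sprintf("Support over %d analysed OTUs:\n", x$n_otus))
  for (l in names(x$proportions))
    cat(sprintf("  %-11s %5.1f%%\n", l, 100 * x$proportions[[l]]))
  cat(sprintf("  sigma-AIC abiotic %.1f, biotic %.1f -> community winner: %s\n",
              x$sigma_aic_abiotic, x$sigma_aic_biotic,
              if (x$sigma_aic_abiotic < x$sigma_aic_biotic) "abiotic" else "biotic"))
  invisible(x)
}
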