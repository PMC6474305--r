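#' Pipeline configuration
#'
#' Defaults follow the analysis workflow: rarefaction to 12,738 sequences
#' per sample before the mixture stage, 6 ecogroups (one per trophic group),
#' delta-AIC support threshold 2, and 10,000 permutations for the guild
#' association test.
#'
#' @param samples_path,otus_path,guilds_path input TSV paths; leave `NULL`
#'   and supply `simulation` to run on generated data.
#' @param simulation optional [sim_config()]; when given, data are simulated
#'   and written alongside the results.
#' @param out_dir output directory.
#' @param rarefaction_depth rarefaction depth for the mixture stage.
#' @param G number of ecogroups.
#' @param delta_aic_threshold AIC-gap for per-OTU support.
#' @param n_perm permutations for the association test.
#' @param min_prevalence,min_total OTU filter for abundance-level stages.
#' @param support_scales which scale levels get per-OTU support models:
#'   subset of c("site", "region", "overall").
#' @param mixture_starts,mixture_max_iter EM fitting controls.
#' @param seed base seed; each stochastic stage derives its own seed from it
#'   (recorded in the manifest).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(samples_path = NULL, otus_path = NULL,
                            guilds_path = NULL, simulation = NULL,
                            out_dir = "mycocontext_out",
                            rarefaction_depth = 12738, G = 6,
                            delta_aic_threshold = 2, n_perm = 10000,
                            min_prevalence = 5, min_total = 0,
                            support_scales = "overall",
                            mixture_starts = 2, mixture_max_iter = 200,
                            seed = 1L) {
  if (is.null(simulation) && (is.null(samples_path) || is.null(otus_path)))
    stop("supply input paths or a simulation config")
  stopifnot(all(support_scales %in% c("site", "region", "overall")))
  structure(list(
    samples_path = samples_path, otus_path = otus_path,
    guilds_path = guilds_path, simulation = simulation, out_dir = out_dir,
    rarefaction_depth = rarefaction_depth, G = G,
    delta_aic_threshold = delta_aic_threshold, n_perm = n_perm,
    min_prevalence = min_prevalence, min_total = min_total,
    support_scales = support_scales, mixture_starts = mixture_starts,
    mixture_max_iter = mixture_max_iter, seed = as.integer(seed)),
    class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full context-dependency analysis
#'
#' Stages, in order: read or simulate the dataset; richness model comparison
#' at every site, region and overall scale; cross-site transfer matrices and
#' region ANOVAs (both variable sets); per-OTU support classification;
#' rarefaction; ecogroup mixtures (abiotic and biotic designs,
#' independently); guild association tests. All stage outputs are TSV files
#' under `config$out_dir`, plus a JSON manifest recording seeds, parameters
#' and per-stage wall time. Identical config and seed give identical numeric
#' outputs. With `G = 1` the association stage is skipped (a single ecogroup
#' admits no association test).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  t_all <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
  }
  seeds <- list(simulate = config$seed,
                rarefy = config$seed + 101L,
                mixture_abiotic = config$seed + 211L,
                mixture_biotic = config$seed + 212L,
                association_abiotic = config$seed + 301L,
                association_biotic = config$seed + 302L)
  timings <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }
  results <- list()

  ## data
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- seeds$simulate
    sim <- timed("data", simulate_dataset(sim_cfg))
    ds <- sim$dataset
    results$truth <- sim$truth
    write_dataset(ds, config$out_dir)
    log_msg("data", "simulated ", nrow(ds$samples), " samples x ",
            ncol(ds$counts), " OTUs")
  } else {
    ds <- timed("data", read_dataset(config$samples_path, config$otus_path,
                                     config$guilds_path, quiet = quiet))
  }
  results$dataset <- ds

  ## richness scaling
  rt <- timed("richness", suppressWarnings(richness_table(ds)))
  write_tsv(rt, file.path(config$out_dir, "richness_comparison.tsv"))
  coefs <- do.call(rbind, lapply(enumerate_scales(ds), function(sc)
    coefficient_table(suppressWarnings(fit_scale_models(ds, sc)))))
  write_tsv(coefs, file.path(config$out_dir, "richness_coefficients.tsv"))
  results$richness <- rt
  log_msg("richness", "fitted ", nrow(rt), " scale comparisons")

  ## transfer
  results$transfer <- list()
  for (v in c("abiotic", "biotic")) {
    tm <- timed(paste0("transfer_", v),
                suppressWarnings(transfer_matrix(ds, variable_set(v))))
    write_tsv(data.frame(train = rownames(tm$values), tm$values,
                         check.names = FALSE),
              file.path(config$out_dir, paste0("transfer_matrix_", v, ".tsv")))
    an <- region_transfer_anova(tm)
    write_tsv(data.frame(variable_set = v, F = an$F, df1 = an$df[1],
                         df2 = an$df[2], p = an$p),
              file.path(config$out_dir, paste0("transfer_anova_", v, ".tsv")))
    write_tsv(data.frame(comparison = rownames(an$tukey), an$tukey,
                         check.names = FALSE),
              file.path(config$out_dir, paste0("transfer_tukey_", v, ".tsv")))
    results$transfer[[v]] <- list(matrix = tm, anova = an)
    log_msg("transfer", v, sprintf(": F(%d,%d) = %.2f, P = %.3g",
                                   an$df[1], an$df[2], an$F, an$p))
  }

  ## per-OTU support
  results$support <- list()
  for (lvl in config$support_scales) {
    scales <- Filter(function(s) s$level == lvl, enumerate_scales(ds))
    for (sc in scales) {
      lab <- scale_label(sc)
      sr <- timed(paste0("support_", lab),
                  suppressWarnings(fit_per_otu_models(
                    ds, sc, config$min_prevalence, config$min_total,
                    config$delta_aic_threshold)))
      write_tsv(sr$table,
                file.path(config$out_dir, paste0("support_", lab, ".tsv")))
      sm <- support_summary(sr)
      write_tsv(data.frame(scale = lab, n_otus = sm$n_otus,
                           t(sm$proportions),
                           sigma_aic_abiotic = sm$sigma_aic_abiotic,
                           sigma_aic_biotic = sm$sigma_aic_biotic),
                file.path(config$out_dir, paste0("support_summary_", lab, ".tsv")))
      results$support[[lab]] <- list(result = sr, summary = sm)
      log_msg("support", lab, ": ", sm$n_otus, " OTUs analysed")
    }
  }

  ## rarefy + mixtures + association
  rare <- timed("rarefy", suppressWarnings(
    rarefy(ds, config$rarefaction_depth, seed = seeds$rarefy)))
  log_msg("rarefy", nrow(rare), " samples at depth ", config$rarefaction_depth)
  rare_samples <- ds$samples[match(rownames(rare), ds$samples$sample_id), ]
  rare <- filter_otus(rare, config$min_prevalence, config$min_total)
  results$mixture <- list()
  results$association <- list()
  for (v in c("abiotic", "biotic")) {
    sc <- scale_spec("overall")
    sm <- rare_samples
    sm$library_size <- rowSums(rare)
    d <- build_design(sm, variable_set(v), sc, mode = "abundance")
    X <- d$X[, -1, drop = FALSE]  # intercept handled by per-OTU alpha
    cont <- setdiff(colnames(X), grep("^site|^season", colnames(X), value = TRUE))
    for (cc in cont) X[, cc] <- as.vector(scale(X[, cc]))
    mod <- timed(paste0("mixture_", v), fit_archetype_mixture(
      rare, X, G = config$G, n_starts = config$mixture_starts,
      seed = seeds[[paste0("mixture_", v)]],
      max_iter = config$mixture_max_iter))
    asn <- assign_ecogroups(mod)
    write_tsv(asn, file.path(config$out_dir, paste0("ecogroups_", v, ".tsv")))
    write_tsv(coefficient_profiles(mod),
              file.path(config$out_dir, paste0("ecogroup_profiles_", v, ".tsv")))
    write_tsv(data.frame(otu_id = rownames(mod$tau), mod$tau,
                         check.names = FALSE),
              file.path(config$out_dir, paste0("ecogroup_tau_", v, ".tsv")))
    jsonlite::write_json(
      list(G = mod$G, pi = mod$pi, beta = mod$beta, theta = mod$theta,
           log_likelihood = mod$log_likelihood, converged = mod$converged,
           n_starts = mod$n_starts, seed = mod$seed, terms = mod$terms),
      file.path(config$out_dir, paste0("ecogroup_model_", v, ".json")),
      digits = NA, auto_unbox = TRUE)
    results$mixture[[v]] <- mod
    log_msg("ecogroups", v, ": logLik ", round(mod$log_likelihood, 1))

    if (config$G < 2) {
      log_msg("association", "skipped: a single ecogroup has no association test")
      next
    }
    guild <- results$dataset$guilds[asn$otu_id]
    assoc <- timed(paste0("association_", v), permutation_chi_squared(
      asn$ecogroup, guild, n_perm = config$n_perm,
      seed = seeds[[paste0("association_", v)]], fisher = TRUE))
    obs <- as.data.frame.matrix(assoc$observed)
    write_tsv(data.frame(ecogroup = rownames(obs), obs, check.names = FALSE),
              file.path(config$out_dir, paste0("association_observed_", v, ".tsv")))
    exp_df <- as.data.frame.matrix(assoc$expected)
    write_tsv(data.frame(ecogroup = rownames(exp_df), exp_df,
                         check.names = FALSE),
              file.path(config$out_dir, paste0("association_expected_", v, ".tsv")))
    write_tsv(data.frame(variable_set = v, chi_squared = assoc$chi_squared,
                         p_perm = assoc$p_perm, p_fisher = assoc$p_fisher,
                         n_perm = assoc$n_perm, seed = assoc$seed),
              file.path(config$out_dir, paste0("association_test_", v, ".tsv")))
    results$association[[v]] <- assoc
    log_msg("association", v, sprintf(": X^2 = %.1f, P_perm = %.4g",
                                      assoc$chi_squared, assoc$p_perm))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mycocontext")),
    r_version = R.version.string,
    seeds = seeds,
    parameters = config[c("rarefaction_depth", "G", "delta_aic_threshold",
                          "n_perm", "min_prevalence", "min_total",
                          "support_scales")],
    stage_seconds = timings,
    total_seconds = round(proc.time()[["elapsed"]] - t_all, 3))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  log_msg("done", "outputs in ", config$out_dir)
  invisible(results)
}
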