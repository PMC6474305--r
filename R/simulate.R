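#' @name synthetic-data
#' @title Seeded synthetic data with the sampling design the analyses assume
#' @description
#' The generator emulates the study design the pipeline targets: 2 regions x
#' 3 sites x 2 seasons x 22 quadrats (264 samples), heterogeneous library
#' sizes, region-structured covariates (one region more saline and more
#' variable, shrub-dominated; the other grass/sedge/rush-dominated), and NB
#' OTU counts whose log-means respond to covariates through group-shared
#' coefficient profiles (the ecogroup structure the mixture model estimates),
#' with trophic-guild labels statistically associated with the true groups.
#' Richness-environment relationships are never injected directly: they
#' emerge from OTU-level responses through NB zeros.
NULL

GENERATIVE_TERMS <- c("seasonwinter", "salinity", "ph", "moisture",
                      "plant_richness", "root_biomass", COVER_COLUMNS)

default_region_profiles <- function() {
  list(
    regionA = list(  # more saline, more variable, shrub-dominated
      salinity_mean = 32, salinity_sd = 6,
      ph_mean = 7.2, ph_sd = 0.4,
      moisture_mean = 45, moisture_sd = 10,
      cover_weights = c(cover_herb = 2, cover_shrub = 4, cover_grass = 1.5,
                        cover_sedge = 1, cover_rush = 0.5, bare = 2),
      plant_richness_rate = 5,
      root_biomass_meanlog = log(5), root_biomass_sdlog = 0.5),
    regionB = list(  # fresher, grass/sedge/rush-dominated
      salinity_mean = 18, salinity_sd = 3,
      ph_mean = 7.2, ph_sd = 0.4,
      moisture_mean = 40, moisture_sd = 10,
      cover_weights = c(cover_herb = 2, cover_shrub = 0.5, cover_grass = 4,
                        cover_sedge = 2.5, cover_rush = 2, bare = 2),
      plant_richness_rate = 5,
      root_biomass_meanlog = log(5), root_biomass_sdlog = 0.5))
}

default_beta_true <- function() {
  p <- length(GENERATIVE_TERMS)
  b <- matrix(0, 3, p, dimnames = list(NULL, GENERATIVE_TERMS))
  b[1, c("seasonwinter", "salinity")] <- c(0.6, 0.5)
  b[2, c("salinity", "root_biomass")] <- c(-0.5, 0.4)
  b[3, c("cover_shrub", "plant_richness")] <- c(-0.4, 0.3)
  b
}

default_guild_association <- function(G) {
  guilds <- trophic_groups()  # six assigned + "unassigned"
  m <- matrix(0.04, G, length(guilds), dimnames = list(NULL, guilds))
  m[, "unassigned"] <- 0.55
  for (g in seq_len(G)) m[g, ((g - 1) %% 6) + 1] <- 0.25
  m / rowSums(m)
}

#' Simulation configuration
#'
#' Defaults reproduce the emulated study design: 2 regions x 3 sites x
#' 2 seasons x 22 quadrats = 264 samples, 300 OTUs in 3 latent response
#' groups, log-normal library sizes clamped to 5,000-50,000.
#'
#' @param n_regions,sites_per_region,quadrats_per_site_season,seasons design
#'   dimensions.
#' @param region_profiles per-region covariate generator parameters (see
#'   `default_region_profiles()` for the field list).
#' @param site_salinity_offsets,site_moisture_offsets per-site mean shifts
#'   (length `sites_per_region`) giving within-region site structure.
#' @param n_otus number of OTUs.
#' @param pi_true mixing proportions of the latent response groups.
#' @param beta_true G x p coefficient matrix over `GENERATIVE_TERMS`
#'   (z-scored covariates; seasonwinter is a 0/1 indicator).
#' @param theta_true per-group NB dispersions.
#' @param alpha_meanlog,alpha_sdlog per-OTU intercept distribution
#'   (log scale); the default centres mean per-OTU counts near
#'   0.5 x library / n_otus. `alpha_meanlog` may also be a vector with one
#'   value per group, to give groups different typical abundances.
#' @param library_meanlog,library_sdlog,library_range library-size
#'   log-normal parameters and clamp range.
#' @param guild_association G x 7 row-stochastic matrix giving the trophic
#'   guild distribution within each latent group.
#' @param seed base RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_regions = 2, sites_per_region = 3,
                       quadrats_per_site_season = 22,
                       seasons = c("summer", "winter"),
                       region_profiles = default_region_profiles(),
                       site_salinity_offsets = NULL,
                       site_moisture_offsets = NULL,
                       n_otus = 300,
                       pi_true = c(0.4, 0.35, 0.25),
                       beta_true = default_beta_true(),
                       theta_true = NULL,
                       alpha_meanlog = NULL, alpha_sdlog = 1,
                       library_meanlog = log(15000), library_sdlog = 0.5,
                       library_range = c(5000, 50000),
                       guild_association = NULL,
                       seed = 1L) {
  if (length(region_profiles) != n_regions)
    stop("need one region profile per region")
  if (is.null(site_salinity_offsets))
    site_salinity_offsets <- if (sites_per_region > 1)
      seq(-2, 2, length.out = sites_per_region) else 0
  if (is.null(site_moisture_offsets))
    site_moisture_offsets <- if (sites_per_region > 1)
      seq(-5, 5, length.out = sites_per_region) else 0
  if (length(site_salinity_offsets) != sites_per_region ||
      length(site_moisture_offsets) != sites_per_region)
    stop("site offset vectors must have length sites_per_region")
  G <- length(pi_true)
  if (abs(sum(pi_true) - 1) > 1e-8 || any(pi_true < 0))
    stop("'pi_true' must be a probability vector")
  beta_true <- as.matrix(beta_true)
  if (nrow(beta_true) != G) stop("'beta_true' needs one row per group")
  if (!identical(colnames(beta_true), GENERATIVE_TERMS))
    stop("'beta_true' columns must be exactly: ",
         paste(GENERATIVE_TERMS, collapse = ", "))
  if (is.null(theta_true)) theta_true <- rep(1, G)
  if (any(theta_true <= 0)) stop("'theta_true' must be positive")
  if (is.null(alpha_meanlog)) alpha_meanlog <- log(0.5 / n_otus)
  if (is.null(guild_association)) guild_association <- default_guild_association(G)
  guild_association <- as.matrix(guild_association)
  if (nrow(guild_association) != G ||
      any(abs(rowSums(guild_association) - 1) > 1e-8))
    stop("'guild_association' must be G x 7 and row-stochastic")
  for (pr in region_profiles)
    if (pr$salinity_sd <= 0 || pr$ph_sd <= 0 || pr$moisture_sd <= 0)
      stop("covariate SDs must be positive")
  structure(list(
    n_regions = n_regions, sites_per_region = sites_per_region,
    quadrats_per_site_season = quadrats_per_site_season, seasons = seasons,
    region_profiles = region_profiles,
    site_salinity_offsets = site_salinity_offsets,
    site_moisture_offsets = site_moisture_offsets,
    n_otus = n_otus, pi_true = pi_true, beta_true = beta_true,
    theta_true = theta_true, alpha_meanlog = alpha_meanlog,
    alpha_sdlog = alpha_sdlog, library_meanlog = library_meanlog,
    library_sdlog = library_sdlog, library_range = library_range,
    guild_association = guild_association, seed = seed), class = "sim_config")
}

#' Simulate the sample metadata table
#'
#' Site-structured draws: normal abiotic covariates with region-level mean
#' shifts and variance differences plus per-site offsets; percentage covers
#' from a region-profiled Dirichlet scaled to sum to 100; Poisson plant
#' richness; log-normal root biomass.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return validated sample metadata data.frame.
#' @export
simulate_covariates <- function(config, seed = config$seed) {
  set.seed(seed)
  regions <- names(config$region_profiles)
  rows <- list()
  for (r in seq_along(regions)) {
    pr <- config$region_profiles[[r]]
    for (s in seq_len(config$sites_per_region)) {
      site <- paste0(regions[r], "_s", s)
      for (season in config$seasons) {
        nq <- config$quadrats_per_site_season
        cw <- pr$cover_weights  # includes a "bare" (uncolonised) component
        gmat <- matrix(stats::rgamma(nq * length(cw), shape = rep(cw, each = nq)),
                       nrow = nq)
        covers <- 100 * gmat / rowSums(gmat)
        colnames(covers) <- names(cw)
        covers <- covers[, names(cw) != "bare", drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sprintf("%s_%s_q%02d", site, substr(season, 1, 1),
                              seq_len(nq)),
          site = site, region = regions[r], season = season,
          salinity = pmax(stats::rnorm(
            nq, pr$salinity_mean + config$site_salinity_offsets[s],
            pr$salinity_sd), 0),
          ph = pmin(pmax(stats::rnorm(nq, pr$ph_mean, pr$ph_sd), 0), 14),
          moisture = pmin(pmax(stats::rnorm(
            nq, pr$moisture_mean + config$site_moisture_offsets[s],
            pr$moisture_sd), 0), 100),
          plant_richness = stats::rpois(nq, pr$plant_richness_rate),
          root_biomass = stats::rlnorm(nq, pr$root_biomass_meanlog,
                                       pr$root_biomass_sdlog),
          covers,
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  validate_sample_table(do.call(rbind, rows))
}

#' Generative covariate design (z-scored continuous terms)
#'
#' The design the counts are generated from and against which group
#' coefficient recovery is judged: a 0/1 winter indicator followed by
#' z-scored continuous covariates (standardised over the supplied samples).
#'
#' @param samples sample metadata data.frame.
#' @return samples x p numeric matrix with columns `GENERATIVE_TERMS`.
#' @export
generative_design <- function(samples) {
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  X <- cbind(seasonwinter = as.numeric(samples$season == "winter"),
             vapply(setdiff(GENERATIVE_TERMS, "seasonwinter"),
                    function(tm) zs(samples[[tm]]), numeric(nrow(samples))))
  colnames(X) <- GENERATIVE_TERMS
  X
}

#' Draw the latent ground truth (groups, intercepts, guilds)
#' @keywords internal
simulate_truth <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  G <- length(config$pi_true)
  group <- sample.int(G, config$n_otus, replace = TRUE, prob = config$pi_true)
  # alpha_meanlog may be a single value or one per group (e.g. to plant a
  # rare responsive group on an abundant flat background)
  aml <- if (length(config$alpha_meanlog) == G)
    config$alpha_meanlog[group] else config$alpha_meanlog
  alpha <- stats::rnorm(config$n_otus, aml, config$alpha_sdlog)
  guilds <- colnames(config$guild_association)
  guild <- vapply(group, function(g)
    sample(guilds, 1, prob = config$guild_association[g, ]), "")
  otu_ids <- sprintf("OTU%04d", seq_len(config$n_otus))
  list(otu_ids = otu_ids, group = group, alpha = alpha,
       guild = stats::setNames(guild, otu_ids),
       beta_true = config$beta_true, pi_true = config$pi_true,
       theta_true = config$theta_true,
       guild_association = config$guild_association)
}

#' Simulate the OTU count table given covariates and truth
#'
#' Library sizes are log-normal (clamped to `config$library_range`); OTU i
#' in true group g has counts
#' \eqn{y_{ij} \sim NB(L_j \exp(\alpha_i + x_j'\beta_g), \theta_g)}.
#'
#' @param samples sample metadata (from [simulate_covariates()]).
#' @param truth latent truth (from `simulate_truth()`).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return samples x OTUs integer matrix with row/column names.
#' @export
simulate_counts <- function(samples, truth, config,
                            seed = config$seed + 2L) {
  set.seed(seed)
  n <- nrow(samples)
  L <- round(pmin(pmax(
    stats::rlnorm(n, config$library_meanlog, config$library_sdlog),
    config$library_range[1]), config$library_range[2]))
  X <- generative_design(samples)
  eta_g <- X %*% t(truth$beta_true)  # n x G
  counts <- matrix(0L, n, length(truth$otu_ids),
                   dimnames = list(samples$sample_id, truth$otu_ids))
  for (i in seq_along(truth$otu_ids)) {
    g <- truth$group[i]
    mu <- L * exp(truth$alpha[i] + eta_g[, g])
    if (any(mu > 1e8))
      stop("mean overflow: reduce alpha/beta magnitudes in the config")
    counts[, i] <- stats::rnbinom(n, size = truth$theta_true[g], mu = mu)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    message(sum(empty), " sample(s) drew zero total counts; ",
            "one read added to keep library sizes positive")
    counts[empty, 1] <- 1L
  }
  counts
}

#' Simulate a complete analysis dataset plus its ground truth
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a `fungal_dataset`) and `truth` (true group
#'   per OTU, generative parameters, guild-association matrix).
#' @export
simulate_dataset <- function(config = sim_config()) {
  samples <- simulate_covariates(config)
  truth <- simulate_truth(config)
  counts <- simulate_counts(samples, truth, config)
  guilds <- data.frame(otu_id = truth$otu_ids,
                       trophic_group = unname(truth$guild),
                       stringsAsFactors = FALSE)
  ds <- fungal_dataset(samples, counts, guilds)
  list(dataset = ds, truth = truth)
}
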