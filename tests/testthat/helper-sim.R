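# Small, fast simulation configs used across the suite.

# Reduced version of the default design: full 2x3x2 site structure but
# fewer quadrats and OTUs.
tiny_config <- function(seed = 1L, n_otus = 60, quadrats = 8, ...) {
  sim_config(n_otus = n_otus, quadrats_per_site_season = quadrats,
             seed = seed, ...)
}

# One global generative process: both regions share the same covariate
# profile and there are no site-level offsets, so site/region labels carry
# no information (used for transfer-calibration null checks).
global_process_config <- function(seed = 1L, n_otus = 60, quadrats = 8) {
  pr <- default_region_profiles()[[1]]
  sim_config(n_otus = n_otus, quadrats_per_site_season = quadrats,
             region_profiles = list(regionA = pr, regionB = pr),
             site_salinity_offsets = c(0, 0, 0),
             site_moisture_offsets = c(0, 0, 0),
             seed = seed)
}

# Two-group mixture data with a clean log-scale separation between the
# group coefficient profiles, constant library sizes (no rarefaction
# distortion); returns counts (samples x OTUs), design, and the truth.
two_group_mixture_data <- function(seed, n_otus = 60, n_samples = 50,
                                   separation = 1) {
  set.seed(seed)
  x1 <- stats::rnorm(n_samples)
  x2 <- stats::rnorm(n_samples)
  X <- cbind(x1 = x1, x2 = x2)
  beta <- rbind(c(separation / 2, 0.4), c(-separation / 2, -0.4))
  pi_true <- c(0.55, 0.45)
  group <- sample.int(2, n_otus, replace = TRUE, prob = pi_true)
  alpha <- stats::rnorm(n_otus, log(40), 0.7)
  theta <- c(1.5, 1.5)
  counts <- matrix(0L, n_samples, n_otus,
                   dimnames = list(paste0("S", seq_len(n_samples)),
                                   paste0("OTU", seq_len(n_otus))))
  for (i in seq_len(n_otus)) {
    mu <- exp(alpha[i] + drop(X %*% beta[group[i], ]))
    counts[, i] <- stats::rnbinom(n_samples, size = theta[group[i]], mu = mu)
  }
  list(counts = counts, design = X, group = group, beta = beta,
       pi = pi_true, theta = theta)
}

# A minimal valid dataset written to TSV files in a temp dir
write_toy_tables <- function(dir) {
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    site = c("A", "A", "B", "B"), region = c("R1", "R1", "R2", "R2"),
    season = c("summer", "winter", "summer", "winter"),
    salinity = c(30, 31, 15, 16), ph = c(7, 7.1, 6.9, 7.2),
    moisture = c(40, 42, 38, 41), plant_richness = c(3, 4, 5, 2),
    root_biomass = c(2.5, 3.1, 1.9, 2.2),
    cover_herb = c(10, 20, 30, 5), cover_shrub = c(40, 30, 5, 10),
    cover_grass = c(20, 10, 40, 50), cover_sedge = c(5, 10, 10, 15),
    cover_rush = c(0, 5, 5, 10))
  counts <- data.frame(sample_id = samples$sample_id,
                       OTU1 = c(0L, 3L, 1L, 2L), OTU2 = c(2L, 0L, 0L, 1L),
                       OTU3 = c(5L, 1L, 4L, 0L))
  guilds <- data.frame(otu_id = c("OTU1", "OTU2"),
                       trophic_group = c("saprotroph", "symbiotroph"))
  sp <- file.path(dir, "samples.tsv"); op <- file.path(dir, "otus.tsv")
  gp <- file.path(dir, "guilds.tsv")
  write.table(samples, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(counts, op, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(guilds, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(samples = sp, otus = op, guilds = gp)
}
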