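test_that("delta-AIC classification boundaries are exact", {
  expect_equal(classify_support(100, 103), "abiotic")   # abiotic lower by 3
  expect_equal(classify_support(103, 100), "biotic")
  expect_equal(classify_support(100, 101.5), "no_support")
  # exhaustive boundary sweep: delta = aic_abiotic - aic_biotic
  deltas <- c(-2.01, -2, 0, 2, 2.01)
  expect_identical(classify_support(100 + deltas, rep(100, 5)),
                   c("abiotic", "no_support", "no_support", "no_support",
                     "biotic"))
  expect_error(classify_support(Inf, 1), "finite")
})

test_that("prevalence/total filter keeps exactly the qualifying OTUs", {
  m <- rbind(c(1, 0), c(1, 0), c(0, 1))
  colnames(m) <- c("a", "b")
  expect_identical(colnames(filter_otus(m, min_prevalence = 2)), "a")
  expect_identical(filter_otus(m, 0, 0), m)
  expect_error(filter_otus(m, 4, 0), "all OTUs removed")
})

test_that("per-OTU models are independent and recover planted drivers", {
  # OTUs with a strong salinity response get abiotic support. Regions share
  # one covariate profile here so the signal is not also expressible
  # through region-structured biotic covariates.
  b <- matrix(0, 2, length(mycocontext:::GENERATIVE_TERMS),
              dimnames = list(NULL, mycocontext:::GENERATIVE_TERMS))
  b[1, "salinity"] <- 1.2  # group 1: salinity-driven; group 2: flat
  pr <- default_region_profiles()[[1]]
  cfg <- sim_config(n_otus = 80, quadrats_per_site_season = 10,
                    region_profiles = list(regionA = pr, regionB = pr),
                    site_salinity_offsets = c(0, 0, 0),
                    site_moisture_offsets = c(0, 0, 0),
                    pi_true = c(0.5, 0.5), beta_true = b, seed = 31)
  sim <- simulate_dataset(cfg)
  sr <- suppressWarnings(
    fit_per_otu_models(sim$dataset, scale_spec("overall"),
                       min_prevalence = 5))
  tab <- sr$table
  g <- sim$truth$group[match(tab$otu_id, sim$truth$otu_ids)]
  expect_gte(mean(tab$label[g == 1] == "abiotic"), 0.9)

  # pure offset noise: when the whole community is flat, counts are
  # proportional to library size and neither variable set fits better
  # beyond chance. The delta-AIC of two non-nested models still fluctuates
  # with sd ~ sqrt(2 (p_a + p_b)), so individual flat OTUs can cross the
  # +/-2 line; the computable null properties are (a) mean delta close to
  # the parameter-count asymmetry of the two designs, and (b) a much
  # larger no_support fraction than for signal OTUs.
  b0 <- matrix(0, 1, length(mycocontext:::GENERATIVE_TERMS),
               dimnames = list(NULL, mycocontext:::GENERATIVE_TERMS))
  cfg0 <- sim_config(n_otus = 80, quadrats_per_site_season = 10,
                     region_profiles = list(regionA = pr, regionB = pr),
                     site_salinity_offsets = c(0, 0, 0),
                     site_moisture_offsets = c(0, 0, 0),
                     pi_true = 1, beta_true = b0, seed = 32)
  sim0 <- simulate_dataset(cfg0)
  sr0 <- suppressWarnings(
    fit_per_otu_models(sim0$dataset, scale_spec("overall"),
                       min_prevalence = 5))
  # overall-scale designs: abiotic has 2 more coefficients than biotic,
  # so E[delta] under the null sits near +2, far from the planted-signal
  # deltas (tens of units)
  expect_lt(abs(mean(sr0$table$delta) - 2), 4)
  expect_gt(mean(sr0$table$label == "no_support"),
            3 * mean(tab$label[g == 1] == "no_support") + 0.05)

  # independence: dropping other OTU columns leaves an OTU's AICs unchanged
  keep <- tab$otu_id[1]
  ds2 <- sim$dataset
  ds2$counts <- ds2$counts[, c(keep, tab$otu_id[2:6]), drop = FALSE]
  sr2 <- suppressWarnings(
    fit_per_otu_models(ds2, scale_spec("overall"), min_prevalence = 5))
  expect_equal(sr2$table[sr2$table$otu_id == keep, c("aic_abiotic", "aic_biotic")],
               tab[tab$otu_id == keep, c("aic_abiotic", "aic_biotic")],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("summary proportions and sigma-AIC follow their definitions", {
  # printed-count arithmetic: 1164/588/247 of 1999
  tab <- data.frame(
    otu_id = paste0("o", 1:1999),
    aic_abiotic = rep(100, 1999), aic_biotic = rep(100, 1999),
    label = rep(c("abiotic", "biotic", "no_support"), c(1164, 588, 247)))
  sm <- support_summary(tab)
  expect_equal(unname(round(sm$proportions, 3)), c(0.582, 0.294, 0.124))
  expect_equal(sm$n_otus, 1999)

  tab2 <- data.frame(otu_id = "x", aic_abiotic = 12.5, aic_biotic = 20,
                     label = "abiotic")
  sm2 <- support_summary(tab2)
  expect_equal(unname(sm2$proportions), c(1, 0, 0))
  expect_equal(sm2$sigma_aic_abiotic, 12.5)

  # sigma-AIC equals an independent summation over per-OTU AICs
  set.seed(40)
  tab3 <- data.frame(otu_id = paste0("o", 1:30),
                     aic_abiotic = runif(30, 50, 150),
                     aic_biotic = runif(30, 50, 150))
  tab3$label <- classify_support(tab3$aic_abiotic, tab3$aic_biotic)
  sm3 <- support_summary(tab3)
  expect_equal(sm3$sigma_aic_abiotic, sum(tab3$aic_abiotic))
  expect_equal(sm3$sigma_aic_biotic, sum(tab3$aic_biotic))
  # proportions are invariant to row (OTU) order
  sm4 <- support_summary(tab3[sample(30), ])
  expect_equal(sm4$proportions, sm3$proportions)
})

test_that("a few strong abiotic OTUs can win sigma-AIC against a biotic majority", {
  # majority of OTUs weakly favour biotic variables, a handful strongly
  # favour abiotic: biotic wins the majority label, abiotic wins sigma-AIC
  tab <- data.frame(
    otu_id = paste0("o", 1:40),
    aic_abiotic = c(rep(103, 35), rep(100, 5)),
    aic_biotic = c(rep(100, 35), rep(200, 5)))
  tab$label <- classify_support(tab$aic_abiotic, tab$aic_biotic)
  sm <- support_summary(tab)
  expect_gt(sm$proportions[["biotic"]], 0.5)
  expect_lt(sm$sigma_aic_abiotic, sm$sigma_aic_biotic)
})
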