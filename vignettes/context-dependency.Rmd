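---
title: "Modelling context dependency of root-associated fungal community drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling context dependency of root-associated fungal community drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Root-associated fungal communities are shaped by both the abiotic
environment (salinity, pH, soil moisture, season) and the surrounding plant
community (species richness, root biomass, growth-form cover). Whether the
*same* drivers operate in different places and at different spatial scales —
whether models of fungal diversity are transferable — is an open question.
`mycocontext` implements a complete statistical framework for asking it with
amplicon (OTU-table) data from a spatially nested design: multiple sites
inside multiple regions, sampled in two seasons.

The framework has five analysis layers, each usable on its own:

1. **Richness models at nested scales.** Per-sample OTU richness is
   modelled with negative-binomial (NB2) GLMs, log link, at three scales —
   each site, each region (sites pooled), and all data pooled — once with
   an *abiotic* variable set and once with a *biotic* one. Models are
   compared by AIC and adjusted D².
2. **Cross-site transfer.** Each site-trained richness model predicts every
   site's richness; the train × target RMSE matrix is summarised by a
   one-way ANOVA on log errors grouped into within-region (one group per
   region, diagonal included) and between-region transfers, with Tukey HSD
   contrasts.
3. **Per-OTU support.** Each OTU's counts are modelled with both variable
   sets (log library size as an offset with coefficient fixed at 1);
   ΔAIC > 2 classifies the OTU as abiotic- or biotic-supported, otherwise
   unsupported. Community totals (ΣAIC) compare the sets at whole-community
   level.
4. **Ecogroups.** A finite mixture of NB regressions (the species
   archetype model) clusters OTUs by the *shape* of their modelled response:
   each of G groups carries a shared coefficient profile and dispersion,
   while per-OTU intercepts absorb abundance differences. Fitted by EM on a
   rarefied table.
5. **Guild association.** Ecogroup assignments are cross-tabulated against
   FUNGuild-style trophic groups and tested with a permutation chi-squared
   test (expected counts from the margins; labels permuted across OTUs).

## Models and their assumptions

### The NB GLM kernel

All count models use the NB2 parameterisation, variance
$\mu + \mu^2/\theta$. Coefficients are estimated by IRLS at fixed
$\theta$, alternated with one-dimensional maximum-likelihood updates of
$\theta$ (search on $\log\theta \in [-7, 16]$), until the relative change in
log-likelihood falls below $10^{-8}$ or 200 alternations. Each IRLS step is
safeguarded by step-halving against the exact likelihood, so fits cannot
oscillate. AIC counts $\theta$ as an estimated parameter
($p = \#\beta + 1$). The null deviance refits an intercept-only model (with
the same offset) at the full model's $\theta$. Adjusted D² uses the
penalised form $1 - \frac{n-1}{n-p}(1 - D^2)$ with
$D^2 = 1 - \text{deviance}/\text{null deviance}$; negative values are
reported as "0 (value)" in formatted tables. D² is computed against the
intercept-only null, not a library-size-adjusted null — with the latter, D²
would measure only the covariates' contribution beyond sequencing depth,
and the two conventions are not comparable; the intercept-only choice keeps
site/region/overall rows on one scale.

Two design-matrix conventions matter for interpretation:

* **Richness mode** places log(library size) as the first *estimated*
  covariate, so deeper-sequenced samples may legitimately show more OTUs
  without that variance being attributed to the environment. A consequence,
  visible in simulations, is that any environmental signal that moves
  *total* abundance (and hence library size) is largely absorbed by this
  term; richness models detect signals that change *which* OTUs are
  present, not how many reads were drawn.
* **Abundance mode** moves log(library size) to an offset with coefficient
  fixed at 1, i.e. counts are assumed proportional to depth and the models
  describe relative abundance.

Categorical terms use treatment contrasts; season's reference level is
summer, so positive season coefficients mean "higher in winter". The
abiotic set gains a site factor only when sites are pooled
(region/overall scales); the biotic set never includes it.

### Transfer and its caveat

Site-trained models contain no site factor, so they transfer to any site
with both seasons present. The ANOVA groups the 36 matrix cells as 9
within-region-A, 9 within-region-B and 18 between-region (diagonal included;
this is the only 3-group partition of 36 cells with error df 33). A caveat
discovered during calibration simulations: the 36 cells are not
independent — every cell in a row shares one trained model, and every cell
in a column shares one target dataset. Under a single global generative
process the ANOVA therefore rejects far more often than its nominal level
(about 25–30 % at α = 0.05 in our simulations, regardless of sample sizes
or effect settings). The F test is best read as descriptive of the error
structure rather than as a calibrated hypothesis test; the package keeps
the procedure because it is the field's reporting convention, and documents
the anti-conservatism here.

### ΔAIC support

The two variable sets are non-nested and differently sized, so under a flat
null ΔAIC is not centred at zero: its mean sits near the parameter-count
difference and its spread is roughly $\sqrt{2(p_a+p_b)}$ — several units.
Individual unresponsive OTUs therefore routinely cross the ±2 line; the
classification is informative in aggregate, not per OTU. A second
simulation finding worth knowing: because the offset is the *observed*
library size (the row sum), OTUs with no environmental response can still
earn genuine support when other OTUs respond — their relative abundance
moves compositionally. Both behaviours are inherent to the ΔAIC-with-offset
design, not artefacts of this implementation.

A threshold of exactly 2 counts as "no support" (the rule is a strict
inequality on both sides).

### The ecogroup mixture

The observed-data log-likelihood is
$$\ell = \sum_i \log \sum_g \pi_g \prod_j
  \mathrm{NB}\!\left(y_{ij};\, \exp(\alpha_i + x_j^\top\beta_g),\, \theta_g\right).$$
The E-step computes responsibilities in log space (log-sum-exp). The M-step
updates $\pi$, refits each group's $(\beta_g, \theta_g)$ by
responsibility-weighted NB regression (a stacked IRLS over all OTU ×
sample observations, warm-started from the current parameters), and updates
the per-OTU intercepts $\alpha_i$ by a vectorised, step-halved Newton
sweep. Every block update is accepted only if it does not decrease its
objective, making the algorithm a generalised EM: the log-likelihood trace
is non-decreasing, which the test suite asserts on every recorded trace.

Design choices, made where the archetype literature varies:

* **Per-OTU intercepts** (default) rather than a shared intercept, so
  grouping reflects response *shape*, not commonness. A
  `shared_intercept` switch provides the other convention.
* **Per-group dispersion** $\theta_g$, keeping the M-step well posed with
  many rare OTUs.
* **Initialisation**: start 1 clusters per-OTU independent NB-GLM
  coefficient vectors with k-means (deterministic given the seed);
  remaining starts draw random responsibilities. The best final
  log-likelihood wins.
* **Stopping**: relative log-likelihood change below $10^{-6}$ or 500
  iterations.
* Groups are reported in decreasing order of $\pi$ (the likelihood is
  invariant to relabelling); ties in assignment go to the lowest index.
* The intended input is a rarefied table, so no offset enters; an offset
  argument exists for unrarefied use. Continuous covariates are z-scored in
  the pipeline's mixture design so that coefficient profiles are comparable
  across terms.

When the mixture is fitted to rarefied counts, coefficients describe
*relative* abundance responses: rarefaction divides by the sample total, so
a covariate that raises the whole community's abundance appears as a
near-zero profile. Group recovery is unaffected (groups differ by contrast,
not level), but absolute coefficient values are compressed relative to the
generative ones — parameter-recovery checks therefore use equal library
sizes.

The default G = 6 matches the number of trophic groups, allowing a
"maximal association" reading of the guild test; G is not selected by
information criteria.

### Permutation chi-squared

Expected counts are $E_{ij} = (\text{row}_i \times \text{col}_j)/N$ and
$X^2 = \sum (O-E)^2/E$. Guild labels are permuted across OTUs; both margins
are preserved, so $E$ is fixed and only $O$ is recomputed. The P-value uses
the add-one estimator $(1 + \#\{X^2_{perm} \ge X^2_{obs}\})/(n_{perm}+1)$,
with floor $1/(n_{perm}+1)$; the default is 10,000 permutations. OTUs with
an unassigned guild are excluded by default (a switch keeps them as a
seventh category), and a Monte-Carlo Fisher-style P-value can be reported
alongside. Levels with zero margins are dropped with a warning.

## The synthetic-data generator

`sim_config()`/`simulate_dataset()` generate data with the structure the
analyses assume, plus a ground-truth record for recovery checks. Defaults
emulate the target sampling design: 2 regions × 3 sites × 2 seasons × 22
quadrats = 264 samples; region A is more saline and more variably so, and
shrub-dominated, while region B is fresher and grass/sedge/rush-dominated
(covers come from a region-profiled Dirichlet that includes a bare-ground
component, so the five covers do not sum to 100). Library sizes are
log-normal, clamped to 5,000–50,000, and 300 OTUs fall into 3 latent
response groups whose coefficient profiles act on z-scored covariates;
counts are NB with per-group dispersion. Trophic-guild labels are drawn
per OTU from a group-specific distribution in which ~55 % of OTUs are
unassigned, matching the common situation that most OTUs lack a FUNGuild
placement. These sizes keep the full pipeline to a few minutes on one CPU;
the real-data scale (thousands of OTUs, median libraries above 100,000) is
a straightforward config change.

Richness–environment relationships are never injected directly: they can
only emerge from OTU-level abundance responses through NB zeros, which is
the mechanism the richness models assume. What the generator does *not*
emulate: phylogenetic or spatial autocorrelation, OTU–OTU interactions,
taxonomy-linked guild structure, or sequencing artefacts (chimeras, index
hopping). Tests passing on generated data therefore validate the
statistical machinery, not robustness to those real-data features.

## Numerical choices and degenerate inputs

* Linear predictors are capped at 30 on the log scale before
  exponentiation; the generator refuses configurations whose means overflow
  10^8.
* Rarefaction is a single seeded draw without replacement; samples below
  the depth are dropped (never up-sampled), mirroring the practice of
  excluding under-sequenced samples. The workflow default depth is 12,738;
  for generator-scale libraries the worked examples use 5,000, which
  retains nearly all samples.
* Designs are checked for full rank (collinear columns are named in the
  error); terms constant within an analysis scope are dropped with a
  warning — e.g. the site factor at site scale.
* All-zero responses, all-zero OTUs, empty scopes, zero RMSE cells
  (guarded before logs) and single-level factors raise informative errors
  or warnings rather than propagating NaNs.
* Every stochastic stage takes an explicit integer seed; the pipeline
  derives per-stage seeds from one base seed and records them in its
  manifest, so a rerun with the same config is numerically identical.

## Known limitations

* The transfer ANOVA's anti-conservatism under exchangeable sites (above).
* ΔAIC support labels for individual OTUs are noisy by construction; use
  the proportions and ΣAIC, not single-OTU labels.
* The mixture likelihood is multimodal; the deterministic k-means start
  plus random restarts is a heuristic, and more starts may be needed for
  large G or weak separation.
* Permutation P-values are exchangeable-label tests of independence
  between the two classifications; they do not account for uncertainty in
  the ecogroup assignment itself.

## A short worked example

```{r, eval = FALSE}
library(mycocontext)

sim <- simulate_dataset(sim_config(n_otus = 60,
                                   quadrats_per_site_season = 8, seed = 7))
ds <- sim$dataset

# 1. richness comparison at every scale
richness_table(ds)[, c("scale", "n", "aic_abiotic", "aic_biotic", "winner")]

# 2. cross-site transfer of the abiotic model
tm <- transfer_matrix(ds, variable_set("abiotic"))
region_transfer_anova(tm)

# 3. per-OTU support at the overall scale
support_summary(fit_per_otu_models(ds, scale_spec("overall")))

# 4 + 5. ecogroups on a rarefied table, then guild association
rare <- rarefy(ds, 5000, seed = 11)
sm <- ds$samples[match(rownames(rare), ds$samples$sample_id), ]
mod <- fit_archetype_mixture(rare, generative_design(sm), G = 6,
                             n_starts = 2, seed = 5)
asn <- assign_ecogroups(mod)
permutation_chi_squared(asn$ecogroup, ds$guilds[asn$otu_id],
                        n_perm = 10000, seed = 3)
```

`run_pipeline(pipeline_config(...))` chains all five layers, writes every
stage's TSV outputs and a JSON manifest, and is byte-reproducible for a
fixed seed.
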