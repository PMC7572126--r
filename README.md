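# miomed

Statistical pipeline for linking diet and lifestyle exposures, fecal
metagenome traits, and cardiometabolic/inflammatory outcomes in a
two-community cohort design. It is written for microbiome epidemiologists
who have a MetaPhlAn-style species table, a HUMAnN-style pathway table, and
participant metadata, and who want to go beyond "who differs" to "through
and with whom": does a taxon *mediate* an exposure–outcome association, and
does its presence *moderate* one?

The package implements, as tested R functions:

* **Diversity and composition** — Chao1
  (S_obs + F1(F1−1)/(2(F2+1))), Shannon H′ = −Σ pᵢ ln pᵢ, evenness
  E = H′/ln S; Bray–Curtis on square-root abundances; one-factor
  **PERMANOVA** with pseudo-F = ((SS_T − SS_W)/(g−1))/(SS_W/(n−g)) and
  permutation p (exhaustive enumeration at small n); NMDS ordination.
* **Differential abundance** — a Kruskal–Wallis gate (α = 0.05) followed by
  a bootstrap-averaged **LDA effect size** on per-million abundances with a
  log₁₀ score threshold of 3.
* **Latent constructs** — principal-axis EFA with varimax rotation and
  regression factor scores; the fixed three-block cytokine panel
  (TNFα/IL-4/IL-12p70; CRP/IL-18/MCP1; IL-15/IL-33/IFNγ/IL-1β).
* **Path-model SEM** — normal-theory ML with analytic gradients, sandwich
  (Huber–White) standard errors, χ²/CFI/SRMR/RMSEA/AIC, and comparison of
  four causal frameworks (microbiome as mediator, as independent input, as
  sole sink, or downstream of inflammation), ranked by lowest AIC.
* **Causal mediation** — OLS product-of-coefficients decomposition
  (ACME = a·b, ADE = c′, Total = a·b + c′) with nonparametric bootstrap
  CIs and p-values, proportion mediated as the bootstrap median, under an
  unadjusted / age / age+island / multivariate adjustment ladder.
* **Moderation scan** — microbiome-wide interaction models
  Y ~ group × taxon-presence with Benjamini–Hochberg control across tested
  taxa, eligibility rules for degenerate taxa, and a cell-means ladder.
* **Cohort statistics** — median (Q1, Q3) tables with ANOVA/ANCOVA
  p-values, a Spearman screen (|ρ| ≥ 0.3, BH q ≤ 0.05), and pathway
  comparisons (Mann–Whitney + BH, bootstrap effect CIs, an 80%-presence
  rule for taxon-stratified rows).
* **A synthetic cohort generator** with planted mediation and moderation
  effects and byte-reproducible output, so the whole pipeline is testable
  without any participant-level data.

## Worked example

```r
library(miomed)

study <- simulate_study(n = 100, seed = 42)   # two islands of 50
filt  <- filter_rare_taxa(study$microbiome)   # <40% prevalence AND <1% mean

d <- bray_curtis(filt$table)                  # sqrt-transformed Bray-Curtis
permanova(d, study$cohort$island, n_perm = 9999, seed = 42)
#> PERMANOVA: pseudo-F = 2.7124 (df 1, 98), p = 0.0021 (9999 permutations)

dat <- study$cohort
dat$mediator_log <- as.numeric(log_offset(
  filt$table$values[, "Lachnospiraceae_bacterium_8_1_57FAA"]))
dat$IL15_log <- as.numeric(log_offset(dat$IL15))
mediate(dat, "ssb", "mediator_log", "IL15_log",
        covariates = "age", n_boot = 1000, seed = 42)
#> Mediation (n = 100, 1000 bootstrap draws, adjusted for: age)
#>   ACME             0.1694 [  0.0689,   0.2773]  p < 0.002
#>   ADE              0.4422 [  0.2648,   0.5989]  p < 0.002
#>   Total            0.6117 [  0.4085,   0.7982]  p < 0.002
#>   Prop. mediated   0.2729 [  0.1316,   0.4534]  p < 0.002
```

Reading this: the two communities differ in species composition (pseudo-F
2.71, permutation p 0.002). For the planted mediator taxon, each daily
serve of sugar-sweetened beverages is associated with a 0.61 log-unit
higher IL-15 concentration in total, of which 0.17 log-units (about 27%,
CI 13–45%) flow through the taxon's abundance — the generator planted
a·b = 0.5 × 0.4 = 0.2 through exactly that path. The moderation scan
at this scale illustrates honest power limits: the planted island ×
*Alistipes onderdonkii* interaction on systolic blood pressure is
estimated at +6.0 mmHg (8 planted) but with SE 5.6 at n = 100 it does not
reach significance — the calibration tests demonstrate detection at
n = 500.

The `analysis/` directory holds numbered driver scripts
(`01_simulate.R` … `07_cohort_stats.R`) that run the same stages on a
written fixture set and leave their tables under `results/`. The full
pipeline is also available as one call, `run_pipeline()`, configured by a
validated YAML file (`validate_config()`), writing per-stage TSVs, a JSON
manifest, and byte-identical output for a fixed seed.

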