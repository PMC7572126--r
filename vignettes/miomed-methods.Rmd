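---
title: "Methods: microbiome mediation and moderation of diet-cardiometabolic risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiome mediation and moderation of diet-cardiometabolic risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

miomed implements the statistical workflow of a two-community cohort design
in which diet and lifestyle exposures, fecal-metagenome traits, and
cardiometabolic/inflammatory outcomes are linked through three complementary
lenses: community-level description (diversity, composition, differential
abundance), latent-construct modelling (factor analysis feeding path
models), and effect decomposition (bootstrap mediation and a
microbiome-wide moderation scan). This vignette records the models, their
assumptions, the tunable parameters, and the numerical and design choices
made where the methods literature leaves them open. Every number quoted
here is computed by the test suite or the analysis scripts; nothing is
transcribed from external sources.

## The synthetic cohort

All stages are exercised on a fully synthetic cohort with known ground
truth, generated by `simulate_study()`. The generator's defaults are the
study conditions and are not tuned per analysis:

* **Design**: n = 100 participants, two island communities of 50
  ("Waiben", "Mer"). Age is normal (mean 42 y on Waiben, +10 y on Mer,
  SD 14) truncated at 15 y; because of the truncation the *realized*
  island age gap is the truncated-normal mean difference (about 9.3 y),
  which is the oracle the tests check against.
* **Exposures** are count-like: sugar-sweetened beverages (SSB),
  fruit, vegetables (serves/day), takeaway and seafood (serves/week) as
  Poisson draws whose rates match the reported medians of such cohorts
  (SSB 1/day, vegetables 3.5/day, island-shifted takeaway and seafood);
  smoking is a zero-inflated count, alcohol a zero-inflated gamma,
  physical activity gamma minutes/week, BMI truncated normal. The source
  design reports exposures only as medians and quartiles, so the
  distributional families here are assumptions, chosen once.
* **Species table**: 100 species (70 "core", 30 rare), log-latent
  abundances mu + Lambda f + noise with a 6-factor loading matrix, mapped
  to compositions by exponentiation and per-sample normalization
  (softmax). The softmax link preserves linear planted paths on the log
  scale that the mediation models use. Entries below a 1e-4 detection
  limit become exact zeros (profiler-like detection), which gives the
  rare species their low prevalence; the rare block is what the
  rare-taxon filter removes, leaving ~70 species, in line with a Chao1
  richness near 70.
* **Planted effects**: the mediator taxon
  (*Lachnospiraceae bacterium 8_1_57FAA*) receives `a_path` = 0.5
  log-units per SSB serve/day; IL-15 receives `b_path` = 0.4 per
  log-unit of mediator abundance plus a direct SSB path `c_prime` = 0.3;
  both blood pressures receive `b_path_map` = 1.5 mmHg per log-unit, so
  MAP = (SBP + 2 DBP)/3 inherits that coefficient exactly. The moderator
  taxon (*Alistipes onderdonkii*) is gated by a Bernoulli(0.6)
  structural zero — detect/non-detect, not rounding — and its absence
  adds `theta_interaction` = 8 mmHg to SBP on Mer only. Eight core
  species carry ±1.5 log-unit island shifts (compositional separation
  between communities), and one species factor carries a mild SSB path
  with a downstream path into the third biomarker factor. The mediator
  deliberately does not load on that factor, so its planted `a_path`
  stays cleanly recoverable by OLS.
* **Cytokine panel**: three latent factors with the fixed indicator
  blocks (Factor 1: TNFa, IL-4, IL-12p70; Factor 2: CRP, IL-18, MCP1;
  Factor 3: IL-15, IL-33, IFNg, IL-1b) through a lognormal link —
  concentrations are strictly positive and right-skewed, hence the
  pipeline tests biomarkers on the log scale.
* **Determinism**: one global seed; every table draws from a named
  substream (`substream_seed()`), so adding a stage never perturbs the
  draws of another, and regenerating with the same seed reproduces the
  tables byte-for-byte.

What the generator does *not* emulate: sequencing reads and profiler
error, taxon-taxon ecological interactions, longitudinal structure,
missing data patterns, and pathway inference (the pathway fixture is drawn
directly from its own factor model). Passing tests therefore demonstrate
the estimators' statistical behaviour under a known compositional
factor-model world, not robustness to real metagenomic artefacts.

## Preprocessing rules

* MAP = (SBP + 2 DBP)/3 mmHg; hypertension is SBP > 140 and/or DBP > 90,
  strict.
* The rare-taxon rule — "present in less than 40% of participants at <1%
  relative abundance" — is grammatically ambiguous. We exclude a taxon
  only when **both** clauses hold (prevalence < 40% AND mean abundance
  < 1%): an OR reading would discard most of a typical species table and
  contradict a retained richness near 70. `filter_rare_taxa(logic =
  "or")` provides the alternate reading. Survivors are *not*
  renormalized. The filter is idempotent.
* Zeros under log transforms take half the smallest positive value of the
  column; the offset is recorded.

## Diversity and composition

Chao1 uses the bias-corrected form S_obs + F1(F1-1)/(2(F2+1)). The
profiler emits proportions, not counts, so abundances are scaled to counts
per million and rounded before Chao1 — documented, and the reason the
richness estimate tracks detected species closely at this depth. Shannon
H' is in nats; evenness E = H'/ln S with E = 0 for a single-species
community.

Bray-Curtis runs on square-root-transformed relative abundances (vegan's
`vegdist`). PERMANOVA is one-factor: with a single fixed factor the
type-III / residual-permutation scheme of the original software reduces to
raw label permutation, so that is what we implement, with the +1 p-value
correction p = (1 + #{F* >= F}) / (1 + n_perm) for validity. For two
groups with few samples the permutation distribution is enumerated
exhaustively whenever the number of distinct label assignments is at most
`n_perm`, and the Monte-Carlo p equals the enumerated p by construction
(the tests verify this against an independent brute-force oracle, and the
pseudo-F against vegan's `adonis2`). NMDS (vegan's engine, isotonic
regression on dissimilarity ranks) defaults to 50 restarts, tolerance
1e-6, 500 iterations; coordinates are centered and principal-axis rotated.

## Differential abundance (KW gate + LDA effect size)

The stage normalizes each sample to one million, gates features by a
tie-corrected Kruskal-Wallis test at alpha = 0.05 (equal to the rank-sum
chi-square form for two classes), and scores survivors by a
bootstrap-averaged linear-discriminant effect size. The published tool's
internals are not specified by its citation, so the effect size here is
this package's documented variant: per bootstrap round (30 rounds,
two-thirds subsampling per class), a regularized LDA is fitted (pooled
covariance shrunk toward its diagonal, fixed lambda = 0.1, since features
can outnumber samples after gating) and a feature's raw effect is the mean
of |class-mean difference| and |its contribution along the unit
discriminant axis|; the score is log10(1 + bootstrap mean). On the
per-million scale the score gate of 3 corresponds to ~1000 counts-per-
million of separation, so the gate binds for low-abundance features while
the KW gate controls the error rate for abundant ones; under null data the
full gate passes features at no more than the alpha rate. Acceptance is by
planted-effect detection and the score-gate contract, not bit-equality
with the original tool. Two classes only, matching the design.

## Latent factors

EFA is principal-axis factoring with iterated communalities (started at
squared multiple correlations, Heywood cases clamped at 0.995 with a
warning), varimax rotation by default, and a sign convention making each
factor's largest-|loading| indicator positive. Extraction and rotation are
not stated in the source design; principal-axis + varimax is standard
practice and downstream stages consume only scores. k = 6 species factors
and k = 3 biomarker factors are treated as fixed study choices, exposed as
parameters (how the 6 was originally chosen — scree, eigenvalue rule — is
not stated).

Scores are Thurstone regression scores F = Z R^-1 Lambda. At the study
scale the species correlation matrix (70 features, n = 100) is numerically
invertible but near-singular, and the literal formula produces degenerate
scores (variances in the hundreds, inter-factor correlations of 1). When
rcond(R) < 1e-8 the implementation therefore inverts the model-implied
correlation Lambda Lambda' + Psi instead, which the uniquenesses bound
away from singularity and which equals the sample-R formula whenever the
model fits a well-conditioned R. This is the package's own numerical
choice; the well-conditioned path is untouched.

## Path models and the four frameworks

Following the two-step approach (EFA scores, then paths over observed
scores), `sem_fit()` minimizes the normal-theory discrepancy
F_ML = ln|Sigma(theta)| + tr(S Sigma^-1) - ln|S| - p by BFGS with an
analytic gradient in a RAM parameterization, starting from per-equation
OLS (10 jittered restarts on failure); residual variances are
log-parameterized, and a non-positive-definite Sigma during the search is
rejected by the line search (the objective returns a large value).
T = (n-1) F_ML; CFI, SRMR and RMSEA follow the standard formulas with the
independence model (diagonal Sigma, closed form T_b = -(n-1) ln|R|) as
baseline; df = 0 gives CFI = 1, RMSEA = 0 by convention.

Exogenous-block (exposure) variances and covariances are fixed to sample
values rather than freed — this keeps df interpretable across frameworks —
and AIC is computed with effective parameters = free parameters + fixed
exogenous moments so the four frameworks, which differ in which moments
are fixed, remain comparable. Standard errors are Huber-White sandwich
estimates from casewise score contributions; the original analysis's
MLR/Yuan-Bentler scaled test statistic is not reproducible from its
description and is not implemented — a documented divergence. Missing data
are handled listwise.

The four frameworks over exposures E, microbiome factors M, biomarker
factors B: (1) E→M, M→B, plus direct E→B; (2) M→B and E→B with M
unrelated to E; (3) E→M only, B unrelated; (4) E→B→M. Blocks without
incoming edges (other than exposures) get free variances and zero
covariances, so frameworks 2-4 assert genuine independence restrictions
and model selection by lowest AIC among converged fits is meaningful. At
n = 100 with weak factor-level signal AIC can prefer the sparser
framework even when the mediation framework fits perfectly — model
selection at study scale is noisy, which the model-recovery test
quantifies at n = 500 (framework 1 recovered in well over 90% of seeds).

## Mediation

`mediate()` fits M = a0 + aX + g'C + e1 and Y = b0 + c'X + bM + d'C + e2
by OLS and decomposes ACME = ab, ADE = c', Total = ab + c' — the linear
no-interaction case, where the identity ACME + ADE = Total holds exactly
in every bootstrap draw (an interaction-free outcome model matches the
source design's description; a flag could average counterfactual
contrasts instead, deliberately out of scope here). Inference is by
resampling participants with replacement (default 1000 draws; percentile
95% intervals; the bootstrap p is the symmetric two-sided tail
2 min(P(draws<=0), P(draws>=0)), reported as < 2/n_boot when a tail is
empty — interval type and draw count are unstated in the source design,
so the defaults are documented and configurable). The proportion mediated
is ACME*/Total* per draw with the median over draws as the point estimate,
matching median-based reporting; draws with Total* = 0 are excluded and
counted. The mediator enters on log relative abundance with the
half-minimum offset (compositional skew); the adjustment-set ladder runs
unadjusted, age, age + island, and a multivariate set (age, BMI, gender,
smoking, fruit, vegetables, takeaway, seafood, alcohol) under a shared
seed.

## Moderation scan

Presence is abundance strictly above 0 (profiler detection). Per taxon the
scan fits Y = b0 + b1 g + b2 presence + b3 (g x presence) + covariates and
Wald-tests b3; BH runs across tested taxa only. Taxa with presence outside
a 0.1-0.9 window or any 2x2 cell below 3 are skipped with a recorded
reason — an interaction with an empty cell is unidentifiable; both bounds
are artifact additions (the source design is silent on degenerate taxa)
and configurable. The ladder refits selected taxa unadjusted,
age-adjusted, and multivariate, reporting the four cell means with
pairwise Welch t-tests (significance flag at p < 0.05, no further
correction, mirroring a display convention; Tukey could be substituted).
Power at study conditions is worth stating plainly: with theta = 8 mmHg,
residual SD 10 mmHg, n = 500 and BH across 70 taxa, the planted taxon's
expected Wald z is ~4.3 against an effective threshold of ~3.4, i.e.
roughly 80% detection; at n = 100 (the study scale) single-seed scans
frequently miss, which is an honest property of the design, not of the
implementation.

## Cohort statistics

Group comparisons report medians (Q1, Q3) on the raw scale with an
unadjusted one-way ANOVA p (identical to the pooled t-test for two
groups — asserted in tests) and an age-adjusted ANCOVA Wald p; flagged
variables are log-transformed before testing (a variable is never
"age-adjusted" against itself). The Spearman screen uses tie-corrected
rho with asymptotic p for n > 10 and the exact null distribution below,
BH across the full biomarker x feature grid, and the pass rule
|rho| >= 0.3 AND q <= 0.05. Pathway comparisons use Mann-Whitney + BH
with a difference-in-mean-proportions effect and a seeded percentile
bootstrap CI (the effect-size definition is unstated in the source
design; difference in mean proportions is the conventional choice);
taxon-stratified rows are first filtered to features detected in at least
80% of either group. UNMAPPED/UNINTEGRATED pathway rows are excluded from
community totals by default, with a flag to retain them.

## Problem sizes and runtime choices

The default pipeline runs at the study scale (n = 100, 9999 permutations,
1000 bootstrap draws, 30 LDA rounds, 50 NMDS restarts) and completes in
seconds. The validation suite sizes its simulations for accuracy of the
check, not exhaustiveness: consistency checks at n = 1000-6000,
calibration sweeps at 100-500 replicates with 200-300 bootstrap draws,
model-selection recovery over 100 seeds. These sizes are the package's
choices and are recorded in the tests themselves.

## Known limitations

* LEfSe scores are a documented variant of the published algorithm, not a
  re-implementation; only two classes are supported.
* The SEM stage is path analysis over factor scores, not a full latent
  CFA, and its robust SEs are sandwich-only (no Yuan-Bentler scaling).
* PERMANOVA is single-factor; covariate-adjusted (multi-factor) designs
  are out of scope.
* Mediation assumes sequential ignorability and linearity; no sensitivity
  analysis is provided.
* The bootstrap percentile interval does not guarantee that the
  full-sample point estimate lies inside it in pathological samples,
  though it does under all tested conditions.
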