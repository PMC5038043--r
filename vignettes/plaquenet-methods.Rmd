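---
title: "Models and design choices in plaquenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in plaquenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

plaquenet reimplements, as a tested pipeline, the statistical analysis
used to separate gingivitis-associated from periodontitis-associated
signals in supragingival-plaque taxon counts: rarefaction-based alpha
diversity with stepwise covariate models, negative-binomial differential
abundance, compositional (SparCC) cooccurrence networks across disease
strata, and Mantel-distance clustering of the per-stratum correlation
matrices. Because the original sequencing data are not redistributed
with the package, a calibrated synthetic-cohort generator provides the
test surface: every stage can be exercised against data whose ground
truth is known. This vignette explains the models, the tunable
parameters, and the design decisions that were genuinely open.

## The clinical design

Each sample is a supragingival plaque community from one woman, with two
disease measures: gingivitis severity as the number of dental-arch
sextants that bleed on probing (BoP, 0–6, treated as continuous) and
periodontitis as a binary classification. The two are correlated
(Spearman rho 0.44 in the study cohort) but not redundant, and the
pipeline's central question is which community features track which
measure. Technical and epidemiological covariates (study site,
nutritional intervention arm, HIV status, sequencing run) enter the
models as adjustment terms.

The printed per-stratum cohort table is embedded as
`table2_strata()`; `expand_table2()` expands it deterministically to 962
per-woman records, from which `cohort_summary()` reproduces the
published headline statistics exactly (822 with gingivitis, 307 with
periodontitis, mean age 25.4, rho 0.44). The study's two cohort tables
disagree slightly (963 vs 962 women, 311 vs 307 with periodontitis); the
per-stratum demographic table is treated as authoritative throughout.

## Alpha diversity

`rarefy()` subsamples one sample's reads to a fixed depth, classically
(without replacement, a multivariate hypergeometric draw) or with
replacement (multinomial). `alpha_diversity()` averages observed
richness and the Shannon index over `iterations` independent draws;
samples below the depth are excluded and reported, never imputed.
Defaults are 5000 reads and 100 iterations, the study's values. Two
conventions needed fixing:

* **Log base.** The Shannon index is reported in nats. The source
  methods never state a base; natural log is the common ecology default.
* **Rarefaction mode.** The methods text says "rarefying", the figure
  captions "sampling with replacement". Both are implemented;
  `without_replacement` is the default because it is the classical
  estimator. For any one sample the two differ only in finite-pool
  correction terms of order depth/total.

`backward_stepwise_lm()` relates a diversity index to covariates by
backward elimination under AIC computed as `n log(RSS/n) + 2k` (k
counting all coefficients including the intercept). At each step the
single term whose removal lowers AIC most is dropped; ties break toward
the term listed last, for determinism. Note the statistical character of
AIC selection: an irrelevant single-degree-of-freedom covariate survives
with probability near `P(chisq_1 > 2) = 0.157` no matter the sample
size, so stepwise retention of a term is weaker evidence than a
coefficient test.

## Differential abundance

The count model is a log-link negative binomial GLM per taxon, fitted to
raw counts with a per-sample normalization offset:

* `size_factors()` computes median-of-ratios factors: the reference set
  is every taxon observed in all samples; a sample's factor is the
  median ratio of its reference counts to the reference geometric means,
  and the factors are rescaled to geometric mean one. A
  `pseudo_reference` fallback handles tables with no all-positive taxon.
* `estimate_dispersion()` profiles the NB likelihood over the dispersion
  `alpha` (variance `mu + alpha mu^2`), refitting the GLM at each
  candidate; the estimate is floored at 1e-8 and falls back to moments
  if the profile fails. No empirical-Bayes shrinkage across taxa is
  applied: the claims tested here concern the model structure, not
  shrinkage details, and per-taxon maximum likelihood keeps each taxon's
  fit self-contained.
* `fit_nb_glm()` solves the GLM by iteratively reweighted least squares
  to relative tolerance 1e-8 (at most 100 iterations), with standard
  errors from the Fisher information.
* `wald_bh()` converts coefficients to two-sided normal-reference
  p-values and Benjamini-Hochberg q-values; q < 0.05 labels a taxon
  disease- or health-associated by coefficient sign.

`run_differential_abundance()` fits one joint model per taxon containing
both focal covariates (BoP continuous, periodontitis binary) and all
adjustment terms, and reports separate tables for the two focal
coefficients plus their intersection. A single joint model — rather than
one model per disease measure — is used because the periodontitis
question is explicitly conditional on gingivitis severity. Categorical
adjustments use treatment coding with the lexicographically first level
as reference; samples missing any design covariate are dropped per
model with a logged count.

**A known limitation worth stating plainly.** Median-of-ratios
normalization assumes the median reference taxon is unchanged. When a
covariate drives large fold changes (a 1.45-fold-per-sextant effect
spans 9-fold across the BoP range), two residual artifacts appear at
cohort sample sizes: taxa depleted strongly enough to hit zeros drop out
of the all-positive reference set, and strongly enriched taxa shift the
median's position within the unchanged taxa's sampling spread. The
result is a systematic residual of a few percent per sextant on null
taxa — materially negligible, but statistically detectable at n of
several hundred, where it can push null taxa past q < 0.05. The test
suite therefore asserts separation of the two disease signals on effect
sizes, not on hit-list membership alone.

## SparCC cooccurrence networks

Relative abundances bias naive correlations (the closure effect: if one
taxon rises, all others' fractions fall). `sparcc()` estimates
correlations between the latent *basis* abundances from log-ratio
variances. Per inference iteration (default 20), per-sample fractions
are drawn from a Dirichlet posterior with add-one prior — the zero
handling; no fixed pseudocount is applied to raw counts — and the
log-ratio variance matrix `t_ij = var(log x_i / x_j)` is formed. Writing
`t_ij = w_i + w_j - 2 rho_ij sqrt(w_i w_j)` and assuming the correlation
cross-terms cancel in aggregate, the basis variances `w` solve a linear
system; correlations follow as
`rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j))`. The strongest pair
above the exclusion threshold (default 0.1) is then removed from the
system and the solve repeated, until no pair exceeds the threshold, half
of all pairs are excluded, or an exclusion would leave a taxon with no
partners. The final matrix is the componentwise median across
iterations, clamped to [-1, 1]. The solver needs at least 4 taxa (the
3-taxon system is solvable but leaves no redundancy for the exclusion
logic; the internal solver is still validated against the exact
3-component closed form in the tests).

The invoked procedure computes Pearson-type correlations of log-ratio
transformed abundances even though the source text calls its outputs
Spearman coefficients; the log-ratio Pearson semantics are implemented,
as that is what the procedure actually does.

`permutation_pvalues()` shuffles every taxon's counts across samples
independently (destroying between-taxon dependence, preserving
marginals; the source text says only that data sets were shuffled),
reruns the full estimator, and reports add-one two-sided pseudo
p-values `(1 + #exceedances) / (1 + n_perm)` — never exactly zero with
finite permutations. An empirical permutation reference is used rather
than a parametric t reference, whose mention in the source is ambiguous.

`strong_edge_cutoff()` is `mean + 1.96 SD` of the upper-triangle
correlations, with the population SD (the sample/population distinction
is negligible at realistic edge counts; population chosen for
determinism). `build_network()` keeps edges with correlation strictly
above the cutoff and permutation p below the significance level —
default 0.05 from the methods text; the figure captions use 0.01, and
the level is a parameter. Isolated nodes are dropped and counted.
`betweenness_ranking()` uses unweighted shortest-path betweenness
(Brandes) with ties broken by node id; a weighted variant uses `1/rho`
edge lengths. `layout_fr()` provides Fruchterman-Reingold coordinates
for export only.

## Stratified networks and Mantel clustering

`cluster_strata()` compares the correlation matrices of the
(BoP, periodontitis) strata by the Mantel distance `1 - r`, with `r` the
Pearson correlation of the strict upper triangles, and clusters them
agglomeratively (complete linkage, the quoted tool's default; average
and single linkage are available). Unadjusted — pre-significance —
correlation matrices are clustered, because the strata differ in sample
size and therefore in permutation power; thresholding first would
confound structure with power. The dendrogram is serialized as Newick
with merge heights as branch lengths.

## Phylotype selection by percent identity

`global_identity()` is Needleman-Wunsch global alignment (match +1,
mismatch -1, linear gap -2) with identity = matched columns / alignment
columns, gap columns counted in the denominator; a `matched_columns`
denominator is available because the external tool originally used for
this step does not restate its definition. N matches nothing, including
another N. `select_by_identity()` selects queries whose best reference
identity strictly exceeds the threshold (default 98.5, the species-level
convention of the oral 16S reference database); ties in the best hit
break by reference id. All-vs-all exact alignment is used — at hundreds
of ~370 nt fragments there is no need for heuristic prefilters.

## The synthetic cohort generator

`generator_config()` + `sample_cohort_metadata()` + `generate_counts()`
emulate the study conditions:

* **Metadata.** BoP severities and periodontitis are drawn with the
  printed per-stratum frequencies; demographics come from the printed
  stratum means/SDs and category splits.
* **Library sizes** are lognormal, moment-matched to the printed mean
  13,565 and SD 6,833 reads. The calibration applies to the *drawn*
  sizes: under the absolute mean model below, covariate effects add
  reads on top, so realized column sums sit a few percent above the
  target by construction.
* **Counts.** The expected count is `mu = s * q * exp(eta)` with `s` the
  library size, `q` the taxon's base relative abundance (deterministic
  lognormal quantiles, log-SD 2, assigned in decreasing order so low
  taxon indices are the abundant, reliably detectable members), and
  `eta` the log-linear effects: `beta_bop * bop + beta_perio * perio`,
  optional confounder terms, an optional per-taxon-sample noise term
  (default off — the model's stochasticity is the NB noise and the
  module factor), and the module term. Counts are NB with variance
  `mu + alpha mu^2`; the default dispersion 0.5 is a realistic mid-range
  for covariate-adjusted 16S counts. For the validation of the published
  1.45-fold-per-sextant effect the focal taxon's dispersion is set to 2,
  which reproduces the printed confidence-interval width for that
  organism (about ±6% per unit); smaller dispersions would make the
  simulated study unrealistically precise.
* **Cooccurrence modules.** Each module is a taxon subset sharing a
  per-sample factor `exp(loading * z)`, `z` standard normal, added on
  the log-mean scale only in the module's active periodontitis stratum.
  The factor is median-one rather than mean-one: a mean-one version
  places the *typical* module sample below the unchanged taxa and
  drags the median-of-ratios factors with it, creating spurious
  associations on null taxa. The mean shift this induces between strata
  (`loading^2 / 2` on the log scale) is folded into the effective
  effect sizes recorded in the ground truth.
* **Default community layout** (100 taxa): an unchanged abundant core
  (ranks 1–20) anchoring normalization; a periodontitis module at ranks
  21–30 — two coaggregation sub-modules sharing the bridging taxon
  T026, so the strong-edge network has clusters connected through a
  high-betweenness hub — which is also disease-associated
  (beta_perio = ln 1.5); a mildly health-associated block at 31–40; a
  gingivitis block at 41–50 with per-sextant folds tapering 1.45 to 1.1
  (the strongest published association downward); a gingivitis-depleted
  block at 51–60; and a rare tail, of which ranks 61–70 form a module
  active in women *without* periodontitis and ranks 61–80 are
  sequence-similar to the periodontitis module, so similarity-based
  selection sweeps in rare relatives that end up isolated in the strong
  network — as in the study, where 22 isolated nodes were dropped.
* **Sequences.** `generate_sequences()` copies a reference and
  substitutes exactly `round((1 - target/100) * L)` positions, so
  identities straddle the 98.5% cutoff by construction.

What the generator does **not** emulate: taxonomic structure and
phylogeny; the upstream read-processing pipeline; zero inflation beyond
the NB; depth-composition coupling (real sequencing fixes the read
budget, so a bloom *displaces* other taxa's reads — the absolute
parameterization instead follows the differential-abundance model being
tested); and an explicit diversity gradient (diversity changes in the
synthetic cohort are whatever the effect blocks induce). Passing tests
therefore validate the estimators against their own model class plus the
compositional observation process, not against every pathology of real
plaque data.

## Numerical choices

Degenerate inputs are errors, not warnings: all-zero taxa before
SparCC, all-zero samples before Bray-Curtis, empty taxon sets, bop
outside 0–6, unknown category labels. Basis variances are floored at
1e-12 before the square root; correlations are clamped to [-1, 1]; the
GLM linear predictor is clamped at ±30 during IRLS; `0 log 0` is 0 in
the Shannon index. PCoA (classical scaling via `cmdscale`) drops
negative-eigenvalue axes and reports their count, with no
Lingoes/Cailliez correction. The single-draw rarefaction used for the
summed-abundance figures is seeded and documented as presentational.
All randomness flows from explicit seed arguments; `run_pipeline()`
derives fixed per-stage substreams from one global seed, so a stage's
results do not depend on which other stages are enabled.

## Problem sizes used in validation

The test suite and the acceptance script validate at sizes chosen to
make the checks sharp while keeping a full run comfortable on a single
CPU: the full pipeline at its default 500 samples x 100 taxa with 100
permutations; SparCC recovery on 20 taxa x 500 samples over 50 seeds;
fold-change coverage at n = 800 over 20 seeds; stratum clustering on 8
balanced strata of 60 women over 20 seeds; oracle checks (exhaustive
betweenness, alignment DP, BH step-up, hypergeometric richness,
rank-sum statistics) on small exact instances.
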