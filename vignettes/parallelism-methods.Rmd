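---
title: "Measuring parallelism of molecular evolution across trait levels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring parallelism of molecular evolution across trait levels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parallevol)
options(parallevol.quiet = TRUE)
```

# The question and the design

Replicate populations adapting independently to the same environment often
converge on the same high-level phenotypes while diverging in the molecular
details — a signature of redundancy in a hierarchically organized trait
architecture. `parallevol` asks the question quantitatively at two molecular
levels: do replicate populations recruit the same genes (transcriptome) and
do they reach the same metabolic state (metabolome)?

The supported design is a common-garden contrast: a set of ancestral
replicate samples (5 by default), `P` evolved populations with a few
replicate samples each (10 populations × 3 replicates for expression,
a 6-population subset × 3 replicates for metabolites). Each evolved
population is contrasted against the *same* ancestral samples, separately,
and parallelism is then a property of the collection of per-population
results.

# Per-population differential calling

## Expression: negative-binomial GLM with likelihood-ratio test

Counts are normalized to counts per million (CPM; plain library-size
scaling — total count — for transparency). Genes are considered expressed
when their mean CPM across all samples is at least `cpm_filter` (default
0.1). Because "at least 0.1 CPM across all samples" can also be read as a
per-sample minimum, `filter_mode = "min"` provides that alternative; the
mean reading is the default because it is the common idiom for thresholds
this low, where a single zero sample should not discard a gene.

For each gene in the 5-vs-3 contrast a negative-binomial GLM with log link
and log-library-size offset is fitted under the full model
(intercept + evolution indicator) and the null model (intercept only).
The evolution effect is tested by the likelihood-ratio statistic
(null deviance − full deviance) against χ² with 1 df, and p-values are
BH-adjusted per population.

Numerical choices:

* The IRLS solver is vectorized across genes (all genes share the 2-column
  design, so the normal equations collapse to closed-form 1×1/2×2 solves),
  with convergence declared at a relative log-likelihood change below 1e-8
  and a 50-iteration cap. Linear predictors are clamped at ±30 so that
  group-separated genes (e.g. all-zero evolved counts) converge to their
  boundary deviance instead of diverging. Genes with zero counts in every
  contrast sample have a degenerate likelihood and are removed before
  fitting (reported as `NA`); genes that still fail to converge are flagged
  and excluded downstream with a logged count.
* The dispersion is a single *common* value per contrast, found by
  maximizing the summed Cox–Reid-adjusted profile likelihood
  (`ℓ − ½ log det(XᵀWX)` per gene) over a log-scale grid with golden-section
  refinement. The Cox–Reid term matters: with only 8 samples and 2 mean
  parameters per gene, unadjusted maximum likelihood underestimates the
  dispersion by roughly a third, which makes the LRT visibly liberal. With
  the adjustment the null type-I rate at 0.05 lands within the test suite's
  [0.03, 0.07] acceptance band. Estimation uses the contrast samples only,
  matching the per-population framing of the analysis. The test suite
  cross-checks the fitted model against an independent GLM implementation
  (edgeR) at a fixed shared dispersion; agreement is at the 1e-5 level.
* Only the significance calls come from the GLM. The reported effect size is
  the descriptive `log2FC = log2((mean CPM evolved + c)/(mean CPM ancestral
  + c))` with pseudocount `c = 0.5` CPM (configurable; `c = 0` recovers the
  plain ratio of means where both means are positive).

## Metabolites: exact small-sample permutation test

Normalized peak areas are log-transformed (natural log by default; the base
only relabels the scale and is configurable) and a metabolite is "detected"
when its log value strictly exceeds `met_detection_floor` (default 10) in
every sample. The test statistic is the difference in group means. With 5+3
observations there are only C(8,3) = 56 distinct reassignments, so the
default is exhaustive enumeration — an exact test — rather than the
equivalent-but-noisier convention of sampling reassignments with
replacement, which remains available (`n_permutations_met_test = 100`)
for procedural fidelity. The p-value is the proportion of reassignments
whose absolute difference strictly exceeds the observed one; so that BH
never receives an exact zero, an exceedance count of zero is reported as
1/57 (exhaustive) or 1/(B+1) (random mode). Zero-variance metabolites get
p = 1 by convention. Metabolite `log2FC` is the group mean difference
converted to log₂ units, i.e. the log₂ ratio of geometric means — the
natural analogue of the CPM ratio on an already-log scale.

# Parallelism statistics and the heterogeneity null

For every population pair, `pairwise_parallelism()` reports the Jaccard
index of the significant-feature sets and Pearson's correlation of the full
log₂FC vectors (all tested features, not only significant ones; pairs of
empty sets yield Jaccard 0 by convention, with a warning).

The heterogeneity test asks whether the observed mean pairwise statistic is
*smaller* than expected when no population-specific effects exist. Following
the per-feature formulation, each feature's values are independently
reshuffled across all evolved samples, the per-population analysis is
re-run against the fixed ancestral samples, and the mean pairwise statistic
is recorded; `p` is the proportion of permuted means strictly below the
observed mean (ties count as "not smaller"). Both the plain proportion and
the add-one variant `(k+1)/(B+1)` are reported, since the plain version can
return an exact 0. The default is 100 permutations.

Two technical points deserve emphasis:

* **Permutation must respect normalization.** Raw counts are not
  exchangeable across samples with different library sizes: naively
  reshuffling them inflates the permuted noise and makes the null
  anti-conservative in the *wrong* direction (observed parallelism looks
  high). The Pearson-statistic null therefore permutes CPM values, and the
  Jaccard-statistic null (which must refit the GLM on counts) moves each
  count together with its own log-library-size offset, using per-observation
  offsets in the refit. Under the generative null this restores
  exchangeability exactly; the test suite verifies near-uniform p-values
  over 40 replicate simulations.
* **Dispersions are estimated once**, on the observed contrasts, and reused
  across permutations: per-feature permutation conserves every gene's value
  multiset, so the profile-likelihood estimate is essentially unchanged,
  and re-estimating it 100 times would dominate the runtime for no
  statistical gain.

Per-feature permutation destroys correlations between features within a
sample; this is the liberal-null reading of the per-gene formulation. A
stricter whole-column alternative (`permute_mode = "columns"`, shuffling
evolved samples' population assignments) is provided for users who want
within-sample correlation preserved.

# Comparing the two levels

The comparison is restricted to populations present in both omics. Feature
counts are equalized before comparing: for the correlation statistic, the
expressed genes are repeatedly downsampled (100×) to the number of tested
metabolites and the per-pair correlations averaged over repetitions; for the
Jaccard statistic, each population's DE gene set is downsampled to its
significant-metabolite count. The per-pair distributions (15 pairs for 6
populations) are then compared with a two-sample t-test — Welch's
unequal-variance test by default, pooled Student's as an option, since the
variance of Jaccard/correlation values need not match across levels. The 15
pairs of 6 populations are not fully independent observations; the t-test
treats them as such, which is the conventional reading, and the
`compare_levels()` inputs are exposed so users can substitute a
permutation-based alternative. `expected_downsample_jaccard()` provides the
closed-form (hypergeometric) expectation of the downsampled Jaccard index
and is verified against exhaustive enumeration in the tests.

# Joint pathway analysis

Per pathway, per omic, per population, the global-test quadratic score
`Q = y_cᵀXXᵀy_c / (m·y_cᵀy_c)` is computed over the contrast samples, where
`y_c` is the centered group indicator and `X` holds the pathway's member
features, each standardized; expression enters as `log2(CPM + c)`.
The p-value is a label-permutation p (default 1000 permutations, strict
exceedance, add-one convention) — exact at n = 8 and free of asymptotic
assumptions; the permutation route was chosen over the asymptotic
distribution of the score precisely because 8 samples is far from
asymptotia. The test operates on the sample-level matrix (the way
quantitative enrichment on a two-group design is defined) rather than on a
precomputed log₂FC list; a pathway needs at least `min_pathway_members = 2`
usable (non-constant, present) members, else it is skipped for that omic.
Per-omic p-values are combined with Fisher's method, `S = −2Σln pᵢ` against
χ²(2k); a pathway testable in one omic only contributes a k = 1 combination,
which is the identity on p and is flagged in the output (`n_omics`).
BH adjustment is applied across pathways within each population, and the
pathways significant in *all* populations are reported with their mean
adjusted p across populations.

# The synthetic-data generator

`simulate_effects()` embodies a hierarchical redundancy model. Each of
`n_metabolites` metabolites owns a disjoint module of `genes_per_module`
(default 5) genes. A module has one shared effect `s_m ~ N(0, 1)` (log₂
scale, drawn once, common to all populations). In each population each
module gene is independently *active* with probability
`redundancy_fraction` (default 0.5); an active gene's effect is
`s_m + u_gp` with population-specific `u_gp ~ N(0, 0.5²)`; inactive genes,
and the background genes outside every module, have effect 0. The
metabolite's effect per population is the mean of its module genes' effects
(sum and signed-max are offered; the gene→metabolite map is a modeling
choice — nothing in a two-level abundance design identifies it — and the
arithmetic mean is the simplest many-to-one aggregation). Because
populations activate different genes but share `s_m`, the metabolite level
is more parallel than the gene level whenever `redundancy_fraction < 1`,
which is exactly the hierarchy hypothesis as a generative statement.

Default magnitudes: shared effects of SD 1 log₂ unit (typical ~2-fold
shifts, the scale seen in strong laboratory adaptation), population-specific
SD 0.5, NB dispersion 0.05 (biological CV ~22%, typical for replicate
cultures), metabolite replicate noise SD 0.2 log units, library sizes
log-normal around 2×10⁶ with 10% CV, baseline log₂-CPM uniform on [−4, 9]
so that the 0.1-CPM filter is genuinely exercised, metabolite baselines
uniform on [10.5, 14] so strong negative effects can push values below the
detection floor.

What the generator does *not* emulate: gene–gene correlation beyond module
co-membership, sample-level batch effects, compositional coupling other
than through the library-size total, mean–dispersion trends, missing-value
structure in peak detection, and nonlinear pathway kinetics (feedback,
substrate competition). Passing tests on this generator therefore show that
the statistics recover the truth of a clean hierarchical model at realistic
noise levels — not that any particular real data set satisfies those
assumptions.

# Reproducibility and problem sizes

A single `rng_seed` in the configuration derives deterministic per-stage
child seeds (`derive_seed()`), so stages re-run in isolation reproduce their
draws and two identical runs produce byte-identical outputs (tables are
written at 6 significant digits, JSON at full precision). The test suite
and the acceptance script size their simulations for a single CPU:
1000–2000 genes and 100 metabolite modules for calibration and power
checks, 40 replicate simulations at 50 permutations for the null-uniformity
property, 20 replicates for the cross-level power property. These sizes were
chosen once as the smallest instances at which the binomial tolerances of
the property checks are informative.

# Known limitations

* The common-dispersion NB model has no per-gene dispersion moderation; in
  data with strong mean–dispersion trends the LRT will be miscalibrated for
  genes far from the common value. The module boundary makes it simple to
  substitute a different fitter.
* The exhaustive metabolite test has granularity 1/56: with few tested
  metabolites, BH at 0.05 behaves in discrete jumps (all-or-none blocks of
  discoveries), which is a property of the design, not of the
  implementation.
* The heterogeneity p has granularity 1/B and is one-sided by construction;
  B = 100 (default) bounds the smallest reportable add-one p at ~0.01.
* Per-pair parallelism values are treated as independent in the cross-level
  t-test (see above).
```{r session}
sessionInfo()
```
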