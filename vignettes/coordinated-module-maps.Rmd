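---
title: "Coordinated module maps: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated module maps: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comodmap)
```

This vignette is the package's account of its statistical machinery: what
each model assumes, which tunable parameters matter and why their
defaults are what they are, what the synthetic generators do and do not
emulate, and the choices we made where the design was genuinely open.

## The module map

The analysis treats a cohort as a gene-by-sample matrix of log2 ratios
(tumor versus a common reference), with missing spots masked. Every
statistic excludes masked entries, so per-sample parameters reflect the
data actually available in that sample.

**Discretization.** After per-gene centering (`center_genes()`), a value
is called induced at `log2_threshold = 1`, i.e. at least 2-fold above the
gene's cohort average, inclusively (`x >= 1` counts). Repression is
symmetric. The inclusive boundary matters only for values exactly at the
threshold but is fixed for reproducibility. The threshold is the one
knob a user should think about: at noise SD 0.5 (typical residual spread
of replicate-merged cDNA log-ratios) a 2-fold cut calls roughly 2% of
null genes per direction, so module enrichment operates on a sparse
discrete matrix.

**Per-sample hypergeometric test.** For a sample with `N` unmasked genes
of which `K` are induced, and a module with `n` unmasked genes of which
`k` are induced, we use the inclusive upper tail `P(X >= k)` of
`Hypergeom(N, K, n)`. Inclusive upper tails are the standard enrichment
convention; the exclusive tail would call `k = 0` "significant" whenever
`K` is small. The same machinery is reused at group level with samples
in place of genes. Statuses are called at a raw `alpha = 0.05` in both
stages; no multiple-testing correction is applied anywhere in the module
map, because the downstream selection step (multiple significant groups,
redundancy removal) is the filter that controls spurious calls.

**Signed fractions.** A group summary reports `+k_ind/n` when induction
is significant, `-k_rep/n` when repression is, 0 when evaluated but not
significant. In the exported table (`format_module_table()`) a cell not
evaluated at all renders as `---`, distinct from `0.0`; the two null
marks mean different things (no test vs a negative result). We chose
single-direction fractions rather than induced-minus-repressed
differences because the signed-fraction semantics reproduces mixed-sign
patterns (a module +0.5 in primaries and −0.4 in metastases) without
conflating the two directions in one number.

**Selection.** `select_modules()` keeps modules significant in at least
`min_significant_groups` groups, then collapses redundant gene sets
(Jaccard ≥ 0.8, the winner having more significant groups, ties by best
p-value). The default of 1 significant group is deliberately permissive —
it is the "anything noteworthy" screen. For claims of robust alteration
we require significance in **four or more groups across categories**, the
same multi-category requirement we use before carrying a module into
network analysis, and the setting used throughout the validation battery:
with ~15 group tests per module at raw α = 0.05, background modules reach
1–3 significant groups by chance, while a genuinely altered module is
significant in most categories simultaneously (8–10 groups for the
planted module of the validation cohort).

## Gene consistency

The score of gene G in a module is
`sum(-ln p_i^s)` over induced samples where G is induced plus
`sum(-ln p_r^s)` over repressed samples where G is repressed, with
`p_i^s`, `p_r^s` the sample's genome-wide induced/repressed fractions.
Three choices were open:

* **Log base.** We fixed the natural log. Any base rescales all scores
  by a constant and leaves p-values invariant, so the choice is cosmetic
  but must be pinned for comparability of reported scores (units: nats).
* **Disagreement.** An induced sample in which G is repressed
  contributes 0, not a penalty; only agreement weights are defined in
  the scoring model, and a penalty would require a second, arbitrary
  weight scale.
* **Null model.** Under the null each status-bearing sample contributes
  its weight independently with probability equal to its own match
  fraction, so the null score is a sum of independent Bernoulli-weighted
  terms. `consistency_pvalue()` enumerates all `2^m` outcomes exactly up
  to `m = 20` status-bearing samples (about 10^6 outcomes, a few MB and
  milliseconds) and switches to seeded Monte-Carlo above that; the
  Monte-Carlo p uses the add-one estimator `(1 + hits)/(n_mc + 1)`, so
  it is never exactly 0 and is conservative at the floor. At the default
  `n_mc = 1e5`, the smallest reportable p is ~1e-5; gene lists cut at
  10^-3.3 or 10^-5 are therefore attainable in either mode. Score
  comparisons against the observed value use a 1e-9 absolute tolerance
  so that floating-point ties (the observed outcome itself) count as
  reaching the score.

## Relevance networks and differential correlation

Within one group, all module gene pairs with at least `min_n = 4`
pairwise-complete samples get a Pearson correlation; the network keeps
pairs with `r²` above a permutation cut-off (`estimate_cutoff()`:
`B = 100` rounds, each independently permuting every gene across the
group's samples; default cut-off is the **maximum** permuted `r²`, the
original relevance-network convention, with the quantile exposed because
gentler cut-offs are defensible). Sample sizes are pair-specific because
masking varies by gene.

The two-group comparison uses Fisher's Z:
`Z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided
normal p. The transform requires `|r| < 1` and `n >= 4`; perfect
correlations are flagged and excluded from testing rather than clamped,
since a clamped value would fabricate a finite Z from an infinite one.
Band labels use `|r|`: none ≤ 0.4 < regular ≤ 0.6 < moderate ≤ 0.8 <
high. Whether the permutation `r²` cut-off should gate the differential
test, or only the Z-test p-value should filter, is genuinely ambiguous;
both paths are implemented and `apply_r2_cutoff` chooses (default off:
the Z-test is self-calibrating, and gating would discard pairs that are
strong in only one group — the interesting ones). No multiplicity
correction over pairs; instead a stringent reporting threshold
(`p < 10^-4.3`) is conventional and exposed.

## Sample discrimination by SOM

`som_cluster()` implements a 1-D online SOM: `k_units = 2`, 1000 epochs,
learning rate decaying linearly from 0.5, Gaussian neighborhood with
radius decaying from 1 to 0.01 (single-unit updates late in training),
prototypes initialized from randomly drawn samples, all under one seed.
A 2-unit SOM is essentially an annealed 2-means, which is the point: the
map is used as a robust two-group splitter, and on separable data it
agrees with `kmeans` up to relabeling (checked in the suite). Missing
values are imputed to 0 for the SOM only — the neutral value on the
gene-centered scale — rather than propagated, because best-matching-unit
distances need complete vectors. Within clusters, display order comes
from average-linkage clustering on `1 - r` correlation distance; blocks
never mix. Cluster–clinical association uses chi-square (Yates-corrected
for 2×2 tables, uncorrected otherwise — the usual convention) and
Mann-Whitney for continuous variables; results are invariant to cluster
relabeling. Note that a comparison of Breslow thickness between clusters
is only defined when both clusters contain primary tumors; otherwise it
is skipped with a note.

## Two-channel preprocessing

Spots with foreground ≤ background in either channel are removed
(inclusive, since equality leaves zero signal after subtraction). M and
A are computed on background-subtracted intensities floored at 0.5
intensity units — after the filter a subtracted value can still be
arbitrarily close to 0, and the floor bounds the log without affecting
ordinary spots. LOWESS uses tricube weights with 3 robustness
iterations, span 0.4 and local degree 1 (`stats::lowess`); degree 2 is
available through a robust `loess`. The fit requires ≥ 10 spots.
Dye-swap merging averages `M_fwd` and `-M_swp`, using the single
available orientation when one is missing; replicate QC is the Pearson
correlation of `M_fwd` with `-M_swp` over shared genes.

## Synthetic data: what it emulates, what it does not

`generate_cohort()` mirrors the study conditions the pipeline targets: a
60-sample cohort (20 primary, 40 metastatic) with plausible clinical
annotations (Breslow depths log-normal around 3 mm — a vertical-growth-
phase primary set — AJCC T classes derived from depth, stages tied to
subtype, metastasis sites, survival times), baseline expression
`Normal(0, noise_sd = 0.5)`, planted modules shifted by an effect in
log2 units in their target group, planted pairs drawn from latent
bivariate normals with a target correlation inside one group only, and
an optional uniform missing mask. Correlation is planted through the
latent normal rather than by rank-reshuffling so that Pearson and
Spearman targets nearly coincide — both statistics are under test.
Decoy modules of background genes give selection something to reject.

What it deliberately does not emulate: platform spot layout or spatial
artifacts, intensity-dependent variance heteroscedasticity after
normalization, correlated missingness, gene–gene correlation beyond the
planted pairs, or any biology. Passing the validation battery therefore
shows the statistics behave as designed under their own assumptions —
calibrated nulls, power where planted structure exists — not that real
cohorts satisfy those assumptions.

`generate_spot_table()` back-computes channel intensities from true
log-ratios plus a constant, linear or curved dye bias over A and additive
log-scale noise, with a stated fraction of spots planted below
background; `generate_tma_scores()` draws Gaussian-copula pairs pushed
onto a skewed gamma margin to emulate immunohistochemistry scores with a
target rank correlation.

## Survival grouping

Outcome groups use a 4-year horizon: death from melanoma within the
horizon is `Death`; survival to the horizon is `Surviving`; deaths from
unrelated causes and censored follow-up shorter than the horizon are
excluded. One reading was open: a patient dying of melanoma *after* the
horizon. We class them `Surviving` — the grouping rule is literally
"died within the horizon" versus "survived the horizon", and the patient
did survive it. Samples lacking a category's attribute (e.g. metastasis
site for a primary) are omitted from that partition with a message, not
an error, because several categories apply only to cohort subsets.

## Validation problem sizes

The test suite and the acceptance script run: the full hypergeometric
grid `N ≤ 30` against an exact enumeration oracle (~87,000 tails);
type-I calibration of the Fisher-Z test at 10,000 replicates per ρ;
differential-network power over 500 replicates of the 12-vs-40 regime;
one 500-gene planted-module cohort end to end; 2,000-spot LOWESS checks;
100 seeded SOM replicates; and 60-replicate Monte-Carlo power for the
KS normality check. These sizes put Monte-Carlo error well inside each
check's tolerance while keeping a full run in the low minutes on one
CPU.

## Known limitations

* Group-level hypergeometric tests treat per-sample statuses as fixed
  labels; uncertainty in the per-sample calls does not propagate.
* The consistency null conditions on the observed module statuses; it
  does not model selection of the module itself.
* The SOM is a two-group splitter; it does not estimate the number of
  clusters.
* Raw α = 0.05 at both module-map stages means single-group calls are
  screens, not discoveries — hence the multi-group selection rule.
* The Fisher-Z test assumes approximate bivariate normality within
  groups; heavy-tailed expression can inflate its type-I error.
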