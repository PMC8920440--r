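---
title: "Methods: detecting multi-omic rejuvenation in three-group designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting multi-omic rejuvenation in three-group designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rejuvenomics)
```

# The scientific problem

Transient expression of the four reprogramming factors (OSKM) in aged mice
partially reverses molecular marks of aging. Detecting that reversal is a
three-group inference problem: a *young* group defines the target state, an
*old* group defines the aged state, and an *old-treated* (old-OSKM) group is
asked whether it moved back toward young. `rejuvenomics` implements the full
analysis chain for three kinds of readout:

* **RRBS methylomes** — per-CpG methylated/unmethylated read counts,
  aggregated to promoters and enhancers, tested for aging differential
  methylation, then classified by a nearest-mean rejuvenation rule;
* **bulk transcriptomes** — preprocessing, aging-DEG selection, gene-set
  signature scores, a competitive rotation test built on the re-standardized
  maxmean statistic, and a Normal-Normal hierarchical pattern model with
  Bayesian-FDR selection plus a sample-randomization control;
* **longitudinal measurements** — paired pre/post changes (blood methylation,
  serum metabolites), a CpG-panel aging clock, and per-metabolite mixed
  models.

Every stage is exercised end-to-end on seeded synthetic data with planted
ground truth, so sensitivity, false-positive rates and parameter recovery are
measurable quantities rather than hopes.

# Region-level differential methylation

**Regions.** Promoters span −2000 bp to +500 bp of the TSS (strand-reflected
for minus-strand genes); H3K27ac peaks that do not overlap any promoter are
enhancers, linked to the nearest TSS within 1 Mb (ties broken toward the
smaller coordinate and flagged). All internal coordinates are 0-based
half-open; the bisulfite coverage format (1-based inclusive) is converted on
read and write.

**Aggregation.** A CpG enters the analysis only when its coverage is at
least `min_reads` (default 5) in *every* sample; a region's value per sample
is the unweighted mean of its retained CpGs' percent methylation. Both the
percentage and the summed methylated/total counts are carried forward.

**Testing.** Per region, a binomial GLM with logit link regresses the
methylated proportion on the group indicator using the per-sample aggregated
counts, with a likelihood-ratio p-value. The significance rule — raw `p < 0.05`
*and* an absolute difference of at least 10 percentage points between the
group means of the region percentage — defines significance. Design choices:

* "Logistic regression" on methylation data admits per-CpG and per-region
  readings; a binomial GLM on counts aggregated over the region's retained
  CpGs is the one consistent with region-level significance and a
  region-level 10-point rule; a quasi-binomial variant (F-test) is available
  via `quasi = TRUE` for overdispersed data.
* No multiple-testing correction enters the significance call (the
  threshold is deliberately a raw p, as is conventional for this screen); a BH-adjusted column is emitted for information.
* Degenerate regions (all 0% or all 100% in both groups) get `p = 1` and a
  flag rather than a numerical failure.

# The rejuvenation rule and temporal classes

A significant aging region (or any feature with young/old/treated means on a
common scale) is **rejuvenated** when the treated mean is strictly closer to
the young mean than to the old mean: `|oskm − young| < |oskm − old|`. Exact
ties fail the rule and are flagged; features with no aging gap
(`young == old`) are flagged and never rejuvenated. The rule is purely
metric, so overshoot past the young mean still counts (flagged `overshoot`
for inspection). Applying the predicate at the end of induction (d7) and
after recovery (d21) yields four temporal classes
(`established_d7_retained`, `established_d7_lost`, `acquired_in_recovery`,
`never`), which partition the features by construction.

# Expression preprocessing and signatures

Raw RPKM-like values are `log2(x + 1)`-transformed (pseudocount 1, the
convention that keeps zeros at zero), quantile-normalized to the
mean empirical distribution (ties share averaged values;
`limma::normalizeQuantiles`), and corrected for library size: a gene-wise
linear model `value ~ group + total_reads` is fitted and the centered
`total_reads` component subtracted. Including the group in the model is what
protects the biology — only covariate-aligned variation is removed. The same
mechanism is reused for the global-signature correction of gene-set scores,
giving one implementation for both corrections.

Aging DEGs satisfy a linear-scale fold change above 1.5 (two-sided, i.e.
`|log2 FC| > log2 1.5`) *and* raw `p < 0.01`. The thresholds do not fix the
test; the default is the empirical-Bayes moderated t described below, with a
plain Welch t via `method = "welch"`.

Gene-set signature scores z-score each gene across samples, average the z
over the member genes per sample, and adjust the resulting set scores for
the *global signature* (the same average over all genes) with the
group-preserving covariate removal above. This adjusts each set for the
association expected of a randomly chosen signature of the same data.

# Competitive rotation testing with the re-standardized maxmean

**Gene scores.** A gene-wise linear model is whitened by QR so that the
requested contrast occupies one coordinate of a `(residual df + 1)`
dimensional space. Residual variances are shrunk toward a common prior
fitted by moment matching of `log s²` (the scaled-F construction; prior
df `d0` solved from a trigamma equation), and the moderated t with
`d + d0` degrees of freedom is mapped to a z-score by matching tail
probabilities.

**Maxmean.** For member z-scores, `s⁺` is the set mean of `max(z, 0)` and
`s⁻` that of `max(−z, 0)`; the statistic is `S = s⁺` (up) when `s⁺ ≥ s⁻`,
else `S = −s⁻` (down). Ties resolve to "up".

**Restandardization** converts this self-contained statistic into a
competitive one. Following the Efron–Tibshirani construction, the moments
are those of the one-sided set mean matching the observed direction over
random same-size gene sets drawn from the catalogue:
`S* = (|S| − mu_rand) / sigma_rand`, sign-mirrored for down sets. For a
standard-normal catalogue `mu_rand` equals the positive-part mean
`1/sqrt(2*pi) ≈ 0.3989` regardless of set size. Moments come from `R`
seeded Monte-Carlo draws (default 2000) or, for small catalogues, from
exhaustive enumeration of all subsets (`mode = "exact"`, which uses the
population SD since the enumeration *is* the population). A degenerate
catalogue (zero moment SD) is an error, not a silent zero.

**Rotations.** Each of `B` iterations replaces the contrast direction with a
random unit vector on the `(d + 1)`-sphere, shared across genes — the
sharing preserves inter-gene correlation, which is what makes rotation
inference valid for correlated expression data at small n. Gene scores and
per-set `S*` are recomputed per rotation, with the variance-prior
hyperparameters `(d0, s0²)` held at their observed-fit values and the random
restandardization sets reused across rotations (a documented budget cap).
P-values use the permutation convention
`p = (1 + #{|S*_rot| ≥ |S*_obs|}) / (B + 1)`, so they are bounded below by
`1/(B + 1)`; directional p-values are emitted alongside. Restandardizing
*inside* the rotation loop is the default (`per_rotation = TRUE`); reusing
the observed moments is available as a switch. Setting
`restandardize = FALSE` exposes the self-contained statistic — useful only
to demonstrate why the competitive version exists: under a shift applied to
*all* genes the competitive test stays calibrated while the self-contained
one rejects wholesale.

# The Normal-Normal pattern model

Each feature (adjusted set score, or gene-level values via the same
interface) follows one of the set partitions ("patterns") of the groups —
five for three groups, enumerated with the rejuvenation pattern
(`young,old_OSKM | old`) first. Within a pattern, every cluster of groups
shares a latent mean `mu ~ N(mu0, tau2)` and observations are
`N(mu, sigma_g²)`. The cluster marginal likelihood is closed-form
(a Normal density in the cluster mean at variance `sigma_g²/n + tau2`, times
the within-cluster residual terms), verified against adaptive quadrature in
the tests. `sigma_g²` is plugged in as the pooled within-group variance
shrunk 30% toward the cross-feature median, which prevents zero-variance
blow-ups at 4–5 samples per group.

`(mu0, tau2)` are fitted by EM with deterministic starting values (grand
mean; between-group variance of feature means) and a Nelder-Mead M-step on
the only terms that depend on them. Convergence requires both a relative
log-likelihood change below `tol` and stability of the pattern weights,
because the likelihood is nearly flat along the weight direction.

**Pattern weights.** The textbook M-step (weights = posterior means) is
unstable in this pattern space: the all-distinct pattern *nests* every other
pattern, so soft updates let it absorb the whole prior mass, which destroys
pattern recovery — we verified that the collapsed state can even carry the
higher likelihood, so this is a property of the soft update, not a local
optimum artifact. The default is therefore a classification EM: weights are
updated from modal (hard) assignments, with two safeguards. Features whose
log marginal likelihoods are numerically constant across patterns (no
pattern evidence — e.g. every feature when `tau2 → 0` under permuted
labels) are counted toward the most parsimonious pattern instead of the
currently largest weight, and the fit runs a second deterministic start from
the evidence-only modal proportions, keeping the higher-likelihood optimum.
`pi_method = "em"` and `"uniform"` remain available; `tau2 = 0` with fixed
weights reproduces the analytic limit where posteriors equal the prior.

**Selection** uses the Bayesian expected-FDR rule: features sorted by
decreasing posterior probability of the target pattern, keeping the largest
prefix whose mean posterior probability of *not* following the pattern is at
most the nominal FDR (default 5%). The rule is monotone in the FDR level.
Note its sharp evidence threshold: a feature can only enter a 5% selection
with posterior near 0.95, and the attainable posterior is capped by the
merge-versus-split Occam factor (roughly `sqrt(1 + n·tau2/sigma²)`) times
the weight odds — at five samples per group this cap is modest, so selection
counts respond abruptly to the signal-to-noise regime. The
**randomization control** re-runs fit + selection after permuting the
sample-to-group assignment (group sizes preserved); with planted structure
the permuted counts collapse toward zero while the observed count stands,
mirroring the contrast between real and randomized group labels.

# Longitudinal analyses

* `delta_change` pairs pre/post rows per subject (incomplete subjects are
  listed and excluded) and returns post − pre.
* `compare_groups(method = "mann_whitney")` compares deltas between two
  groups. For combined n ≤ 18 the p-value is exact by full enumeration of
  the rank-sum permutation distribution with mid-ranks for ties, two-sided
  by doubling the smaller tail (identical to the exact Wilcoxon p when there
  are no ties; R's built-in test cannot be exact under ties). The canonical
  noiseless scenario — four subjects drifting +4 units, three reverting −4 —
  gives the extreme configuration with exact `p = 2/35 ≈ 0.0571`.
* `compare_groups(method = "auto_paired_t")` tests mean delta = 0, gated on
  a Shapiro–Wilk normality check at 0.05 with a flagged signed-rank
  fallback. All-tied deltas give `p = 1` with a degenerate flag.
* `clock_fit` averages a CpG panel per animal, then fits OLS of percent
  methylation on age (weeks) and reports slope, intercept and Pearson r.
  Zero-slope, zero-noise data flag the correlation as undefined rather than
  producing 0/0.
* `metabolite_mixed_model` fits, per metabolite,
  `value ~ timepoint (+ batch) + (1 | specimen)` by REML (log scale by
  default) and reports the Wald test of the timepoint effect with
  Satterthwaite degrees of freedom. Singular random-effect fits fall back to
  a fixed-effects model that keeps the specimen as a fixed effect whenever
  repeated measures exist — in the zero-between-subject-variance limit this
  is exactly the paired t. Two-batch designs enter as a fixed batch effect.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated; their defaults are fixed, not tuning knobs.

**Methylome** (`simulate_methylome`): three groups of 5 samples (optionally
a fourth end-of-induction group), ~5 CpGs per region, negative-binomial
coverage with mean 30 and dispersion 5, baseline methylation Beta(2, 2),
30% of regions aging-affected with 20–40 percentage-point effects (55%
hypermethylated), 40% of aging regions reverted with strength 0.8–1, and an
error floor of 0.02 modelling bisulfite non-conversion. Baselines are
rejection-sampled (deterministically under the seed) so the planted effect
always fits inside the floor — configurations where no baseline can host the
effect raise a "degenerate effect" error. Per-CpG jitter is drawn once per
CpG and shared across samples, so region aggregation is meaningful. All
randomness derives from per-region sub-streams of one seed: enlarging
`n_regions` never perturbs earlier regions.

**Expression** (`simulate_expression`): disjoint gene sets assigned to the
five patterns, member genes sharing the pattern's group shift plus a
rho-weighted within-set latent factor (default rho = 0.2) that makes the
competitive null non-trivial; gene baselines `N(5, 1.5²)` in log2 units,
residual SD 0.5, and multiplicative library-size factors on the raw scale so
preprocessing has something to remove. Shift signs alternate across the sets
of a pattern by default (`balance_directions`): real aging signatures mix
up- and down-regulated programs, and a strongly one-sided signal in a large
fraction of genes would additionally distort quantile normalization.

**Longitudinal** (`simulate_longitudinal`): two rows per subject with a
subject random intercept; given the subject, post − pre is
`N(group delta, 2·within_sd²)`. `within_sd = 0` plants deltas exactly —
the default scenario (+4 control drift, −4 treated reversal, total
between-group difference 8 units) is the canonical paired-methylation
design.

What the generators do *not* emulate: read-level artifacts (FASTQ, alignment,
UMI structure), spatially correlated methylation beyond the region unit,
isoform-level expression, heavy-tailed or batch-confounded expression noise,
and metabolite-panel correlation structure. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
generative assumptions, not robustness to every artifact of real data.

# Validation scale and numerical choices

The test suite validates, among others: region aggregation against
brute-force re-aggregation; the rejuvenation classifier against brute force
on 10⁵ random triples; differential-methylation sensitivity ≥ 0.9 and
false-positive rate ≤ 0.07 on 2000 planted regions with rejuvenated-fraction
recovery within ±0.07; rotation-test calibration on 100 disjoint null sets
(B = 999) with power checks on a 1.5-z planted set across 100 replicates;
Monte-Carlo restandardization against exhaustive enumeration of a size-8
catalogue; the closed-form cluster marginal against quadrature to relative
error < 1e-8; ≥ 90% modal-pattern recovery on 1000 gene-level features at
effect 3× the observation SD with realized Bayesian FDR ≤ 7.5%; and the
randomization control on 300 score-level sets (150 planted rejuvenated at
2.5 log2 units — chosen inside the regime where the selection rule has
power, see the Occam-cap note above). Problem sizes keep the full suite
within a few minutes on one CPU.

Numerical conventions worth knowing: methylation proportions are clipped to
`[floor, 1 − floor]`; the t→z map uses log-scale tail probabilities for
stability; `p = (1 + k)/(B + 1)` never returns zero; nearest-gene ties and
classification ties are deterministic and flagged; EM starting values are
fixed for reproducibility; the two EM starts are both deterministic.

# Known limitations

* The pattern model's selection count is regime-sensitive (the Occam cap):
  with five samples per group and weak coordination, the 5%-FDR selection
  can be empty even when modal-pattern recovery is high. The modal counts
  are the more stable summary at this scale.
* The Normal-Normal fit here is self-contained and is not expected to
  reproduce number-for-number the output of other hierarchical-mixture
  implementations; validation is by recovery on planted data.
* The binomial differential-methylation GLM assumes no overdispersion beyond
  the region aggregate; the quasi-binomial switch exists for data where that
  fails.
* Enhancer-gene linking by nearest TSS within 1 Mb is a heuristic — the
  standard proximity convention, not a claim about regulatory contact.
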