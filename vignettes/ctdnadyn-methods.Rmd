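---
title: "Methods: paired ctDNA dynamics, signatures and biomarker survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired ctDNA dynamics, signatures and biomarker survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. It covers the statistical procedures, the tunable
parameters and their defaults, what the synthetic-cohort generator does and
does not emulate, the numerical conventions, and known limitations.

## The setting

A randomized trial collects plasma for circulating tumor DNA (ctDNA) panel
sequencing at the first treatment dose (C1D1) and at end of treatment (EoT).
Each sample yields somatic alteration calls — SNVs, indels, gene
amplifications, gene fusions — with variant allele frequencies (VAFs, stored
as fractions throughout; percentages exist only in display code). Baseline
tumors additionally have bulk expression profiles (log2(TPM + 1)), and each
patient carries arm assignment, time on treatment, survival endpoints and
baseline covariates. The questions: which alterations emerge under treatment
pressure, how clonal are they, how fast do they accumulate per arm, which
mutational processes produce them, and which baseline genomic or
transcriptomic features predict acquisition or treatment benefit.

## Alteration dynamics

`classify_alteration_status()` assigns each distinct alteration observed at
either timepoint of a patient exactly one status:

* **acquired** — detected at EoT only;
* **maintained** — detected at both timepoints;
* **lost** — detected at C1D1 only.

Identity is exact (chrom, pos, ref, alt) for SNVs/indels and (gene, class)
for amplifications/fusions, which carry no substitution coordinates.
Detection is presence in the reported call set regardless of VAF; an
optional `min_vaf` presence threshold exists but defaults to 0 because
status is defined by detection, not magnitude. The three statuses partition
the key union — a property the test suite checks against a brute-force
set-algebra oracle on thousands of random paired sets.

Gene-level displays use the precedence **maintained > acquired > lost**
(`aggregate_gene_status()`). Frequency summaries
(`summarize_acquisition_frequency()`) take an explicit evaluable
denominator and accept (gene, class) queries, because a maintained point
mutation must not mask an acquired fusion in the same gene. Percentages are
rounded to one decimal, halves away from zero, the convention of printed
clinical tables. Two denominator conventions coexist in practice — all
paired patients, or only patients without the baseline alteration — so
`exclude_baseline` is an explicit switch rather than a hidden default.

`association_2x2()` reports the sample cross-ratio OR = ad/bc with the
Haldane–Anscombe 0.5 correction when exactly one cell is zero (flagged in
the output), and a two-sided Fisher exact p-value. The conditional-MLE odds
ratio that `fisher.test()` would report is deliberately not used as the
estimate: the cross-ratio is what count tables print.

## Clonality

`compute_clonality()` computes, for every VAF-bearing EoT alteration,
`ratio = VAF / maxVAF`, where maxVAF is the maximum VAF over all somatic
VAF-bearing alterations of the same EoT sample — including the alteration
itself (the inclusive convention; whether to exclude the focal alteration is
genuinely open, and the inclusive sample-level definition is the one we
adopt and document). Ratios are in [0, 1] by construction and exactly one
alteration per sample attains 1 unless tied. `ratio <= 0.3` is flagged
subclonal — the boundary belongs to the subclonal side. Amplifications and
fusions have no VAF, hence no ratio. A sample with no VAF-bearing calls is
*undetected* (`NA`), deliberately distinct from zero, and a zero maxVAF is
an error rather than an infinite ratio.

`compare_clonality()` uses the two-sided Wilcoxon rank-sum test: exact
enumeration when the combined n is at most 20 and tie-free, otherwise the
normal approximation with tie correction (no continuity correction, so
identical groups give p = 1 exactly).

## Acquisition rates

`compute_rates()` divides each patient's acquired-alteration count by months
on treatment; a constant acquisition rate over the treatment interval is
assumed throughout (no time-varying rates). For log-scale display, zero
rates are recoded to half the smallest nonzero rate (`display_rate`).

`fit_poisson_mixture()` models counts with exposure offsets:
count_i ~ sum_k w_k Poisson(lambda_k t_i). We fit the mixture on counts with
offsets rather than on precomputed rates: a rate of 2/0.5 months and 20/5
months carry very different information, and the offset formulation weights
them correctly. EM details:

* initialisation by a quantile split of observed rates, with log-normal
  jitter across `n_restarts` (default 20) seeded restarts; best restart by
  log-likelihood;
* the log-likelihood is asserted nondecreasing at every EM iteration
  (a violated assertion is a bug, not a warning);
* convergence when the log-likelihood changes by less than `tol = 1e-8`;
* components reported in ascending rate order, making the fit invariant to
  label permutation and patient order;
* K = 1 reduces exactly to the closed-form MLE sum(y)/sum(t);
* all-zero counts with K > 1 warn about degeneracy.

K defaults to 3 (low/medium/high subgroups); `scan_poisson_mixture()`
reports BIC over K = 1..5 since no selection rule is canonical here.

`compare_rates_nb()` compares arms by negative-binomial regression of counts
on arm indicators with log-exposure offsets (dispersion by maximum
likelihood via `MASS::glm.nb`); exponentiated coefficients are
acquisition-rate ratios versus the reference arm with Wald 95% CIs. When the
NB fit fails — typically because the data show no overdispersion and theta
diverges — the function falls back to a Poisson GLM and flags it.

## Mutational signatures

`pool_variants()` applies the pooling filters for group-wise signature
analysis: baseline pool = C1D1 VAF > 1%; acquired pool = absent (or VAF 0)
at C1D1 and VAF > 0 at EoT. An alteration with C1D1 VAF in (0, 1%] falls in
neither pool, so the pools are disjoint by construction. A VAF of 0 is
treated as assay-undetected; the data cannot distinguish true absence.

`build_spectrum()` maps SNVs to the 96 canonical pyrimidine-centric
trinucleotide channels: purine-reference substitutions are
reverse-complemented (context and alternate allele), so a substitution and
its reverse complement always land on the same channel — an involution
consistency the tests verify directly. Reference mismatches are errors
naming the position; contig-edge SNVs are skipped with a warning. Only SNVs
enter spectra; indels carry no substitution context. Protein-altering
filtering is not performed (the pipeline has no annotator); all SNVs are
used, and this is a documented deviation from consequence-filtered practice.

`refit_exposures()` solves the standard refitting problem
min ||c - P e||, e >= 0 by Lawson–Hanson NNLS against a user-supplied
(never downloaded) reference matrix, reporting raw exposures, proportions
with sub-1% attributions zeroed (parsimony; the raw solution is kept
alongside), relative L2 reconstruction error and cosine similarity. The
residual is zero whenever the spectrum lies in the reference's nonnegative
cone. De novo extraction (NMF) is out of scope.

## Expression scores

All scoring operates on genes x samples matrices of log2(TPM + 1); the +1
pseudocount is applied uniformly (including inside geometric scores, where
the literature is ambiguous — we document the choice rather than guess what
any particular study did).

* `filter_top_iqr()` keeps the top quartile of genes by IQR, ties broken by
  gene symbol for determinism.
* `zscore_genes()` uses the n-1 sample SD; zero-variance genes are set to 0
  and flagged.
* `geometric_signature_score()` is the mean of log2(TPM + 1) over signature
  genes — the log of the geometric mean of TPM + 1. Two genes at 7 TPM give
  exactly log2(8) = 3.
* `bm_subtype()` computes sum_g w_g z_g over a 44-gene weight table and
  calls BM1 strictly above 1.5 (1.5 itself is BM2). The published weight
  table belongs to a third-party publication; the package ships
  `synthetic_bm_weights()`, a synthetic stand-in with the same shape, and
  real weights are supplied as data.
* `ssgsea_score()` implements the rank-weighted ECDF-difference single-sample
  enrichment score with exponent 0.25 and average-rank ties (ordering ties
  broken by gene symbol). Because it is rank-based it is invariant to
  strictly monotone transforms of a sample's profile.
* `median_split()` sends values at or below the median to "low"; for even n
  the median is the midpoint of the central order statistics.

## Gene ranking and preranked GSEA

`rank_genes_by_model()` fits one Cox model per z-scaled gene (within an arm,
or with a gene x treatment product term across two arms) and returns signed
Wald z statistics; non-convergent genes are dropped with a message. Under a
generative null these z-scores are standard normal — a calibration the test
suite checks by Kolmogorov–Smirnov.

`preranked_gsea()` is the classic running-sum statistic: genes ordered by
decreasing statistic, hits weighted by |statistic|^p (p = 1 default,
p = 0 unweighted), misses decrement uniformly; ES is the maximum deviation.
The null permutes gene labels (`n_perm` default 10,000, seeded);
p = (1 + #{same-sign permutation ES at least as extreme}) / (1 + #same-sign),
NES = ES / mean(|same-sign permutation ES|), and Benjamini–Hochberg
adjustment is applied across genesets (`bh_adjust()`). Ranking ties break by
gene symbol so results are gene-order invariant. Multilevel p-value
refinement is out of scope; with 10,000 permutations the smallest
attainable p is about 1e-4.

## Survival

`km_fit()`, `cox_fit()` and `interaction_test()` wrap the survival package
with strict validation and tidy outputs. Tied event times use the Efron
approximation. Interaction tests include treatment, biomarker and their
product, reporting the product term's Wald test; continuous biomarkers enter
untransformed, while median-split labels are for display-oriented subgroup
fits. Non-convergence and monotone likelihoods (|coef| > 15 or non-finite
SEs) raise errors with diagnostics instead of returning unstable fits.
Proportional-hazards diagnostics are not gated on: none of the supported
analyses condition on them, and silent refusal would be worse than a
documented assumption.

## The synthetic-cohort generator

`simulate_cohort()` exists because patient-level data of this kind are
access-restricted. It generates, per patient:

* an arm (defaults 112/112/94 paired patients — triplet/doublet/control);
* a per-patient acquisition rate = arm rate x a mixture multiplier
  (defaults: arm means 0.34/0.30/0.20 per month, i.e. ratios 1.7 and 1.5
  versus control; mixture weights 0.65/0.30/0.05 with multipliers
  0.3/1.2/8 renormalised to mean 1 — a low/medium/high continuum whose
  high tail is compressed relative to the most extreme hypermutator
  phenotypes seen clinically);
* time on treatment ~ log-normal (medians 4.3/4.2/1.8 months; the
  distribution of time on treatment is not something the analysis
  prescribes, so it is a configurable input rather than a fixed law);
* a baseline ctDNA tumor fraction ~ log-normal (median 12%, heavy-tailed,
  truncated to (0.001, 1)); baseline alteration VAFs are tumor fraction x a
  mostly-clonal Beta(5, 1.2) cancer-cell fraction, so truncal variants
  cluster near the sample maxVAF; the truncal driver SNV has CCF 1 and is
  detectable at baseline with probability 0.904;
* Poisson(baseline_mutation_rate = 10) additional baseline alterations,
  maintained at EoT with probability 0.7 (0.9 for the driver); EoT VAFs
  track a drifted tumor fraction;
* Poisson(rate x months) acquired alterations present only at EoT, with
  VAF = subclonal_vaf_scale (0.15) x EoT tumor fraction x log-normal noise,
  giving a median EoT VAF/maxVAF well below 0.3 so the subclonality
  comparison has signal; acquired identities are drawn from a
  resistance-gene-weighted pool and re-drawn on key collision so the
  per-patient acquired count stays exactly Poisson;
* substitution channels drawn from configurable signature mixtures over a
  bundled synthetic reference (`synthetic_signature_reference()`): clock-like
  and mismatch-repair-like signatures at baseline everywhere,
  oxidative-damage-like T>C / T>G signatures only in treatment-arm acquired
  pools. SNVs are placed at genome positions whose trinucleotide context
  matches the drawn channel, on a small deterministic synthetic genome
  (`synthetic_reference_genome()`, 3 x 8 kb), so the channel mapper recovers
  the intended channel exactly;
* immune, cell-cycle and subtype expression programs on latent activities
  (the cell-cycle latent correlates 0.6 with the log rate multiplier,
  linking proliferation to acquisition as the analysis expects to detect);
  filler genes are pure noise;
* exponential survival under a proportional-hazards linear predictor with
  arm effects, an arm-specific immune effect (-0.30/+0.30/0.05 — a
  qualitative treatment-by-biomarker interaction), covariate effects (ECOG,
  log CRP, organ count, prior irinotecan — simple categorical/continuous
  stand-ins so adjusted-model code paths are exercised; the real covariate
  encodings are trial-specific), and exponential censoring targeting 30%.

Everything is seeded; a fixed seed gives byte-identical output and the
global RNG state is restored. The `truth` block records per-patient rates,
mixture components, latent activities, subtype labels and all configured
parameters for recovery tests.

**What it does not emulate:** read-level sequencing noise and
VAF-dependent detection sensitivity, clonal hematopoiesis artifacts, tumor
phylogenies, batch effects, dependent censoring, and correlations between
time on treatment and survival beyond those induced by shared arm effects.
Passing tests therefore demonstrate estimator correctness and calibration
under the stated generative model, not robustness to every artifact of real
panel data.

## Problem sizes and numerical conventions

The test and acceptance suites size their simulations to be decisive yet
quick: classification oracles run on 1,000 random paired sets; Wilcoxon
enumeration covers every group-shape up to combined n = 20; Fisher tables up
to total 30; NB coverage uses 100 cohorts of 200 patients/arm at generative
ratio 1.7 (single-component mixture, rates 2 and 3.4/month as the canonical
recovery experiment) and 500 null cohorts of 100/arm for type-I error;
mixture recovery uses 20 replicates of the lambda = (0.5, 20), n = 200
experiment — the low-rate component's empirical mean alone has ~14% relative
sampling error per draw, so replication is what makes a 15% accuracy band a
test of the estimator rather than of one draw; signature recovery uses
n = 5,000 multinomial spectra; survival calibration uses 100–200 replicates
at n = 200–600. The acceptance script simulates the default 318-patient
cohort once for descriptive quantities and averages the NB rate ratio over
20 replicate cohorts because a single cohort of that size estimates a rate
ratio with roughly ±40% relative CI width.

Other conventions: variant coordinates are 1-based inclusive; percentages
round half away from zero to one decimal; signature reference columns must
sum to 1 within 1e-6; mixture weights within 1e-9; EM tolerance 1e-8; NNLS
exposures below 1% of total are zeroed only in the reported proportions.

## Known limitations

* Gene-level precedence can hide co-occurring statuses in displays; the
  alteration-level table is always available and is what the rate and
  signature machinery consume.
* The NB arm comparison assumes a common dispersion across arms.
* ssGSEA scores are not rescaled across samples (no cohort-level min-max
  normalisation); comparisons should stay within one matrix.
* The preranked GSEA gene-permutation null ignores inter-gene correlation,
  as all preranked approaches do.
* Clonality ignores copy number; ratios are not cancer-cell fractions.
* The synthetic expression model is Gaussian on the log scale with
  program-plus-noise structure; it does not reproduce mean-variance
  relationships of real RNA-seq.
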