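# ctdnadyn

Analysis of **paired longitudinal ctDNA profiles** from randomized oncology
trials: what resistance alterations appear in plasma between the first dose
(C1D1) and end of treatment (EoT), how clonal they are, how fast patients
acquire them under different regimens, what mutational processes generate
them, and how baseline transcriptomic programs relate to both acquisition and
survival benefit.

The package is written for translational biomarker analysts. Patient-level
trial data of this kind are typically access-restricted, so a first-class
synthetic-cohort generator with a fully recorded generative truth ships with
the package: every estimator can be exercised, calibrated and stress-tested
without external data, and the same code runs unchanged on real variant/
expression/metadata tables.

## What it computes

**Alteration dynamics.** Each alteration observed in either sample of a pair
gets exactly one status: *acquired* (EoT only), *maintained* (both), *lost*
(C1D1 only). SNVs/indels are identified by exact (chrom, pos, ref, alt);
amplifications and fusions at (gene, class). Gene-level summaries apply the
precedence maintained > acquired > lost. Frequencies are reported as
`count / denominator` with one-decimal, half-away-from-zero percentages.

**Clonality.** For every VAF-bearing EoT alteration,
`ratio = VAF / maxVAF` where maxVAF is the sample maximum (a circulating
tumor-fraction proxy); `ratio <= 0.3` is called subclonal. Acquired and
maintained ratios are compared with a two-sided Wilcoxon rank-sum test
(exact for combined n <= 20 without ties).

**Acquisition rates.** Per patient, `rate = acquired count / months on
treatment` (constant-rate assumption). Rate subgroups (low/medium/high) come
from a Poisson mixture fitted by EM on counts with exposure offsets,

&nbsp;&nbsp;&nbsp;&nbsp;count_i ~ sum_k w_k Poisson(lambda_k t_i),

with seeded multi-restart initialisation and ascending-rate canonical
ordering; K = 1 reduces to the closed-form MLE sum(y)/sum(t). Arms are
compared by negative-binomial regression with log-exposure offsets;
exponentiated coefficients are acquisition-rate ratios.

**Mutational signatures.** SNVs pooled by (arm, origin) — baseline = C1D1
VAF > 1%, acquired = absent at C1D1 and VAF > 0 at EoT — are tabulated over
the canonical 96 pyrimidine-centric trinucleotide channels and refit against
a reference signature matrix P by non-negative least squares,
`min ||c - P e||_2, e >= 0`, reporting exposures, pruned proportions,
relative reconstruction error and cosine similarity.

**Expression scores and enrichment.** Geometric-mean scores in
log2(TPM + 1) space (cytolytic = GZMA/PRF1, CD8 = CD8A/CD8B, a 20-gene
immune score), weighted z-score subtype calls (BM1 if score > 1.5),
single-sample GSEA, top-quartile IQR gene filtering, per-gene Cox z-score
rankings and preranked GSEA with a gene-permutation null and
Benjamini–Hochberg control.

**Survival.** Kaplan–Meier (median + 95% CI), Cox proportional hazards
(Efron ties, optional covariate adjustment) and treatment-by-biomarker
interaction Wald tests, all returning tidy tibbles.

## Worked example

```r
library(ctdnadyn)

cohort <- simulate_cohort(cohort_config(seed = 42))
cohort
#> <ctdna_cohort>
#>   318 patients (control=94, doublet=112, triplet=112)
#>   6336 variant calls; expression 402 genes x 318 samples
#>   seed 42

status <- classify_alteration_status(cohort$variants)
dplyr::count(status, status)
#>   status         n
#> 1 acquired     385
#> 2 lost         945
#> 3 maintained  2503

summarize_acquisition_frequency(
  status, c("KRAS", "MET"), denominator = nrow(cohort$patients),
  classes = c("SNV", "amplification"))
#>   gene  variant_class count denominator percent
#> 1 KRAS  SNV              50         318    15.7
#> 2 MET   amplification    30         318     9.4

compare_clonality(compute_clonality(status))
#>   n_acquired n_maintained median_acquired median_maintained     W   p_value
#> 1        306         2231           0.109             0.851  2536 4.45e-177

rates <- compute_rates(status, cohort$patients)
compare_rates_nb(rates, reference_arm = "control")
#>   arm     reference rate_ratio conf.low conf.high p_value family            theta
#> 1 doublet control         1.73    0.989      3.04 0.0546  negative_binomial 0.540
#> 2 triplet control         2.36    1.35       4.10 0.00241 negative_binomial 0.540

tidy(fit_poisson_mixture(rates, K = 3, seed = 1))
#>   component weight rate_per_month n_assigned
#> 1         1 0.799           0.117        278
#> 2         2 0.168           0.540         30
#> 3         3 0.0338          2.79          10
```

Reading the output: acquired alterations are strongly subclonal (median
EoT VAF/maxVAF 0.109 vs 0.851 for maintained alterations), the treatment
arms acquire alterations faster than control (point estimates 1.7–2.4x;
the generative ratios are 1.5 and 1.7, within the reported CIs), and the
cohort splits into low/medium/high acquisition-rate subgroups. All numbers
above are from the code as shown.

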