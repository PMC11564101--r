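# shared fixtures built in code

# small, fast cohort for smoke-level checks
small_cohort <- function(seed = 1, ...) {
  simulate_cohort(cohort_config(
    n_per_arm = c(triplet = 25, doublet = 25, control = 20),
    baseline_mutation_rate = 6,
    n_filler_genes = 30,
    seed = seed,
    ...
  ))
}

# lean two-arm config with a single-component rate mixture and explicit rates,
# for rate-recovery experiments
two_arm_config <- function(seed, rate_control = 2, rate_triplet = 3.4,
                           n = 200, baseline_mutation_rate = 2) {
  cohort_config(
    n_per_arm = c(triplet = n, control = n),
    baseline_mutation_rate = baseline_mutation_rate,
    acquisition_rate_per_month = c(triplet = rate_triplet, control = rate_control),
    rate_mixture = list(weights = c(all = 1), multipliers = c(all = 1)),
    signature_mix = list(
      baseline = c(SBS1like = 0.35, SBS5like = 0.40, SBS15like = 0.25),
      acquired = list(triplet = c(SBS17blike = 1), control = c(SBS5like = 1))
    ),
    n_filler_genes = 5,
    seed = seed
  )
}

# hand-built paired variant table: one patient, explicit statuses
toy_paired_variants <- function() {
  tibble::tribble(
    ~patient_id, ~timepoint, ~gene, ~variant_class, ~chrom, ~pos, ~ref, ~alt, ~vaf, ~protein_change,
    "P1", "C1D1", "BRAF", "SNV", "ctg1", 100L, "A", "T", 0.40, "V600E",
    "P1", "EoT",  "BRAF", "SNV", "ctg1", 100L, "A", "T", 0.35, "V600E",
    "P1", "C1D1", "TP53", "SNV", "ctg1", 200L, "C", "G", 0.20, NA,
    "P1", "EoT",  "KRAS", "SNV", "ctg1", 300L, "G", "A", 0.05, NA,
    "P1", "EoT",  "MET",  "amplification", NA, NA, NA, NA, NA, NA
  )
}

# random paired call sets over a small key universe, for oracle comparisons
random_paired_calls <- function(n_keys = 10) {
  keys <- tibble::tibble(
    gene = sample(c("KRAS", "NRAS", "MET", "TP53", "APC"), n_keys, replace = TRUE),
    variant_class = sample(c("SNV", "amplification"), n_keys, replace = TRUE,
                           prob = c(0.8, 0.2)),
    pos = sample(1000L:9999L, n_keys)
  )
  keys <- keys %>%
    dplyr::mutate(
      chrom = ifelse(variant_class == "SNV", "ctg1", NA_character_),
      pos = ifelse(variant_class == "SNV", pos, NA_integer_),
      ref = ifelse(variant_class == "SNV", "C", NA_character_),
      alt = ifelse(variant_class == "SNV", "T", NA_character_)
    ) %>%
    dplyr::distinct(gene, variant_class, chrom, pos, ref, alt)
  in_c1d1 <- runif(nrow(keys)) < 0.6
  in_eot <- runif(nrow(keys)) < 0.6
  keep <- in_c1d1 | in_eot
  keys <- keys[keep, ]; in_c1d1 <- in_c1d1[keep]; in_eot <- in_eot[keep]
  mk <- function(tp, sel) {
    if (!any(sel)) return(NULL)
    keys[sel, ] %>%
      dplyr::mutate(patient_id = "P1", timepoint = tp,
                    vaf = ifelse(variant_class == "SNV",
                                 round(runif(sum(sel), 0.001, 0.5), 4), NA_real_),
                    protein_change = NA_character_)
  }
  dplyr::bind_rows(mk("C1D1", in_c1d1), mk("EoT", in_eot))
}

library(dplyr, warn.conflicts = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
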