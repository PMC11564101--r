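# Synthetic-cohort generator. Emulates the statistical structure a paired
# baseline / end-of-treatment ctDNA biomarker study assumes: arm-specific
# mutation-acquisition rates with a low/medium/high rate mixture, heavy-tailed
# baseline VAFs, subclonal end-of-treatment VAFs, signature-shaped
# substitution spectra, immune / cell-cycle expression programs, and
# covariate-linked proportional-hazards survival. Every generative parameter
# is recorded in a truth block so downstream estimators can be tested for
# recovery.

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by [simulate_cohort()].
#' Defaults encode the study conditions the package is designed around:
#' paired-arm sizes 112 / 112 / 94, arm acquisition-rate ratios of 1.7
#' (triplet) and 1.5 (doublet) versus control, a three-component
#' low/medium/high rate mixture, end-of-treatment VAFs that are subclonal
#' relative to the sample maxVAF, oxidative-damage-like substitution
#' signatures appearing only in treatment-arm acquired variants, and an
#' immune program whose survival effect differs by arm (a qualitative
#' treatment-by-biomarker interaction).
#'
#' @param n_per_arm named integer vector of paired patients per arm.
#' @param baseline_mutation_rate expected truncal (baseline) alterations per
#'   patient (Poisson mean).
#' @param acquisition_rate_per_month named positive vector: expected acquired
#'   alterations per month per arm (mean over the rate mixture). Zero is
#'   allowed and yields no acquired alterations.
#' @param rate_mixture list with `weights` and `multipliers` (same length);
#'   per-patient rate = arm rate x multiplier drawn from this mixture.
#'   Multipliers are renormalised so the weighted mean is 1 (arm means are
#'   preserved). Use a single component to disable rate heterogeneity.
#' @param subclonal_vaf_scale mean of acquired EoT VAF as a fraction of the
#'   sample maxVAF, in (0, 1].
#' @param maintain_prob probability a baseline alteration is still detected
#'   at EoT (the complement is "lost").
#' @param baseline_vaf_meanlog,baseline_vaf_sdlog log-normal parameters of
#'   the per-patient baseline ctDNA tumor fraction (the sample maxVAF scale),
#'   truncated to (1e-3, 1); individual baseline VAFs are this fraction times
#'   a mostly-clonal per-variant cancer-cell fraction (Beta(5, 1.2)).
#' @param signature_mix list with `baseline` (named weights over reference
#'   signatures, all arms) and `acquired` (named list per arm).
#' @param reference signature reference matrix (default
#'   [synthetic_signature_reference()]).
#' @param genome named character vector of contig sequences (default
#'   [synthetic_reference_genome()]).
#' @param n_filler_genes expression genes beyond the program genes.
#' @param expression_effects named list of program effect sizes (log2 units
#'   per latent SD): `immune`, `cell_cycle`, `bm`.
#' @param cell_cycle_rate_cor correlation between the cell-cycle latent and
#'   the (standardised log) acquisition-rate multiplier.
#' @param tot_meanlog,tot_sdlog log-normal time-on-treatment parameters
#'   (named per-arm meanlog).
#' @param survival_params list: `baseline_hazard` (events/month),
#'   `log_hr_arm`, `log_hr_immune_by_arm` (arm-specific effect of the immune
#'   latent; unequal values encode an interaction), `log_hr_covariates`
#'   (named: ecog, log_crp, organs_3plus, prior_irinotecan), `pfs_hazard_ratio`.
#' @param censoring_rate target fraction censored, in \[0, 1).
#' @param braf_detect_prob probability the truncal driver SNV is detectable
#'   at baseline.
#' @param seed integer seed; a fixed seed makes [simulate_cohort()] output
#'   byte-identical across runs.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_per_arm = c(triplet = 112, doublet = 112, control = 94),
    baseline_mutation_rate = 10,
    acquisition_rate_per_month = c(triplet = 0.34, doublet = 0.30, control = 0.20),
    rate_mixture = list(weights = c(low = 0.65, medium = 0.30, high = 0.05),
                        multipliers = c(low = 0.3, medium = 1.2, high = 8)),
    subclonal_vaf_scale = 0.15,
    maintain_prob = 0.70,
    baseline_vaf_meanlog = log(0.12),
    baseline_vaf_sdlog = 1.3,
    signature_mix = list(
      baseline = c(SBS1like = 0.35, SBS5like = 0.40, SBS15like = 0.25),
      acquired = list(
        triplet = c(SBS1like = 0.15, SBS5like = 0.25, SBS15like = 0.10,
                    SBS17blike = 0.50),
        doublet = c(SBS1like = 0.15, SBS5like = 0.25, SBS15like = 0.10,
                    SBS17alike = 0.20, SBS17blike = 0.30),
        control = c(SBS1like = 0.35, SBS5like = 0.40, SBS15like = 0.25)
      )
    ),
    reference = synthetic_signature_reference(),
    genome = synthetic_reference_genome(),
    n_filler_genes = 320,
    expression_effects = list(immune = 1.2, cell_cycle = 1.2, bm = 1.0),
    cell_cycle_rate_cor = 0.6,
    tot_meanlog = c(triplet = log(4.3), doublet = log(4.2), control = log(1.8)),
    tot_sdlog = 0.5,
    survival_params = list(
      baseline_hazard = 0.12,
      log_hr_arm = c(triplet = -0.45, doublet = -0.40, control = 0),
      log_hr_immune_by_arm = c(triplet = -0.30, doublet = 0.30, control = 0.05),
      log_hr_covariates = c(ecog = 0.5, log_crp = 0.2, organs_3plus = 0.3,
                            prior_irinotecan = 0.1),
      pfs_hazard_ratio = 2
    ),
    censoring_rate = 0.30,
    braf_detect_prob = 0.904,
    seed = 1L) {

  cfg <- list(
    n_per_arm = n_per_arm,
    baseline_mutation_rate = baseline_mutation_rate,
    acquisition_rate_per_month = acquisition_rate_per_month,
    rate_mixture = rate_mixture,
    subclonal_vaf_scale = subclonal_vaf_scale,
    maintain_prob = maintain_prob,
    baseline_vaf_meanlog = baseline_vaf_meanlog,
    baseline_vaf_sdlog = baseline_vaf_sdlog,
    signature_mix = signature_mix,
    reference = reference,
    genome = genome,
    n_filler_genes = n_filler_genes,
    expression_effects = expression_effects,
    cell_cycle_rate_cor = cell_cycle_rate_cor,
    tot_meanlog = tot_meanlog,
    tot_sdlog = tot_sdlog,
    survival_params = survival_params,
    censoring_rate = censoring_rate,
    braf_detect_prob = braf_detect_prob,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  bad_arm <- setdiff(names(cfg$n_per_arm), arm_levels)
  if (length(bad_arm) > 0) {
    abort(sprintf("unknown arm label(s): %s", paste(bad_arm, collapse = ", ")))
  }
  if (length(cfg$n_per_arm) == 0 || any(cfg$n_per_arm < 1)) {
    abort("n_per_arm must be positive counts")
  }
  if (cfg$baseline_mutation_rate < 0) abort("baseline_mutation_rate must be >= 0")
  rates <- cfg$acquisition_rate_per_month
  if (is.null(names(rates)) || !all(names(cfg$n_per_arm) %in% names(rates))) {
    abort("acquisition_rate_per_month must be named for every arm in n_per_arm")
  }
  if (any(rates < 0)) abort("acquisition rates must be >= 0")
  w <- cfg$rate_mixture$weights
  if (abs(sum(w) - 1) > 1e-9) abort("rate_mixture weights must sum to 1 (within 1e-9)")
  if (any(w < 0) || any(cfg$rate_mixture$multipliers <= 0)) {
    abort("rate_mixture weights must be >= 0 and multipliers > 0")
  }
  if (cfg$subclonal_vaf_scale <= 0 || cfg$subclonal_vaf_scale > 1) {
    abort("subclonal_vaf_scale must be in (0, 1]")
  }
  if (cfg$maintain_prob < 0 || cfg$maintain_prob > 1) abort("maintain_prob must be in [0, 1]")
  sigs <- colnames(cfg$reference)
  check_mix <- function(mix, label) {
    if (abs(sum(mix) - 1) > 1e-9) abort(sprintf("signature mix '%s' must sum to 1", label))
    if (!all(names(mix) %in% sigs)) {
      abort(sprintf("signature mix '%s' names unknown signature(s)", label))
    }
  }
  check_mix(cfg$signature_mix$baseline, "baseline")
  for (arm in names(cfg$n_per_arm)) {
    if (is.null(cfg$signature_mix$acquired[[arm]])) {
      abort(sprintf("signature_mix$acquired missing arm '%s'", arm))
    }
    check_mix(cfg$signature_mix$acquired[[arm]], paste0("acquired/", arm))
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    abort("censoring_rate must be in [0, 1)")
  }
  invisible(cfg)
}

# truncated log-normal via inverse-CDF (proper truncation, vectorised)
rtrunc_lnorm <- function(n, meanlog, sdlog, lo = 1e-4, hi = 1) {
  u <- runif(n, stats::plnorm(lo, meanlog, sdlog), stats::plnorm(hi, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

# acquired-alteration gene/class pool (resistance-gene-weighted); weights are
# relative and need not sum to 1
acquired_gene_pool <- function() {
  tibble(
    gene = c("KRAS", "NRAS", "MAP2K1", "MET", "KRAS", "BRAF", "IGF1R",
             "MET", "BRAF", "ALK", "EGFR", "PIK3CA", "SMAD4", "FAT1"),
    variant_class = c("SNV", "SNV", "SNV", "amplification", "amplification",
                      "amplification", "amplification", "fusion", "fusion",
                      "fusion", "SNV", "SNV", "SNV", "SNV"),
    weight = c(0.28, 0.18, 0.07, 0.13, 0.05, 0.03, 0.02,
               0.03, 0.02, 0.01, 0.04, 0.05, 0.04, 0.05)
  )
}

baseline_gene_pool <- function() {
  c("TP53", "APC", "SMAD4", "FAT1", "RNF43", "LRP1B", "PIK3CA", "KRAS",
    "ARID1A", "SOX9", "TCF7L2", "FBXW7", "ATM", "KMT2D", "AMER1", "PTEN",
    "BCL9", "GNAS", "ZFHX3", "CTNNB1")
}

# draw SNV placements with prescribed channel mixture: sample channels, then
# genome positions whose canonical context matches; emit strand-correct
# ref/alt so the channel mapper recovers the intended channel exactly
place_snvs <- function(n, channel_probs, ctx_index) {
  channels <- sbs_channels()
  if (n == 0) {
    return(tibble(chrom = character(), pos = integer(),
                  ref = character(), alt = character()))
  }
  ch <- sample(channels, n, replace = TRUE, prob = channel_probs)
  ctx <- paste0(substr(ch, 1, 1), substr(ch, 3, 3), substr(ch, 7, 7))
  alt_pyr <- substr(ch, 5, 5)
  split_idx <- split(seq_len(n), ctx)
  res <- purrr::map_dfr(names(split_idx), function(cx) {
    rows <- split_idx[[cx]]
    pool <- ctx_index[[cx]]
    pick <- pool[sample.int(nrow(pool), length(rows), replace = TRUE), ]
    centre <- substr(cx, 2, 2)
    ref <- ifelse(pick$purine, chartr("CT", "GA", centre), centre)
    alt <- ifelse(pick$purine, chartr("ACGT", "TGCA", alt_pyr[rows]), alt_pyr[rows])
    tibble(row = rows, chrom = pick$chrom, pos = as.integer(pick$pos),
           ref = ref, alt = alt)
  })
  res %>% arrange(.data$row) %>% select(-"row")
}

#' Simulate a paired-ctDNA biomarker cohort
#'
#' Generates patients, paired C1D1/EoT variant calls, a baseline expression
#' matrix and survival outcomes under the generative model described in
#' [cohort_config()], together with a `truth` block recording every
#' generative quantity (per-patient rates and mixture components, latent
#' program activities, subtype labels, signature mixtures) for recovery
#' testing. With a fixed seed the output is byte-identical across runs; the
#' global RNG state is left untouched.
#'
#' @param config a [cohort_config()].
#' @return an object of class `ctdna_cohort`: a list with tibbles `patients`
#'   and `variants`, matrix `expression` (genes x samples, log2(TPM+1)
#'   scale), list `truth`, and the `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  arms <- names(cfg$n_per_arm)
  n <- sum(cfg$n_per_arm)
  arm <- rep(arms, cfg$n_per_arm)
  patient_id <- sprintf("PT%04d", seq_len(n))
  ctx_index <- context_index(cfg$genome)

  # --- per-patient acquisition rates from the mixture -----------------------
  mw <- cfg$rate_mixture$weights
  mult <- cfg$rate_mixture$multipliers
  mult <- mult / sum(mw * mult)  # weighted mean 1 so arm means are preserved
  comp <- sample(seq_along(mw), n, replace = TRUE, prob = mw)
  rate <- cfg$acquisition_rate_per_month[arm] * mult[comp]

  tot <- rlnorm(n, cfg$tot_meanlog[arm], cfg$tot_sdlog)

  # --- latent expression programs -------------------------------------------
  immune <- rnorm(n)
  rho <- cfg$cell_cycle_rate_cor
  mult_std <- if (length(unique(mult)) > 1) {
    as.numeric(scale(log(mult)))[comp]
  } else rep(0, n)
  cell_cycle <- rho * mult_std + sqrt(max(0, 1 - rho^2)) * rnorm(n)
  bm1 <- rbinom(n, 1, 1 / 3)

  # --- covariates ------------------------------------------------------------
  ecog <- rbinom(n, 1, 0.5)
  crp <- rlnorm(n, log(8), 0.9)
  organs_3plus <- rbinom(n, 1, 0.45)
  prior_irinotecan <- rbinom(n, 1, 0.5)

  # --- survival under proportional hazards -----------------------------------
  sp <- cfg$survival_params
  lhc <- sp$log_hr_covariates
  lp <- sp$log_hr_arm[arm] + sp$log_hr_immune_by_arm[arm] * immune +
    lhc[["ecog"]] * ecog + lhc[["log_crp"]] * scale(log(crp))[, 1] +
    lhc[["organs_3plus"]] * organs_3plus + lhc[["prior_irinotecan"]] * prior_irinotecan
  h_os <- sp$baseline_hazard * exp(lp)
  t_os <- rexp(n, h_os)
  cr <- cfg$censoring_rate
  if (cr > 0) {
    t_cens <- rexp(n, sp$baseline_hazard * cr / (1 - cr))
  } else {
    t_cens <- rep(Inf, n)
  }
  os_months <- pmin(t_os, t_cens)
  os_event <- as.integer(t_os <= t_cens)
  h_pfs <- h_os * sp$pfs_hazard_ratio
  t_pfs <- rexp(n, h_pfs)
  pfs_months <- pmin(t_pfs, t_cens)
  pfs_event <- as.integer(t_pfs <= t_cens)

  patients <- tibble(
    patient_id = patient_id, arm = arm,
    time_on_treatment_months = tot,
    os_months = os_months, os_event = os_event,
    pfs_months = pfs_months, pfs_event = pfs_event,
    ecog = ecog, crp = crp, organs_3plus = organs_3plus,
    prior_irinotecan = prior_irinotecan
  )

  # --- baseline (truncal) variants -------------------------------------------
  braf_present <- rbinom(n, 1, cfg$braf_detect_prob) == 1
  n_other <- rpois(n, cfg$baseline_mutation_rate)
  base_rows <- tibble(
    patient_id = rep(patient_id, n_other),
    gene = sample(baseline_gene_pool(), sum(n_other), replace = TRUE),
    variant_class = sample(variant_class_levels, sum(n_other), replace = TRUE,
                           prob = c(0.80, 0.08, 0.08, 0.04))
  )
  braf_rows <- tibble(
    patient_id = patient_id[braf_present],
    gene = "BRAF", variant_class = "SNV"
  )
  base_rows <- bind_rows(braf_rows, base_rows)
  base_rows$is_braf_v600e <- base_rows$gene == "BRAF" & base_rows$variant_class == "SNV" &
    seq_len(nrow(base_rows)) <= nrow(braf_rows)

  base_probs <- as.numeric(cfg$reference %*%
                             mix_to_vector(cfg$signature_mix$baseline, colnames(cfg$reference)))
  base_rows <- attach_coordinates(base_rows, base_probs, ctx_index, cfg$genome)

  # shared per-patient ctDNA tumor fraction (heavy-tailed) times a per-variant
  # cancer-cell fraction that is mostly clonal: truncal baseline variants
  # therefore cluster near the sample maxVAF, while acquired variants below
  # sit at a subclonal fraction of it
  tf_c1d1 <- stats::setNames(
    rtrunc_lnorm(n, cfg$baseline_vaf_meanlog, cfg$baseline_vaf_sdlog,
                 lo = 1e-3, hi = 1),
    patient_id)
  tf_eot <- pmin(1, pmax(1e-3, tf_c1d1 * exp(rnorm(n, 0, 0.5))))
  names(tf_eot) <- patient_id

  has_vaf <- base_rows$variant_class %in% c("SNV", "indel")
  ccf <- stats::rbeta(nrow(base_rows), 5, 1.2)
  drv <- base_rows$is_braf_v600e
  ccf[drv] <- 1  # truncal driver defines the tumor fraction
  base_rows$vaf <- ifelse(has_vaf,
                          pmax(1e-4, tf_c1d1[base_rows$patient_id] * ccf),
                          NA_real_)
  base_rows$protein_change <- ifelse(drv, "V600E", NA_character_)

  maintain_p <- ifelse(base_rows$is_braf_v600e, 0.9, cfg$maintain_prob)
  maintained <- rbinom(nrow(base_rows), 1, maintain_p) == 1
  eot_maint <- base_rows[maintained, ]
  ccf_eot <- ccf[maintained] * exp(rnorm(nrow(eot_maint), 0, 0.2))
  eot_maint$vaf <- ifelse(
    is.na(eot_maint$vaf), NA_real_,
    pmin(1, pmax(1e-4, tf_eot[eot_maint$patient_id] * pmin(ccf_eot, 1)))
  )

  # --- acquired variants (Poisson counts, EoT only) --------------------------
  n_acq <- rpois(n, rate * tot)
  pool <- acquired_gene_pool()
  acq_idx <- sample.int(nrow(pool), sum(n_acq), replace = TRUE, prob = pool$weight)
  acq_rows <- tibble(
    patient_id = rep(patient_id, n_acq),
    gene = pool$gene[acq_idx],
    variant_class = pool$variant_class[acq_idx],
    is_braf_v600e = FALSE
  )
  # arm-specific acquired substitution spectra
  acq_rows$arm <- rep(arm, n_acq)
  acq_probs <- lapply(arms, function(a) {
    as.numeric(cfg$reference %*%
                 mix_to_vector(cfg$signature_mix$acquired[[a]],
                               colnames(cfg$reference)))
  })
  names(acq_probs) <- arms
  acq_list <- lapply(arms, function(a) {
    attach_coordinates(acq_rows %>% filter(.data$arm == a), acq_probs[[a]],
                       ctx_index, cfg$genome)
  })
  acq_rows <- bind_rows(acq_list)

  # each acquired event must carry a distinct alteration identity, distinct
  # also from the patient's baseline alterations; otherwise gene-level
  # amplification/fusion keys collide at high rates and the classified
  # acquired count would fall below its generative Poisson count. Colliding
  # draws are re-drawn (eventually as SNVs, whose coordinate key space is
  # effectively collision-free).
  if (nrow(acq_rows) > 0) {
    base_keys <- paste(base_rows$patient_id, alteration_key(base_rows))
    snv_pool <- which(pool$variant_class == "SNV")
    for (it in seq_len(30)) {
      akey <- paste(acq_rows$patient_id, alteration_key(acq_rows))
      dup <- duplicated(akey) | akey %in% base_keys
      if (!any(dup)) break
      ids <- if (it > 15) snv_pool else seq_len(nrow(pool))
      redraw <- sample(ids, sum(dup), replace = TRUE, prob = pool$weight[ids])
      acq_rows$gene[dup] <- pool$gene[redraw]
      acq_rows$variant_class[dup] <- pool$variant_class[redraw]
      for (a in arms) {
        sel <- which(dup & acq_rows$arm == a)
        if (length(sel) == 0) next
        placed <- attach_coordinates(acq_rows[sel, ], acq_probs[[a]],
                                     ctx_index, cfg$genome)
        acq_rows[sel, c("chrom", "pos", "ref", "alt")] <-
          placed[c("chrom", "pos", "ref", "alt")]
      }
    }
  }
  acq_rows <- acq_rows %>% select(-"arm")

  # subclonal VAFs: on average subclonal_vaf_scale of the EoT tumor fraction
  scale_noise <- exp(rnorm(nrow(acq_rows), 0, 0.8) - 0.8^2 / 2)
  acq_rows$vaf <- ifelse(
    acq_rows$variant_class %in% c("SNV", "indel"),
    pmin(1, pmax(1e-4,
                 cfg$subclonal_vaf_scale * tf_eot[acq_rows$patient_id] * scale_noise)),
    NA_real_
  )
  acq_rows$protein_change <- NA_character_

  c1d1 <- base_rows %>% mutate(timepoint = "C1D1")
  eot <- bind_rows(eot_maint, acq_rows) %>% mutate(timepoint = "EoT")
  variants <- bind_rows(c1d1, eot) %>% select(-"is_braf_v600e")
  variants$key <- alteration_key(variants)
  variants <- variants %>%
    arrange(.data$patient_id, .data$timepoint, dplyr::desc(.data$vaf)) %>%
    distinct(.data$patient_id, .data$timepoint, .data$key, .keep_all = TRUE) %>%
    select(-"key") %>%
    select(all_of(variant_cols)) %>%
    arrange(.data$patient_id, .data$timepoint, .data$gene, .data$pos)

  expression <- simulate_expression(cfg, patient_id, immune, cell_cycle, bm1)

  truth <- list(
    patients = tibble(patient_id = patient_id, arm = arm,
                      rate_per_month = unname(rate), rate_component = comp,
                      immune_latent = immune, cell_cycle_latent = cell_cycle,
                      bm1 = bm1, linear_predictor = as.numeric(lp)),
    arm_rates = cfg$acquisition_rate_per_month,
    rate_multipliers = mult,
    rate_weights = mw,
    signature_mix = cfg$signature_mix,
    survival_params = cfg$survival_params
  )

  structure(
    list(patients = patients, variants = validate_variant_table(variants),
         expression = expression, truth = truth, config = cfg),
    class = "ctdna_cohort"
  )
}

mix_to_vector <- function(mix, sig_names) {
  v <- stats::setNames(rep(0, length(sig_names)), sig_names)
  v[names(mix)] <- mix
  v
}

# assign coordinates: SNVs via channel-directed placement, indels/amps/fusions
# via simple draws (indels at random interior positions; amplifications and
# fusions are gene-level events without coordinates)
attach_coordinates <- function(rows, channel_probs, ctx_index, genome) {
  if (nrow(rows) == 0) {
    rows$chrom <- character(0); rows$pos <- integer(0)
    rows$ref <- character(0); rows$alt <- character(0)
    return(rows)
  }
  rows$chrom <- NA_character_; rows$pos <- NA_integer_
  rows$ref <- NA_character_; rows$alt <- NA_character_
  snv <- which(rows$variant_class == "SNV")
  if (length(snv) > 0) {
    placed <- place_snvs(length(snv), channel_probs, ctx_index)
    rows$chrom[snv] <- placed$chrom
    rows$pos[snv] <- placed$pos
    rows$ref[snv] <- placed$ref
    rows$alt[snv] <- placed$alt
  }
  ind <- which(rows$variant_class == "indel")
  if (length(ind) > 0) {
    ctg <- sample(names(genome), length(ind), replace = TRUE)
    p <- vapply(ctg, function(cg) sample.int(nchar(genome[[cg]]) - 2L, 1) + 1L, integer(1))
    refb <- substr(genome[ctg], p, p)
    rows$chrom[ind] <- ctg
    rows$pos[ind] <- as.integer(p)
    rows$ref[ind] <- refb
    rows$alt[ind] <- paste0(refb, sample(c("A", "C", "G", "T"), length(ind), replace = TRUE))
  }
  rows
}

simulate_expression <- function(cfg, sample_ids, immune, cell_cycle, bm1) {
  gs <- default_gene_sets()
  bmw <- synthetic_bm_weights()
  immune_genes <- unique(c(gs$cytolytic, gs$cd8, gs$icr, "TLR7", "CD7",
                           "CD3E", "CD2", "LCK", "ZAP70"))
  cc_genes <- gs$cell_cycle
  filler <- sprintf("GENE%04d", seq_len(cfg$n_filler_genes))
  genes <- unique(c(immune_genes, cc_genes, bmw$gene, filler))
  n_g <- length(genes)
  n_s <- length(sample_ids)

  mu <- runif(n_g, 1, 8)
  mat <- matrix(rnorm(n_g * n_s, 0, 1), n_g, n_s) + mu
  rownames(mat) <- genes
  colnames(mat) <- sample_ids

  eff <- cfg$expression_effects
  mat[immune_genes, ] <- mat[immune_genes, ] +
    rep(eff$immune * immune, each = length(immune_genes))
  mat[cc_genes, ] <- mat[cc_genes, ] +
    rep(eff$cell_cycle * cell_cycle, each = length(cc_genes))
  bm_dir <- sign(bmw$weight)
  mat[bmw$gene, ] <- mat[bmw$gene, ] + outer(eff$bm * bm_dir, bm1)
  pmax(mat, 0)  # log2(TPM+1) values are nonnegative
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  cat("<ctdna_cohort>\n")
  cat(sprintf("  %d patients (%s)\n", nrow(x$patients),
              paste(sprintf("%s=%d", names(table(x$patients$arm)),
                            as.integer(table(x$patients$arm))), collapse = ", ")))
  cat(sprintf("  %d variant calls; expression %d genes x %d samples\n",
              nrow(x$variants), nrow(x$expression), ncol(x$expression)))
  cat(sprintf("  seed %d\n", x$config$seed))
  invisible(x)
}

#' Build a worked-count fixture
#'
#' Constructs a minimal paired cohort in which exactly `numerator` of
#' `denominator` patients carry an end-of-treatment-only (acquired)
#' alteration of the given gene and class, and every patient carries an
#' unrelated maintained truncal alteration so all patients are paired and
#' evaluable. Useful for reproducing printed count -> percentage summaries
#' through the full classification machinery.
#'
#' @param numerator patients carrying the acquired alteration.
#' @param denominator total paired (evaluable) patients.
#' @param gene,variant_class the labelled alteration.
#' @param arm arm label for all patients.
#' @return list with `variants` (validated tibble) and `patients` (tibble).
#' @export
simulate_worked_counts <- function(numerator, denominator, gene = "MET",
                                   variant_class = "amplification",
                                   arm = "triplet") {
  if (numerator < 0 || denominator < 1 || numerator > denominator) {
    abort("need 0 <= numerator <= denominator, denominator >= 1")
  }
  assert_enum(arm, arm_levels, "arm")
  assert_enum(variant_class, variant_class_levels, "variant_class")
  pid <- sprintf("WC%04d", seq_len(denominator))
  truncal <- tibble(
    patient_id = rep(pid, each = 2),
    timepoint = rep(c("C1D1", "EoT"), denominator),
    gene = "BRAF", variant_class = "SNV",
    chrom = "ctg1", pos = 101L, ref = "A", alt = "T",
    vaf = 0.25, protein_change = "V600E"
  )
  carriers <- pid[seq_len(numerator)]
  is_coord <- variant_class %in% c("SNV", "indel")
  acquired <- tibble(
    patient_id = carriers,
    timepoint = "EoT",
    gene = gene, variant_class = variant_class,
    chrom = if (is_coord) "ctg1" else NA_character_,
    pos = if (is_coord) 201L else NA_integer_,
    ref = if (is_coord) "C" else NA_character_,
    alt = if (is_coord) "A" else NA_character_,
    vaf = if (is_coord) 0.02 else NA_real_,
    protein_change = NA_character_
  )
  patients <- tibble(
    patient_id = pid, arm = arm,
    time_on_treatment_months = 4,
    os_months = 10, os_event = 1, pfs_months = 5, pfs_event = 1
  )
  list(variants = validate_variant_table(bind_rows(truncal, acquired)),
       patients = patients)
}
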