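# Paired-sample alteration dynamics: acquired / maintained / lost status at
# the alteration level, gene-level aggregation with a fixed precedence rule,
# and the frequency / association summaries built on top.

#' Classify alteration status between paired samples
#'
#' Each distinct alteration (exact (gene, class, chrom, pos, ref, alt)
#' identity for SNV/indel; (gene, class) for amplification/fusion) observed
#' at either timepoint of one patient receives exactly one status:
#' `acquired` (EoT only), `maintained` (both timepoints) or `lost` (C1D1
#' only). Status is presence-based — a detected call counts regardless of its
#' VAF (an optional `min_vaf` presence threshold is available and defaults
#' to 0, i.e. detection as reported).
#'
#' @param variants paired variant table for one or more patients (rows at
#'   both timepoints); classification is per patient.
#' @param min_vaf optional VAF presence threshold; VAF-bearing calls below it
#'   are treated as undetected. Default 0.
#' @param collapse_duplicates if `TRUE`, duplicate alteration keys within one
#'   timepoint are collapsed to the maximum-VAF call; if `FALSE` (default)
#'   they are an error.
#' @return tibble with one row per (patient, alteration): `patient_id`,
#'   `gene`, `variant_class`, `chrom`, `pos`, `ref`, `alt`, `status`,
#'   `c1d1_vaf`, `eot_vaf`. The statuses partition the key union:
#'   acquired + maintained + lost = distinct keys.
#' @export
classify_alteration_status <- function(variants, min_vaf = 0,
                                       collapse_duplicates = FALSE) {
  variants <- validate_variant_table(variants)
  if (min_vaf > 0) {
    variants <- variants %>%
      filter(is.na(.data$vaf) | .data$vaf >= min_vaf)
  }
  variants$key <- alteration_key(variants)
  dup <- variants %>%
    dplyr::count(.data$patient_id, .data$timepoint, .data$key) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    if (!collapse_duplicates) {
      abort(sprintf("duplicate alteration key within one timepoint (patient %s, %s): %s",
                    dup$patient_id[1], dup$timepoint[1], dup$key[1]))
    }
    variants <- variants %>%
      arrange(.data$patient_id, .data$timepoint, dplyr::desc(.data$vaf)) %>%
      distinct(.data$patient_id, .data$timepoint, .data$key, .keep_all = TRUE)
  }
  # presence = the call appears at that timepoint (VAF may legitimately be NA
  # for amplifications/fusions), so track presence separately from VAF
  pres <- variants %>%
    distinct(.data$patient_id, .data$key, .data$timepoint) %>%
    mutate(present = TRUE) %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "present",
                       values_fill = FALSE)
  if (!"C1D1" %in% names(pres)) pres$C1D1 <- FALSE
  if (!"EoT" %in% names(pres)) pres$EoT <- FALSE
  vafs <- variants %>%
    select("patient_id", "key", "timepoint", "vaf") %>%
    tidyr::pivot_wider(names_from = "timepoint", values_from = "vaf")
  if (!"C1D1" %in% names(vafs)) vafs$C1D1 <- NA_real_
  if (!"EoT" %in% names(vafs)) vafs$EoT <- NA_real_

  meta <- variants %>%
    distinct(.data$patient_id, .data$key, .keep_all = TRUE) %>%
    select("patient_id", "key", "gene", "variant_class", "chrom", "pos",
           "ref", "alt")
  out <- meta %>%
    left_join(pres %>% rename(c1d1_present = "C1D1", eot_present = "EoT"),
              by = c("patient_id", "key")) %>%
    left_join(vafs %>% rename(c1d1_vaf = "C1D1", eot_vaf = "EoT"),
              by = c("patient_id", "key")) %>%
    mutate(status = case_when(
      .data$c1d1_present & .data$eot_present ~ "maintained",
      .data$eot_present ~ "acquired",
      TRUE ~ "lost"
    )) %>%
    select("patient_id", "gene", "variant_class", "chrom", "pos", "ref",
           "alt", "status", "c1d1_vaf", "eot_vaf") %>%
    arrange(.data$patient_id, .data$gene, .data$pos)
  out
}

#' Aggregate alteration statuses to gene level
#'
#' One record per (patient, gene) applying the precedence
#' maintained > acquired > lost: a gene with any maintained alteration is
#' shown as maintained, otherwise acquired if any acquired, otherwise lost.
#' Supporting alteration counts per status are retained.
#'
#' @param status_records output of [classify_alteration_status()].
#' @return tibble: `patient_id`, `gene`, `gene_status`, `n_acquired`,
#'   `n_maintained`, `n_lost`.
#' @export
aggregate_gene_status <- function(status_records) {
  assert_cols(status_records, c("patient_id", "gene", "status"), "status records")
  assert_enum(status_records$status, status_levels, "status")
  status_records %>%
    group_by(.data$patient_id, .data$gene) %>%
    summarise(
      n_acquired = sum(.data$status == "acquired"),
      n_maintained = sum(.data$status == "maintained"),
      n_lost = sum(.data$status == "lost"),
      .groups = "drop"
    ) %>%
    mutate(gene_status = case_when(
      .data$n_maintained > 0 ~ "maintained",
      .data$n_acquired > 0 ~ "acquired",
      TRUE ~ "lost"
    )) %>%
    select("patient_id", "gene", "gene_status", "n_acquired", "n_maintained",
           "n_lost") %>%
    arrange(.data$patient_id, .data$gene)
}

#' Frequency summary from a count and denominator
#'
#' @param count,denominator nonnegative counts with `denominator >= 1`.
#' @return tibble with `count`, `denominator`, `percent` (one decimal, halves
#'   away from zero — the convention used for printed clinical summaries).
#' @export
frequency_summary <- function(count, denominator) {
  if (any(denominator < 1)) abort("denominator must be >= 1")
  if (any(count < 0 | count > denominator)) abort("need 0 <= count <= denominator")
  tibble(count = count, denominator = denominator,
         percent = round_half_up(100 * count / denominator, 1))
}

#' Summarise acquisition frequency per queried alteration
#'
#' For each queried gene (optionally restricted to a variant class, so that
#' e.g. an acquired fusion is counted separately from a maintained point
#' mutation in the same gene), counts patients whose precedence status
#' (maintained > acquired > lost over the matching records) is `acquired`,
#' over an explicit evaluable denominator, and reports the percentage at
#' one-decimal precision. When `exclude_baseline = TRUE` the denominator is
#' reduced to patients without a baseline (maintained or lost) record of the
#' query, matching the "patients without the baseline alteration" convention;
#' otherwise the supplied denominator is used as-is (both conventions appear
#' in practice, so this is configurable).
#'
#' @param records alteration-level status records
#'   ([classify_alteration_status()]) or gene-level records
#'   ([aggregate_gene_status()]); the status column is detected.
#' @param genes character vector of gene symbols to summarise.
#' @param denominator evaluable paired-patient count (>= 1).
#' @param classes optional variant class per query (recycled); `NA` matches
#'   any class. Requires alteration-level records.
#' @param exclude_baseline drop patients with a baseline record of the query
#'   from that query's denominator.
#' @return tibble: `gene`, `variant_class`, `count`, `denominator`,
#'   `percent`.
#' @export
summarize_acquisition_frequency <- function(records, genes, denominator,
                                            classes = NA_character_,
                                            exclude_baseline = FALSE) {
  if (denominator < 1) abort("denominator must be >= 1")
  status_col <- if ("status" %in% names(records)) "status" else "gene_status"
  assert_cols(records, c("patient_id", "gene", status_col), "status records")
  classes <- rep_len(classes, length(genes))
  if (any(!is.na(classes)) && !"variant_class" %in% names(records)) {
    abort("class-specific queries need alteration-level records with variant_class")
  }
  purrr::map_dfr(seq_along(genes), function(i) {
    g <- genes[i]; cl <- classes[i]
    rec <- records %>% filter(.data$gene == g)
    if (!is.na(cl)) rec <- rec %>% filter(.data$variant_class == cl)
    per_patient <- rec %>%
      group_by(.data$patient_id) %>%
      summarise(st = if (any(.data[[status_col]] == "maintained")) "maintained"
                else if (any(.data[[status_col]] == "acquired")) "acquired"
                else "lost",
                .groups = "drop")
    denom <- denominator
    if (exclude_baseline) {
      denom <- denominator - sum(per_patient$st %in% c("maintained", "lost"))
    }
    frequency_summary(sum(per_patient$st == "acquired"), denom) %>%
      mutate(gene = g, variant_class = cl, .before = 1)
  })
}

#' Fraction of patients with two or more acquired alterations, per arm
#'
#' Counts acquired-status gene records per patient (optionally restricted to
#' a gene set) and reports, per arm, the fraction of paired patients with at
#' least two.
#'
#' @param gene_records output of [aggregate_gene_status()].
#' @param patients patient table with `patient_id` and `arm`; defines the
#'   paired denominator per arm.
#' @param genes optional gene restriction.
#' @return tibble: `arm`, `n_paired`, `n_multi`, `fraction`, `percent`.
#' @export
count_multi_acquired <- function(gene_records, patients, genes = NULL) {
  assert_cols(patients, c("patient_id", "arm"), "patient table")
  rec <- gene_records
  if (!is.null(genes)) rec <- rec %>% filter(.data$gene %in% genes)
  per_patient <- rec %>%
    filter(.data$gene_status == "acquired") %>%
    dplyr::count(.data$patient_id, name = "n_acquired_genes")
  patients %>%
    left_join(per_patient, by = "patient_id") %>%
    mutate(n_acquired_genes = dplyr::coalesce(.data$n_acquired_genes, 0L)) %>%
    group_by(.data$arm) %>%
    summarise(n_paired = dplyr::n(),
              n_multi = sum(.data$n_acquired_genes >= 2),
              .groups = "drop") %>%
    mutate(fraction = .data$n_multi / .data$n_paired,
           percent = round_half_up(100 * .data$fraction, 1))
}

#' Detection concordance between two assays
#'
#' Given per-patient detection flags from two assays, reports the detection
#' count and percentage in each assay (over that assay's own population) and
#' in both (over the intersection population).
#'
#' @param set_a,set_b data frames with `patient_id` and logical/0-1
#'   `detected`.
#' @return tibble with rows `assay_a`, `assay_b`, `both`: `count`,
#'   `denominator`, `percent` (one decimal).
#' @export
detection_concordance <- function(set_a, set_b) {
  assert_cols(set_a, c("patient_id", "detected"), "set_a")
  assert_cols(set_b, c("patient_id", "detected"), "set_b")
  inter <- inner_join(
    set_a %>% select("patient_id", det_a = "detected"),
    set_b %>% select("patient_id", det_b = "detected"),
    by = "patient_id"
  )
  if (nrow(inter) == 0) abort("no patients assayed by both")
  bind_rows(
    frequency_summary(sum(set_a$detected), nrow(set_a)) %>%
      mutate(population = "assay_a", .before = 1),
    frequency_summary(sum(set_b$detected), nrow(set_b)) %>%
      mutate(population = "assay_b", .before = 1),
    frequency_summary(sum(inter$det_a & inter$det_b), nrow(inter)) %>%
      mutate(population = "both", .before = 1)
  )
}

#' 2x2 association: odds ratio and Fisher exact test
#'
#' The odds ratio is the sample cross-ratio (a*d)/(b*c) for the table
#' \[exposure x outcome\]; with exactly one zero cell the Haldane-Anscombe
#' 0.5 continuity correction is applied to every cell and flagged. The
#' two-sided p-value is the Fisher exact test (hypergeometric). A degenerate
#' margin (an all-zero row or column) yields an undefined odds ratio (`NA`)
#' with p = 1.
#'
#' @param exposure,outcome equal-length 0/1 (or logical) vectors per patient.
#' @return one-row tibble: cell counts `n11` (exposed & outcome), `n10`,
#'   `n01`, `n00`, `odds_ratio`, `haldane_corrected`, `p_value`.
#' @export
association_2x2 <- function(exposure, outcome) {
  stopifnot(length(exposure) == length(outcome))
  e <- as.integer(as.logical(exposure))
  o <- as.integer(as.logical(outcome))
  if (anyNA(e) || anyNA(o)) abort("exposure/outcome must be 0/1 without NA")
  a <- sum(e == 1 & o == 1); b <- sum(e == 1 & o == 0)
  c_ <- sum(e == 0 & o == 1); d <- sum(e == 0 & o == 0)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  n_zero <- sum(tab == 0)
  haldane <- FALSE
  if (degenerate) {
    or <- NA_real_
    warn("degenerate 2x2 margin: odds ratio undefined")
  } else if (n_zero == 1) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    haldane <- TRUE
  } else {
    or <- (a * d) / (b * c_)
  }
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  tibble(n11 = a, n10 = b, n01 = c_, n00 = d,
         odds_ratio = or, haldane_corrected = haldane, p_value = p)
}
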