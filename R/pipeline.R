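# End-to-end pipeline runner: executes the analysis stages in dependency
# order over a cohort (simulated or read from disk) and writes per-stage
# TSV/JSON outputs plus a machine-readable summary.

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: paired status classification -> gene-level
#' aggregation -> acquisition frequencies -> clonality and the
#' acquired-vs-maintained comparison -> per-patient rates, Poisson mixture
#' and negative-binomial arm comparison -> pooled spectra and signature
#' refitting -> expression scores (skipped with a message if the cohort has
#' no expression data) -> survival (KM by arm, per-arm Cox for the cytolytic
#' split, treatment-by-biomarker interaction). Each stage's table is written
#' to `out_dir` when given; a summary list is always returned.
#'
#' @param cohort a `ctdna_cohort` (see [simulate_cohort()]) or a list with
#'   `variants`, `patients` and optionally `expression`.
#' @param out_dir optional output directory; created if missing.
#' @param top_alterations data frame with `gene` and `variant_class`
#'   (`NA` = any class) defining the top acquired resistance alterations:
#'   default RAS/MAP2K1 mutations and MET amplification.
#' @param genome reference sequences for spectrum construction.
#' @param reference signature reference for refitting.
#' @param bm_weights subtype weight table.
#' @param mixture_K Poisson mixture components.
#' @param seed seed for the mixture restarts.
#' @return (invisibly) a named list of stage results; element `summary` is a
#'   flat list of headline numbers.
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         top_alterations = data.frame(
                           gene = c("KRAS", "NRAS", "MAP2K1", "MET"),
                           variant_class = c("SNV", "SNV", "SNV", "amplification")
                         ),
                         genome = synthetic_reference_genome(),
                         reference = synthetic_signature_reference(),
                         bm_weights = synthetic_bm_weights(),
                         mixture_K = 3, seed = 1L) {
  variants <- validate_variant_table(cohort$variants)
  patients <- validate_patient_table(cohort$patients)

  status <- classify_alteration_status(variants)
  gene_status <- aggregate_gene_status(status)
  paired_n <- dplyr::n_distinct(patients$patient_id)
  freq <- summarize_acquisition_frequency(status, top_alterations$gene, paired_n,
                                          classes = top_alterations$variant_class)
  multi <- count_multi_acquired(gene_status, patients, genes = NULL)

  clon <- compute_clonality(status)
  clon_test <- if (all(c("acquired", "maintained") %in% clon$status)) {
    compare_clonality(clon)
  } else NULL

  rates <- compute_rates(status, patients)
  mixture <- fit_poisson_mixture(rates, K = mixture_K, seed = seed)
  nb <- if (dplyr::n_distinct(rates$arm) >= 2 && "control" %in% rates$arm) {
    compare_rates_nb(rates, reference_arm = "control")
  } else NULL

  exposures <- refit_group_exposures(variants, patients, genome, reference)

  scores <- NULL
  surv <- list()
  if (!is.null(cohort$expression)) {
    scores <- score_expression(cohort$expression, bm_weights)
    dat <- patients %>%
      left_join(scores, by = c(patient_id = "sample_id"))
    surv$km_by_arm <- km_fit(dat, group = "arm")
    two_arm <- dat %>% filter(.data$arm %in% c("control", "triplet"))
    if (dplyr::n_distinct(two_arm$arm) == 2 && sum(two_arm$os_event) >= 10) {
      surv$interaction_cytolytic <- interaction_test(
        two_arm, treatment = "arm", biomarker = "cytolytic")
    }
  } else {
    inform("no expression data: expression and interaction stages skipped")
  }

  summary <- list(
    n_patients = nrow(patients),
    n_variants = nrow(variants),
    n_acquired = sum(status$status == "acquired"),
    n_maintained = sum(status$status == "maintained"),
    n_lost = sum(status$status == "lost"),
    median_clonality_acquired = median(clon$ratio[clon$status == "acquired"]),
    median_clonality_maintained = median(clon$ratio[clon$status == "maintained"]),
    clonality_p = if (!is.null(clon_test)) clon_test$p_value else NA_real_,
    mixture_rates = mixture$rates,
    rate_ratios = if (!is.null(nb)) stats::setNames(nb$rate_ratio, nb$arm) else NULL,
    interaction_p = if (!is.null(surv$interaction_cytolytic)) {
      surv$interaction_cytolytic$p_value
    } else NA_real_
  )

  results <- list(status = status, gene_status = gene_status,
                  frequency = freq, multi_acquired = multi,
                  clonality = clon, clonality_test = clon_test,
                  rates = rates, mixture = mixture, nb_comparison = nb,
                  exposures = exposures, scores = scores, survival = surv,
                  summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(status, file.path(out_dir, "alteration_status.tsv"))
    readr::write_tsv(gene_status, file.path(out_dir, "gene_status.tsv"))
    readr::write_tsv(freq, file.path(out_dir, "acquisition_frequency.tsv"))
    readr::write_tsv(multi, file.path(out_dir, "multi_acquired.tsv"))
    readr::write_tsv(clon, file.path(out_dir, "clonality.tsv"))
    readr::write_tsv(rates, file.path(out_dir, "rates.tsv"))
    readr::write_tsv(exposures, file.path(out_dir, "signature_exposures.tsv"))
    if (!is.null(scores)) {
      readr::write_tsv(scores, file.path(out_dir, "expression_scores.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
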