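# Clonality: per-sample maxVAF, per-alteration EoT VAF / maxVAF ratios, and
# the acquired-vs-maintained subclonality comparison.

#' Maximum VAF of a sample
#'
#' The maximum variant allele frequency over the somatic, VAF-bearing
#' alterations in one sample — a standard circulating-tumor-fraction proxy.
#' Amplifications and fusions carry no VAF and do not contribute. A sample
#' with no VAF-bearing calls has no detectable ctDNA signal and returns `NA`
#' ("undetected"), which is deliberately distinct from zero.
#'
#' @param calls variant calls for one sample (one patient, one timepoint).
#' @return a single VAF fraction, or `NA_real_` if undetected.
#' @export
compute_max_vaf <- function(calls) {
  assert_cols(calls, "vaf", "calls")
  v <- calls$vaf[!is.na(calls$vaf)]
  if (length(v) == 0) return(NA_real_)
  max(v)
}

#' Per-alteration clonality ratios at end of treatment
#'
#' For every VAF-bearing alteration present at EoT, computes
#' `ratio = eot_vaf / max_vaf`, where `max_vaf` is the sample-level maximum
#' over all VAF-bearing EoT alterations of the same patient (including the
#' alteration itself, so exactly one alteration per sample attains ratio 1
#' unless tied). Ratios at or below the threshold are flagged subclonal
#' (boundary inclusive). Amplifications/fusions have no VAF and are
#' excluded; patients whose EoT maxVAF is undetected or zero are an error.
#'
#' @param status_records output of [classify_alteration_status()]; rows with
#'   a non-`NA` `eot_vaf` are used.
#' @param subclonal_threshold subclonality cutoff on the ratio (default 0.3).
#' @return tibble: `patient_id`, `gene`, `variant_class`, `status`,
#'   `eot_vaf`, `max_vaf`, `ratio`, `subclonal`.
#' @export
compute_clonality <- function(status_records, subclonal_threshold = 0.3) {
  assert_cols(status_records, c("patient_id", "gene", "variant_class",
                                "status", "eot_vaf"), "status records")
  eot <- status_records %>% filter(!is.na(.data$eot_vaf))
  if (nrow(eot) == 0) abort("no VAF-bearing EoT alterations")
  out <- eot %>%
    group_by(.data$patient_id) %>%
    mutate(max_vaf = max(.data$eot_vaf)) %>%
    ungroup()
  if (any(out$max_vaf <= 0)) {
    bad <- out$patient_id[out$max_vaf <= 0][1]
    abort(sprintf("patient %s has EoT maxVAF of 0: clonality undefined", bad))
  }
  out %>%
    mutate(ratio = .data$eot_vaf / .data$max_vaf,
           subclonal = .data$ratio <= subclonal_threshold) %>%
    select("patient_id", "gene", "variant_class", "status", "eot_vaf",
           "max_vaf", "ratio", "subclonal")
}

#' Compare clonality of acquired versus maintained alterations
#'
#' Two-sided Wilcoxon rank-sum test of the EoT VAF/maxVAF ratios of
#' acquired-status alterations against maintained-status alterations. The
#' exact distribution is used for combined n <= 20 without ties; otherwise
#' the normal approximation with tie correction.
#'
#' @param clonality output of [compute_clonality()], or a list/two vectors
#'   via `acquired` and `maintained`.
#' @param acquired,maintained optional numeric ratio vectors, overriding
#'   `clonality`.
#' @return one-row tibble: group sizes and medians, rank-sum statistic `W`,
#'   `p_value`, `exact` flag.
#' @export
compare_clonality <- function(clonality = NULL, acquired = NULL, maintained = NULL) {
  if (is.null(acquired) || is.null(maintained)) {
    assert_cols(clonality, c("status", "ratio"), "clonality records")
    acquired <- clonality$ratio[clonality$status == "acquired"]
    maintained <- clonality$ratio[clonality$status == "maintained"]
  }
  if (length(acquired) == 0 || length(maintained) == 0) {
    abort("both acquired and maintained groups must be nonempty")
  }
  ties <- anyDuplicated(c(acquired, maintained)) > 0
  exact <- (length(acquired) + length(maintained) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(acquired, maintained, alternative = "two.sided",
                exact = exact, correct = FALSE)
  )
  tibble(n_acquired = length(acquired), n_maintained = length(maintained),
         median_acquired = median(acquired), median_maintained = median(maintained),
         W = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}
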