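# Signature refitting: group-wise pooling of variants into baseline and
# acquired origins, and non-negative least-squares exposure refitting against
# a reference signature matrix.

#' Pool paired variants into baseline and acquired groups
#'
#' Applies the pooling filters used for group-wise signature analysis:
#' an alteration is in the *baseline* pool if its C1D1 VAF exceeds
#' `baseline_vaf_min` (default 1%), and in the *acquired* pool if it is
#' absent (or VAF 0) at C1D1 and present with VAF > 0 at EoT. Alterations
#' with a C1D1 VAF in (0, `baseline_vaf_min`\] fall in neither pool, so the
#' pools never overlap. Groups are keyed by arm and origin.
#'
#' @param variants paired variant table (both timepoints).
#' @param patients patient table supplying `arm` per `patient_id`.
#' @param baseline_vaf_min baseline C1D1 VAF threshold as a fraction
#'   (default 0.01 = 1%).
#' @return tibble of pooled variants with `arm` and
#'   `origin` (`"baseline"`/`"acquired"`) columns, one row per (patient,
#'   alteration) in a pool, carrying the coordinate columns for spectrum
#'   construction.
#' @export
pool_variants <- function(variants, patients, baseline_vaf_min = 0.01) {
  status <- classify_alteration_status(variants)
  assert_cols(patients, c("patient_id", "arm"), "patient table")
  pooled <- status %>%
    mutate(origin = case_when(
      !is.na(.data$c1d1_vaf) & .data$c1d1_vaf > baseline_vaf_min ~ "baseline",
      (is.na(.data$c1d1_vaf) | .data$c1d1_vaf == 0) & .data$status != "lost" &
        !is.na(.data$eot_vaf) & .data$eot_vaf > 0 ~ "acquired",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$origin)) %>%
    left_join(patients %>% select("patient_id", "arm"), by = "patient_id")
  pooled
}

#' Refit signature exposures by non-negative least squares
#'
#' Solves `min || counts - P e ||_2` subject to `e >= 0` (Lawson-Hanson NNLS)
#' for a 96-channel spectrum against a reference signature matrix `P`, the
#' standard refitting formulation for quantifying predefined mutational
#' signatures in a pooled spectrum. Reports raw exposures, proportions with
#' sub-1% attributions zeroed (attribution parsimony; the raw solution is
#' kept alongside), the relative L2 reconstruction error and the cosine
#' similarity between the spectrum and its reconstruction.
#'
#' @param counts numeric vector of 96 channel counts (named by channel or in
#'   canonical [sbs_channels()] order), or a spectrum tibble from
#'   [build_spectrum()] for a single group.
#' @param reference validated reference matrix (see [sbs_reference()]).
#' @param prune_below proportions below this fraction of the total exposure
#'   are zeroed in `proportion` (default 0.01; set 0 to disable).
#' @return object of class `sbs_refit` with [tidy()] (per-signature exposure,
#'   raw and pruned proportion) and [glance()] (reconstruction error, cosine
#'   similarity, n_mutations) methods.
#' @export
refit_exposures <- function(counts, reference, prune_below = 0.01) {
  reference <- sbs_reference(reference)
  channels <- sbs_channels()
  if (is.data.frame(counts)) {
    assert_cols(counts, c("channel", "count"), "spectrum")
    if (nrow(counts) != 96) abort("spectrum tibble must have exactly 96 rows (one group)")
    counts <- stats::setNames(counts$count, counts$channel)
  }
  if (!is.null(names(counts))) {
    if (!setequal(names(counts), channels)) abort("count names must be the 96 canonical channels")
    counts <- counts[channels]
  } else if (length(counts) != 96) {
    abort("counts must have length 96")
  }
  if (any(counts < 0)) abort("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) abort("zero spectrum: nothing to refit")

  sol <- pracma::lsqnonneg(reference, as.numeric(counts))
  e <- stats::setNames(pmax(sol$x, 0), colnames(reference))
  recon <- as.numeric(reference %*% e)
  resid <- sqrt(sum((counts - recon)^2))
  rel_err <- resid / sqrt(sum(counts^2))
  cosine <- if (sum(recon^2) == 0) 0 else {
    sum(counts * recon) / (sqrt(sum(counts^2)) * sqrt(sum(recon^2)))
  }
  prop_raw <- if (sum(e) == 0) e else e / sum(e)
  prop <- prop_raw
  prop[prop < prune_below] <- 0
  if (sum(prop) > 0) prop <- prop / sum(prop)

  structure(list(
    signatures = colnames(reference), exposures = e,
    proportion_raw = prop_raw, proportion = prop,
    reconstruction_error = rel_err, cosine_similarity = cosine,
    n_mutations = total, counts = as.numeric(counts)
  ), class = "sbs_refit")
}

#' @export
print.sbs_refit <- function(x, ...) {
  cat(sprintf("<sbs_refit> %d mutations, relative error %.4g, cosine %.4f\n",
              x$n_mutations, x$reconstruction_error, x$cosine_similarity))
  print(tidy(x))
  invisible(x)
}

#' @rdname refit_exposures
#' @param x,... an `sbs_refit` object.
#' @export
tidy.sbs_refit <- function(x, ...) {
  tibble(signature = x$signatures, exposure = unname(x$exposures),
         proportion_raw = unname(x$proportion_raw),
         proportion = unname(x$proportion))
}

#' @rdname refit_exposures
#' @export
glance.sbs_refit <- function(x, ...) {
  tibble(n_mutations = x$n_mutations,
         reconstruction_error = x$reconstruction_error,
         cosine_similarity = x$cosine_similarity)
}

#' Group-wise signature refit of pooled spectra
#'
#' Convenience wrapper: pools paired variants (see [pool_variants()]), builds
#' a 96-channel spectrum per (arm, origin) group and refits each against the
#' reference.
#'
#' @inheritParams pool_variants
#' @param genome named character vector of contig sequences.
#' @param reference signature reference matrix.
#' @param min_mutations groups with fewer usable SNVs are skipped (default 20).
#' @return tibble keyed by `arm`, `origin`, `signature` with exposures,
#'   proportions and per-group fit diagnostics.
#' @export
refit_group_exposures <- function(variants, patients, genome, reference,
                                  baseline_vaf_min = 0.01, min_mutations = 20) {
  pooled <- pool_variants(variants, patients, baseline_vaf_min)
  spectra <- build_spectrum(pooled, genome, by = c("arm", "origin"))
  spectra %>%
    group_by(.data$arm, .data$origin) %>%
    dplyr::group_modify(function(df, key) {
      if (sum(df$count) < min_mutations) {
        inform(sprintf("skipping %s/%s: only %d SNVs", key$arm, key$origin,
                       sum(df$count)))
        return(tibble())
      }
      fit <- refit_exposures(stats::setNames(df$count, df$channel), reference)
      tidy(fit) %>%
        mutate(n_mutations = fit$n_mutations,
               reconstruction_error = fit$reconstruction_error,
               cosine_similarity = fit$cosine_similarity)
    }) %>%
    ungroup()
}
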