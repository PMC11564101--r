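# Survival-based gene ranking and preranked GSEA with a gene-permutation
# null and Benjamini-Hochberg control across genesets.

#' Rank genes by Cox-model association
#'
#' Fits one Cox proportional-hazards model per gene on z-scaled expression.
#' In `univariable` mode (within one arm, or the whole table) the ranking
#' statistic is the gene coefficient's Wald z; in `interaction` mode the
#' model is `gene * treatment` over two arms and the statistic is the
#' product-term Wald z. Genes whose model fails to converge are dropped with
#' a message.
#'
#' @param mat genes x samples matrix of log2(TPM + 1) values (typically
#'   already filtered with [filter_top_iqr()]); column names must match
#'   `patients$patient_id`.
#' @param patients patient table with survival columns.
#' @param mode `"univariable"` or `"interaction"`.
#' @param arms arm(s) to include: one arm for univariable-by-arm rankings,
#'   exactly two for interaction mode (the second is the treatment level).
#' @param time_col,event_col survival columns (default OS).
#' @return tibble: `gene`, `statistic` (signed z), sorted decreasing.
#' @export
rank_genes_by_model <- function(mat, patients, mode = c("univariable", "interaction"),
                                arms = NULL, time_col = "os_months",
                                event_col = "os_event") {
  mode <- match.arg(mode)
  assert_cols(patients, c("patient_id", "arm", time_col, event_col), "patient table")
  if (!is.null(arms)) patients <- patients %>% filter(.data$arm %in% arms)
  if (mode == "interaction" && (is.null(arms) || length(arms) != 2)) {
    abort("interaction mode needs exactly two arms (reference first)")
  }
  keep <- intersect(colnames(mat), patients$patient_id)
  if (length(keep) < 2) abort("expression samples and patient table do not align")
  patients <- patients %>% filter(.data$patient_id %in% keep)
  mat <- mat[, patients$patient_id, drop = FALSE]
  if (sum(patients[[event_col]]) < 10) {
    warn("fewer than 10 events: gene ranking will be unstable")
  }
  z <- zscore_genes(mat)
  surv <- survival::Surv(patients[[time_col]], patients[[event_col]])
  treat <- if (mode == "interaction") {
    as.integer(patients$arm == arms[2])
  } else NULL

  stats_out <- vapply(rownames(z), function(g) {
    x <- z[g, ]
    fit <- tryCatch({
      if (mode == "univariable") {
        survival::coxph(surv ~ x)
      } else {
        survival::coxph(surv ~ x * treat)
      }
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) return(NA_real_)
    sm <- summary(fit)$coefficients
    row <- if (mode == "univariable") "x" else "x:treat"
    if (!row %in% rownames(sm)) return(NA_real_)
    unname(sm[row, "z"])
  }, numeric(1))

  dropped <- sum(!is.finite(stats_out))
  if (dropped > 0) {
    inform(sprintf("%d gene(s) dropped (non-convergent or degenerate model)", dropped))
  }
  tibble(gene = rownames(z), statistic = unname(stats_out)) %>%
    filter(is.finite(.data$statistic)) %>%
    arrange(dplyr::desc(.data$statistic))
}

# ES of a preranked running sum given sorted |stat|^p weights and hit
# positions; extremes occur immediately after a hit (positive side) or just
# before a hit (negative side), so only hit positions need evaluating
running_sum_es <- function(weights_sorted, hit_idx, n) {
  k <- length(hit_idx)
  w <- weights_sorted[hit_idx]
  denom_hit <- sum(w)
  denom_miss <- n - k
  cum_hit <- cumsum(w) / denom_hit
  miss_before <- (hit_idx - seq_len(k)) / denom_miss
  after <- cum_hit - miss_before
  before <- c(0, cum_hit[-k]) - miss_before
  i_max <- which.max(after)
  i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) after[i_max] else before[i_min]
}

#' Preranked gene set enrichment analysis
#'
#' Standard preranked running-sum GSEA: genes are ordered by decreasing
#' ranking statistic; in-set positions increment the running sum by
#' `|statistic|^p` (normalised), out-of-set positions decrement uniformly;
#' the enrichment score (ES) is the maximum deviation from zero. The null is
#' `n_perm` random gene-label permutations (random draws of set positions);
#' the p-value is the smoothed fraction of same-sign permutation ES values
#' at least as extreme, `(1 + more extreme) / (1 + same sign)`, and
#' NES = ES / mean(|same-sign permutation ES|). Benjamini-Hochberg adjustment
#' is applied across genesets. Ties in the ranking are broken by gene symbol
#' so results are order-invariant.
#'
#' @param ranks tibble with `gene` and `statistic` (see
#'   [rank_genes_by_model()]), or a named numeric vector.
#' @param genesets named list of gene symbol vectors.
#' @param n_perm permutations (default 10000; fewer than 100 warns).
#' @param p hit-weight exponent (default 1; 0 = unweighted).
#' @param min_size genesets with fewer overlapping genes are skipped.
#' @param seed integer seed for the permutation stream.
#' @return tibble: `geneset`, `size`, `es`, `nes`, `p_value`, `p_adjust`,
#'   `leading_edge` (list column of genes).
#' @export
preranked_gsea <- function(ranks, genesets, n_perm = 10000, p = 1,
                           min_size = 5, seed = 1L) {
  if (is.numeric(ranks) && !is.null(names(ranks))) {
    ranks <- tibble(gene = names(ranks), statistic = unname(ranks))
  }
  assert_cols(ranks, c("gene", "statistic"), "ranks")
  if (anyDuplicated(ranks$gene) > 0) abort("duplicate genes in ranking")
  if (!all(is.finite(ranks$statistic))) abort("ranking statistics must be finite")
  if (n_perm < 100) warn("n_perm < 100: permutation p-values will be coarse")

  ord <- order(-ranks$statistic, ranks$gene)
  genes <- ranks$gene[ord]
  stat <- ranks$statistic[ord]
  n <- length(genes)
  w <- abs(stat)^p

  with_seed(seed, {
    res <- purrr::map_dfr(names(genesets), function(nm) {
      hit_idx <- which(genes %in% genesets[[nm]])
      k <- length(hit_idx)
      if (k < min_size || k >= n) {
        inform(sprintf("geneset '%s' skipped (overlap %d)", nm, k))
        return(tibble())
      }
      es <- running_sum_es(w, hit_idx, n)
      perm_es <- vapply(seq_len(n_perm), function(i) {
        running_sum_es(w, sort(sample.int(n, k)), n)
      }, numeric(1))
      same <- perm_es[sign(perm_es) == sign(es)]
      p_val <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
      # leading edge: in-set genes at or before the running-sum extreme
      le <- leading_edge_genes(w, hit_idx, n, genes, es)
      tibble(geneset = nm, size = k, es = es, nes = nes, p_value = p_val,
             leading_edge = list(le))
    })
  })
  if (nrow(res) == 0) return(res)
  res$p_adjust <- bh_adjust(res$p_value)
  res %>% select("geneset", "size", "es", "nes", "p_value", "p_adjust",
                 "leading_edge")
}

leading_edge_genes <- function(w, hit_idx, n, genes, es) {
  k <- length(hit_idx)
  cum_hit <- cumsum(w[hit_idx]) / sum(w[hit_idx])
  miss_before <- (hit_idx - seq_len(k)) / (n - k)
  if (es >= 0) {
    peak <- which.max(cum_hit - miss_before)
    genes[hit_idx[seq_len(peak)]]
  } else {
    before <- c(0, cum_hit[-k]) - miss_before
    trough <- which.min(before)
    genes[hit_idx[hit_idx >= hit_idx[trough]]]
  }
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control with monotonicity enforcement,
#' order-preserving in its input.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    abort("p-values must be in [0, 1] without NA")
  }
  p.adjust(pvals, method = "BH")
}
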