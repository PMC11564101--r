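# Expression-based signature scores and subtype calls. Expression matrices
# are genes x samples on the log2(TPM + 1) scale throughout.

#' Keep the most variably expressed genes (by IQR)
#'
#' Retains the `ceiling(fraction * n_genes)` genes with the largest
#' interquartile range across samples; ties are broken by gene-symbol
#' lexicographic order so the result is deterministic.
#'
#' @param mat genes x samples numeric matrix with rownames.
#' @param fraction fraction of genes to keep (default 0.25, the top
#'   quartile).
#' @return the filtered matrix.
#' @export
filter_top_iqr <- function(mat, fraction = 0.25) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (nrow(mat) < 4) abort("need at least 4 genes")
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  iqr <- apply(mat, 1, IQR)
  keep_n <- ceiling(fraction * nrow(mat))
  ord <- order(-iqr, rownames(mat))
  mat[sort(ord[seq_len(keep_n)]), , drop = FALSE]
}

#' Per-gene z-scores
#'
#' Scales each gene (row) to mean 0 and unit sample (n-1) standard
#' deviation. Zero-variance genes cannot be scaled; they are set to 0 and
#' listed in the `flagged_genes` attribute with a warning.
#'
#' @param mat genes x samples numeric matrix.
#' @return matrix of the same shape; attribute `flagged_genes` names any
#'   constant genes.
#' @export
zscore_genes <- function(mat) {
  stopifnot(is.matrix(mat))
  mu <- rowMeans(mat)
  s <- apply(mat, 1, sd)
  flagged <- rownames(mat)[s == 0]
  if (length(flagged) > 0) {
    warn(sprintf("%d constant gene(s) set to z = 0: %s", length(flagged),
                 paste(head(flagged, 5), collapse = ", ")))
  }
  s[s == 0] <- 1
  z <- (mat - mu) / s
  attr(z, "flagged_genes") <- flagged
  z
}

#' Geometric-mean signature score
#'
#' The mean over signature genes of log2(TPM + 1) expression per sample —
#' equivalently the log of the geometric mean of (TPM + 1). This is the form
#' of the two-gene cytolytic score (GZMA, PRF1), the CD8 score (CD8A, CD8B)
#' and the 20-gene immunologic-constant-of-rejection score; values are in
#' log2(TPM) units (two genes at 7 TPM give log2(8) = 3).
#'
#' @param mat genes x samples matrix of log2(TPM + 1) values.
#' @param genes signature gene symbols; all must be present (missing genes
#'   are an error listing them).
#' @param score_name label written to the `score` column name metadata.
#' @return tibble: `sample_id`, `score`, `score_name`.
#' @export
geometric_signature_score <- function(mat, genes, score_name = "signature") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  missing <- setdiff(genes, rownames(mat))
  if (length(missing) > 0) {
    abort(sprintf("signature gene(s) missing from matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  score <- colMeans(mat[genes, , drop = FALSE])
  tibble(sample_id = colnames(mat), score = unname(score),
         score_name = score_name)
}

#' Cytolytic score
#'
#' Convenience wrapper: [geometric_signature_score()] over GZMA and PRF1,
#' the standard two-gene cytolytic-activity metric.
#'
#' @inheritParams geometric_signature_score
#' @export
cytolytic_score <- function(mat) {
  geometric_signature_score(mat, default_gene_sets()$cytolytic, "cytolytic")
}

#' Weighted z-score subtype call (BM1/BM2)
#'
#' Computes per-sample `score = sum_g w_g * z_g` over the 44 subtyping genes
#' and calls BM1 when the score exceeds `threshold` (default 1.5) and BM2
#' otherwise — a score of exactly 1.5 is BM2 (the boundary belongs to BM2).
#' Genes missing from the matrix are imputed as z = 0 with a warning.
#'
#' @param mat genes x samples matrix of log2(TPM + 1) values.
#' @param weights data frame with `gene` and `weight` columns (e.g. the
#'   published 44-gene table, or [synthetic_bm_weights()] for testing).
#' @param threshold BM1 decision boundary (default 1.5, exclusive).
#' @return tibble: `sample_id`, `bm_score`, `bm_subtype`.
#' @export
bm_subtype <- function(mat, weights = synthetic_bm_weights(), threshold = 1.5) {
  assert_cols(weights, c("gene", "weight"), "weights")
  if (nrow(weights) == 0) abort("empty weight table")
  present <- weights$gene %in% rownames(mat)
  if (any(!present)) {
    warn(sprintf("%d subtyping gene(s) absent; imputed as z = 0",
                 sum(!present)))
  }
  w <- weights[present, ]
  z <- zscore_genes(mat[w$gene, , drop = FALSE])
  score <- as.numeric(crossprod(w$weight, z))
  tibble(sample_id = colnames(mat), bm_score = score,
         bm_subtype = if_else(score > threshold, "BM1", "BM2"))
}

#' Single-sample GSEA enrichment score
#'
#' Rank-based single-sample enrichment: per sample, genes are ordered by
#' decreasing expression (ties broken by gene symbol for determinism, with
#' average ranks used as weights) and the score is the sum over the ranking
#' of the difference between the weighted in-set ECDF (rank weights raised to
#' `exponent`) and the unweighted out-of-set ECDF. Because it uses ranks
#' only, the score is invariant to strictly monotone transforms of a
#' sample's expression values.
#'
#' @param mat genes x samples matrix.
#' @param geneset character vector of gene symbols; the intersection with
#'   the matrix genes must be nonempty.
#' @param exponent rank weighting exponent (default 0.25).
#' @param score_name label for the output.
#' @return tibble: `sample_id`, `score`, `score_name`.
#' @export
ssgsea_score <- function(mat, geneset, exponent = 0.25, score_name = "ssgsea") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  genes <- rownames(mat)
  inset <- genes %in% geneset
  if (!any(inset)) abort("geneset has no overlap with matrix genes")
  n <- length(genes)
  n_in <- sum(inset)
  scores <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ord <- order(-x, genes)             # decreasing expression, stable ties
    r <- rank(x, ties.method = "average")  # high expression = high rank weight
    hit <- inset[ord]
    w <- r[ord]^exponent
    p_in <- cumsum(w * hit) / sum(w[hit])
    p_out <- cumsum(!hit) / (n - n_in)
    sum(p_in - p_out)
  }, numeric(1))
  tibble(sample_id = colnames(mat), score = scores, score_name = score_name)
}

#' Median split into high/low groups
#'
#' Values at or below the median are `low`, values above are `high` (ties at
#' the median go low); for even n the median is the midpoint of the two
#' central order statistics. If all values are identical every sample is
#' `low`, with a warning.
#'
#' @param scores numeric vector (n >= 2).
#' @return character vector of `"high"`/`"low"`, same order as input.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) abort("need at least 2 values")
  if (anyNA(scores)) abort("scores must not contain NA")
  m <- median(scores)
  if (all(scores == scores[1])) {
    warn("all values identical: every sample assigned 'low'")
  }
  if_else(scores <= m, "low", "high")
}

#' Score a cohort's expression matrix
#'
#' Convenience wrapper computing the standard score panel per sample:
#' cytolytic, CD8 and 20-gene immune (geometric scores), cell-cycle ssGSEA,
#' BM weighted z-score subtype, and the cytolytic median-split group.
#'
#' @param mat genes x samples matrix of log2(TPM + 1) values.
#' @param bm_weights weight table for [bm_subtype()].
#' @return tibble keyed by `sample_id` with one column per score.
#' @export
score_expression <- function(mat, bm_weights = synthetic_bm_weights()) {
  gs <- default_gene_sets()
  cyt <- cytolytic_score(mat)
  cd8 <- geometric_signature_score(mat, intersect(gs$cd8, rownames(mat)), "cd8")
  icr <- geometric_signature_score(mat, intersect(gs$icr, rownames(mat)), "icr")
  cc <- ssgsea_score(mat, gs$cell_cycle, score_name = "cell_cycle")
  bm <- bm_subtype(mat, bm_weights)
  tibble(sample_id = cyt$sample_id,
         cytolytic = cyt$score,
         cytolytic_group = median_split(cyt$score),
         cd8 = cd8$score, icr = icr$score,
         cell_cycle_ssgsea = cc$score,
         cell_cycle_group = median_split(cc$score)) %>%
    left_join(bm, by = "sample_id")
}
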