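test_that("top-IQR filter keeps the right count with deterministic ties", {
  set.seed(1)
  mat <- matrix(rnorm(8 * 10), 8, 10,
                dimnames = list(paste0("G", 1:8), paste0("S", 1:10)))
  kept <- filter_top_iqr(mat, 0.25)
  expect_equal(nrow(kept), 2)
  iqr <- apply(mat, 1, IQR)
  expect_setequal(rownames(kept), names(sort(iqr, decreasing = TRUE))[1:2])

  # constant gene never retained when most genes vary
  mat2 <- rbind(mat, FLAT = rep(5, 10))
  expect_false("FLAT" %in% rownames(filter_top_iqr(mat2, 0.5)))

  # brute-force sort oracle on a larger random matrix
  big <- matrix(rnorm(100 * 20), 100, 20,
                dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:20)))
  kept_big <- filter_top_iqr(big, 0.25)
  iqr_big <- apply(big, 1, IQR)
  oracle <- rownames(big)[order(-iqr_big, rownames(big))][1:25]
  expect_setequal(rownames(kept_big), oracle)
})

test_that("gene z-scores have mean 0, sd 1, are idempotent; constants flagged", {
  set.seed(2)
  mat <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("G", 1:5), paste0("S", 1:10)))
  z <- zscore_genes(mat)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-9)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  expect_equal(unname(zscore_genes(z)), unname(z), tolerance = 1e-12)

  # two-sample gene: symmetric z
  two <- matrix(c(1, 5), 1, 2, dimnames = list("G", c("a", "b")))
  expect_equal(as.vector(zscore_genes(two)), c(-1, 1) / sqrt(2))

  const <- rbind(mat, K = rep(3, 10))
  expect_warning(zc <- zscore_genes(const), "constant gene")
  expect_equal(unname(zc["K", ]), rep(0, 10))
  expect_equal(attr(zc, "flagged_genes"), "K")
})

test_that("geometric signature score follows log2(TPM + 1) arithmetic", {
  tpm <- matrix(c(7, 7, 0, 0, 15, 7), 2, 3,
                dimnames = list(c("GZMA", "PRF1"), c("s1", "s2", "s3")))
  mat <- log2(tpm + 1)
  sc <- cytolytic_score(mat)
  expect_equal(sc$score[sc$sample_id == "s1"], 3)       # log2(8)
  expect_equal(sc$score[sc$sample_id == "s2"], 0)       # all-zero TPM
  # doubling one gene's (TPM+1) raises a 2-gene score by exactly 0.5
  s3 <- sc$score[sc$sample_id == "s3"]
  tpm2 <- tpm; tpm2["GZMA", "s3"] <- 31                 # (15+1)*2 - 1
  sc2 <- cytolytic_score(log2(tpm2 + 1))
  expect_equal(sc2$score[sc2$sample_id == "s3"], s3 + 0.5)

  expect_error(geometric_signature_score(mat, c("GZMA", "NOPE")), "NOPE")
})

test_that("BM subtyping respects the 1.5 boundary (boundary is BM2)", {
  w <- tibble::tibble(gene = c("A", "B"), weight = c(1, 0.5))
  # construct samples whose z-scores are known: 3 samples, gene values chosen
  mat <- matrix(c(0, 0, 1, 1, 2, 2), 2, 3,
                dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  z <- zscore_genes(mat)
  score <- as.numeric(crossprod(w$weight, z))
  bm <- bm_subtype(mat, w, threshold = 1.5)
  expect_equal(bm$bm_score, score)
  expect_equal(bm$bm_subtype, ifelse(score > 1.5, "BM1", "BM2"))

  # all z = 0 -> score 0 -> BM2; exact threshold -> BM2
  flat <- matrix(5, 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
  suppressWarnings(bm0 <- bm_subtype(flat, w))
  expect_equal(bm0$bm_subtype, rep("BM2", 3))
  expect_equal(bm_subtype(mat, w, threshold = max(score))$bm_subtype[which.max(score)],
               "BM2")

  expect_error(bm_subtype(mat, w[0, ]), "empty")
  expect_warning(bm_subtype(mat, tibble::tibble(gene = c("A", "ZZ"),
                                                weight = c(1, 1))), "absent")
})

test_that("synthetic cohorts with an active subtype program separate BM1 from BM2", {
  co <- small_cohort(seed = 19)
  bm <- bm_subtype(co$expression)
  truth <- co$truth$patients
  called_bm1 <- bm$bm_subtype[match(truth$patient_id, bm$sample_id)] == "BM1"
  rate_active <- mean(called_bm1[truth$bm1 == 1])
  rate_inactive <- mean(called_bm1[truth$bm1 == 0])
  expect_gt(rate_active, rate_inactive)
})

test_that("ssGSEA is rank-based and maximal when the set occupies the top ranks", {
  set.seed(3)
  genes <- paste0("G", 1:8)
  mat <- matrix(sample(8), 8, 1, dimnames = list(genes, "s1"))
  geneset_size <- 2
  # enumerate all placements of a 2-gene set; top-expression placement maximal
  placements <- utils::combn(8, geneset_size)
  scores <- apply(placements, 2, function(idx) {
    ssgsea_score(mat, genes[idx])$score
  })
  top_idx <- order(-mat[, 1])[1:geneset_size]
  top_score <- ssgsea_score(mat, genes[top_idx])$score
  expect_equal(max(scores), top_score)
  expect_equal(sum(scores == max(scores)), 1)

  # invariance under strictly monotone transform
  mat2 <- mat; mat2[, 1] <- exp(mat[, 1] / 2)
  expect_equal(ssgsea_score(mat2, genes[c(2, 5)])$score,
               ssgsea_score(mat, genes[c(2, 5)])$score)

  # random placement: mean score near 0 relative to the maximal score
  set.seed(4)
  rand <- replicate(300, ssgsea_score(mat, sample(genes, 2))$score)
  expect_lt(abs(mean(rand)), 0.1 * top_score)

  expect_error(ssgsea_score(mat, c("nope")), "no overlap")
})

test_that("median split sends ties at the median to low", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 2, 3)), c("low", "low", "low", "high"))
  x <- c(5, 1, 3, 2, 4)
  expect_equal(median_split(x), median_split(rev(x))[5:1])
  expect_warning(g <- median_split(c(2, 2, 2)), "identical")
  expect_equal(g, rep("low", 3))
  expect_error(median_split(1), "at least 2")
})

test_that("cytolytic score tracks the immune ssGSEA score on shared-program cohorts", {
  co <- small_cohort(seed = 23)
  cyt <- cytolytic_score(co$expression)
  icr_genes <- default_gene_sets()$icr
  ss <- ssgsea_score(co$expression, icr_genes)
  expect_gt(cor(cyt$score, ss$score, method = "spearman"), 0.5)
})
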