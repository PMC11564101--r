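# direct running-sum oracle: full cumulative walk over all positions
es_oracle <- function(stat_sorted, hit, p = 1) {
  w <- abs(stat_sorted)^p
  n <- length(stat_sorted)
  k <- sum(hit)
  steps <- ifelse(hit, w / sum(w[hit]), -1 / (n - k))
  rs <- cumsum(steps)
  rs[which.max(abs(rs))]
}

test_that("preranked ES equals the hand-computed running sum on a toy ranking", {
  stat <- c(3, 2.5, 2, 1, -0.5, -1, -2, -3)
  names(stat) <- paste0("g", 1:8)
  hit <- names(stat) %in% c("g2", "g4")
  res <- preranked_gsea(stat, list(S = c("g2", "g4")), n_perm = 200,
                        min_size = 2, seed = 1)
  expect_equal(res$es, es_oracle(stat, hit), tolerance = 1e-12)

  # negative-side set
  hit2 <- names(stat) %in% c("g7", "g8")
  res2 <- preranked_gsea(stat, list(S = c("g7", "g8")), n_perm = 200,
                         min_size = 2, seed = 1)
  expect_equal(res2$es, es_oracle(stat, hit2), tolerance = 1e-12)
  expect_lt(res2$es, 0)
})

test_that("unweighted singleton set ranked first attains ES = 1", {
  stat <- stats::setNames(seq(10, 1), paste0("g", 1:10))
  res <- preranked_gsea(stat, list(S = "g1"), n_perm = 100, p = 0,
                        min_size = 1, seed = 2)
  expect_equal(res$es, 1)
})

test_that("ES sign flips when the ranking is negated", {
  set.seed(5)
  stat <- stats::setNames(rnorm(40), paste0("g", 1:40))
  gs <- list(S = paste0("g", sample(40, 8)))
  a <- preranked_gsea(stat, gs, n_perm = 500, seed = 3)
  b <- preranked_gsea(-stat, gs, n_perm = 500, seed = 3)
  expect_equal(a$es, -b$es, tolerance = 1e-12)
})

test_that("GSEA is invariant to gene order given identical statistics and seed", {
  set.seed(6)
  stat <- tibble::tibble(gene = paste0("g", 1:30), statistic = rnorm(30))
  gs <- list(S = paste0("g", 1:6))
  a <- preranked_gsea(stat, gs, n_perm = 300, seed = 9)
  b <- preranked_gsea(stat[sample(30), ], gs, n_perm = 300, seed = 9)
  expect_equal(a, b)
})

test_that("leading edge is a subset of the geneset and adjusted p >= p", {
  set.seed(7)
  stat <- stats::setNames(rnorm(100), paste0("g", 1:100))
  gs <- list(A = paste0("g", 1:10), B = paste0("g", sample(100, 15)))
  res <- preranked_gsea(stat, gs, n_perm = 500, seed = 4)
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
  for (i in seq_len(nrow(res))) {
    expect_true(all(res$leading_edge[[i]] %in% gs[[res$geneset[i]]]))
  }
})

test_that("ES agrees with the fgsea implementation as an independent cross-check", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  stat <- stats::setNames(rnorm(200), paste0("g", 1:200))
  gs <- list(S1 = paste0("g", sample(200, 20)), S2 = paste0("g", sample(200, 8)))
  mine <- preranked_gsea(stat, gs, n_perm = 200, seed = 5)
  sorted <- sort(stat, decreasing = TRUE)
  for (nm in names(gs)) {
    idx <- which(names(sorted) %in% gs[[nm]])
    ref_es <- fgsea::calcGseaStat(sorted, idx, gseaParam = 1)
    expect_equal(mine$es[mine$geneset == nm], ref_es, tolerance = 1e-9,
                 info = nm)
  }
})

test_that("random genesets yield approximately uniform permutation p-values", {
  set.seed(11)
  stat <- stats::setNames(rnorm(300), paste0("g", 1:300))
  ps <- vapply(1:120, function(i) {
    gs <- list(S = sample(names(stat), 10))
    preranked_gsea(stat, gs, n_perm = 250, seed = 100 + i)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the textbook step-up formula", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))
    out <- numeric(m)
    out[o] <- adj
    out
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene ranking by Cox model is deterministic and null-calibrated", {
  set.seed(14)
  n <- 120
  pats <- tibble::tibble(
    patient_id = sprintf("S%03d", 1:n), arm = "triplet",
    os_months = rexp(n, 0.1), os_event = rbinom(n, 1, 0.8)
  )
  mat <- matrix(rnorm(150 * n), 150, n,
                dimnames = list(sprintf("g%03d", 1:150), pats$patient_id))
  rk <- rank_genes_by_model(mat, pats)
  expect_equal(nrow(rk), 150)
  # null z-scores approximately standard normal
  ks <- suppressWarnings(stats::ks.test(rk$statistic, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  # duplicated gene rows get identical statistics
  mat2 <- rbind(mat[1:20, ], COPY = mat[1, ])
  rk2 <- rank_genes_by_model(mat2, pats)
  expect_equal(rk2$statistic[rk2$gene == "COPY"],
               rk2$statistic[rk2$gene == "g001"])
})

test_that("the gene driving the hazard ranks at the top", {
  hits <- vapply(1:5, function(s) {
    set.seed(500 + s)
    n <- 150
    driver <- rnorm(n)
    haz <- 0.08 * exp(0.9 * driver)
    pats <- tibble::tibble(
      patient_id = sprintf("S%03d", 1:n), arm = "triplet",
      os_months = rexp(n, haz), os_event = 1
    )
    mat <- rbind(matrix(rnorm(60 * n), 60, n), DRIVER = driver)
    rownames(mat) <- c(sprintf("g%03d", 1:60), "DRIVER")
    colnames(mat) <- pats$patient_id
    rk <- rank_genes_by_model(mat, pats)
    rk$gene[which.max(abs(rk$statistic))] == "DRIVER"
  }, logical(1))
  expect_gte(sum(hits), 4)
})

test_that("interaction-mode ranking recovers an arm-specific gene effect", {
  set.seed(21)
  n <- 200
  arm <- rep(c("control", "triplet"), each = n / 2)
  gene_x <- rnorm(n)
  haz <- 0.08 * exp(ifelse(arm == "triplet", 0.9, -0.9) * gene_x)
  pats <- tibble::tibble(
    patient_id = sprintf("S%03d", 1:n), arm = arm,
    os_months = rexp(n, haz), os_event = 1
  )
  mat <- rbind(matrix(rnorm(40 * n), 40, n), XGENE = gene_x)
  rownames(mat) <- c(sprintf("g%03d", 1:40), "XGENE")
  colnames(mat) <- pats$patient_id
  rk <- rank_genes_by_model(mat, pats, mode = "interaction",
                            arms = c("control", "triplet"))
  expect_equal(rk$gene[which.max(abs(rk$statistic))], "XGENE")
  expect_error(rank_genes_by_model(mat, pats, mode = "interaction"),
               "exactly two arms")
})
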