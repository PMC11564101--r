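# brute-force set-algebra oracle: statuses from plain set operations on keys
oracle_status <- function(c1d1_keys, eot_keys) {
  list(
    acquired = sort(setdiff(eot_keys, c1d1_keys)),
    maintained = sort(intersect(c1d1_keys, eot_keys)),
    lost = sort(setdiff(c1d1_keys, eot_keys))
  )
}

status_keys <- function(status) {
  key <- ifelse(status$variant_class %in% c("SNV", "indel"),
                paste(status$gene, status$variant_class, status$chrom,
                      status$pos, status$ref, status$alt, sep = ":"),
                paste(status$gene, status$variant_class, sep = ":"))
  split(key, status$status)
}

test_that("status classification follows the paired-presence rules", {
  status <- classify_alteration_status(toy_paired_variants())
  expect_equal(nrow(status), 4)
  get <- function(g) status$status[status$gene == g]
  expect_equal(get("BRAF"), "maintained")
  expect_equal(get("TP53"), "lost")
  expect_equal(get("KRAS"), "acquired")
  expect_equal(get("MET"), "acquired")
  # presence-based: a key in both timepoints is maintained regardless of VAF
  v <- toy_paired_variants()
  v$vaf[v$gene == "BRAF" & v$timepoint == "EoT"] <- 0.0001
  expect_equal(classify_alteration_status(v)$status[
    classify_alteration_status(v)$gene == "BRAF"], "maintained")
})

test_that("status classification equals the set-algebra oracle on random paired sets", {
  set.seed(401)
  for (i in 1:200) {
    calls <- random_paired_calls(n_keys = sample(1:10, 1))
    if (is.null(calls) || nrow(calls) == 0) next
    status <- classify_alteration_status(calls)
    got <- status_keys(status)
    keys_tp <- function(tp) {
      sub <- calls[calls$timepoint == tp, ]
      if (nrow(sub) == 0) return(character())
      ifelse(sub$variant_class %in% c("SNV", "indel"),
             paste(sub$gene, sub$variant_class, sub$chrom, sub$pos, sub$ref,
                   sub$alt, sep = ":"),
             paste(sub$gene, sub$variant_class, sep = ":"))
    }
    want <- oracle_status(keys_tp("C1D1"), keys_tp("EoT"))
    for (s in c("acquired", "maintained", "lost")) {
      expect_equal(sort(got[[s]] %||% character()), want[[s]],
                   info = sprintf("iteration %d status %s", i, s))
    }
    # partition property
    expect_equal(nrow(status),
                 length(union(keys_tp("C1D1"), keys_tp("EoT"))))
  }
})

test_that("duplicate keys within a timepoint error unless collapsed by max VAF", {
  v <- toy_paired_variants()
  dup <- v[1, ]
  dup$vaf <- 0.1
  v2 <- rbind(v, dup)
  expect_error(classify_alteration_status(v2), "duplicate alteration key")
  st <- classify_alteration_status(v2, collapse_duplicates = TRUE)
  expect_equal(st$c1d1_vaf[st$gene == "BRAF"], 0.40)  # max retained
})

test_that("gene precedence maintained > acquired > lost holds for all 7 combinations", {
  combos <- expand.grid(a = 0:1, m = 0:1, l = 0:1)
  combos <- combos[rowSums(combos) > 0, ]
  for (i in seq_len(nrow(combos))) {
    n_a <- combos$a[i]; n_m <- combos$m[i]; n_l <- combos$l[i]
    rec <- tibble::tibble(
      patient_id = "P1", gene = "KRAS",
      status = c(rep("acquired", n_a), rep("maintained", n_m), rep("lost", n_l))
    )
    # invariance to record order
    rec <- rec[sample(nrow(rec)), ]
    g <- aggregate_gene_status(rec)
    want <- if (n_m > 0) "maintained" else if (n_a > 0) "acquired" else "lost"
    expect_equal(g$gene_status, want, info = paste(n_a, n_m, n_l))
    expect_equal(nrow(g), 1)
  }
})

test_that("acquisition frequencies reproduce printed percentages with half-up rounding", {
  fs <- frequency_summary(c(22, 19, 13, 11, 7, 368, 476, 492),
                          c(112, 112, 318, 318, 318, 404, 503, 544))
  expect_equal(fs$percent, c(19.6, 17.0, 4.1, 3.5, 2.2, 91.1, 94.6, 90.4))
  expect_equal(frequency_summary(0, 112)$percent, 0)
  expect_error(frequency_summary(3, 0), "denominator")
  # half away from zero at the boundary
  expect_equal(round_half_up(19.65), 19.7)
  expect_equal(round_half_up(-19.65), -19.7)
})

test_that("evaluable-denominator convention can exclude baseline carriers", {
  gs <- tibble::tibble(
    patient_id = sprintf("P%d", 1:6),
    gene = "MET",
    gene_status = c("acquired", "acquired", "maintained", "lost", "acquired", "maintained")
  )
  with_baseline <- summarize_acquisition_frequency(gs, "MET", denominator = 10)
  expect_equal(with_baseline$count, 3)
  expect_equal(with_baseline$denominator, 10)
  without <- summarize_acquisition_frequency(gs, "MET", denominator = 10,
                                             exclude_baseline = TRUE)
  expect_equal(without$denominator, 7)  # 3 baseline carriers removed
})

test_that("multi-acquired fraction matches the Poisson tail 1 - e^-l (1 + l)", {
  set.seed(55)
  lambda <- 1.3
  n <- 4000
  counts <- rpois(n, lambda)
  gene_records <- tibble::tibble(
    patient_id = rep(sprintf("P%04d", 1:n), counts),
    gene = paste0("G", sequence(counts)),  # distinct genes per patient
    gene_status = "acquired"
  )
  patients <- tibble::tibble(patient_id = sprintf("P%04d", 1:n), arm = "triplet")
  got <- count_multi_acquired(gene_records, patients)
  p_true <- 1 - exp(-lambda) * (1 + lambda)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(got$fraction - p_true), 3 * se)
  # patient with exactly one acquired gene is not counted
  one <- count_multi_acquired(
    tibble::tibble(patient_id = "P1", gene = "KRAS", gene_status = "acquired"),
    tibble::tibble(patient_id = "P1", arm = "control"))
  expect_equal(one$n_multi, 0)
})

test_that("detection concordance reports counts over the stated denominators", {
  a <- tibble::tibble(patient_id = sprintf("P%03d", 1:503),
                      detected = c(rep(TRUE, 476), rep(FALSE, 27)))
  b <- tibble::tibble(patient_id = sprintf("P%03d", 1:404),
                      detected = c(rep(TRUE, 368), rep(FALSE, 36)))
  cc <- detection_concordance(a, b)
  expect_equal(cc$percent[cc$population == "assay_a"], 94.6)
  expect_equal(cc$count[cc$population == "both"], 368)
  expect_equal(cc$denominator[cc$population == "both"], 404)
  expect_equal(cc$percent[cc$population == "both"], 91.1)
  # identical mappings: both-percent equals the single-assay percent
  cc2 <- detection_concordance(b, b)
  expect_equal(cc2$percent[cc2$population == "both"],
               cc2$percent[cc2$population == "assay_a"])
  expect_error(detection_concordance(a, tibble::tibble(patient_id = "ZZZ",
                                                       detected = TRUE)),
               "no patients")
})

# exhaustive hypergeometric enumeration for the two-sided Fisher p
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("2x2 association: cross-ratio OR and Fisher p match oracles", {
  r <- association_2x2(rep(c(1, 0), c(100, 200)),
                       c(rep(1, 10), rep(0, 90), rep(1, 2), rep(0, 198)))
  expect_equal(r$odds_ratio, 11.0)
  expect_false(r$haldane_corrected)

  sym <- association_2x2(rep(c(1, 1, 0, 0), each = 5),
                         rep(c(1, 0, 1, 0), each = 5))
  expect_equal(sym$odds_ratio, 1.0)
  expect_equal(sym$p_value, 1.0)

  # Haldane correction on a single zero cell, flagged
  hz <- association_2x2(rep(c(1, 0), c(10, 10)),
                        c(rep(1, 10), rep(1, 3), rep(0, 7)))
  expect_true(hz$haldane_corrected)
  expect_equal(hz$odds_ratio, (10.5 * 7.5) / (0.5 * 3.5))

  set.seed(77)
  for (i in 1:50) {
    cells <- as.vector(rmultinom(1, size = sample(4:30, 1), prob = rep(1/4, 4)))
    e <- rep(c(1, 1, 0, 0), cells)
    o <- rep(c(1, 0, 1, 0), cells)
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0 ||
        sum(cells[c(1, 3)]) == 0 || sum(cells[c(2, 4)]) == 0) next
    got <- association_2x2(e, o)
    expect_equal(got$p_value, fisher_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10, info = paste(cells, collapse = ","))
  }
})
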