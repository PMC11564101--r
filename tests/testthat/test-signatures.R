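test_that("channel labels are the canonical 96 set", {
  ch <- sbs_channels()
  expect_length(ch, 96)
  expect_equal(anyDuplicated(ch), 0)
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", ch)))
  expect_equal(ch[1], "A[C>A]A")
})

test_that("trinucleotide channels are strand-normalised", {
  genome <- c(c1 = "AACAT", c2 = "ATGAT")
  # pyrimidine reference: identity mapping
  expect_equal(trinucleotide_channel("c1", 3L, "C", "T", genome), "A[C>T]A")
  # purine reference: reverse complement of triplet and alt
  # c2 context TGA with G>A -> revcomp(TGA) = TCA, alt A -> T: T[C>T]A
  expect_equal(trinucleotide_channel("c2", 3L, "G", "A", genome), "T[C>T]A")
  # reference mismatch errors with the position named
  expect_error(trinucleotide_channel("c1", 3L, "G", "A", genome),
               "reference mismatch at c1:3")
  # contig edge is skipped with a warning, not an error
  expect_warning(res <- trinucleotide_channel("c1", 1L, "A", "G", genome),
                 "contig edge")
  expect_true(is.na(res))
})

test_that("a substitution and its reverse complement map to the same channel", {
  genome <- synthetic_reference_genome(1, 2000)
  rc_genome <- c(ctg1 = revcomp(genome[["ctg1"]]))
  n <- nchar(genome[["ctg1"]])
  set.seed(10)
  pos <- sample(2:(n - 1), 60)
  ref <- substr(rep(genome[["ctg1"]], 60), pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "x")
  fwd <- trinucleotide_channel(rep("ctg1", 60), pos, ref, alt, genome)
  rev_pos <- n - pos + 1L
  rev <- trinucleotide_channel(rep("ctg1", 60), rev_pos,
                               chartr("ACGT", "TGCA", ref),
                               chartr("ACGT", "TGCA", alt), rc_genome)
  expect_equal(fwd, rev)
})

test_that("spectra count SNVs only and sum to the usable SNV count", {
  co <- small_cohort(seed = 2)
  spec <- build_spectrum(co$variants, co$config$genome)
  n_snv <- sum(co$variants$variant_class == "SNV")
  expect_equal(sum(spec$count), n_snv)
  expect_equal(nrow(spec), 96)
})

test_that("pooling applies the baseline >1% and acquired C1D1=0 filters", {
  v <- tibble::tribble(
    ~patient_id, ~timepoint, ~gene, ~variant_class, ~chrom, ~pos, ~ref, ~alt, ~vaf, ~protein_change,
    "P1", "C1D1", "A1", "SNV", "ctg1", 10L, "C", "T", 0.005, NA,  # below 1%: no pool
    "P1", "EoT",  "A1", "SNV", "ctg1", 10L, "C", "T", 0.050, NA,
    "P1", "C1D1", "A2", "SNV", "ctg1", 20L, "C", "T", 0.020, NA,  # baseline pool
    "P1", "EoT",  "A2", "SNV", "ctg1", 20L, "C", "T", 0.030, NA,
    "P1", "EoT",  "A3", "SNV", "ctg1", 30L, "C", "T", 0.002, NA   # acquired pool
  )
  p <- tibble::tibble(patient_id = "P1", arm = "triplet")
  pooled <- pool_variants(v, p)
  expect_equal(pooled$origin[pooled$gene == "A2"], "baseline")
  expect_equal(pooled$origin[pooled$gene == "A3"], "acquired")
  expect_false("A1" %in% pooled$gene)  # in neither pool
  # partition: never both pools
  expect_equal(anyDuplicated(pooled[c("patient_id", "gene")]), 0)
})

test_that("NNLS refit is exact for spectra inside the reference cone", {
  ref <- synthetic_signature_reference()
  counts <- 1000 * ref[, "SBS17blike"]
  fit <- refit_exposures(counts, ref, prune_below = 0)
  expect_lt(fit$reconstruction_error, 1e-6)
  expect_equal(unname(fit$exposures["SBS17blike"]), 1000, tolerance = 1e-4)
  expect_lt(sum(fit$exposures) - 1000, 1e-3)
  expect_gt(fit$cosine_similarity, 1 - 1e-9)

  mix <- 600 * ref[, "SBS1like"] + 400 * ref[, "SBS5like"]
  fit2 <- refit_exposures(mix, ref, prune_below = 0)
  expect_lt(fit2$reconstruction_error, 1e-8)
  expect_equal(unname(fit2$proportion_raw[c("SBS1like", "SBS5like")]),
               c(0.6, 0.4), tolerance = 1e-6)

  expect_error(refit_exposures(rep(0, 96), ref), "zero spectrum")
})

test_that("multinomial spectra recover mixing proportions within 0.05", {
  ref <- synthetic_signature_reference()
  p <- 0.7 * ref[, "SBS15like"] + 0.3 * ref[, "SBS17alike"]
  set.seed(606)
  counts <- as.vector(rmultinom(1, 5000, p))
  names(counts) <- rownames(ref)
  fit <- refit_exposures(counts, ref)
  expect_lt(abs(fit$proportion[["SBS15like"]] - 0.7), 0.05)
  expect_lt(abs(fit$proportion[["SBS17alike"]] - 0.3), 0.05)
})

test_that("NNLS matches a simplex grid oracle on 2-signature problems", {
  ref <- synthetic_signature_reference()[, c("SBS1like", "SBS17blike")]
  set.seed(17)
  p_true <- 0.35 * ref[, 1] + 0.65 * ref[, 2]
  counts <- as.vector(rmultinom(1, 800, p_true))
  fit <- refit_exposures(stats::setNames(counts, rownames(ref)), ref,
                         prune_below = 0)
  got_q <- fit$proportion_raw[[1]]

  # grid over the mixing fraction q at 0.001 resolution; scale solved in
  # closed form for each direction
  qs <- seq(0, 1, by = 0.001)
  sse <- vapply(qs, function(q) {
    d <- q * ref[, 1] + (1 - q) * ref[, 2]
    s <- max(0, sum(counts * d) / sum(d^2))
    sum((counts - s * d)^2)
  }, numeric(1))
  q_grid <- qs[which.min(sse)]
  expect_lt(abs(got_q - q_grid), 0.002)
  # NNLS residual is never worse than the grid optimum
  expect_lte(fit$reconstruction_error^2 * sum(counts^2), min(sse) + 1e-6)
})

test_that("sub-1% exposures are zeroed in reported proportions but kept raw", {
  ref <- synthetic_signature_reference()
  counts <- 2000 * (0.995 * ref[, "SBS5like"] + 0.005 * ref[, "SBS1like"])
  fit <- refit_exposures(counts, ref)
  expect_equal(fit$proportion[["SBS1like"]], 0)
  expect_gt(fit$proportion_raw[["SBS1like"]], 0)
  expect_equal(sum(fit$proportion), 1)
})

test_that("group-wise refit finds treatment-specific acquired signatures", {
  co <- simulate_cohort(two_arm_config(seed = 12, n = 120))
  out <- refit_group_exposures(co$variants, co$patients,
                               co$config$genome, co$config$reference)
  acq_trip <- out %>% filter(arm == "triplet", origin == "acquired")
  expect_gt(acq_trip$proportion[acq_trip$signature == "SBS17blike"], 0.5)
  base_trip <- out %>% filter(arm == "triplet", origin == "baseline")
  expect_lt(base_trip$proportion[base_trip$signature == "SBS17blike"], 0.2)
})
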