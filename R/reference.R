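# Bundled synthetic reference assets. Everything here is generated
# deterministically in code: a small synthetic genome for trinucleotide
# contexts, a synthetic SBS reference matrix for refitting tests and
# simulations, and a synthetic stand-in for the 44-gene weighted subtyping
# table (the published weights belong to a third-party publication and are
# not shipped).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic reference genome for trinucleotide contexts
#'
#' A few kilobases of deterministic random sequence, enough that every one of
#' the 32 canonical pyrimidine-centric trinucleotide contexts occurs many
#' times. Used by the cohort simulator to place SNVs with prescribed
#' substitution channels and by the channel mapper in tests. The sequence is
#' a fixed function of its arguments (internal fixed seed), so simulator and
#' analysis always agree on contexts.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bases.
#' @return named character vector of contig sequences (`ctg1`, `ctg2`, ...).
#' @export
synthetic_reference_genome <- function(n_contigs = 3, contig_length = 8000) {
  stopifnot(n_contigs >= 1, contig_length >= 100)
  with_seed(990137, {
    seqs <- vapply(seq_len(n_contigs), function(i) {
      paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE), collapse = "")
    }, character(1))
  })
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  seqs
}

# canonical 32 contexts: X(C|T)Y
canonical_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(c("C", "T"), function(m) {
    as.vector(t(outer(bases, bases, function(x, y) paste0(x, m, y))))
  }))
}

# index every interior genome position by its canonical (pyrimidine-centric)
# trinucleotide context; purine-centred positions are recorded with
# purine = TRUE so channel-directed placement can emit the correct strand
# representation
context_index <- function(genome) {
  idx <- purrr::map_dfr(names(genome), function(ctg) {
    s <- genome[[ctg]]
    n <- nchar(s)
    pos <- 2:(n - 1)
    triplet <- substr(rep(s, length(pos)), pos - 1, pos + 1)
    centre <- substr(triplet, 2, 2)
    purine <- centre %in% c("A", "G")
    canon <- triplet
    canon[purine] <- revcomp(canon[purine])
    tibble(chrom = ctg, pos = pos, context = canon, purine = purine)
  })
  split(idx[c("chrom", "pos", "purine")], idx$context)
}

#' Synthetic SBS signature reference
#'
#' Five synthetic single-base-substitution signatures with shapes that echo
#' well-known catalogue entries so simulated cohorts behave like the real
#' phenomenon, without claiming the catalogue's values: a CpG C>T
#' deamination-like signature (`SBS1like`), a flat clock-like signature
#' (`SBS5like`), a broad C>T mismatch-repair-like signature (`SBS15like`),
#' and two oxidative-damage-like signatures concentrated in T>C
#' (`SBS17alike`) and T>G (`SBS17blike`). All channels have nonzero
#' probability; columns sum to 1.
#'
#' @return a validated 96 x 5 signature reference matrix (see
#'   [sbs_reference()]).
#' @export
synthetic_signature_reference <- function() {
  channels <- sbs_channels()
  sub <- sub(".*\\[(.*)\\].*", "\\1", channels)
  flank5 <- substr(channels, 1, 1)
  flank3 <- substr(channels, 7, 7)

  base <- rep(0.05 / 96, 96)  # smoothing floor keeps every channel observable
  sigs <- list(
    SBS1like  = base + 0.95 * (sub == "C>T" & flank3 == "G") / 4,
    SBS5like  = rep(1 / 96, 96),
    SBS15like = base + 0.95 * (sub == "C>T") / 16,
    SBS17alike = base + 0.95 * (sub == "T>C" & flank5 %in% c("C", "T")) / 8,
    SBS17blike = base + 0.95 * (sub == "T>G" & flank3 == "T") / 4
  )
  probs <- vapply(sigs, function(p) p / sum(p), numeric(96))
  rownames(probs) <- channels
  sbs_reference(probs)
}

#' Synthetic 44-gene subtype weight table
#'
#' A stand-in for the published 44-gene weighted z-score subtyping table
#' (the real weights come from a third-party publication and are supplied by
#' the user as a TSV in practice). Gene symbols are synthetic (`BMS01` ...)
#' and weights are deterministic, mixing positive and negative contributions
#' so the weighted-sum machinery and the 1.5 decision boundary are fully
#' exercised.
#'
#' @return tibble with columns `gene` and `weight` (44 rows).
#' @export
synthetic_bm_weights <- function() {
  k <- 44
  gene <- sprintf("BMS%02d", seq_len(k))
  weight <- round(0.08 + 0.22 * (seq_len(k) %% 7) / 6, 3) * rep_len(c(1, -1), k)
  tibble(gene = gene, weight = weight)
}

#' Default immune and proliferation gene assets
#'
#' Small gene lists used by the scoring functions and the cohort simulator:
#' the two-gene cytolytic pair (GZMA, PRF1), the CD8 pair (CD8A, CD8B), a
#' 20-gene immunologic-constant-of-rejection style Th1/cytotoxic list, and a
#' cell-cycle/proliferation list anchored on CCNB1 and CDK1.
#'
#' @return named list of character vectors.
#' @export
default_gene_sets <- function() {
  list(
    cytolytic = c("GZMA", "PRF1"),
    cd8 = c("CD8A", "CD8B"),
    icr = c("IFNG", "STAT1", "IRF1", "IL12B", "TBX21", "CD8A", "CD8B",
            "CXCL9", "CXCL10", "CCL5", "GZMA", "GZMB", "GZMH", "PRF1",
            "GNLY", "CD274", "CTLA4", "FOXP3", "IDO1", "PDCD1"),
    cell_cycle = c("CCNB1", "CDK1", "CCNA2", "CDC20", "PLK1", "BUB1",
                   "AURKA", "MKI67", "TOP2A", "CCNE1", "CDK4", "E2F1")
  )
}
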