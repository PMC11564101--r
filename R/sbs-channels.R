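# 96-channel single-base-substitution (SBS) machinery: canonical channel
# labels, strand normalisation and spectrum construction.

#' Canonical 96 SBS channel labels
#'
#' Pyrimidine-centric convention: six substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G), each in 16 trinucleotide contexts, labelled `X[R>A]Y`.
#' Substitutions observed with a purine reference are mapped onto these
#' channels by reverse complement. Order is substitution-major, then 5'
#' flank, then 3' flank (the conventional catalogue order).
#'
#' @return character vector of the 96 labels.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    ref <- substr(s, 1, 1)
    as.vector(t(outer(bases, bases, function(x, y) paste0(x, "[", s, "]", y))))
  }))
}

#' Reverse complement of a DNA string vector
#'
#' @param x character vector of A/C/G/T strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), character(1))
}

#' Map SNVs to trinucleotide substitution channels
#'
#' Looks up the trinucleotide context of each single-nucleotide variant in a
#' reference sequence and assigns the canonical pyrimidine-centric channel.
#' Purine-reference substitutions are reverse-complemented (context and
#' alternate allele) before labelling, so a substitution and its reverse
#' complement always map to the same channel.
#'
#' @param chrom,pos,ref,alt vectors describing SNVs (1-based positions).
#' @param genome named character vector of contig sequences (see
#'   [read_fasta()]).
#' @return character vector of channel labels; `NA` (with a warning) for
#'   variants at a contig edge where a flanking base is unavailable.
#' @export
trinucleotide_channel <- function(chrom, pos, ref, alt, genome) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  bad_contig <- setdiff(unique(chrom), names(genome))
  if (length(bad_contig) > 0) {
    abort(sprintf("contig(s) not in reference: %s", paste(bad_contig, collapse = ", ")))
  }
  out <- rep(NA_character_, n)
  lens <- nchar(genome)
  edge <- pos < 2 | pos > (lens[chrom] - 1)
  if (any(edge)) {
    warn(sprintf("%d SNV(s) at contig edge skipped (no flanking base)", sum(edge)))
  }
  idx <- which(!edge)
  if (length(idx) == 0) return(out)
  triplet <- substr(genome[chrom[idx]], pos[idx] - 1, pos[idx] + 1)
  ref_obs <- substr(triplet, 2, 2)
  mism <- which(ref_obs != ref[idx])
  if (length(mism) > 0) {
    i <- idx[mism[1]]
    abort(sprintf("reference mismatch at %s:%d: variant ref %s, reference sequence has %s",
                  chrom[i], pos[i], ref[i], ref_obs[mism[1]]))
  }
  a <- alt[idx]
  purine <- ref[idx] %in% c("A", "G")
  triplet[purine] <- revcomp(triplet[purine])
  a[purine] <- chartr("ACGT", "TGCA", a[purine])
  out[idx] <- paste0(substr(triplet, 1, 1), "[", substr(triplet, 2, 2), ">", a,
                     "]", substr(triplet, 3, 3))
  out
}

#' Build 96-channel spectra from SNV tables
#'
#' Counts SNVs per trinucleotide substitution channel, optionally within
#' groups (e.g. arm x origin from [pool_variants()]). Non-SNV rows are
#' ignored: SBS signatures are substitution-defined, so indels,
#' amplifications and fusions carry no channel.
#'
#' @param variants data frame with `variant_class`, `chrom`, `pos`, `ref`,
#'   `alt` and any grouping columns.
#' @param genome named character vector of contig sequences.
#' @param by character vector of grouping column names (default none: one
#'   pooled spectrum).
#' @return tibble with grouping columns, `channel` (all 96, in canonical
#'   order) and `count`; total count per group equals the number of usable
#'   SNVs.
#' @export
build_spectrum <- function(variants, genome, by = character()) {
  variants <- as_tibble(variants)
  assert_cols(variants, c("variant_class", "chrom", "pos", "ref", "alt"), "variant table")
  snv <- variants %>% filter(.data$variant_class == "SNV")
  channels <- sbs_channels()
  if (nrow(snv) > 0) {
    snv$channel <- trinucleotide_channel(snv$chrom, snv$pos, snv$ref, snv$alt, genome)
    snv <- snv %>% filter(!is.na(.data$channel))
  } else {
    snv$channel <- character(0)
  }
  grid <- if (length(by) == 0) {
    tibble(channel = channels)
  } else {
    groups <- variants %>% distinct(across(all_of(by)))
    tidyr::crossing(groups, channel = channels)
  }
  counts <- snv %>%
    group_by(across(all_of(c(by, "channel")))) %>%
    summarise(count = dplyr::n(), .groups = "drop")
  grid %>%
    left_join(counts, by = c(by, "channel")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L),
           channel = factor(.data$channel, levels = channels)) %>%
    arrange(across(all_of(by)), .data$channel) %>%
    mutate(channel = as.character(.data$channel))
}
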