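# Readers/writers for the tabular interchange formats the pipeline touches.
# All readers validate and reject malformed fields rather than coercing;
# writer/reader pairs are inverse on valid data.

variant_cols <- c("patient_id", "timepoint", "gene", "variant_class",
                  "chrom", "pos", "ref", "alt", "vaf", "protein_change")

#' Validate a somatic variant call table
#'
#' Checks the invariants of the variant-call schema: one row per alteration
#' observation in one sample, with `timepoint` in `C1D1`/`EoT`,
#' `variant_class` in `SNV`/`indel`/`amplification`/`fusion`, VAF stored as a
#' fraction in \[0, 1\] (absent for amplifications and fusions, which carry no
#' allele frequency), and coordinate fields present for SNV/indel only. SNVs
#' must have single-base `ref != alt` and `pos >= 1`.
#'
#' @param variants a data frame of variant calls.
#' @return the validated table as a tibble (invisibly usable in pipes).
#' @export
validate_variant_table <- function(variants) {
  variants <- as_tibble(variants)
  assert_cols(variants, setdiff(variant_cols, "protein_change"), "variant table")
  if (!"protein_change" %in% names(variants)) {
    variants$protein_change <- NA_character_
  }
  fail_row <- function(idx, msg) {
    abort(sprintf("variant table row %d: %s", idx, msg))
  }
  assert_enum(variants$timepoint, timepoint_levels, "timepoint")
  assert_enum(variants$variant_class, variant_class_levels, "variant_class")

  bad_vaf <- which(!is.na(variants$vaf) & (variants$vaf < 0 | variants$vaf > 1))
  if (length(bad_vaf) > 0) {
    fail_row(bad_vaf[1], sprintf("vaf %.4g outside [0, 1] (VAFs are fractions, not percents)",
                                 variants$vaf[bad_vaf[1]]))
  }
  coord <- variants$variant_class %in% c("SNV", "indel")
  bad_pos <- which(coord & (is.na(variants$pos) | variants$pos < 1))
  if (length(bad_pos) > 0) fail_row(bad_pos[1], "SNV/indel requires pos >= 1")
  bad_chrom <- which(coord & (is.na(variants$chrom) | variants$chrom == ""))
  if (length(bad_chrom) > 0) fail_row(bad_chrom[1], "SNV/indel requires chrom")

  snv <- variants$variant_class == "SNV"
  bases <- c("A", "C", "G", "T")
  bad_snv <- which(snv & (!variants$ref %in% bases | !variants$alt %in% bases |
                            variants$ref == variants$alt))
  if (length(bad_snv) > 0) {
    fail_row(bad_snv[1], "SNV requires single-base ref and alt with ref != alt")
  }
  bad_na <- which(is.na(variants$patient_id) | is.na(variants$gene))
  if (length(bad_na) > 0) fail_row(bad_na[1], "patient_id and gene are required")
  variants[variant_cols]
}

#' Read / write a variant call table (TSV)
#'
#' Tab-separated with the columns `patient_id`, `timepoint`, `gene`,
#' `variant_class`, `chrom`, `pos`, `ref`, `alt`, `vaf`, `protein_change`.
#' This dialect is a documented stand-in for vendor ctDNA panel exports,
#' whose schemas are proprietary.
#'
#' @param path file path.
#' @return `read_variant_table()` returns a validated tibble.
#' @export
read_variant_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timepoint = readr::col_character(),
    gene = readr::col_character(),
    variant_class = readr::col_character(),
    chrom = readr::col_character(),
    pos = readr::col_integer(),
    ref = readr::col_character(),
    alt = readr::col_character(),
    vaf = readr::col_double(),
    protein_change = readr::col_character()
  ), progress = FALSE)
  validate_variant_table(df)
}

#' @rdname read_variant_table
#' @param variants validated variant table.
#' @export
write_variant_table <- function(variants, path) {
  variants <- validate_variant_table(variants)
  readr::write_tsv(variants, path, progress = FALSE)
  invisible(path)
}

#' Read / write a patient metadata table (TSV)
#'
#' One row per patient: `patient_id`, `arm` (triplet/doublet/control),
#' `time_on_treatment_months`, `os_months`, `os_event`, `pfs_months`,
#' `pfs_event`, plus any additional covariate columns (kept as-is).
#'
#' @param path file path.
#' @return a validated tibble.
#' @export
read_patient_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_patient_table(df)
}

#' @rdname read_patient_table
#' @param patients patient table.
#' @export
write_patient_table <- function(patients, path) {
  patients <- validate_patient_table(patients)
  readr::write_tsv(patients, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_patient_table
#' @export
validate_patient_table <- function(patients) {
  patients <- as_tibble(patients)
  assert_cols(patients, c("patient_id", "arm", "time_on_treatment_months",
                          "os_months", "os_event", "pfs_months", "pfs_event"),
              "patient table")
  assert_enum(patients$arm, arm_levels, "arm")
  if (anyDuplicated(patients$patient_id) > 0) {
    abort("duplicate patient_id in patient table")
  }
  for (col in c("os_event", "pfs_event")) {
    if (!all(patients[[col]] %in% c(0, 1))) {
      abort(sprintf("%s must be 0/1", col))
    }
  }
  for (col in c("os_months", "pfs_months")) {
    if (any(patients[[col]] < 0, na.rm = TRUE)) abort(sprintf("%s must be nonnegative", col))
  }
  if (any(patients$time_on_treatment_months <= 0, na.rm = TRUE)) {
    abort("time_on_treatment_months must be positive")
  }
  patients
}

#' Read / write an expression matrix (TSV)
#'
#' First column `gene`, remaining columns samples; values are expected on the
#' log2(TPM + 1) scale. Duplicate gene symbols and non-finite values are
#' rejected.
#'
#' @param path file path.
#' @return a numeric matrix with genes as rownames and samples as colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "gene") abort("expression TSV must have 'gene' as first column")
  if (anyDuplicated(df$gene) > 0) {
    dup <- df$gene[duplicated(df$gene)][1]
    abort(sprintf("duplicate gene symbol in expression matrix: %s", dup))
  }
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$gene
  if (!is.numeric(mat) || any(!is.finite(mat))) {
    abort("expression matrix contains non-numeric or non-finite values")
  }
  mat
}

#' @rdname read_expression_matrix
#' @param mat genes-by-samples numeric matrix with dimnames.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- tibble(gene = rownames(mat)) %>%
    dplyr::bind_cols(as_tibble(mat))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write genesets in GMT format
#'
#' Standard GMT: one geneset per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return a named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    abort(sprintf("GMT line %d has fewer than 3 fields (name, description, >=1 member)", bad[1]))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names(sets)) > 0) abort("duplicate geneset name in GMT")
  sets
}

#' @rdname read_gmt
#' @param genesets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(genesets, path, descriptions = NULL) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  descriptions <- descriptions %||% rep("na", length(genesets))
  lines <- vapply(seq_along(genesets), function(i) {
    paste(c(names(genesets)[i], descriptions[i], genesets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct / read / write a 96-channel signature reference
#'
#' A signature reference is a 96 x K column-stochastic matrix: rows are the
#' canonical pyrimidine-centric trinucleotide substitution channels (see
#' [sbs_channels()]), columns are signature ids, and each column sums to 1.
#'
#' @param probs numeric matrix, 96 channels x K signatures; rownames must be
#'   the canonical channel labels (any order), colnames the signature ids.
#' @return a validated 96 x K matrix in canonical channel order.
#' @export
sbs_reference <- function(probs) {
  stopifnot(is.matrix(probs))
  channels <- sbs_channels()
  if (is.null(rownames(probs)) || !setequal(rownames(probs), channels) ||
      nrow(probs) != 96) {
    abort("signature reference must have the 96 canonical channel labels as rownames")
  }
  if (is.null(colnames(probs)) || anyDuplicated(colnames(probs)) > 0) {
    abort("signature reference needs unique signature ids as colnames")
  }
  if (any(probs < 0)) abort("signature probabilities must be nonnegative")
  sums <- colSums(probs)
  bad <- which(abs(sums - 1) > 1e-6)
  if (length(bad) > 0) {
    abort(sprintf("signature column '%s' sums to %.6g, not 1", colnames(probs)[bad[1]], sums[bad[1]]))
  }
  probs[channels, , drop = FALSE]
}

#' @rdname sbs_reference
#' @param path file path to a TSV with first column `channel` and one column
#'   per signature.
#' @export
read_signature_reference <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "channel") abort("signature TSV must have 'channel' as first column")
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$channel
  sbs_reference(mat)
}

#' @rdname sbs_reference
#' @param reference validated reference matrix.
#' @export
write_signature_reference <- function(reference, path) {
  reference <- sbs_reference(reference)
  df <- tibble(channel = rownames(reference)) %>%
    dplyr::bind_cols(as_tibble(reference))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings returning plain named character vectors
#' (contig name, first whitespace-delimited token of the header, to
#' uppercase sequence), which is all the trinucleotide-context machinery
#' needs.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(names(out)) > 0) abort("duplicate contig name in FASTA")
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
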