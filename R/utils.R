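# internal helpers shared across modules

#' Round half away from zero
#'
#' Frequency tables report percentages rounded to one decimal with halves
#' rounded away from zero (so 19.65 -> 19.7), matching how clinical count
#' summaries are conventionally printed. Base R's `round()` rounds half to
#' even and would disagree on exact .x5 values.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 1).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x))
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

arm_levels <- c("triplet", "doublet", "control")
timepoint_levels <- c("C1D1", "EoT")
variant_class_levels <- c("SNV", "indel", "amplification", "fusion")
status_levels <- c("acquired", "maintained", "lost")

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    abort(sprintf("invalid %s value(s): %s (allowed: %s)",
                  what, paste(bad, collapse = ", "),
                  paste(levels, collapse = ", ")))
  }
  invisible(x)
}

# alteration identity: coordinates for SNV/indel, gene-level for
# amplification/fusion (these carry no substitution coordinates)
alteration_key <- function(df) {
  assert_cols(df, c("gene", "variant_class"), "variant table")
  coord <- df$variant_class %in% c("SNV", "indel")
  key <- ifelse(
    coord,
    paste(df$gene, df$variant_class, df$chrom, df$pos, df$ref, df$alt, sep = ":"),
    paste(df$gene, df$variant_class, sep = ":")
  )
  key
}

`%||%` <- rlang::`%||%`
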