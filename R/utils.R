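## Internal helpers shared across modules.

#' Canonical chromosome ordering used for all deterministic output sorting
#'
#' Autosomes in numeric order, then X, Y, MT, then anything else
#' lexicographically. Chromosome names are used without a "chr" prefix
#' everywhere in the package (the prefix is stripped on read).
#' @param contig character vector of contig names
#' @return integer rank usable as a sort key
#' @keywords internal
contigRank <- function(contig) {
  contig <- normalizeContig(contig)
  special <- c(X = 23L, Y = 24L, MT = 25L)
  rank <- suppressWarnings(as.integer(contig))
  rank[contig %in% names(special)] <- special[contig[contig %in% names(special)]]
  # unknown contigs sort after the named ones, alphabetically
  unknown <- is.na(rank)
  if (any(unknown)) {
    rank[unknown] <- 25L + match(contig[unknown], sort(unique(contig[unknown])))
  }
  rank
}

#' Strip "chr" prefixes and map mitochondrial aliases to "MT"
#' @keywords internal
normalizeContig <- function(contig) {
  contig <- sub("^chr", "", as.character(contig), ignore.case = TRUE)
  contig[contig %in% c("M", "mt", "m")] <- "MT"
  contig
}

#' Variant key "contig:pos:ref:alt"
#' @keywords internal
variantKey <- function(contig, pos, ref, alt) {
  paste(normalizeContig(contig), pos, ref, alt, sep = ":")
}

#' Round half away from zero (commercial rounding)
#'
#' `base::round()` rounds half to even; reported percentages and means use
#' half-up at the printed precision.
#' @param x numeric
#' @param digits decimal places
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a denominator, half-up rounded
#' @param num numerator count
#' @param den denominator count
#' @param digits decimal places of the printed percentage
#' @export
derivedPercent <- function(num, den, digits = 1) {
  if (den == 0) return(NA_real_)
  roundHalfUp(100 * num / den, digits)
}

#' Mean variants per case, half-up rounded to 2 decimals
#' @param n_variants total variant count
#' @param n_cases number of cases carrying them
#' @export
derivedMean <- function(n_variants, n_cases) {
  if (n_cases == 0) return(NA_real_)
  roundHalfUp(n_variants / n_cases, 2)
}

## order index for (contig, pos, ref, alt) with the canonical contig ranking
variantOrder <- function(contig, pos, ref, alt) {
  order(contigRank(contig), pos, ref, alt, method = "radix")
}

## order for candidate rows: case id first, then variant key
candidateOrder <- function(case_id, contig, pos, ref, alt) {
  order(case_id, contigRank(contig), pos, ref, alt, method = "radix")
}

## semicolon-joined string for list columns in the report, "" for empty
joinField <- function(x) {
  if (length(x) == 0 || all(is.na(x))) return("")
  paste(x[!is.na(x)], collapse = ";")
}

## format a frequency for the report: 6 significant digits, "" for NA
formatFreq <- function(x) {
  ifelse(is.na(x), "", formatC(signif(x, 6), format = "g", digits = 6))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
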