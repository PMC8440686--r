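## The candidate table: one row per (case, variant) surviving the filter
## stack, carrying every report annotation. Written as TSV with "##" header
## comment lines stamping knowledge-table versions. An MS-Excel mirror is
## deliberately not produced: the TSV is the testable, diff-able contract.

#' The fixed candidate-table column contract
#'
#' 31 columns, stable order. Frequencies are printed to 6 significant digits;
#' list-valued fields are semicolon-joined.
#' @return character vector of column names
#' @export
candidateTableColumns <- function() {
  c("case_id", "family_id", "ern", "contig", "pos", "ref", "alt", "gene",
    "consequence", "genotype_index", "genotypes_family", "allelic_fraction",
    "af_external", "af_internal", "clinical_significance", "condition",
    "first_plp_year", "omim_associations", "inheritance_modes",
    "first_association_year", "pli", "oe", "acmg_class", "acmg_criteria",
    "phenotype_terms", "consanguinity_reported", "consanguinity_inferred",
    "segregation", "roh_region", "cnv_check", "status")
}

candidateStatusVocabulary <- function() {
  c("candidate", "prioritised", "solved", "under_evaluation",
    "het_AR_candidate", "rejected")
}

#' Write the candidate table
#'
#' Rows are sorted deterministically by (case id, contig, pos, ref, alt).
#' Knowledge-table version stamps are written as `##` comment lines ahead of
#' the header so distributed copies are traceable to their annotation
#' snapshot.
#'
#' @param rows candidate data.frame (columns of [candidateTableColumns()])
#' @param path output TSV path
#' @param versions optional named character of knowledge-table versions
#' @return `path`, invisibly
#' @export
writeCandidateTable <- function(rows, path, versions = character()) {
  cols <- candidateTableColumns()
  stopifnot(all(cols %in% names(rows)))
  if (nrow(rows) && !all(rows$status %in% candidateStatusVocabulary())) {
    stop("candidate row with status outside the closed vocabulary", call. = FALSE)
  }
  rows <- rows[candidateOrder(rows$case_id, rows$contig, rows$pos,
                              rows$ref, rows$alt), cols, drop = FALSE]
  out <- rows
  for (fc in c("allelic_fraction", "af_external", "af_internal", "pli", "oe")) {
    out[[fc]] <- formatFreq(rows[[fc]])
  }
  for (ic in c("first_plp_year", "first_association_year")) {
    out[[ic]] <- ifelse(is.na(rows[[ic]]), "", as.character(rows[[ic]]))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(versions)) {
    writeLines(sprintf("## %s=%s", nm, versions[[nm]]), con)
  }
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a candidate table written by [writeCandidateTable()]
#' @param path TSV path
#' @return data.frame with typed columns; `##` version stamps are attached as
#'   the `"versions"` attribute
#' @export
readCandidateTable <- function(path) {
  lines <- readLines(path)
  stamps <- grep("^## ", lines, value = TRUE)
  lines <- lines[!grepl("^## ", lines)]
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", check.names = FALSE)
  if (!identical(names(df), candidateTableColumns())) {
    stop("candidate table header does not match the column contract", call. = FALSE)
  }
  for (nc in c("allelic_fraction", "af_external", "af_internal", "pli", "oe")) {
    df[[nc]] <- suppressWarnings(as.numeric(ifelse(df[[nc]] == "", NA, df[[nc]])))
  }
  for (ic in c("pos", "genotype_index", "first_plp_year", "first_association_year")) {
    df[[ic]] <- suppressWarnings(as.integer(ifelse(df[[ic]] == "", NA, df[[ic]])))
  }
  if (length(stamps)) {
    kv <- sub("^## ", "", stamps)
    attr(df, "versions") <- stats::setNames(sub("^[^=]*=", "", kv),
                                            sub("=.*$", "", kv))
  }
  df
}
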