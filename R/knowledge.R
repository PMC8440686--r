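## Knowledge tables: ClinVar-style assertions, external population allele
## frequencies, gene-disease associations with first-report years, gene
## constraint scores (pLI / o-e) and precomputed ACMG classes. All joins are
## exact: by (contig,pos,ref,alt) key for variant-level tables, by uppercase
## gene symbol for gene-level tables.

SIGNIFICANCE_VOCAB <- c("pathogenic", "likely_pathogenic", "vus",
                        "likely_benign", "benign", "conflicting")

#' Load and join the knowledge tables
#'
#' Duplicate variant keys in the assertion table are collapsed
#' deterministically (order-independent): concordant pathogenic-direction
#' assertions collapse to the most severe of them, concordant benign-direction
#' to the most severe benign label, anything mixed to `conflicting`. A
#' separate `any_plp` flag records whether any assertion was P/LP — the
#' sensitivity-oriented qualification used by the default filter preset.
#' `first_plp_year` is the earliest year among P/LP assertions.
#'
#' @param assertions path to TSV `contig,pos,ref,alt,significance,condition,first_plp_year`
#' @param frequencies path to TSV `contig,pos,ref,alt,af`; absence of a key
#'   means the variant was never observed in the reference population
#' @param gene2disease path to TSV `gene,omim_id,inheritance,first_year`
#' @param constraint path to TSV `gene,pli,oe`
#' @param acmg optional path to TSV `contig,pos,ref,alt,class,criteria`
#' @param versions named character of table version stamps for the report
#' @return a [KnowledgeBase-class]
#' @export
loadKnowledge <- function(assertions, frequencies, gene2disease, constraint,
                          acmg = NULL, versions = character()) {
  ## everything is read as character first: allele columns like "T" must
  ## never be parsed as logicals; numeric columns are converted explicitly
  readTsv <- function(path, need, label) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "", colClasses = "character")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop(label, " table lacks mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (nc in intersect(c("af", "pli", "oe"), names(df))) {
      df[[nc]] <- as.numeric(df[[nc]])
    }
    for (ic in intersect(c("pos", "first_plp_year", "first_year"), names(df))) {
      df[[ic]] <- suppressWarnings(as.integer(df[[ic]]))
    }
    df
  }

  asrt <- readTsv(assertions, c("contig", "pos", "ref", "alt", "significance",
                                "condition", "first_plp_year"), "assertion")
  if (nrow(asrt) && !all(asrt$significance %in% SIGNIFICANCE_VOCAB)) {
    stop("assertion significance outside closed vocabulary", call. = FALSE)
  }
  asrt$key <- variantKey(asrt$contig, asrt$pos, asrt$ref, asrt$alt)
  collapsed <- collapseAssertions(asrt)

  freq <- readTsv(frequencies, c("contig", "pos", "ref", "alt", "af"), "frequency")
  frequencies <- stats::setNames(
    as.numeric(freq$af), variantKey(freq$contig, freq$pos, freq$ref, freq$alt))
  # duplicate keys keep the maximum observed frequency (conservative for rarity)
  if (anyDuplicated(names(frequencies))) {
    frequencies <- tapply(frequencies, names(frequencies), max)
    frequencies <- stats::setNames(as.numeric(frequencies), names(frequencies))
  }

  g2d <- readTsv(gene2disease, c("gene", "omim_id", "inheritance", "first_year"),
                 "gene-disease")
  g2d$gene <- toupper(g2d$gene)
  g2d <- g2d[order(g2d$gene, g2d$omim_id), , drop = FALSE]
  rownames(g2d) <- NULL

  cons <- readTsv(constraint, c("gene", "pli", "oe"), "constraint")
  cons$gene <- toupper(cons$gene)

  acmgDf <- if (is.null(acmg)) {
    data.frame(key = character(), class = character(), criteria = character(),
               stringsAsFactors = FALSE)
  } else {
    a <- readTsv(acmg, c("contig", "pos", "ref", "alt", "class", "criteria"), "ACMG")
    data.frame(key = variantKey(a$contig, a$pos, a$ref, a$alt),
               class = a$class, criteria = a$criteria, stringsAsFactors = FALSE)
  }

  new("KnowledgeBase",
    assertions = collapsed,
    frequencies = frequencies,
    gene2disease = g2d,
    constraint = cons,
    acmg = acmgDf,
    versions = versions
  )
}

## deterministic, order-independent collapse of duplicate assertion keys
collapseAssertions <- function(asrt) {
  if (!nrow(asrt)) {
    return(data.frame(key = character(), significance = character(),
                      condition = character(), first_plp_year = integer(),
                      any_plp = logical(), n_assertions = integer(),
                      stringsAsFactors = FALSE))
  }
  plpSet <- c("pathogenic", "likely_pathogenic")
  blbSet <- c("benign", "likely_benign")
  keys <- sort(unique(asrt$key))
  res <- lapply(keys, function(k) {
    g <- asrt[asrt$key == k, , drop = FALSE]
    sigs <- unique(g$significance)
    anyPlp <- any(sigs %in% plpSet)
    collapsed <- if (length(sigs) == 1L) {
      sigs
    } else if (all(sigs %in% plpSet)) {
      "pathogenic"                       # P beats LP when concordant in direction
    } else if (all(sigs %in% blbSet)) {
      "benign"
    } else {
      "conflicting"
    }
    plpRows <- g$significance %in% plpSet
    condSrc <- if (anyPlp) g$condition[plpRows] else g$condition
    yr <- suppressWarnings(min(g$first_plp_year[plpRows], na.rm = TRUE))
    data.frame(
      key = k,
      significance = collapsed,
      condition = paste(sort(unique(condSrc[nzchar(condSrc)])), collapse = "; "),
      first_plp_year = if (is.finite(yr)) as.integer(yr) else NA_integer_,
      any_plp = anyPlp,
      n_assertions = nrow(g),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Internal cohort allele frequency
#'
#' The denominator counts one representative per family — the index case —
#' so a large sequenced family cannot suppress its own causal variant.
#' Missing calls never contribute to the denominator; with no called alleles
#' the frequency is 0.
#'
#' @param alleleCounts integer vector of index-case alt dosages at one site
#'   (`NA` = uncalled)
#' @param ploidy integer vector of matching ploidies (default diploid)
#' @return allele frequency in `[0, 1]`
#' @export
internalAlleleFrequency <- function(alleleCounts, ploidy = rep(2L, length(alleleCounts))) {
  called <- !is.na(alleleCounts)
  denom <- sum(ploidy[called])
  if (denom == 0) return(0)
  sum(alleleCounts[called]) / denom
}

#' Internal allele frequencies across a cohort of case bundles
#'
#' One pass over every family's index genotypes; returns the family-
#' deduplicated cohort frequency for every variant key observed anywhere in
#' the cohort. An index whose per-family VCF does not contain a site is
#' counted as homozygous-reference there (no alt was called for a sequenced
#' experiment), whereas an explicit missing call (`./.`) is excluded from the
#' denominator. Default per-index ploidy at absent sites is 1 on MT, 1 on X
#' for male indexes, 2 otherwise.
#'
#' @param bundles list of [CaseBundle-class]
#' @return named numeric: variant key -> internal allele frequency
#' @export
cohortInternalFrequencies <- function(bundles) {
  keyList <- lapply(bundles, function(b) variantKeys(b@variants))
  allKeys <- sort(unique(unlist(keyList)))
  keyContig <- sub(":.*$", "", allKeys)
  num <- stats::setNames(numeric(length(allKeys)), allKeys)
  den <- stats::setNames(numeric(length(allKeys)), allKeys)
  for (i in seq_along(bundles)) {
    b <- bundles[[i]]
    idx <- indexId(b)
    sex <- pedMembers(b@pedigree)$sex[pedMembers(b@pedigree)$is_index]
    defaultP <- ifelse(keyContig == "MT", 1,
                       ifelse(keyContig == "X" & identical(sex, "male"), 1, 2))
    den <- den + defaultP
    g <- genotypes(b@variants)[, idx]
    p <- ploidies(b@variants)[, idx]
    here <- match(keyList[[i]], allKeys)
    called <- !is.na(g)
    num[here[called]] <- num[here[called]] + g[called]
    den[here[called]] <- den[here[called]] + (p[called] - defaultP[here[called]])
    den[here[!called]] <- den[here[!called]] - defaultP[here[!called]]
  }
  af <- ifelse(den > 0, num / den, 0)
  stats::setNames(as.numeric(af), allKeys)
}

#' Annotate a VariantSet against the knowledge base
#'
#' Non-destructive: returns a data.frame aligned to the records of `vs`
#' (genotypes and positions in `vs` are untouched). Every knowledge field is
#' populated or explicitly `NA`; external frequency defaults to 0 for keys
#' never observed in the reference population.
#'
#' @param vs a [VariantSet-class]
#' @param kb a [KnowledgeBase-class]
#' @param af_internal named numeric of internal cohort frequencies (from
#'   [cohortInternalFrequencies()]); keys absent default to 0
#' @return data.frame with columns `key`, `af_external`, `af_internal`,
#'   `significance`, `condition`, `first_plp_year`, `any_plp`,
#'   `omim_associations`, `inheritance_modes`, `first_association_year`,
#'   `pli`, `oe`, `acmg_class`, `acmg_criteria`
#' @export
annotateVariants <- function(vs, kb, af_internal = numeric()) {
  keys <- variantKeys(vs)
  genes <- toupper(variantInfo(vs)$gene)

  ai <- match(keys, kb@assertions$key)
  fi <- kb@frequencies[keys]
  fi[is.na(fi)] <- 0                      # never observed -> frequency 0
  inti <- af_internal[keys]
  inti[is.na(inti)] <- 0

  g2d <- kb@gene2disease
  assoc <- lapply(genes, function(g) g2d[g2d$gene == g, , drop = FALSE])
  ci <- match(genes, kb@constraint$gene)
  mi <- match(keys, kb@acmg$key)

  data.frame(
    key = keys,
    af_external = as.numeric(fi),
    af_internal = as.numeric(inti),
    significance = kb@assertions$significance[ai],
    condition = kb@assertions$condition[ai],
    first_plp_year = kb@assertions$first_plp_year[ai],
    any_plp = ifelse(is.na(ai), FALSE, kb@assertions$any_plp[ai]),
    omim_associations = vapply(assoc, function(a) joinField(a$omim_id), character(1)),
    inheritance_modes = vapply(assoc, function(a) joinField(sort(unique(a$inheritance))),
                               character(1)),
    first_association_year = vapply(assoc, function(a) {
      if (!nrow(a)) return(NA_integer_)
      as.integer(min(a$first_year, na.rm = TRUE))
    }, integer(1)),
    pli = kb@constraint$pli[ci],
    oe = kb@constraint$oe[ci],
    acmg_class = kb@acmg$class[mi],
    acmg_criteria = kb@acmg$criteria[mi],
    stringsAsFactors = FALSE
  )
}

## inheritance modes of a gene's associations, e.g. c("AD","AR")
geneInheritanceModes <- function(kb, gene) {
  sort(unique(kb@gene2disease$inheritance[kb@gene2disease$gene == toupper(gene)]))
}
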