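## VCF read/write. Parsing is delegated to VariantAnnotation; this module
## only decomposes multi-allelic sites, converts GT strings to alt-allele
## dosages with explicit ploidy, and extracts alt-read fractions from AD.
## Inputs are assumed pre-normalized (left-aligned) by the upstream calling
## pipeline; no indel re-normalization is attempted here.

#' Read a family VCF into a VariantSet
#'
#' Multi-allelic sites are decomposed into one record per alternate allele;
#' genotypes become alt-allele dosages with per-cell ploidy taken from the GT
#' string itself (haploid GT such as `1` on male X or mitochondrial calls gets
#' ploidy 1). Missing calls (`./.` or `.`) are `NA` — never assumed
#' homozygous-reference. Records are sorted by (contig, pos, ref, alt).
#'
#' @param path VCF 4.x file (plain or bgzipped)
#' @param pedigree optional [FamilyPedigree-class]; the index sample must be
#'   present among the VCF sample columns (fatal otherwise), other members
#'   missing from the VCF are tolerated with a warning
#' @return a [VariantSet-class]
#' @export
readVcfRecords <- function(path, pedigree = NULL) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "GRCh37"),
    error = function(e) stop("malformed VCF '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  samples <- colnames(vcf)
  if (!is.null(pedigree)) {
    idx <- indexId(pedigree)
    if (!idx %in% samples) {
      stop("index case '", idx, "' absent from VCF sample columns of ", path,
           call. = FALSE)
    }
    absent <- setdiff(pedigree@members$experiment_id, samples)
    if (length(absent)) {
      warning("pedigree members missing from VCF (tolerated): ",
              paste(absent, collapse = ", "), call. = FALSE)
    }
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- normalizeContig(as.character(GenomicRanges::seqnames(rr)))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  nAlt <- lengths(altList)
  altFlat <- as.character(unlist(altList))
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
    VariantAnnotation::geno(vcf)$AD
  } else NULL
  filt <- as.character(VariantAnnotation::filt(vcf))
  infoDf <- VariantAnnotation::info(vcf)
  gene <- if ("GENE" %in% names(infoDf)) as.character(infoDf$GENE) else rep(NA_character_, length(rr))
  csq <- if ("CSQ" %in% names(infoDf)) as.character(infoDf$CSQ) else rep(NA_character_, length(rr))

  siteOf <- rep(seq_along(nAlt), nAlt)        # expanded row -> original site
  altIdx <- unlist(lapply(nAlt, seq_len))     # which alt allele (1-based)
  nRec <- length(siteOf)
  nSmp <- length(samples)

  genoM <- matrix(NA_integer_, nRec, nSmp, dimnames = list(NULL, samples))
  ploidyM <- matrix(2L, nRec, nSmp, dimnames = list(NULL, samples))
  afM <- matrix(NA_real_, nRec, nSmp, dimnames = list(NULL, samples))

  for (s in seq_len(nSmp)) {
    g <- gt[siteOf, s]
    alleles <- strsplit(g, "[/|]")
    pl <- lengths(alleles)
    miss <- vapply(alleles, function(a) any(a == ".") || length(a) == 0, logical(1))
    cnt <- integer(nRec)
    tgt <- as.character(altIdx)
    for (i in seq_len(nRec)) {
      cnt[i] <- sum(alleles[[i]] == tgt[i])
    }
    genoM[, s] <- ifelse(miss, NA_integer_, cnt)
    ploidyM[, s] <- as.integer(pl)
    ploidyM[miss, s] <- ifelse(pl[miss] >= 1, pmax(1L, pl[miss]), 2L)
    if (!is.null(ad)) {
      for (i in seq_len(nRec)) {
        depths <- ad[[siteOf[i], s]]
        if (is.null(depths) || all(is.na(depths))) next
        tot <- sum(depths, na.rm = TRUE)
        aD <- depths[altIdx[i] + 1L]
        if (tot > 0 && !is.na(aD)) afM[i, s] <- aD / tot
      }
    }
  }

  meta <- data.frame(
    contig = contig[siteOf],
    pos = pos[siteOf],
    ref = ref[siteOf],
    alt = altFlat,
    gene = gene[siteOf],
    consequence = csq[siteOf],
    filter = filt[siteOf],
    stringsAsFactors = FALSE
  )
  meta$gene[is.na(meta$gene) | meta$gene == ""] <- "INTERGENIC"
  ctg <- GenomeInfoDb::seqlengths(rr)
  contigs <- stats::setNames(as.numeric(ctg), normalizeContig(names(ctg)))
  contigs <- contigs[!is.na(contigs)]
  VariantSet(meta, genoM, ploidyM, afM, contigs = contigs)
}

#' Write a VariantSet as a VCF 4.2 text file
#'
#' The exact inverse of [readVcfRecords()] for decomposed records: each row
#' becomes one biallelic VCF line. Genotypes are emitted as `0/1`-style GT
#' (haploid `0`/`1` where ploidy is 1); rows carrying allelic fractions get an
#' `AD` field at a nominal depth of 1000 reads so fractions survive the round
#' trip at 3 decimals.
#'
#' @param vs a [VariantSet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeVcfRecords <- function(vs, path) {
  samples <- colnames(vs@geno)
  hasAD <- any(!is.na(vs@afrac))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  ctg <- vs@contigs
  if (!length(ctg)) {
    nm <- unique(vs@meta$contig)
    ctg <- stats::setNames(rep(2.5e8, length(nm)), nm)
  }
  for (nm in names(ctg)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", nm, as.integer(ctg[[nm]])), con)
  }
  writeLines(c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Functional consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  ), con)
  if (hasAD) {
    writeLines('##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">', con)
  }
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  m <- vs@meta
  for (i in seq_len(nrow(m))) {
    rowHasAd <- hasAD && any(!is.na(vs@afrac[i, ]))
    fmt <- if (rowHasAd) "GT:AD" else "GT"
    cells <- vapply(seq_along(samples), function(s) {
      gtStr <- gtString(vs@geno[i, s], vs@ploidy[i, s])
      if (!rowHasAd) return(gtStr)
      af <- vs@afrac[i, s]
      adStr <- if (is.na(af)) "." else {
        a <- as.integer(round(af * 1000))
        paste(1000L - a, a, sep = ",")
      }
      paste(gtStr, adStr, sep = ":")
    }, character(1))
    info <- sprintf("GENE=%s;CSQ=%s", m$gene[i], m$consequence[i])
    writeLines(paste(c(m$contig[i], m$pos[i], ".", m$ref[i], m$alt[i], "50",
                       m$filter[i], info, fmt, cells), collapse = "\t"), con)
  }
  invisible(path)
}

gtString <- function(count, ploidy) {
  if (is.na(count)) {
    return(if (ploidy == 1L) "." else paste(rep(".", ploidy), collapse = "/"))
  }
  alleles <- c(rep("0", ploidy - count), rep("1", count))
  paste(alleles, collapse = "/")
}
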