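## The filter stack. A variant survives iff the conjunction of active
## predicates holds; the conjunction is evaluated as a pure per-variant
## predicate, so filter application order cannot change the result.
## Segregation verdicts are attached to surviving rows — they annotate, they
## do not filter (unless the segregation_filter switch is set for stricter
## reanalysis rounds).

#' Run the filter stack on one case
#'
#' Survival predicate (all must hold):
#' external AF strictly below `af_external_max`; internal cohort AF strictly
#' below `af_internal_max`; gene in the resolved panel; a P/LP assertion
#' (when `require_plp`, qualification per `plp_aggregation`); consequence in
#' the whitelist (when one is set); position inside the region restriction
#' (when one is set); and the index case carries at least one alt allele.
#'
#' @param bundle a [CaseBundle-class]
#' @param kb a [KnowledgeBase-class]
#' @param config a [FilterConfig-class]
#' @param af_internal named numeric of cohort internal frequencies
#' @param hpo_gene_map,ontology required only when `config` has no explicit
#'   panel and per-case on-the-fly panels must be built
#' @return list with `rows` (candidate data.frame, possibly 0 rows),
#'   `funnel` (named integer of per-stage survivor counts), `roh`
#'   (the index case's ROH segments) and `froh`
#' @export
runFilterStack <- function(bundle, kb, config, af_internal = numeric(),
                           hpo_gene_map = NULL, ontology = NULL) {
  vs <- bundle@variants
  ped <- bundle@pedigree
  idx <- indexId(ped)
  ann <- annotateVariants(vs, kb, af_internal)
  m <- variantInfo(vs)
  g <- genotypes(vs)
  p <- ploidies(vs)
  af <- allelicFractions(vs)

  panel <- config@panel
  if (is.null(panel)) {
    if (is.null(hpo_gene_map) || is.null(ontology)) {
      stop("no explicit panel configured and no HPO-gene map/ontology supplied",
           call. = FALSE)
    }
    panel <- onTheFlyPanel(bundle@phenotype$hpo %||% character(),
                           hpo_gene_map, ontology,
                           panel_id = paste0("otf-", idx))
    if (!length(panelGenes(panel))) {
      stop("case ", idx, ": empty on-the-fly panel and no explicit panel; ",
           "case skipped", call. = FALSE)
    }
  }

  # index ROH / consanguinity (always computed: it is a report annotation)
  rohSegs <- detectRoh(homozygositySites(vs, idx),
                       min_length_bp = config@roh_min_length_bp,
                       min_sites = config@roh_min_sites,
                       max_het = config@roh_max_het)
  autoLen <- sum(vs@contigs[!names(vs@contigs) %in% c("X", "Y", "MT")])
  if (!length(autoLen) || autoLen == 0) autoLen <- 2.88e9  # GRCh37 autosome
  consang <- inferConsanguinity(rohSegs, autoLen, config@froh_threshold)

  inRegion <- function(contig, pos, regions) {
    if (!nrow(regions)) return(rep(FALSE, length(pos)))
    ok <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(regions))) {
      ok <- ok | (contig == regions$contig[r] &
                  pos >= regions$start[r] & pos <= regions$end[r])
    }
    ok
  }

  gIdx <- g[, idx]
  pass_rare_ext <- ann$af_external < config@af_external_max
  pass_rare_int <- ann$af_internal < config@af_internal_max
  pass_panel <- toupper(m$gene) %in% panelGenes(panel)
  pass_plp <- if (!config@require_plp) rep(TRUE, nrow(m)) else {
    if (config@plp_aggregation == "any") ann$any_plp
    else !is.na(ann$significance) &
      ann$significance %in% c("pathogenic", "likely_pathogenic")
  }
  pass_csq <- if (!length(config@consequence_whitelist)) rep(TRUE, nrow(m)) else {
    m$consequence %in% config@consequence_whitelist
  }
  pass_region <- switch(config@region_restriction,
    none = rep(TRUE, nrow(m)),
    roh = inRegion(m$contig, m$pos,
                   rohSegs[, c("contig", "start", "end"), drop = FALSE]),
    custom = inRegion(m$contig, m$pos, config@custom_regions)
  )
  pass_carrier <- !is.na(gIdx) & gIdx >= 1L

  keep <- pass_rare_ext & pass_rare_int & pass_panel & pass_plp &
    pass_csq & pass_region & pass_carrier
  funnel <- c(
    total = nrow(m),
    rare_external = sum(pass_rare_ext),
    rare_internal = sum(pass_rare_ext & pass_rare_int),
    in_panel = sum(pass_rare_ext & pass_rare_int & pass_panel),
    plp_asserted = sum(pass_rare_ext & pass_rare_int & pass_panel & pass_plp),
    index_carrier = sum(keep)
  )

  rows <- buildCandidateRows(bundle, which(keep), ann, rohSegs, consang, config)

  if (config@segregation_filter && nrow(rows)) {
    rows <- rows[grepl("=yes", rows$segregation, fixed = TRUE), , drop = FALSE]
  }
  list(rows = rows, funnel = funnel, roh = rohSegs, froh = consang$froh)
}

buildCandidateRows <- function(bundle, keepIdx, ann, rohSegs, consang, config) {
  vs <- bundle@variants
  ped <- bundle@pedigree
  idx <- indexId(ped)
  m <- variantInfo(vs)
  g <- genotypes(vs)
  p <- ploidies(vs)
  af <- allelicFractions(vs)
  pheno <- bundle@phenotype
  members <- pedMembers(ped)
  relIds <- setdiff(members$experiment_id, idx)
  relIds <- relIds[relIds %in% colnames(g)]
  fid <- members$father_id[members$is_index]
  mid <- members$mother_id[members$is_index]

  rows <- vector("list", length(keepIdx))
  # precompute compound-het pairing per gene over the surviving set
  survKeys <- ann$key[keepIdx]
  survGenes <- toupper(m$gene[keepIdx])
  pairTag <- stats::setNames(rep("", length(keepIdx)), survKeys)
  for (gene in unique(survGenes)) {
    sel <- keepIdx[survGenes == gene]
    gv <- data.frame(
      key = ann$key[sel],
      g_index = g[sel, idx],
      g_father = if (!is.na(fid) && fid %in% colnames(g)) g[sel, fid] else NA_integer_,
      g_mother = if (!is.na(mid) && mid %in% colnames(g)) g[sel, mid] else NA_integer_,
      stringsAsFactors = FALSE
    )
    prs <- compoundHetPairs(gv, ped)
    if (nrow(prs)) {
      for (r in seq_len(nrow(prs))) {
        tag1 <- sprintf("AR-comphet=yes(%s with %s)", prs$phase[r], prs$key2[r])
        tag2 <- sprintf("AR-comphet=yes(%s with %s)", prs$phase[r], prs$key1[r])
        pairTag[prs$key1[r]] <- if (nzchar(pairTag[prs$key1[r]]))
          paste(pairTag[prs$key1[r]], tag1, sep = "|") else tag1
        pairTag[prs$key2[r]] <- if (nzchar(pairTag[prs$key2[r]]))
          paste(pairTag[prs$key2[r]], tag2, sep = "|") else tag2
      }
    }
  }

  inRoh <- function(contig, pos) {
    if (!nrow(rohSegs)) return(FALSE)
    any(rohSegs$contig == contig & rohSegs$start <= pos & rohSegs$end >= pos)
  }

  for (n in seq_along(keepIdx)) {
    i <- keepIdx[n]
    genosAll <- stats::setNames(as.integer(g[i, ]), colnames(g))
    ploidAll <- stats::setNames(as.integer(p[i, ]), colnames(p))
    verdicts <- vapply(config@segregation_models, function(mod) {
      v <- segregate(genosAll, ploidAll, ped, mod, contig = m$contig[i],
                     afrac_index = af[i, idx],
                     allow_reduced_penetrance = config@allow_reduced_penetrance,
                     mosaic_af_bound = config@mosaic_af_bound)
      sprintf("%s=%s", mod, if (v$consistent) "yes" else "no")
    }, character(1))
    segStr <- paste(verdicts, collapse = "|")
    ctag <- pairTag[[ann$key[i]]]
    if (nzchar(ctag)) segStr <- paste(segStr, ctag, sep = "|")

    isHomDiploid <- !is.na(g[i, idx]) && p[i, idx] == 2L && g[i, idx] == 2L
    cnvFlag <- if (!isHomDiploid) "na" else {
      cnvCrosscheck(m$contig[i], m$pos[i], bundle@cnv, idx)
    }
    relStr <- joinField(vapply(relIds, function(r) {
      sprintf("%s=%s", r, ifelse(is.na(g[i, r]), ".", g[i, r]))
    }, character(1)))
    phenoStr <- joinField(c(pheno$hpo %||% character(), pheno$ordo %||% character()))

    rows[[n]] <- data.frame(
      case_id = idx,
      family_id = familyId(ped),
      ern = pheno$ern %||% NA_character_,
      contig = m$contig[i], pos = m$pos[i], ref = m$ref[i], alt = m$alt[i],
      gene = toupper(m$gene[i]),
      consequence = m$consequence[i],
      genotype_index = as.integer(g[i, idx]),
      genotypes_family = relStr,
      allelic_fraction = af[i, idx],
      af_external = ann$af_external[i],
      af_internal = ann$af_internal[i],
      clinical_significance = ann$significance[i] %||% NA_character_,
      condition = ann$condition[i] %||% NA_character_,
      first_plp_year = ann$first_plp_year[i],
      omim_associations = ann$omim_associations[i],
      inheritance_modes = ann$inheritance_modes[i],
      first_association_year = ann$first_association_year[i],
      pli = ann$pli[i],
      oe = ann$oe[i],
      acmg_class = ann$acmg_class[i] %||% NA_character_,
      acmg_criteria = ann$acmg_criteria[i] %||% NA_character_,
      phenotype_terms = phenoStr,
      consanguinity_reported = reportedConsanguinityLabel(pheno$consanguinity),
      consanguinity_inferred = sprintf("froh=%.4f;%s", consang$froh,
                                       if (consang$consanguineous) "yes" else "no"),
      segregation = segStr,
      roh_region = if (inRoh(m$contig[i], m$pos[i])) "yes" else "no",
      cnv_check = cnvFlag,
      status = "candidate",
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      data.frame(matrix(nrow = 0, ncol = length(candidateTableColumns()))),
      candidateTableColumns())
  if (nrow(out)) {
    out <- out[candidateOrder(out$case_id, out$contig, out$pos, out$ref, out$alt), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

reportedConsanguinityLabel <- function(x) {
  if (is.null(x) || is.na(x)) "unknown" else if (isTRUE(x)) "yes" else "no"
}

#' Re-status lone heterozygous hits in recessive-only genes
#'
#' A single heterozygous candidate in a gene whose disease associations are
#' exclusively autosomal recessive cannot explain the phenotype on its own;
#' it is re-statused `het_AR_candidate` for follow-up. Genes contributing two
#' or more candidate rows for the case (potential compound heterozygotes)
#' keep their `candidate` status.
#'
#' @param rows candidate data.frame
#' @param kb a [KnowledgeBase-class]
#' @return `rows` with updated `status`
#' @export
flagHetArCandidates <- function(rows, kb) {
  if (!nrow(rows)) return(rows)
  for (i in seq_len(nrow(rows))) {
    if (rows$status[i] != "candidate") next
    modes <- geneInheritanceModes(kb, rows$gene[i])
    if (!identical(modes, "AR")) next
    het <- !is.na(rows$genotype_index[i]) && rows$genotype_index[i] == 1L
    if (!het) next
    sameGene <- sum(rows$case_id == rows$case_id[i] & rows$gene == rows$gene[i])
    if (sameGene == 1L) rows$status[i] <- "het_AR_candidate"
  }
  rows
}
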