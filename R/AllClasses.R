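## Central S4 containers. One normalized alternate allele per variant row;
## genotypes are alt-allele dosages with explicit per-cell ploidy so that
## hemizygous X (males) and mitochondrial calls are first-class.

#' VariantSet: decomposed, annotated variant calls for one family
#'
#' A matrix-shaped container holding one row per (contig, pos, ref, alt)
#' alternate allele and one column per sequenced family member. Multi-allelic
#' sites are decomposed on read, so every row carries exactly one alt allele.
#' Genotypes are stored as alt-allele dosages (`0`, `1`, `2`; `NA` = uncalled),
#' with a parallel ploidy matrix (1 for hemizygous male X and mitochondrial
#' calls, 2 otherwise) and an optional allelic-fraction matrix supporting
#' mosaic-candidate flagging.
#'
#' @slot meta data.frame with columns `contig`, `pos`, `ref`, `alt`, `gene`,
#'   `consequence`, `filter`; rows sorted by (contig, pos, ref, alt)
#' @slot geno integer matrix of alt-allele dosages, variants x samples
#' @slot ploidy integer matrix, same shape as `geno`
#' @slot afrac numeric matrix of alt-read fractions in `[0, 1]` (`NA` when the
#'   caller emitted no allelic depths)
#' @slot contigs named numeric vector of contig lengths (bp), used when the
#'   set is written back to VCF
#' @export
setClass("VariantSet",
  representation(
    meta = "data.frame",
    geno = "matrix",
    ploidy = "matrix",
    afrac = "matrix",
    contigs = "numeric"
  )
)

setValidity("VariantSet", function(object) {
  m <- object@meta
  need <- c("contig", "pos", "ref", "alt", "gene", "consequence", "filter")
  if (!all(need %in% names(m))) {
    return(paste("meta lacks columns:", paste(setdiff(need, names(m)), collapse = ", ")))
  }
  if (nrow(m) != nrow(object@geno)) return("meta and geno row counts differ")
  if (!identical(dim(object@geno), dim(object@ploidy))) return("geno/ploidy shape mismatch")
  if (!identical(dim(object@geno), dim(object@afrac))) return("geno/afrac shape mismatch")
  if (nrow(m) > 0) {
    if (any(m$pos < 1)) return("pos must be >= 1 (1-based VCF convention)")
    if (any(m$ref == m$alt)) return("ref equal to alt")
    if (any(grepl(",", m$alt, fixed = TRUE))) return("multi-allelic alt not decomposed")
    over <- !is.na(object@geno) & object@geno > object@ploidy
    if (any(over)) return("allele dosage exceeds ploidy")
  }
  TRUE
})

#' Construct a VariantSet
#'
#' @param meta variant table (see [VariantSet-class])
#' @param geno integer dosage matrix (variants x samples, named columns)
#' @param ploidy integer ploidy matrix; defaults to 2 everywhere
#' @param afrac allelic-fraction matrix; defaults to all-`NA`
#' @param contigs named contig lengths
#' @return a [VariantSet-class]
#' @export
VariantSet <- function(meta, geno, ploidy = NULL, afrac = NULL, contigs = numeric()) {
  meta$contig <- normalizeContig(meta$contig)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(ploidy)) {
    ploidy <- matrix(2L, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  }
  storage.mode(ploidy) <- "integer"
  if (is.null(afrac)) {
    afrac <- matrix(NA_real_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  }
  ord <- variantOrder(meta$contig, meta$pos, meta$ref, meta$alt)
  meta <- meta[ord, , drop = FALSE]
  rownames(meta) <- NULL
  new("VariantSet",
    meta = meta,
    geno = geno[ord, , drop = FALSE],
    ploidy = ploidy[ord, , drop = FALSE],
    afrac = afrac[ord, , drop = FALSE],
    contigs = contigs
  )
}

#' FamilyPedigree: one family of a rare-disease cohort
#'
#' Members are listed with sex, affected status and parental links; exactly
#' one member is flagged as the index case (the proband the reanalysis query
#' is run on). The family structure class drives cohort accounting:
#' `trio` (index plus both parents, nobody else), `singleton` (index only),
#' `other` (anything else).
#'
#' @slot family_id family identifier
#' @slot members data.frame with columns `experiment_id`, `sex`
#'   (male/female/unknown), `affected` (logical), `father_id`, `mother_id`
#'   (`NA` when absent), `is_index`
#' @slot structure_class one of `trio`, `singleton`, `other`
#' @export
setClass("FamilyPedigree",
  representation(
    family_id = "character",
    members = "data.frame",
    structure_class = "character"
  )
)

setValidity("FamilyPedigree", function(object) {
  m <- object@members
  need <- c("experiment_id", "sex", "affected", "father_id", "mother_id", "is_index")
  if (!all(need %in% names(m))) return("members table lacks required columns")
  if (sum(m$is_index) != 1L) return("exactly one index case must be flagged")
  ids <- m$experiment_id
  for (p in c(m$father_id, m$mother_id)) {
    if (!is.na(p) && !(p %in% ids)) return(paste("unresolved parent reference:", p))
  }
  if (!object@structure_class %in% c("trio", "singleton", "other")) {
    return("structure_class must be trio, singleton or other")
  }
  cls <- classifyStructure(m)
  if (!identical(cls, object@structure_class)) {
    return(sprintf("structure_class '%s' inconsistent with members (expected '%s')",
                   object@structure_class, cls))
  }
  TRUE
})

## total classification: every member table maps to exactly one class
classifyStructure <- function(members) {
  idx <- members[members$is_index, , drop = FALSE]
  n <- nrow(members)
  if (n == 1L) return("singleton")
  bothParents <- !is.na(idx$father_id) && !is.na(idx$mother_id)
  if (n == 3L && bothParents) return("trio")
  "other"
}

#' Construct a FamilyPedigree
#' @param family_id family identifier
#' @param members member table (see [FamilyPedigree-class])
#' @return a [FamilyPedigree-class]
#' @export
FamilyPedigree <- function(family_id, members) {
  members$father_id <- as.character(members$father_id)
  members$mother_id <- as.character(members$mother_id)
  rownames(members) <- NULL
  new("FamilyPedigree",
    family_id = as.character(family_id),
    members = members,
    structure_class = classifyStructure(members)
  )
}

#' GenePanel: a named set of gene symbols used as a filter
#'
#' @slot panel_id panel identifier
#' @slot source one of `ERN-curated`, `external`, `on-the-fly`
#' @slot genes uppercase gene symbols, sorted, unique; may be empty only for
#'   degenerate on-the-fly panels built from phenotype records without usable
#'   terms (the engine then refuses to run the case without an explicit panel)
#' @export
setClass("GenePanel",
  representation(panel_id = "character", source = "character", genes = "character")
)

setValidity("GenePanel", function(object) {
  if (!object@source %in% c("ERN-curated", "external", "on-the-fly")) {
    return("source must be ERN-curated, external or on-the-fly")
  }
  if (length(object@genes) == 0 && object@source != "on-the-fly") {
    return("curated/external panels must be non-empty")
  }
  if (any(object@genes != toupper(object@genes))) return("gene symbols must be uppercase")
  TRUE
})

#' Construct a GenePanel
#' @param panel_id panel identifier
#' @param genes character vector of gene symbols (case-normalized to upper)
#' @param source provenance label
#' @return a [GenePanel-class]
#' @export
GenePanel <- function(panel_id, genes, source = "external") {
  new("GenePanel",
    panel_id = as.character(panel_id),
    source = source,
    genes = sort(unique(toupper(as.character(genes))))
  )
}

setClassUnion("GenePanelOrNULL", c("GenePanel", "NULL"))

#' HpoOntology: a phenotype-term DAG
#'
#' Minimal ontology model: term identifiers plus parent links (`is_a`).
#' The root term and terms under excluded branches (inheritance-mode,
#' clinical-modifier, frequency) are never used for gene matching.
#'
#' @slot terms all term ids
#' @slot parents named list: term -> character vector of parent ids
#' @slot children named list: term -> character vector of child ids
#' @slot root ontology root id
#' @slot excluded_roots branch roots excluded from phenotype matching
#' @slot labels named character: term -> label
#' @export
setClass("HpoOntology",
  representation(
    terms = "character",
    parents = "list",
    children = "list",
    root = "character",
    excluded_roots = "character",
    labels = "character"
  )
)

setValidity("HpoOntology", function(object) {
  allp <- unique(unlist(object@parents, use.names = FALSE))
  if (length(allp) && !all(allp %in% object@terms)) return("unresolved parent term")
  # acyclicity by Kahn's algorithm
  indeg <- vapply(object@parents[object@terms], length, integer(1))
  names(indeg) <- object@terms
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in object@children[[t]] %||% character()) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(object@terms)) return("ontology graph contains a cycle")
  TRUE
})

#' Construct an HpoOntology from parent links
#' @param parents named list term -> character vector of parent ids
#' @param root root term id
#' @param excluded_roots branch roots excluded from matching
#' @param labels optional named character of term labels
#' @return an [HpoOntology-class]
#' @export
HpoOntology <- function(parents, root = "HP:0000001",
                        excluded_roots = character(), labels = character()) {
  terms <- sort(unique(c(names(parents), unlist(parents, use.names = FALSE), root)))
  parents <- parents[intersect(names(parents), terms)]
  full <- setNames(vector("list", length(terms)), terms)
  full[names(parents)] <- parents
  children <- setNames(vector("list", length(terms)), terms)
  for (t in names(full)) {
    for (p in full[[t]]) children[[p]] <- c(children[[p]], t)
  }
  new("HpoOntology",
    terms = terms, parents = full, children = children,
    root = root, excluded_roots = excluded_roots, labels = labels
  )
}

#' KnowledgeBase: joined annotation lookup tables
#'
#' Holds the five knowledge tables the engine annotates against: collapsed
#' pathogenicity assertions, external population allele frequencies,
#' gene-disease associations with first-report years, gene constraint scores
#' and precomputed ACMG classifications. Duplicate assertion keys are
#' collapsed deterministically on load (see [loadKnowledge()]).
#'
#' @slot assertions data.frame keyed by variant: `key`, `significance`,
#'   `condition`, `first_plp_year`, `any_plp`, `n_assertions`
#' @slot frequencies named numeric: variant key -> external allele frequency;
#'   absence of a key means "never observed" (frequency 0)
#' @slot gene2disease data.frame: `gene`, `omim_id`, `inheritance`, `first_year`
#' @slot constraint data.frame: `gene`, `pli`, `oe`
#' @slot acmg data.frame: `key`, `class`, `criteria`
#' @slot versions named character of table version stamps for the report header
#' @export
setClass("KnowledgeBase",
  representation(
    assertions = "data.frame",
    frequencies = "numeric",
    gene2disease = "data.frame",
    constraint = "data.frame",
    acmg = "data.frame",
    versions = "character"
  )
)

setValidity("KnowledgeBase", function(object) {
  sig <- object@assertions$significance
  vocab <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign",
             "benign", "conflicting")
  if (length(sig) && !all(sig %in% vocab)) return("significance outside closed vocabulary")
  fr <- object@frequencies
  if (length(fr) && (any(fr < 0) || any(fr > 1))) return("allele frequency outside [0,1]")
  g2d <- object@gene2disease
  if (nrow(g2d) && !all(g2d$inheritance %in% c("AD", "AR", "XL", "MT"))) {
    return("inheritance mode outside {AD, AR, XL, MT}")
  }
  cs <- object@constraint
  if (nrow(cs)) {
    if (any(stats::na.omit(cs$pli) < 0 | stats::na.omit(cs$pli) > 1)) return("pLI outside [0,1]")
    if (any(stats::na.omit(cs$oe) < 0)) return("o/e ratio negative")
  }
  plp <- sig %in% c("pathogenic", "likely_pathogenic")
  yr <- object@assertions$first_plp_year
  if (length(yr) && any(plp & is.na(yr))) {
    return("P/LP assertions must carry a first_plp_year")
  }
  TRUE
})

#' FilterConfig: the configurable filter stack
#'
#' Defaults reproduce the first-round "low-hanging fruit" preset: rare
#' variants (external population allele frequency < 0.01, internal cohort
#' frequency < 0.02) in the case's gene panel that carry a pathogenic or
#' likely-pathogenic assertion. Segregation verdicts annotate candidate rows
#' but do not filter unless `segregation_filter` is set.
#'
#' @slot af_external_max external allele-frequency ceiling (strict `<`)
#' @slot af_internal_max internal cohort allele-frequency ceiling (strict `<`)
#' @slot panel a [GenePanel-class], or `NULL` to build per-case on-the-fly
#'   panels from phenotype terms
#' @slot require_plp require a pathogenic/likely-pathogenic assertion
#' @slot plp_aggregation `"any"` (any assertion P/LP qualifies) or
#'   `"concordant"` (collapsed significance itself must be P/LP)
#' @slot consequence_whitelist consequence terms to keep; empty = off
#' @slot region_restriction `"none"`, `"roh"` (restrict to the index case's
#'   runs of homozygosity) or `"custom"`
#' @slot custom_regions data.frame `contig`/`start`/`end` (1-based inclusive)
#'   used when `region_restriction == "custom"`
#' @slot segregation_models models evaluated and reported per row
#' @slot segregation_filter drop rows with no consistent model
#' @slot case_selection experiment ids to process; empty = all
#' @slot allow_reduced_penetrance tolerate unaffected het carriers under
#'   dominant inheritance
#' @slot mosaic_af_bound allelic-fraction bound flagging mosaic candidates
#' @slot roh_min_length_bp,roh_min_sites,roh_max_het ROH caller parameters
#' @slot froh_threshold FROH at or above which a case is called consanguineous
#' @slot min_depth,min_gq genotype-quality knobs, `NA` = off
#' @export
setClass("FilterConfig",
  representation(
    af_external_max = "numeric",
    af_internal_max = "numeric",
    panel = "GenePanelOrNULL",
    require_plp = "logical",
    plp_aggregation = "character",
    consequence_whitelist = "character",
    region_restriction = "character",
    custom_regions = "data.frame",
    segregation_models = "character",
    segregation_filter = "logical",
    case_selection = "character",
    allow_reduced_penetrance = "logical",
    mosaic_af_bound = "numeric",
    roh_min_length_bp = "numeric",
    roh_min_sites = "integer",
    roh_max_het = "integer",
    froh_threshold = "numeric",
    min_depth = "numeric",
    min_gq = "numeric"
  )
)

setValidity("FilterConfig", function(object) {
  if (object@af_external_max < 0 || object@af_external_max > 1) return("af_external_max outside [0,1]")
  if (object@af_internal_max < 0 || object@af_internal_max > 1) return("af_internal_max outside [0,1]")
  if (!object@region_restriction %in% c("none", "roh", "custom")) {
    return("region_restriction must be none, roh or custom")
  }
  if (!object@plp_aggregation %in% c("any", "concordant")) {
    return("plp_aggregation must be 'any' or 'concordant'")
  }
  known <- c("AD-denovo", "AD-inherited", "AR-hom", "XL", "MT", "mosaic-candidate")
  if (!all(object@segregation_models %in% known)) return("unknown segregation model")
  active <- object@af_external_max < 1 || object@af_internal_max < 1 ||
    !is.null(object@panel) || object@require_plp ||
    length(object@consequence_whitelist) > 0 ||
    object@region_restriction != "none"
  if (!active) return("at least one filter must be active")
  TRUE
})

#' The first-round "low-hanging fruit" filter preset
#'
#' Rare (external AF < 0.01, internal cohort AF < 0.02), panel-restricted,
#' asserted pathogenic/likely-pathogenic. Segregation annotates, never
#' filters; no consequence whitelist (the P/LP requirement subsumes impact).
#'
#' @param panel a [GenePanel-class], or `NULL` for per-case on-the-fly panels
#' @param ... overrides for any [FilterConfig-class] slot
#' @return a [FilterConfig-class]
#' @export
lowHangingFruitConfig <- function(panel = NULL, ...) {
  cfg <- new("FilterConfig",
    af_external_max = 0.01,
    af_internal_max = 0.02,
    panel = panel,
    require_plp = TRUE,
    plp_aggregation = "any",
    consequence_whitelist = character(),
    region_restriction = "none",
    custom_regions = data.frame(contig = character(), start = integer(), end = integer()),
    segregation_models = c("AD-denovo", "AD-inherited", "AR-hom", "XL", "MT",
                           "mosaic-candidate"),
    segregation_filter = FALSE,
    case_selection = character(),
    allow_reduced_penetrance = FALSE,
    mosaic_af_bound = 0.30,
    roh_min_length_bp = 1e6,
    roh_min_sites = 25L,
    roh_max_het = 1L,
    froh_threshold = 0.03,
    min_depth = NA_real_,
    min_gq = NA_real_
  )
  dots <- list(...)
  for (nm in names(dots)) slot(cfg, nm) <- dots[[nm]]
  validObject(cfg)
  cfg
}

#' CaseBundle: everything the engine needs for one family
#'
#' @slot variants the family's [VariantSet-class]
#' @slot pedigree the family's [FamilyPedigree-class]
#' @slot phenotype named list for the index case: `experiment_id`, `hpo`,
#'   `ordo`, `omim`, `ern`, `consanguinity` (logical, `NA` = unknown)
#' @slot cnv data.frame of CNV calls for family members (may have zero rows):
#'   `experiment_id`, `contig`, `start`, `end`, `copy_state`
#' @export
setClass("CaseBundle",
  representation(
    variants = "VariantSet",
    pedigree = "FamilyPedigree",
    phenotype = "list",
    cnv = "data.frame"
  )
)

#' Construct a CaseBundle
#' @param variants a [VariantSet-class]
#' @param pedigree a [FamilyPedigree-class]
#' @param phenotype index-case phenotype list (see [CaseBundle-class])
#' @param cnv CNV call table, zero rows when none are available
#' @return a [CaseBundle-class]
#' @export
CaseBundle <- function(variants, pedigree, phenotype = list(), cnv = emptyCnvTable()) {
  new("CaseBundle", variants = variants, pedigree = pedigree,
      phenotype = phenotype, cnv = cnv)
}

emptyCnvTable <- function() {
  data.frame(experiment_id = character(), contig = character(),
             start = integer(), end = integer(), copy_state = character(),
             stringsAsFactors = FALSE)
}
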