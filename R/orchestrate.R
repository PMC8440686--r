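## Run orchestration: sequential per-case execution over a cohort directory,
## with per-case failure isolation, a run manifest (config hash, inputs,
## knowledge versions, per-case query status and filter-stage funnel) and
## deterministic outputs.
##
## Cohort directory convention (as produced by simulateCohort, and the
## expected layout for real inputs):
##   vcf/<family_id>.vcf      per-family multi-sample VCF
##   cohort.ped               6-column pedigree file
##   phenotypes.json          phenopacket-style phenotype records
##   knowledge/assertions.tsv, frequencies.tsv, gene2disease.tsv,
##             constraint.tsv, acmg.tsv, hpo2gene.tsv
##   ontology.obo             phenotype ontology
##   panels/<ERN>.tsv         per-network gene panels
##   cnv.bed                  optional CNV calls (BED dialect)
##   config.yaml              optional filter configuration

#' Load a filter configuration from YAML
#'
#' Unknown keys are ignored; missing keys keep the low-hanging-fruit preset
#' defaults.
#' @param path YAML file
#' @param panel optional [GenePanel-class] overriding any panel setting
#' @return a [FilterConfig-class]
#' @export
readFilterConfig <- function(path, panel = NULL) {
  y <- yaml::read_yaml(path)
  cfg <- lowHangingFruitConfig(panel = panel)
  numKeys <- c("af_external_max", "af_internal_max", "mosaic_af_bound",
               "roh_min_length_bp", "froh_threshold", "min_depth", "min_gq")
  for (k in numKeys) if (!is.null(y[[k]])) slot(cfg, k) <- as.numeric(y[[k]])
  for (k in c("roh_min_sites", "roh_max_het")) {
    if (!is.null(y[[k]])) slot(cfg, k) <- as.integer(y[[k]])
  }
  for (k in c("require_plp", "segregation_filter", "allow_reduced_penetrance")) {
    if (!is.null(y[[k]])) slot(cfg, k) <- as.logical(y[[k]])
  }
  for (k in c("plp_aggregation", "region_restriction")) {
    if (!is.null(y[[k]])) slot(cfg, k) <- as.character(y[[k]])
  }
  if (!is.null(y$segregation_models)) {
    slot(cfg, "segregation_models") <- as.character(y$segregation_models)
  }
  if (!is.null(y$case_selection)) {
    slot(cfg, "case_selection") <- as.character(y$case_selection)
  }
  validObject(cfg)
  cfg
}

loadCohortInputs <- function(dir) {
  versions <- c(assertions = "unversioned", frequencies = "unversioned",
                gene2disease = "unversioned")
  cfgPath <- file.path(dir, "config.yaml")
  if (file.exists(cfgPath)) {
    y <- yaml::read_yaml(cfgPath)
    if (!is.null(y$knowledge_versions)) {
      versions <- unlist(y$knowledge_versions)
    }
  }
  kdir <- file.path(dir, "knowledge")
  kb <- loadKnowledge(
    assertions = file.path(kdir, "assertions.tsv"),
    frequencies = file.path(kdir, "frequencies.tsv"),
    gene2disease = file.path(kdir, "gene2disease.tsv"),
    constraint = file.path(kdir, "constraint.tsv"),
    acmg = if (file.exists(file.path(kdir, "acmg.tsv"))) file.path(kdir, "acmg.tsv"),
    versions = versions
  )
  pedigrees <- readPed(file.path(dir, "cohort.ped"))
  phenotypes <- readPhenotypeRecords(file.path(dir, "phenotypes.json"))
  panelFiles <- list.files(file.path(dir, "panels"), pattern = "\\.tsv$",
                           full.names = TRUE)
  panels <- lapply(panelFiles, readGenePanel, source = "ERN-curated")
  names(panels) <- vapply(panels, panelId, character(1))
  cnv <- if (file.exists(file.path(dir, "cnv.bed"))) {
    readCnvCalls(file.path(dir, "cnv.bed"))
  } else emptyCnvTable()
  ontPath <- file.path(dir, "ontology.obo")
  ontology <- if (file.exists(ontPath)) readObo(ontPath) else NULL
  mapPath <- file.path(kdir, "hpo2gene.tsv")
  hpoMap <- if (file.exists(mapPath)) readHpoGeneMap(mapPath, ontology) else NULL
  list(kb = kb, pedigrees = pedigrees, phenotypes = phenotypes,
       panels = panels, cnv = cnv, ontology = ontology, hpoMap = hpoMap,
       versions = versions)
}

#' Reanalyse a cohort directory with the configured filter stack
#'
#' Cases are processed sequentially; a failure in one case is logged in the
#' manifest and does not abort the cohort. Cases already marked solved in the
#' registry are skipped unless `include_solved`. Results (candidate table,
#' manifest, registry) are written to `out_dir` when given.
#'
#' @param dir cohort directory (layout above)
#' @param config a [FilterConfig-class]; default the low-hanging-fruit preset
#'   with each case's network panel
#' @param registry case registry (data.frame) carried over from earlier
#'   rounds; default empty
#' @param include_solved reprocess solved cases
#' @param out_dir optional output directory
#' @return list: `rows` (candidate table), `manifest`, `registry`,
#'   `inputs` (loaded cohort inputs)
#' @export
reanalyseCohort <- function(dir, config = NULL, registry = newCaseRegistry(),
                            include_solved = FALSE, out_dir = NULL) {
  inputs <- loadCohortInputs(dir)
  if (is.null(config)) {
    cfgPath <- file.path(dir, "config.yaml")
    config <- if (file.exists(cfgPath)) readFilterConfig(cfgPath)
              else lowHangingFruitConfig()
  }

  pedigrees <- inputs$pedigrees
  caseIds <- vapply(pedigrees, indexId, character(1))
  selected <- names(pedigrees)
  if (length(config@case_selection)) {
    selected <- selected[caseIds %in% config@case_selection]
  }
  if (!include_solved) {
    selected <- selected[!caseIds[selected] %in% solvedCases(registry)]
  }
  if (!length(selected)) {
    stop("no cases selected for reanalysis", call. = FALSE)
  }

  ## pass 1: load every family's VariantSet (also feeds the internal AF)
  bundles <- list()
  caseStatus <- list()
  for (fam in selected) {
    ped <- pedigrees[[fam]]
    vcfPath <- file.path(dir, "vcf", paste0(fam, ".vcf"))
    bundles[[fam]] <- tryCatch({
      vs <- readVcfRecords(vcfPath, ped)
      CaseBundle(vs, ped, phenotypeFor(inputs$phenotypes, indexId(ped)),
                 cnv = inputs$cnv)
    }, error = function(e) {
      caseStatus[[fam]] <<- paste("load-failed:", conditionMessage(e))
      NULL
    })
  }
  ok <- !vapply(bundles, is.null, logical(1))
  afInternal <- cohortInternalFrequencies(bundles[ok])

  ## pass 2: sequential per-case filter stack
  allRows <- list()
  funnels <- list()
  for (fam in names(bundles)[ok]) {
    b <- bundles[[fam]]
    ern <- b@phenotype$ern
    cfgCase <- config
    if (is.null(config@panel) && !is.null(ern) && !is.na(ern) &&
        ern %in% names(inputs$panels)) {
      cfgCase@panel <- inputs$panels[[ern]]
    }
    res <- tryCatch(
      runFilterStack(b, inputs$kb, cfgCase, afInternal,
                     hpo_gene_map = inputs$hpoMap, ontology = inputs$ontology),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      caseStatus[[fam]] <- paste("failed:", conditionMessage(res))
      next
    }
    rows <- flagHetArCandidates(res$rows, inputs$kb)
    allRows[[fam]] <- rows
    funnels[[fam]] <- as.list(res$funnel)
    caseStatus[[fam]] <- sprintf("ok:%d", nrow(rows))
  }

  rows <- do.call(rbind, c(allRows, list(emptyCandidateTable())))
  rows <- rows[candidateOrder(rows$case_id, rows$contig, rows$pos,
                              rows$ref, rows$alt), , drop = FALSE]
  rownames(rows) <- NULL

  manifest <- list(
    config_hash = hashConfig(config),
    input_dir = normalizePath(dir),
    knowledge_versions = as.list(inputs$versions),
    n_cases_selected = length(selected),
    n_cases_processed = sum(grepl("^ok:", unlist(caseStatus[selected]))),
    case_status = caseStatus[order(names(caseStatus))],
    funnel = funnels[order(names(funnels))]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeCandidateTable(rows, file.path(out_dir, "candidates.tsv"),
                        versions = inputs$versions)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeCaseRegistry(registry, file.path(out_dir, "registry.tsv"))
  }
  list(rows = rows, manifest = manifest, registry = registry, inputs = inputs)
}

emptyCandidateTable <- function() {
  cols <- candidateTableColumns()
  df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  for (ic in c("pos", "genotype_index", "first_plp_year", "first_association_year")) {
    df[[ic]] <- integer(0)
  }
  for (nc in c("allelic_fraction", "af_external", "af_internal", "pli", "oe")) {
    df[[nc]] <- numeric(0)
  }
  df[cols]
}

hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  vals <- lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (is(v, "GenePanel")) paste(panelId(v), length(panelGenes(v))) else v
  })
  writeLines(utils::capture.output(utils::str(vals)), tmp)
  unname(tools::md5sum(tmp))
}

#' Summarize a completed run directory
#'
#' @param run_dir directory written by [reanalyseCohort()] (needs
#'   `candidates.tsv`, `manifest.json`, `registry.tsv`)
#' @param cohort_dir the cohort input directory (pedigrees and phenotypes)
#' @return a `CohortSummary`; summary TSVs are written next to the inputs
#' @export
summarizeRun <- function(run_dir, cohort_dir) {
  manifestPath <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifestPath)) {
    stop("missing manifest.json in ", run_dir, call. = FALSE)
  }
  rows <- readCandidateTable(file.path(run_dir, "candidates.tsv"))
  registry <- readCaseRegistry(file.path(run_dir, "registry.tsv"))
  pedigrees <- readPed(file.path(cohort_dir, "cohort.ped"))
  phenotypes <- readPhenotypeRecords(file.path(cohort_dir, "phenotypes.json"))
  s <- summarizeCohort(rows, registry, pedigrees, phenotypes)
  writeCohortSummary(s, file.path(run_dir, "summary"))
  s
}

#' Build on-the-fly panels for every phenotyped case
#'
#' @param cohort_dir cohort directory (ontology, HPO-gene map, phenotypes)
#' @param out_dir where to write one panel TSV per case
#' @param mode,expand passed to [onTheFlyPanel()]
#' @return named list of [GenePanel-class]
#' @export
buildOnTheFlyPanels <- function(cohort_dir, out_dir = NULL,
                                mode = "union", expand = TRUE) {
  ontology <- readObo(file.path(cohort_dir, "ontology.obo"))
  hpoMap <- readHpoGeneMap(file.path(cohort_dir, "knowledge", "hpo2gene.tsv"),
                           ontology)
  phenotypes <- readPhenotypeRecords(file.path(cohort_dir, "phenotypes.json"))
  panels <- list()
  for (i in seq_len(nrow(phenotypes))) {
    eid <- phenotypes$experiment_id[i]
    panels[[eid]] <- onTheFlyPanel(phenotypes$hpo[[i]], hpoMap, ontology,
                                   mode = mode, expand = expand,
                                   panel_id = paste0("otf-", eid))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (eid in names(panels)) {
      writeGenePanel(panels[[eid]], file.path(out_dir, paste0(eid, ".tsv")))
    }
  }
  panels
}
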