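## Seedable synthetic-cohort generator. Emulates the statistical structure
## the engine assumes — family-structure mix, planted causative variants
## under every supported inheritance model, knowledge tables with controlled
## assertion years — on a deliberately small genome (two 10 Mb autosomes, a
## 5 Mb X and MT) so ROH logic is exercised cheaply. Every output is a plain
## text file; running twice with the same spec is byte-identical.

SIM_CONTIGS <- c("1" = 10e6, "2" = 10e6, "X" = 5e6, "MT" = 16569)
SIM_ERNS <- c("ITHACA", "RND", "euroNMD", "GENTURIS")
SIM_MODELS <- c("AD-denovo", "AD-inherited", "AR-hom", "AR-hom-in-ROH",
                "AR-comphet", "XL", "MT", "mosaic", "het-AR-only", "none")

#' Specification for a synthetic cohort
#'
#' Defaults encode the study conditions the generator emulates: a cohort
#' that is 28% trios, 68% singletons and 4% other structures; background
#' variant frequencies log-uniform over `[1e-5, 0.5]` so the rarity filters
#' have bite; planted-variant model mix dominated by autosomal dominant and
#' recessive disease with X-linked, mitochondrial and mosaic minorities plus
#' lone-het recessive flags and negative-control families.
#'
#' @param n_families number of families
#' @param seed RNG seed (mandatory)
#' @param structure_mix named proportions over trio/singleton/other
#' @param model_mix named proportions over
#'   `r paste(SIM_MODELS, collapse = ", ")`
#' @param n_background background variant records per family
#' @param background_af_range log-uniform range of background population AFs
#' @param planted_af_range log-uniform range of planted-variant AFs
#' @param planted_af_missing_rate fraction of planted variants absent from
#'   the frequency table (unobserved in the reference population)
#' @param gene_year_probs named probabilities of the gene first-association
#'   year bins `>=2017`, `2015-2016`, `2010-2014`, `<2010`
#' @param variant_year_probs same for the first P/LP assertion year
#' @return a `SimSpec` list
#' @export
simSpec <- function(n_families = 200,
                    seed,
                    structure_mix = c(trio = 0.28, singleton = 0.68, other = 0.04),
                    model_mix = c("AD-denovo" = 0.20, "AD-inherited" = 0.20,
                                  "AR-hom" = 0.10, "AR-hom-in-ROH" = 0.08,
                                  "AR-comphet" = 0.10, "XL" = 0.07,
                                  "MT" = 0.025, "mosaic" = 0.025,
                                  "het-AR-only" = 0.10, "none" = 0.10),
                    n_background = 120,
                    background_af_range = c(1e-5, 0.5),
                    planted_af_range = c(1e-5, 5e-3),
                    planted_af_missing_rate = 0.2,
                    gene_year_probs = c(">=2017" = 0.13, "2015-2016" = 0.09,
                                        "2010-2014" = 0.31, "<2010" = 0.47),
                    variant_year_probs = c(">=2017" = 0.39, "2015-2016" = 0.21,
                                           "2010-2014" = 0.31, "<2010" = 0.09)) {
  if (missing(seed)) stop("a seed is mandatory for simulation", call. = FALSE)
  stopifnot(abs(sum(structure_mix) - 1) < 1e-9,
            abs(sum(model_mix) - 1) < 1e-9,
            all(names(model_mix) %in% SIM_MODELS))
  spec <- list(n_families = n_families, seed = as.integer(seed),
               structure_mix = structure_mix, model_mix = model_mix,
               n_background = n_background,
               background_af_range = background_af_range,
               planted_af_range = planted_af_range,
               planted_af_missing_rate = planted_af_missing_rate,
               gene_year_probs = gene_year_probs,
               variant_year_probs = variant_year_probs)
  class(spec) <- "SimSpec"
  spec
}

## ---- gene model ---------------------------------------------------------

simGeneTable <- function() {
  slot <- function(i) 200000 + (i - 1) * 260000
  mk <- function(contig, idx, class, prefix) {
    data.frame(gene = sprintf("%s%03d", prefix, idx),
               contig = contig, start = slot(idx), end = slot(idx) + 150000,
               class = class, stringsAsFactors = FALSE)
  }
  genes <- rbind(
    mk("1", 1:15, "AD", "GA"), mk("1", 16:30, "AR", "GA"),
    mk("1", 31:36, "decoy", "GA"),
    mk("2", 1:15, "AD", "GB"), mk("2", 16:30, "AR", "GB"),
    mk("2", 31:36, "decoy", "GB")
  )
  xg <- data.frame(gene = sprintf("GX%03d", 1:6), contig = "X",
                   start = 300000 + (0:5) * 700000,
                   end = 300000 + (0:5) * 700000 + 150000,
                   class = "XL", stringsAsFactors = FALSE)
  mt <- data.frame(gene = "GMT001", contig = "MT", start = 1, end = 16569,
                   class = "MT", stringsAsFactors = FALSE)
  rbind(genes, xg, mt)
}

geneAt <- function(genes, contig, pos) {
  hit <- genes$contig == contig & genes$start <= pos & genes$end >= pos
  if (any(hit)) genes$gene[which(hit)[1]] else "INTERGENIC"
}

sampleYear <- function(n, probs) {
  bin <- sample(names(probs), n, replace = TRUE, prob = probs)
  vapply(bin, function(b) switch(b,
    ">=2017" = sample(2017:2020, 1),
    "2015-2016" = sample(2015:2016, 1),
    "2010-2014" = sample(2010:2014, 1),
    "<2010" = sample(1992:2009, 1)), numeric(1))
}

randAllele <- function(n, not = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(not)) {
    clash <- out == not
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == not
    }
  }
  out
}

## ---- cohort generation --------------------------------------------------

#' Simulate a self-contained cohort fixture directory
#'
#' Writes per-family multi-sample VCFs, a cohort PED, phenopacket-style
#' phenotype JSON, knowledge tables (assertions, frequencies, gene-disease
#' associations with first-report years, constraint scores, ACMG classes,
#' HPO-gene map), a small ontology in OBO, per-network gene panels, a CNV
#' BED-dialect file, a filter configuration and the planted-variant truth
#' table. Planted variants are consistent with their inheritance model
#' (genotypes, parental origin, a >= 1.2 Mb homozygous flank for
#' AR-hom-in-ROH, allelic fractions 0.05-0.25 for mosaics) and carry P/LP
#' assertions with panel membership, so they are detectable by the default
#' preset — except deliberate negative-control decoys whose population
#' frequency disqualifies them.
#'
#' @param spec a [simSpec()] list
#' @param dir output directory (created)
#' @return the truth table data.frame, invisibly; all files are in `dir`
#' @export
simulateCohort <- function(spec, dir) {
  stopifnot(inherits(spec, "SimSpec"))
  set.seed(spec$seed)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "knowledge"), showWarnings = FALSE)
  dir.create(file.path(dir, "panels"), showWarnings = FALSE)

  genes <- simGeneTable()
  disease <- genes[genes$class != "decoy", , drop = FALSE]

  ## gene-disease associations (+ a few AD genes with a second AR association)
  g2d <- data.frame(
    gene = disease$gene,
    omim_id = sprintf("OMIM:%06d", 100000 + seq_len(nrow(disease))),
    inheritance = c(AD = "AD", AR = "AR", XL = "XL", MT = "MT")[disease$class],
    first_year = sampleYear(nrow(disease), spec$gene_year_probs),
    stringsAsFactors = FALSE
  )
  dual <- disease$gene[disease$class == "AD"][c(3, 9)]
  g2d <- rbind(g2d, data.frame(
    gene = dual, omim_id = sprintf("OMIM:%06d", 200000 + seq_along(dual)),
    inheritance = "AR", first_year = sampleYear(length(dual), spec$gene_year_probs),
    stringsAsFactors = FALSE))

  constraint <- data.frame(
    gene = genes$gene,
    pli = round(ifelse(genes$class == "AD", stats::runif(nrow(genes), 0.7, 1),
                       stats::runif(nrow(genes), 0, 1)), 4),
    oe = round(stats::runif(nrow(genes), 0.1, 1), 4),
    stringsAsFactors = FALSE
  )

  ## ontology + HPO-gene map
  ont <- simOntology()
  leafTerms <- setdiff(ont@terms,
                       c(ont@root, "HP:0000118", ont@excluded_roots,
                         descendantClosure(ont@excluded_roots, ont),
                         unlist(ont@parents, use.names = FALSE)))
  hpoMap <- data.frame(
    hpo_id = leafTerms[1 + (seq_len(nrow(disease)) - 1) %% length(leafTerms)],
    gene = disease$gene, stringsAsFactors = FALSE)

  ## per-network panels: all disease genes minus a small random holdout
  ## (holdout restricted to autosomal genes so every X/MT gene stays covered)
  panels <- list()
  autoGenes <- disease$gene[disease$class %in% c("AD", "AR")]
  for (e in SIM_ERNS) {
    panels[[e]] <- sort(setdiff(disease$gene, sample(autoGenes, 3)))
  }

  ## background variant pool shared across families (internal-AF bite)
  nPool <- max(300, spec$n_background * 3)
  poolContig <- sample(c("1", "2"), nPool, replace = TRUE)
  poolPos <- vapply(poolContig, function(ctg) {
    sample.int(SIM_CONTIGS[[ctg]] - 1000, 1)
  }, numeric(1))
  poolRef <- randAllele(nPool)
  poolAlt <- randAllele(nPool, not = poolRef)
  lafr <- log(spec$background_af_range)
  poolAf <- exp(stats::runif(nPool, lafr[1], lafr[2]))
  poolGene <- vapply(seq_len(nPool), function(i) {
    geneAt(genes, poolContig[i], poolPos[i])
  }, character(1))
  poolKey <- variantKey(poolContig, poolPos, poolRef, poolAlt)
  dup <- duplicated(poolKey)
  if (any(dup)) {
    keep <- !dup
    poolContig <- poolContig[keep]; poolPos <- poolPos[keep]
    poolRef <- poolRef[keep]; poolAlt <- poolAlt[keep]
    poolAf <- poolAf[keep]; poolGene <- poolGene[keep]; poolKey <- poolKey[keep]
    nPool <- sum(keep)
  }
  poolCsq <- sample(c("missense_variant", "synonymous_variant", "intron_variant",
                      "splice_region_variant"), nPool, replace = TRUE)

  ## family-level draws
  nFam <- spec$n_families
  famIds <- sprintf("FAM%04d", seq_len(nFam))
  structure <- sample(names(spec$structure_mix), nFam, replace = TRUE,
                      prob = spec$structure_mix)
  models <- sample(names(spec$model_mix), nFam, replace = TRUE,
                   prob = spec$model_mix)
  ernOf <- sample(SIM_ERNS, nFam, replace = TRUE,
                  prob = c(1472, 2048, 616, 275) / 4411)

  pedigrees <- list()
  phenoRows <- list()
  truth <- list()
  assertRows <- list()
  acmgRows <- list()
  freqRows <- list(data.frame(contig = poolContig, pos = poolPos, ref = poolRef,
                              alt = poolAlt, af = signif(poolAf, 6),
                              stringsAsFactors = FALSE))
  # a random 5% of rare pool variants stay unobserved in the frequency table
  rarePool <- which(poolAf < 0.001)
  hideFreq <- sample(rarePool, ceiling(length(rarePool) * 0.05))
  freqRows[[1]] <- freqRows[[1]][-hideFreq, , drop = FALSE]
  cnvRows <- list()
  usedKeys <- new.env(hash = TRUE)

  ## background benign/VUS assertions on a slice of the pool
  bgAssert <- sample(nPool, ceiling(nPool * 0.08))
  assertRows[[1]] <- data.frame(
    contig = poolContig[bgAssert], pos = poolPos[bgAssert],
    ref = poolRef[bgAssert], alt = poolAlt[bgAssert],
    significance = sample(c("benign", "likely_benign", "vus"),
                          length(bgAssert), replace = TRUE),
    condition = "not provided", first_plp_year = NA_integer_,
    stringsAsFactors = FALSE)
  acmgBg <- sample(nPool, ceiling(nPool * 0.2))
  acmgRows[[1]] <- data.frame(
    contig = poolContig[acmgBg], pos = poolPos[acmgBg],
    ref = poolRef[acmgBg], alt = poolAlt[acmgBg],
    class = "vus", criteria = "PM2", stringsAsFactors = FALSE)

  drawPlantedSite <- function(geneRow) {
    repeat {
      pos <- sample(seq(geneRow$start, geneRow$end), 1)
      ref <- randAllele(1)
      alt <- randAllele(1, not = ref)
      key <- variantKey(geneRow$contig, pos, ref, alt)
      if (is.null(usedKeys[[key]]) && !key %in% poolKey) {
        usedKeys[[key]] <- TRUE
        return(list(contig = geneRow$contig, pos = pos, ref = ref, alt = alt,
                    key = key))
      }
    }
  }

  for (f in seq_len(nFam)) {
    fam <- famIds[f]
    model <- models[f]
    struct <- structure[f]
    idx <- paste0("E", fam, "_01")
    father <- paste0("E", fam, "_02")
    mother <- paste0("E", fam, "_03")
    idxSex <- if (model == "XL") "male" else sample(c("male", "female"), 1)
    hasFather <- struct == "trio"
    hasMother <- struct %in% c("trio", "other")
    memberIds <- c(idx, if (hasFather) father, if (hasMother) mother)
    fatherAffected <- model == "AD-inherited" && hasFather

    pedigrees[[fam]] <- FamilyPedigree(fam, data.frame(
      experiment_id = memberIds,
      sex = c(idxSex, if (hasFather) "male", if (hasMother) "female"),
      affected = c(TRUE, if (hasFather) fatherAffected, if (hasMother) FALSE),
      father_id = c(if (hasFather) father else NA_character_,
                    if (hasFather) NA_character_, if (hasMother) NA_character_),
      mother_id = c(if (hasMother) mother else NA_character_,
                    if (hasFather) NA_character_, if (hasMother) NA_character_),
      is_index = c(TRUE, if (hasFather) FALSE, if (hasMother) FALSE),
      stringsAsFactors = FALSE
    ))

    ## variant records accumulate as rows of a per-family meta + genotypes
    nMem <- length(memberIds)
    recs <- list()
    addRec <- function(contig, pos, ref, alt, gene, csq, dosage, ploidy,
                       afrac = NA_real_) {
      recs[[length(recs) + 1L]] <<- list(
        contig = contig, pos = pos, ref = ref, alt = alt, gene = gene,
        csq = csq, dosage = dosage, ploidy = ploidy, afrac = afrac)
    }

    ## background: sample from the shared pool
    bg <- sort(sample(nPool, spec$n_background))
    for (b in bg) {
      dos <- stats::rbinom(nMem, 2, poolAf[b])
      if (all(dos == 0)) dos[sample(nMem, 1)] <- 1L
      addRec(poolContig[b], poolPos[b], poolRef[b], poolAlt[b], poolGene[b],
             poolCsq[b], dos, rep(2L, nMem))
    }

    ## planted causative variant(s)
    panelGenesHere <- panels[[ernOf[f]]]
    pickGene <- function(class) {
      cand <- disease[disease$class == class & disease$gene %in% panelGenesHere, ,
                      drop = FALSE]
      if (class == "AR") {
        # lone-het flags need recessive-only genes
        cand <- cand[!cand$gene %in% dual, , drop = FALSE]
      }
      cand[sample(nrow(cand), 1), , drop = FALSE]
    }
    dosOf <- function(dIdx, dFa, dMo) {
      c(dIdx, if (hasFather) dFa, if (hasMother) dMo)
    }
    plantOne <- function(site, gene, dosage, ploidy, afrac = NA_real_,
                         expected = "candidate", detectable = TRUE,
                         af_rare = TRUE) {
      addRec(site$contig, site$pos, site$ref, site$alt, gene,
             "missense_variant", dosage, ploidy, afrac)
      af <- if (af_rare) {
        if (stats::runif(1) < spec$planted_af_missing_rate) NA_real_ else {
          lpr <- log(spec$planted_af_range)
          signif(exp(stats::runif(1, lpr[1], lpr[2])), 6)
        }
      } else signif(stats::runif(1, 0.02, 0.10), 6)
      if (!is.na(af)) {
        freqRows[[length(freqRows) + 1L]] <<- data.frame(
          contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
          af = af, stringsAsFactors = FALSE)
      }
      sig <- sample(c("pathogenic", "likely_pathogenic"), 1, prob = c(0.7, 0.3))
      assertRows[[length(assertRows) + 1L]] <<- data.frame(
        contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
        significance = sig,
        condition = paste("Synthetic disorder", gene),
        first_plp_year = sampleYear(1, spec$variant_year_probs),
        stringsAsFactors = FALSE)
      acmgRows[[length(acmgRows) + 1L]] <<- data.frame(
        contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
        class = sig, criteria = "PVS1;PM2", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        family_id = fam, case_id = idx, model = model,
        contig = site$contig, pos = site$pos, ref = site$ref, alt = site$alt,
        gene = gene, key = site$key, detectable = detectable,
        expected_status = expected, stringsAsFactors = FALSE)
    }

    consangReported <- FALSE
    if (model == "AD-denovo") {
      gr <- pickGene("AD"); s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(1L, 0L, 0L), rep(2L, nMem))
    } else if (model == "AD-inherited") {
      gr <- pickGene("AD"); s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(1L, 1L, 0L), rep(2L, nMem))
    } else if (model %in% c("AR-hom", "AR-hom-in-ROH")) {
      gr <- pickGene("AR"); s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(2L, 1L, 1L), rep(2L, nMem))
      if (model == "AR-hom-in-ROH") {
        consangReported <- TRUE
        ## the flank must be a clean homozygous stretch: background sites that
        ## happened to fall inside it are forced hom-ref for the index
        for (ri in seq_along(recs)) {
          r <- recs[[ri]]
          if (r$contig == s$contig && abs(r$pos - s$pos) <= 750000 &&
              r$ploidy[1] == 2L && r$dosage[1] == 1L) {
            recs[[ri]]$dosage[1] <- 0L
          }
        }
        ## homozygous flank: >= 1.2 Mb of common sites where the index is hom
        offs <- sort(unique(round(stats::runif(34, -750000, 750000))))
        for (o in offs) {
          p <- s$pos + o
          if (p < 1 || p > SIM_CONTIGS[[s$contig]] || p == s$pos) next
          fref <- randAllele(1); falt <- randAllele(1, not = fref)
          idxHom <- sample(c(0L, 2L), 1)
          dPar <- 1L
          addRec(s$contig, p, fref, falt, geneAt(genes, s$contig, p),
                 "intron_variant", dosOf(idxHom, dPar, dPar), rep(2L, nMem))
          freqRows[[length(freqRows) + 1L]] <- data.frame(
            contig = s$contig, pos = p, ref = fref, alt = falt,
            af = signif(stats::runif(1, 0.1, 0.5), 6), stringsAsFactors = FALSE)
        }
      }
    } else if (model == "AR-comphet") {
      gr <- pickGene("AR")
      s1 <- drawPlantedSite(gr); s2 <- drawPlantedSite(gr)
      while (s2$pos == s1$pos) s2 <- drawPlantedSite(gr)
      plantOne(s1, gr$gene, dosOf(1L, 1L, 0L), rep(2L, nMem))
      plantOne(s2, gr$gene, dosOf(1L, 0L, 1L), rep(2L, nMem))
    } else if (model == "XL") {
      gr <- pickGene("XL"); s <- drawPlantedSite(gr)
      # male index hemizygous; father hemizygous ref; mother carrier
      addDos <- dosOf(1L, 0L, 1L)
      addPlo <- c(1L, if (hasFather) 1L, if (hasMother) 2L)
      plantOne(s, gr$gene, addDos, addPlo)
    } else if (model == "MT") {
      gr <- disease[disease$class == "MT", , drop = FALSE]
      s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(1L, 0L, 1L), rep(1L, nMem))
    } else if (model == "mosaic") {
      gr <- pickGene("AD"); s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(1L, 0L, 0L), rep(2L, nMem),
               afrac = round(stats::runif(1, 0.05, 0.25), 3))
    } else if (model == "het-AR-only") {
      gr <- pickGene("AR"); s <- drawPlantedSite(gr)
      fromFather <- stats::runif(1) < 0.5
      plantOne(s, gr$gene,
               dosOf(1L, if (fromFather) 1L else 0L, if (fromFather) 0L else 1L),
               rep(2L, nMem), expected = "het_AR_candidate")
    } else {
      ## negative control: decoy is P/LP and in panel but too common
      gr <- pickGene("AD"); s <- drawPlantedSite(gr)
      plantOne(s, gr$gene, dosOf(1L, 0L, 0L), rep(2L, nMem),
               expected = "none", detectable = FALSE, af_rare = FALSE)
      ## occasional irrelevant het-deletion CNV call elsewhere
      if (stats::runif(1) < 0.3) {
        cnvRows[[length(cnvRows) + 1L]] <- data.frame(
          contig = sample(c("1", "2"), 1),
          start = sample.int(9e6, 1), width = sample(5000:50000, 1),
          experiment_id = idx, stringsAsFactors = FALSE)
      }
    }

    ## assemble the family VariantSet and write its VCF
    meta <- data.frame(
      contig = vapply(recs, `[[`, character(1), "contig"),
      pos = vapply(recs, function(r) as.integer(r$pos), integer(1)),
      ref = vapply(recs, `[[`, character(1), "ref"),
      alt = vapply(recs, `[[`, character(1), "alt"),
      gene = vapply(recs, `[[`, character(1), "gene"),
      consequence = vapply(recs, `[[`, character(1), "csq"),
      filter = "PASS", stringsAsFactors = FALSE)
    genoM <- t(vapply(recs, function(r) as.integer(r$dosage), integer(nMem)))
    ploM <- t(vapply(recs, function(r) as.integer(r$ploidy), integer(nMem)))
    afM <- matrix(NA_real_, nrow(meta), nMem)
    afM[, 1] <- vapply(recs, function(r) r$afrac, numeric(1))
    if (nMem == 1L) { genoM <- matrix(genoM, ncol = 1); ploM <- matrix(ploM, ncol = 1) }
    colnames(genoM) <- colnames(ploM) <- colnames(afM) <- memberIds
    ## dosages above ploidy cannot occur by construction; guard background X? (autosomal only)
    vs <- VariantSet(meta, genoM, ploM, afM, contigs = SIM_CONTIGS)
    writeVcfRecords(vs, file.path(dir, "vcf", paste0(fam, ".vcf")))

    ## phenotype record for the index
    geneTerm <- if (model == "none") character() else {
      hpoMap$hpo_id[match(truth[[length(truth)]]$gene, hpoMap$gene)]
    }
    noise <- sample(leafTerms, 2)
    phenoRows[[length(phenoRows) + 1L]] <- list(
      experiment_id = idx,
      hpo = sort(unique(c(geneTerm, noise))),
      ordo = sprintf("ORPHA:%d", sample(100000:999999, 1)),
      omim = character(),
      ern = ernOf[f],
      consanguinity = consangReported)
  }

  ## ---- write cohort-level files ----------------------------------------
  writePed(pedigrees, file.path(dir, "cohort.ped"))

  pheno <- data.frame(
    experiment_id = vapply(phenoRows, `[[`, character(1), "experiment_id"),
    ern = vapply(phenoRows, `[[`, character(1), "ern"),
    consanguinity = vapply(phenoRows, `[[`, logical(1), "consanguinity"),
    stringsAsFactors = FALSE)
  pheno$hpo <- lapply(phenoRows, `[[`, "hpo")
  pheno$ordo <- lapply(phenoRows, `[[`, "ordo")
  pheno$omim <- lapply(phenoRows, `[[`, "omim")
  writePhenotypeRecords(pheno, file.path(dir, "phenotypes.json"))

  writeTsv <- function(df, name) {
    utils::write.table(df, file.path(dir, "knowledge", name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  writeTsv(do.call(rbind, assertRows), "assertions.tsv")
  freq <- do.call(rbind, freqRows)
  freq <- freq[!duplicated(variantKey(freq$contig, freq$pos, freq$ref, freq$alt)), ]
  writeTsv(freq, "frequencies.tsv")
  writeTsv(g2d, "gene2disease.tsv")
  writeTsv(constraint, "constraint.tsv")
  writeTsv(do.call(rbind, acmgRows), "acmg.tsv")
  writeTsv(hpoMap, "hpo2gene.tsv")
  writeObo(ont, file.path(dir, "ontology.obo"))
  for (e in SIM_ERNS) {
    writeLines(c("gene", panels[[e]]), file.path(dir, "panels", paste0(e, ".tsv")))
  }
  if (length(cnvRows)) {
    cnv <- do.call(rbind, cnvRows)
    writeCnvCalls(data.frame(
      experiment_id = cnv$experiment_id, contig = cnv$contig,
      start = cnv$start, end = cnv$start + cnv$width,
      copy_state = "deletion-het", stringsAsFactors = FALSE),
      file.path(dir, "cnv.bed"))
  }
  truthDf <- do.call(rbind, truth)
  utils::write.table(truthDf, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(
    preset = "low_hanging_fruit",
    af_external_max = 0.01, af_internal_max = 0.02, require_plp = TRUE,
    panels_dir = "panels", knowledge_versions = list(
      assertions = "synthetic-v1", frequencies = "synthetic-v1",
      gene2disease = "synthetic-v1")),
    file.path(dir, "config.yaml"))
  invisible(truthDf)
}

#' Read a planted-variant truth table written by [simulateCohort()]
#' @param path `truth.tsv` path
#' @return data.frame with typed columns (`detectable` logical, `pos` integer)
#' @export
readTruthTable <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  df$pos <- as.integer(df$pos)
  df$detectable <- df$detectable == "TRUE"
  df
}

## small synthetic phenotype ontology: root -> phenotypic-abnormality branch
## (6 systems x 4 mid terms x 2 leaves) plus an excluded modifier branch
simOntology <- function() {
  parents <- list("HP:0000118" = "HP:0000001",
                  "HP:0012823" = "HP:0000001",
                  "HP:0012824" = "HP:0012823")
  n <- 0
  for (b in 1:6) {
    branch <- sprintf("HP:%07d", 1000000 + b)
    parents[[branch]] <- "HP:0000118"
    for (m in 1:4) {
      mid <- sprintf("HP:%07d", 2000000 + b * 100 + m)
      parents[[mid]] <- branch
      for (l in 1:2) {
        leaf <- sprintf("HP:%07d", 3000000 + b * 1000 + m * 10 + l)
        parents[[leaf]] <- mid
      }
    }
  }
  HpoOntology(parents, root = "HP:0000001", excluded_roots = "HP:0012823")
}
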