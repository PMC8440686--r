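# Domain types and format readers/writers.

vcfHeader <- function(samples) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1,length=10000000>",
    "##contig=<ID=X,length=5000000>",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

test_that("VCF genotypes map to alt dosages and missing stays unknown", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader(c("E1", "E2", "E3")),
    "1\t100\t.\tA\tT\t50\tPASS\tGENE=GENE1;CSQ=missense_variant\tGT\t0/1\t0/0\t./."),
    path)
  vs <- readVcfRecords(path, trioPed())
  expect_equal(nVariants(vs), 1L)
  g <- genotypes(vs)
  expect_identical(unname(g[1, "E1"]), 1L)
  expect_identical(unname(g[1, "E2"]), 0L)
  expect_true(is.na(g[1, "E3"]))
  expect_identical(variantInfo(vs)$gene, "GENE1")
})

test_that("multi-allelic sites decompose with allele conservation", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader(c("E1", "E2", "E3")),
    "1\t200\t.\tC\tG,T\t50\tPASS\tGENE=GENE2;CSQ=stop_gained\tGT\t1/2\t0/1\t2/2",
    "1\t300\t.\tG\tA\t50\tPASS\tGENE=GENE3;CSQ=missense_variant\tGT\t0/1\t0/0\t0/0"),
    path)
  vs <- readVcfRecords(path)
  expect_equal(nVariants(vs), 3L)
  site2 <- variantInfo(vs)$pos == 200
  expect_setequal(variantInfo(vs)$alt[site2], c("G", "T"))
  # conservation: total alt dosage equals total ALT alleles in the input GTs
  expect_equal(sum(genotypes(vs)[site2, ]), 1L + 1L + 1L + 2L)
  g <- genotypes(vs)[site2, ]
  alt <- variantInfo(vs)$alt[site2]
  expect_identical(unname(g[alt == "G", "E1"]), 1L)   # 1/2 has one G allele
  expect_identical(unname(g[alt == "T", "E1"]), 1L)
  expect_identical(unname(g[alt == "T", "E3"]), 2L)
})

test_that("index case absent from the VCF is fatal, other members tolerated", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(vcfHeader(c("E1", "E2")),
    "1\t100\t.\tA\tT\t50\tPASS\tGENE=G1;CSQ=missense_variant\tGT\t0/1\t0/0"),
    path)
  expect_warning(readVcfRecords(path, trioPed()), "missing from VCF")
  pedWrongIndex <- FamilyPedigree("F9", data.frame(
    experiment_id = "E9", sex = "male", affected = TRUE,
    father_id = NA_character_, mother_id = NA_character_, is_index = TRUE,
    stringsAsFactors = FALSE))
  expect_error(readVcfRecords(path, pedWrongIndex), "index case")
})

test_that("a written VariantSet re-reads identically (round trip)", {
  vs <- randomVariantSet(n = 100, seed = 7)
  path <- tempfile(fileext = ".vcf")
  writeVcfRecords(vs, path)
  back <- readVcfRecords(path)
  expect_equal(variantInfo(back), variantInfo(vs))
  expect_identical(genotypes(back), genotypes(vs))
  expect_identical(ploidies(back), ploidies(vs))
  expect_equal(allelicFractions(back), allelicFractions(vs), tolerance = 1e-9)
})

test_that("pedigree classification is total: trio, singleton, other", {
  path <- tempfile(fileext = ".ped")
  writeLines(c(
    "F1\tC1\tP1\tM1\t1\t2", "F1\tP1\t0\t0\t1\t1", "F1\tM1\t0\t0\t2\t1",
    "F2\tS1\t0\t0\t2\t2",
    "F3\tC3\t0\tM3\t1\t2", "F3\tM3\t0\t0\t2\t1"), path)
  peds <- readPed(path)
  expect_identical(structureClass(peds$F1), "trio")
  expect_identical(structureClass(peds$F2), "singleton")
  expect_identical(structureClass(peds$F3), "other")
  expect_identical(indexId(peds$F1), "C1")
  # every family got exactly one class
  cls <- vapply(peds, structureClass, character(1))
  expect_true(all(cls %in% c("trio", "singleton", "other")))
})

test_that("PED edge cases: unknown sex warns, cyclic parentage is fatal", {
  p1 <- tempfile()
  writeLines("F1\tA\t0\t0\t9\t2", p1)
  expect_warning(peds <- readPed(p1), "unknown sex")
  expect_identical(pedMembers(peds$F1)$sex, "unknown")
  p2 <- tempfile()
  writeLines(c("F1\tA\tB\t0\t1\t2", "F1\tB\tA\t0\t1\t1"), p2)
  expect_error(readPed(p2), "cyclic")
})

test_that("phenotype records parse, validate HPO ids, partition by network", {
  path <- tempfile(fileext = ".json")
  recs <- data.frame(experiment_id = c("E1", "E2", "E3", "E4"),
                     ern = c("RND", "RND", "ITHACA", "ITHACA"),
                     consanguinity = c(TRUE, FALSE, NA, FALSE),
                     stringsAsFactors = FALSE)
  recs$hpo <- list("HP:0001250", c("HP:0001250", "HP:0004322"),
                   character(), "HP:0002110")
  recs$ordo <- list("ORPHA:123", character(), character(), character())
  recs$omim <- list(character(), "OMIM:101600", character(), character())
  writePhenotypeRecords(recs, path)
  back <- readPhenotypeRecords(path)
  expect_equal(nrow(back), 4L)
  expect_length(back$hpo[[1]], 1L)
  expect_equal(as.vector(table(back$ern)), c(2L, 2L))
  expect_true(back$consanguinity[1])
  expect_true(is.na(back$consanguinity[3]))
  # malformed HPO id is dropped with a warning
  bad <- recs[1, ]
  bad$hpo <- list("HP:12")
  p2 <- tempfile(fileext = ".json")
  writePhenotypeRecords(bad, p2)
  expect_warning(b2 <- readPhenotypeRecords(p2), "malformed")
  expect_length(b2$hpo[[1]], 0L)
  expect_error(readPhenotypeRecords(path, ern_vocabulary = "euroNMD"),
               "outside configured vocabulary")
})

test_that("CNV BED dialect converts to 1-based inclusive coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tdeletion-het\tE1", path)
  cnv <- readCnvCalls(path)
  expect_identical(cnv$contig, "1")
  expect_identical(cnv$start, 1000L)
  expect_identical(cnv$end, 2000L)
  p2 <- tempfile()
  writeLines("1\t10\t20\tweird-state\tE1", p2)
  expect_error(readCnvCalls(p2), "copy_state")
})

test_that("candidate table: empty file, ordering, contract width, round trip", {
  empty <- RDReanalysis:::emptyCandidateTable()
  path <- tempfile(fileext = ".tsv")
  writeCandidateTable(empty, path)
  expect_length(readLines(path), 1L)        # header only
  expect_identical(strsplit(readLines(path), "\t")[[1]], candidateTableColumns())

  row1 <- empty[0, ]
  mk <- function(case, pos, af) {
    r <- as.list(rep(NA, ncol(empty)))
    names(r) <- names(empty)
    r$case_id <- case; r$family_id <- "F1"; r$ern <- "RND"
    r$contig <- "1"; r$pos <- pos; r$ref <- "A"; r$alt <- "T"
    r$gene <- "GENE1"; r$consequence <- "missense_variant"
    r$genotype_index <- 1L; r$genotypes_family <- "E2=0;E3=1"
    r$af_external <- af; r$af_internal <- 0.001
    r$clinical_significance <- "pathogenic"; r$condition <- "Disorder X"
    r$first_plp_year <- 2015L; r$omim_associations <- "OMIM:1"
    r$inheritance_modes <- "AD"; r$first_association_year <- 2010L
    r$pli <- 0.987654321; r$oe <- 0.25
    r$acmg_class <- "pathogenic"; r$acmg_criteria <- "PVS1;PM2"
    r$phenotype_terms <- "HP:0001250"; r$consanguinity_reported <- "no"
    r$consanguinity_inferred <- "froh=0.0000;no"
    r$segregation <- "AD-denovo=yes"; r$roh_region <- "no"
    r$cnv_check <- "na"; r$status <- "candidate"
    as.data.frame(r, stringsAsFactors = FALSE)
  }
  rows <- rbind(mk("E1", 500L, 1.23456789e-4), mk("E1", 100L, 0.002))
  writeCandidateTable(rows, path, versions = c(assertions = "v1"))
  lines <- readLines(path)
  expect_equal(sum(grepl("^## ", lines)), 1L)
  expect_equal(length(lines), 4L)           # stamp + header + 2 rows
  back <- readCandidateTable(path)
  expect_equal(ncol(back), length(candidateTableColumns()))
  expect_identical(back$pos, c(100L, 500L)) # deterministic (case, position) order
  expect_identical(back$case_id, c("E1", "E1"))
  # frequencies survive to 6 significant digits; strings/integers bit-exact
  expect_equal(back$af_external[2], signif(1.23456789e-4, 6))
  expect_identical(back$first_plp_year, c(2015L, 2015L))
  expect_identical(attr(back, "versions")[["assertions"]], "v1")
  # unknown status is refused
  rows$status[1] <- "nonsense"
  expect_error(writeCandidateTable(rows, path), "closed vocabulary")
})

test_that("VariantSet validity enforces the record invariants", {
  meta <- data.frame(contig = "1", pos = 10L, ref = "A", alt = "A",
                     gene = "G", consequence = "x", filter = "PASS",
                     stringsAsFactors = FALSE)
  g <- matrix(0L, 1, 1, dimnames = list(NULL, "E1"))
  expect_error(VariantSet(meta, g), "ref equal to alt")
  meta$alt <- "T,G"
  expect_error(VariantSet(meta, g), "not decomposed")
  meta$alt <- "T"
  meta$pos <- 0L
  expect_error(VariantSet(meta, g), "pos")
  meta$pos <- 10L
  g[1, 1] <- 3L
  expect_error(VariantSet(meta, g), "exceeds ploidy")
})
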