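# Knowledge-table loading, assertion collapse, internal cohort allele
# frequency and the annotation join.

test_that("assertion lookup and collapse rules", {
  kb <- loadKnowledgeFixture()
  a <- kb@assertions
  expect_identical(a$significance[a$key == "1:100:A:T"], "pathogenic")

  # duplicate key with {likely_pathogenic, benign} collapses to conflicting,
  # but the any-P/LP qualification survives for the sensitivity-oriented filter
  dup <- data.frame(contig = c("1", "1"), pos = c(100, 100),
                    ref = c("A", "A"), alt = c("T", "T"),
                    significance = c("likely_pathogenic", "benign"),
                    condition = c("Disorder X", "not provided"),
                    first_plp_year = c(2018, NA), stringsAsFactors = FALSE)
  kb2 <- loadKnowledgeFixture(assertions = dup)
  a2 <- kb2@assertions
  expect_identical(a2$significance, "conflicting")
  expect_true(a2$any_plp)
  expect_identical(a2$first_plp_year, 2018L)

  # concordant-direction duplicates collapse to the most severe label
  dup$significance <- c("likely_pathogenic", "pathogenic")
  dup$first_plp_year <- c(2018, 2012)
  kb3 <- loadKnowledgeFixture(assertions = dup)
  expect_identical(kb3@assertions$significance, "pathogenic")
  expect_identical(kb3@assertions$first_plp_year, 2012L)
})

test_that("assertion collapse is order-independent under row shuffling", {
  set.seed(11)
  base <- data.frame(
    contig = "1", pos = rep(1:20, each = 3), ref = "A", alt = "T",
    significance = sample(c("pathogenic", "likely_pathogenic", "benign",
                            "vus", "likely_benign"), 60, replace = TRUE),
    condition = sample(c("C1", "C2"), 60, replace = TRUE),
    first_plp_year = sample(c(2005:2020, NA), 60, replace = TRUE),
    stringsAsFactors = FALSE)
  base$first_plp_year[!base$significance %in% c("pathogenic", "likely_pathogenic")] <- NA
  # P/LP rows need a year for the KnowledgeBase validity rule
  plp <- base$significance %in% c("pathogenic", "likely_pathogenic")
  base$first_plp_year[plp & is.na(base$first_plp_year)] <- 2010
  kbA <- loadKnowledgeFixture(assertions = base)
  kbB <- loadKnowledgeFixture(assertions = base[sample(nrow(base)), ])
  expect_identical(kbA@assertions, kbB@assertions)
})

test_that("missing mandatory column is fatal and names the column", {
  dir <- tempfile()
  dir.create(dir)
  utils::write.table(data.frame(contig = "1", pos = 1, ref = "A", alt = "T"),
                     file.path(dir, "bad.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  good <- writeKnowledgeFixture(tempfile("kb"))
  expect_error(
    loadKnowledge(file.path(dir, "bad.tsv"), good$frequencies,
                  good$gene2disease, good$constraint),
    "significance")
})

test_that("empty frequency table means every lookup is unobserved (af 0)", {
  kb <- loadKnowledgeFixture(
    frequencies = data.frame(contig = character(), pos = numeric(),
                             ref = character(), alt = character(),
                             af = numeric(), stringsAsFactors = FALSE))
  vs <- randomVariantSet(5, samples = "E1", seed = 3)
  ann <- annotateVariants(vs, kb)
  expect_true(all(ann$af_external == 0))
})

test_that("internal allele frequency follows the family-deduplicated definition", {
  # 10 index cases, one het carrier -> 1/20
  expect_equal(internalAlleleFrequency(c(1L, rep(0L, 9))), 0.05)
  # no carriers -> 0; nothing called -> 0
  expect_equal(internalAlleleFrequency(rep(0L, 10)), 0)
  expect_equal(internalAlleleFrequency(rep(NA_integer_, 4)), 0)
  # missing calls leave the denominator
  expect_equal(internalAlleleFrequency(c(2L, NA, 0L)), 0.5)
  # hemizygous sites use ploidy-1 denominators
  expect_equal(internalAlleleFrequency(c(1L, 0L, 1L), ploidy = c(1L, 1L, 1L)), 2 / 3)
})

test_that("cohort internal frequencies equal a brute-force recount", {
  set.seed(23)
  nFam <- 50
  bundles <- lapply(seq_len(nFam), function(i) {
    vs <- randomVariantSet(n = 30, samples = paste0("E", i, "_", 1:1),
                           seed = 1000 + i)
    ped <- FamilyPedigree(paste0("F", i), data.frame(
      experiment_id = sampleIds(vs)[1], sex = "female", affected = TRUE,
      father_id = NA_character_, mother_id = NA_character_, is_index = TRUE,
      stringsAsFactors = FALSE))
    CaseBundle(vs, ped)
  })
  af <- cohortInternalFrequencies(bundles)

  # brute force: walk every bundle independently, tally alleles per key;
  # an index without the site counts as hom-ref at the default ploidy
  tally <- list()
  for (b in bundles) {
    keys <- variantKeys(b@variants)
    g <- genotypes(b@variants)[, 1]
    p <- ploidies(b@variants)[, 1]
    sex <- pedMembers(b@pedigree)$sex[1]
    for (k in names(af)) {
      i <- match(k, keys)
      ctg <- strsplit(k, ":")[[1]][1]
      defP <- if (ctg == "MT") 1 else if (ctg == "X" && sex == "male") 1 else 2
      cur <- tally[[k]] %||% c(num = 0, den = 0)
      if (is.na(i)) {
        cur <- cur + c(0, defP)
      } else if (!is.na(g[i])) {
        cur <- cur + c(g[i], p[i])
      }
      tally[[k]] <- cur
    }
  }
  brute <- vapply(names(af), function(k) {
    t <- tally[[k]]; if (t["den"] > 0) t[["num"]] / t[["den"]] else 0
  }, numeric(1))
  expect_equal(af, brute[names(af)])
  expect_true(all(af >= 0 & af <= 1))
})

test_that("annotation joins every table and is non-destructive", {
  meta <- data.frame(contig = c("1", "2"), pos = c(100L, 500L),
                     ref = c("A", "C"), alt = c("T", "G"),
                     gene = c("GENE1", "NOSUCH"), consequence = "missense_variant",
                     filter = "PASS", stringsAsFactors = FALSE)
  g <- matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "E1"))
  vs <- VariantSet(meta, g)
  before <- variantInfo(vs)
  kb <- loadKnowledgeFixture(
    acmg = data.frame(contig = "1", pos = 100, ref = "A", alt = "T",
                      class = "pathogenic", criteria = "PVS1;PM2",
                      stringsAsFactors = FALSE))
  ann <- annotateVariants(vs, kb, af_internal = c("1:100:A:T" = 0.004))
  hit <- ann[ann$key == "1:100:A:T", ]
  expect_identical(hit$significance, "pathogenic")
  expect_equal(hit$af_external, 1e-4)
  expect_equal(hit$af_internal, 0.004)
  expect_identical(hit$omim_associations, "OMIM:100001")
  expect_identical(hit$inheritance_modes, "AD")
  expect_equal(hit$pli, 0.99)
  expect_identical(hit$acmg_class, "pathogenic")
  miss <- ann[ann$key != "1:100:A:T", ]
  expect_true(is.na(miss$significance))
  expect_equal(miss$af_external, 0)        # unobserved -> 0, record retained
  expect_identical(miss$omim_associations, "")
  expect_true(is.na(miss$pli))
  # annotation never mutates the variant container
  expect_identical(variantInfo(vs), before)
})

test_that("large annotation join matches a naive nested-loop merge", {
  set.seed(5)
  vs <- randomVariantSet(n = 400, samples = "E1", seed = 99)
  m <- variantInfo(vs)
  pick <- sample(nrow(m), 150)
  asrt <- data.frame(contig = m$contig[pick], pos = m$pos[pick],
                     ref = m$ref[pick], alt = m$alt[pick],
                     significance = "pathogenic", condition = "D",
                     first_plp_year = 2016, stringsAsFactors = FALSE)
  fpick <- sample(nrow(m), 200)
  freq <- data.frame(contig = m$contig[fpick], pos = m$pos[fpick],
                     ref = m$ref[fpick], alt = m$alt[fpick],
                     af = runif(200, 0, 0.5), stringsAsFactors = FALSE)
  genes <- unique(m$gene)[1:20]
  g2d <- data.frame(gene = genes, omim_id = paste0("OMIM:", seq_along(genes)),
                    inheritance = "AR", first_year = 2011,
                    stringsAsFactors = FALSE)
  cons <- data.frame(gene = genes, pli = runif(20), oe = runif(20),
                     stringsAsFactors = FALSE)
  kb <- loadKnowledgeFixture(assertions = asrt, frequencies = freq,
                             gene2disease = g2d, constraint = cons)
  ann <- annotateVariants(vs, kb)

  fkey <- variantKey(freq$contig, freq$pos, freq$ref, freq$alt)
  akey <- variantKey(asrt$contig, asrt$pos, asrt$ref, asrt$alt)
  for (i in seq_len(nrow(m))) {            # naive per-record scan
    k <- variantKey(m$contig[i], m$pos[i], m$ref[i], m$alt[i])
    expAf <- 0
    for (j in seq_along(fkey)) if (fkey[j] == k) expAf <- max(expAf, freq$af[j])
    expect_equal(ann$af_external[i], expAf)
    expect_identical(ann$any_plp[i], k %in% akey)
    gi <- match(m$gene[i], cons$gene)
    if (is.na(gi)) expect_true(is.na(ann$pli[i]))
    else expect_equal(ann$pli[i], cons$pli[gi])
  }
})
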