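# The filter stack, het-AR re-statusing, case tagging, year binning and
# cohort summary arithmetic.

# one hand-built case: trio, two genes, one planted pathogenic variant plus
# assorted rows that each fail exactly one filter
engineFixture <- function() {
  meta <- data.frame(
    contig = "1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "T",
    gene = c("GENE1", "GENE1", "GENE2", "NOPANEL", "GENE1"),
    consequence = "missense_variant", filter = "PASS",
    stringsAsFactors = FALSE)
  g <- matrix(c(1L, 1L, 1L, 1L, 0L,      # index
                0L, 0L, 0L, 0L, 0L,
                0L, 1L, 0L, 0L, 1L),
              5, 3, dimnames = list(NULL, c("E1", "E2", "E3")))
  vs <- VariantSet(meta, g, contigs = c("1" = 10e6))
  asrt <- data.frame(
    contig = "1", pos = c(100, 300, 400, 500),
    ref = "A", alt = "T",
    significance = "pathogenic", condition = "Disorder",
    first_plp_year = 2016, stringsAsFactors = FALSE)
  # pos 200 has no P/LP assertion; pos 300 is too common externally
  freq <- data.frame(contig = "1", pos = c(100, 200, 300, 400, 500),
                     ref = "A", alt = "T",
                     af = c(1e-4, 1e-4, 0.02, 1e-4, 1e-4),
                     stringsAsFactors = FALSE)
  g2d <- data.frame(gene = c("GENE1", "GENE2", "NOPANEL"),
                    omim_id = paste0("OMIM:", 1:3),
                    inheritance = "AD", first_year = 2011,
                    stringsAsFactors = FALSE)
  cons <- data.frame(gene = c("GENE1", "GENE2"), pli = 0.9, oe = 0.3,
                     stringsAsFactors = FALSE)
  kb <- loadKnowledgeFixture(assertions = asrt, frequencies = freq,
                             gene2disease = g2d, constraint = cons)
  bundle <- CaseBundle(vs, trioPed(), list(
    experiment_id = "E1", hpo = "HP:0001250", ordo = character(),
    omim = character(), ern = "RND", consanguinity = FALSE))
  cfg <- lowHangingFruitConfig(panel = GenePanel("P1", c("GENE1", "GENE2")))
  list(bundle = bundle, kb = kb, cfg = cfg)
}

test_that("the preset keeps the planted variant and each broken row fails", {
  fx <- engineFixture()
  res <- runFilterStack(fx$bundle, fx$kb, fx$cfg)
  # pos 100 passes everything; 200 lacks P/LP; 300 too common (0.02 >= 0.01);
  # 400 is off-panel; 500 not carried by the index
  expect_identical(res$rows$pos, 100L)
  expect_identical(res$rows$status, "candidate")
  expect_identical(res$rows$clinical_significance, "pathogenic")
  expect_match(res$rows$segregation, "AD-denovo=yes")
  expect_equal(unname(res$funnel[["total"]]), 5)
  expect_equal(unname(res$funnel[["index_carrier"]]), 1)
})

test_that("the rarity bound is strict: af_external 0.02 fails, 0.0099 passes", {
  fx <- engineFixture()
  loose <- fx$cfg
  slot(loose, "af_external_max") <- 0.021
  res <- runFilterStack(fx$bundle, fx$kb, loose)
  expect_setequal(res$rows$pos, c(100L, 300L))
  exact <- fx$cfg
  slot(exact, "af_external_max") <- 0.02    # strict <: 0.02 still fails
  res2 <- runFilterStack(fx$bundle, fx$kb, exact)
  expect_identical(res2$rows$pos, 100L)
})

test_that("internal cohort frequency filters at its own threshold", {
  fx <- engineFixture()
  af <- c("1:100:A:T" = 0.05)               # common inside the cohort
  res <- runFilterStack(fx$bundle, fx$kb, fx$cfg, af_internal = af)
  expect_equal(nrow(res$rows), 0L)
})

test_that("tightening thresholds or shrinking the panel never adds rows", {
  run <- acceptanceRun()
  bundle <- run$result$inputs |> (function(inputs) {
    ped <- inputs$pedigrees[[1]]
    vs <- readVcfRecords(file.path(run$dir, "vcf",
                                   paste0(familyId(ped), ".vcf")), ped)
    CaseBundle(vs, ped, phenotypeFor(inputs$phenotypes, indexId(ped)))
  })()
  kb <- run$result$inputs$kb
  panel <- run$result$inputs$panels[[bundle@phenotype$ern]]
  base <- lowHangingFruitConfig(panel = panel, require_plp = FALSE)
  rows0 <- runFilterStack(bundle, kb, base)$rows
  keys0 <- variantKey(rows0$contig, rows0$pos, rows0$ref, rows0$alt)
  for (afMax in c(0.005, 0.001, 1e-4)) {
    cfg <- base
    slot(cfg, "af_external_max") <- afMax
    keys <- with(runFilterStack(bundle, kb, cfg)$rows,
                 variantKey(contig, pos, ref, alt))
    expect_true(all(keys %in% keys0))
    keys0prev <- keys
  }
  shrunk <- base
  slot(shrunk, "panel") <- GenePanel("half", panelGenes(panel)[
    seq_len(length(panelGenes(panel)) %/% 2)])
  keysS <- with(runFilterStack(bundle, kb, shrunk)$rows,
                variantKey(contig, pos, ref, alt))
  expect_true(all(keysS %in% keys0))
})

test_that("the survivor set equals a naive per-variant predicate evaluation", {
  run <- acceptanceRun()
  inputs <- run$result$inputs
  kb <- inputs$kb
  fams <- names(inputs$pedigrees)[1:25]
  bundles <- lapply(fams, function(f) {
    ped <- inputs$pedigrees[[f]]
    vs <- readVcfRecords(file.path(run$dir, "vcf", paste0(f, ".vcf")), ped)
    CaseBundle(vs, ped, phenotypeFor(inputs$phenotypes, indexId(ped)))
  })
  names(bundles) <- fams
  afInt <- cohortInternalFrequencies(bundles)
  for (f in fams[1:8]) {
    b <- bundles[[f]]
    panel <- inputs$panels[[b@phenotype$ern]]
    cfg <- lowHangingFruitConfig(panel = panel)
    rows <- runFilterStack(b, kb, cfg, af_internal = afInt)$rows
    ann <- annotateVariants(b@variants, kb, afInt)
    m <- variantInfo(b@variants)
    gIdx <- genotypes(b@variants)[, indexId(b)]
    naive <- character()
    for (i in seq_len(nrow(m))) {          # plain conjunction, one row at a time
      if (is.na(gIdx[i]) || gIdx[i] < 1) next
      if (!(ann$af_external[i] < 0.01)) next
      if (!(ann$af_internal[i] < 0.02)) next
      if (!toupper(m$gene[i]) %in% panelGenes(panel)) next
      if (!isTRUE(ann$any_plp[i])) next
      naive <- c(naive, ann$key[i])
    }
    expect_setequal(variantKey(rows$contig, rows$pos, rows$ref, rows$alt), naive)
  }
})

test_that("lone hets in recessive-only genes are re-statused, pairs are not", {
  fx <- engineFixture()
  rows <- runFilterStack(fx$bundle, fx$kb, fx$cfg)$rows
  # GENE1 is AD: the lone het stays a candidate
  expect_identical(flagHetArCandidates(rows, fx$kb)$status, "candidate")
  # re-declare GENE1 as AR-only: the lone het becomes het_AR_candidate
  kbAr <- loadKnowledgeFixture(
    assertions = data.frame(contig = "1", pos = 100, ref = "A", alt = "T",
                            significance = "pathogenic", condition = "D",
                            first_plp_year = 2016, stringsAsFactors = FALSE),
    gene2disease = data.frame(gene = "GENE1", omim_id = "OMIM:9",
                              inheritance = "AR", first_year = 2011,
                              stringsAsFactors = FALSE))
  expect_identical(flagHetArCandidates(rows, kbAr)$status, "het_AR_candidate")
  # two candidate rows in the same AR gene (potential compound het) both stay
  rows2 <- rbind(rows, rows)
  rows2$pos[2] <- 150L
  expect_identical(flagHetArCandidates(rows2, kbAr)$status,
                   c("candidate", "candidate"))
})

test_that("case tagging updates rows, registry, and is guarded", {
  fx <- engineFixture()
  loose <- fx$cfg
  slot(loose, "af_external_max") <- 0.021
  rows <- runFilterStack(fx$bundle, fx$kb, loose)$rows   # two rows for E1
  reg <- newCaseRegistry()
  out <- tagCaseStatus(reg, rows, "E1", "solved", variant_keys = "1:100:A:T")
  expect_identical(out$rows$status[out$rows$pos == 100], "solved")
  expect_identical(out$rows$status[out$rows$pos == 300], "rejected")
  expect_identical(solvedCases(out$registry), "E1")
  expect_error(tagCaseStatus(reg, rows, "E1", "solved", variant_keys = "1:9:A:T"),
               "not among case")
  expect_error(tagCaseStatus(reg, rows, "E1", "solved"), "requires variant keys")
  # registry TSV round trip
  p <- tempfile()
  writeCaseRegistry(out$registry, p)
  expect_identical(readCaseRegistry(p), out$registry)
})

test_that("randomized decision sequences match an event-log replay oracle", {
  set.seed(404)
  fx <- engineFixture()
  loose <- fx$cfg
  slot(loose, "af_external_max") <- 0.021
  baseRows <- runFilterStack(fx$bundle, fx$kb, loose)$rows
  for (rep in 1:10) {
    events <- lapply(1:6, function(i) {
      d <- sample(c("solved", "under_evaluation", "unsolved", "prioritised"), 1)
      list(decision = d,
           keys = if (d %in% c("solved", "prioritised")) "1:100:A:T" else character())
    })
    reg <- newCaseRegistry(); rows <- baseRows
    for (e in events) {
      st <- tagCaseStatus(reg, rows, "E1", e$decision, e$keys)
      reg <- st$registry; rows <- st$rows
    }
    # oracle: the registry state is determined by the last event alone
    last <- events[[length(events)]]
    expect_equal(nrow(reg), 1L)
    expect_identical(reg$status, last$decision)
    expect_identical(reg$solved_keys, paste(last$keys, collapse = ";"))
  }
})

test_that("year binning assigns bins and tallies correctly", {
  empty <- RDReanalysis:::emptyCandidateTable()
  yb0 <- yearBinCausatives(empty)
  expect_true(all(yb0$n == 0))
  mkSolved <- function(gy, vy) {
    r <- empty[0, ]
    n <- length(gy)
    r <- data.frame(first_association_year = gy, first_plp_year = vy)
    r
  }
  one <- mkSolved(2018L, 2019L)
  yb <- yearBinCausatives(one)
  expect_equal(yb$n[yb$level == "gene" & yb$bin == ">=2017"], 1L)
  expect_equal(yb$n[yb$level == "variant" & yb$bin == ">=2017"], 1L)
  # 124 synthetic rows with known years equal a direct tally
  set.seed(12)
  gy <- sample(c(2018L, 2015L, 2012L, 2000L, NA), 124, replace = TRUE)
  vy <- sample(1995:2020, 124, replace = TRUE)
  yb <- yearBinCausatives(mkSolved(gy, vy))
  expect_equal(yb$n[yb$level == "gene" & yb$bin == ">=2017"],
               sum(gy >= 2017, na.rm = TRUE))
  expect_equal(yb$n[yb$level == "gene" & yb$bin == "unknown"], sum(is.na(gy)))
  expect_equal(yb$n[yb$level == "variant" & yb$bin == "2010-2014"],
               sum(vy >= 2010 & vy <= 2014))
  expect_equal(sum(yb$n[yb$level == "variant"]), 124L)
})

test_that("summary reconciliation on a tiny assembled cohort", {
  fx <- engineFixture()
  rows <- runFilterStack(fx$bundle, fx$kb, fx$cfg)$rows
  peds <- list(F1 = trioPed("F1"), F2 = singletonPed("F2", id = "E9"))
  # second case: no rows, tagged unsolved implicitly
  pheno <- data.frame(experiment_id = c("E1"), ern = "RND",
                      consanguinity = FALSE, stringsAsFactors = FALSE)
  pheno$hpo <- list("HP:0001250"); pheno$ordo <- list(character())
  pheno$omim <- list(character())
  st <- tagCaseStatus(newCaseRegistry(), rows, "E1", "solved",
                      variant_keys = "1:100:A:T")
  s <- summarizeCohort(st$rows, st$registry, peds, pheno)
  expect_equal(s$total$n_cases, 2)
  expect_equal(s$total$n_trio, 1)
  expect_equal(s$total$n_singleton, 1)
  expect_equal(s$total$n_cases_with_candidates, 1)
  expect_equal(s$total$n_solved, 1)
  expect_equal(s$total$n_unsolved, 1)
  expect_equal(s$total$n_candidate_variants, 1)   # solved row still counted
  # per-network counts sum to the totals
  expect_equal(sum(s$by_ern$n_cases_with_candidates),
               s$total$n_cases_with_candidates)
})
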