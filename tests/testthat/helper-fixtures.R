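# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from static data files.

# a trio pedigree: index E1, father E2 (affected when aff_father), mother E3
trioPed <- function(fam = "F1", index_sex = "male", aff_father = FALSE) {
  FamilyPedigree(fam, data.frame(
    experiment_id = c("E1", "E2", "E3"),
    sex = c(index_sex, "male", "female"),
    affected = c(TRUE, aff_father, FALSE),
    father_id = c("E2", NA, NA),
    mother_id = c("E3", NA, NA),
    is_index = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  ))
}

singletonPed <- function(fam = "F1", index_sex = "female", id = "E1") {
  FamilyPedigree(fam, data.frame(
    experiment_id = id, sex = index_sex, affected = TRUE,
    father_id = NA_character_, mother_id = NA_character_, is_index = TRUE,
    stringsAsFactors = FALSE
  ))
}

# a small random VariantSet for round-trip / property tests
randomVariantSet <- function(n = 100, samples = c("E1", "E2", "E3"), seed = 1) {
  set.seed(seed)
  contig <- sample(c("1", "2", "X", "MT"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.07, 0.03))
  lens <- c("1" = 9e6, "2" = 9e6, "X" = 4.9e6, "MT" = 16000)
  pos <- integer(n)
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    pos[sel] <- sample.int(lens[[ctg]], sum(sel))   # unique within contig
  }
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  meta <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                     gene = sprintf("G%03d", sample(50, n, replace = TRUE)),
                     consequence = "missense_variant", filter = "PASS",
                     stringsAsFactors = FALSE)
  nS <- length(samples)
  plo <- matrix(2L, n, nS, dimnames = list(NULL, samples))
  plo[contig == "MT", ] <- 1L
  plo[contig == "X", 1] <- 1L               # treat sample 1 as male
  geno <- matrix(0L, n, nS, dimnames = list(NULL, samples))
  for (s in seq_len(nS)) {
    geno[, s] <- vapply(plo[, s], function(p) sample(0:p, 1), integer(1))
  }
  geno[sample(length(geno), n %/% 10)] <- NA_integer_
  afrac <- matrix(NA_real_, n, nS, dimnames = list(NULL, samples))
  mos <- sample(n, 5)
  afrac[mos, 1] <- round(runif(5, 0.05, 0.95), 3)
  geno[mos, 1] <- pmin(1L, plo[mos, 1])     # carriers where a fraction exists
  VariantSet(meta, geno, plo, afrac,
             contigs = c("1" = 10e6, "2" = 10e6, "X" = 5e6, "MT" = 16569))
}

# minimal knowledge tables written to a temp dir; returns the path list
writeKnowledgeFixture <- function(dir,
                                  assertions = NULL, frequencies = NULL,
                                  gene2disease = NULL, constraint = NULL,
                                  acmg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (is.null(assertions)) {
    assertions <- data.frame(contig = "1", pos = 100, ref = "A", alt = "T",
                             significance = "pathogenic", condition = "Disorder X",
                             first_plp_year = 2015, stringsAsFactors = FALSE)
  }
  if (is.null(frequencies)) {
    frequencies <- data.frame(contig = "1", pos = 100, ref = "A", alt = "T",
                              af = 0.0001, stringsAsFactors = FALSE)
  }
  if (is.null(gene2disease)) {
    gene2disease <- data.frame(gene = "GENE1", omim_id = "OMIM:100001",
                               inheritance = "AD", first_year = 2012,
                               stringsAsFactors = FALSE)
  }
  if (is.null(constraint)) {
    constraint <- data.frame(gene = "GENE1", pli = 0.99, oe = 0.2,
                             stringsAsFactors = FALSE)
  }
  list(
    assertions = w(assertions, "assertions.tsv"),
    frequencies = w(frequencies, "frequencies.tsv"),
    gene2disease = w(gene2disease, "gene2disease.tsv"),
    constraint = w(constraint, "constraint.tsv"),
    acmg = if (!is.null(acmg)) w(acmg, "acmg.tsv")
  )
}

loadKnowledgeFixture <- function(...) {
  paths <- writeKnowledgeFixture(tempfile("kb"), ...)
  loadKnowledge(paths$assertions, paths$frequencies, paths$gene2disease,
                paths$constraint, paths$acmg)
}

# a small hand-built ontology: root -> A -> (B, C); B -> D; excluded branch M
chainOntology <- function() {
  HpoOntology(list(
    "HP:0000118" = "HP:0000001",
    "HP:0000002" = "HP:0000118",            # A
    "HP:0000003" = "HP:0000002",            # B
    "HP:0000004" = "HP:0000002",            # C
    "HP:0000005" = "HP:0000003",            # D (leaf under B)
    "HP:0012823" = "HP:0000001",
    "HP:0012824" = "HP:0012823"
  ), root = "HP:0000001", excluded_roots = "HP:0012823")
}
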