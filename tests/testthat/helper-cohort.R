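# The shared 200-family synthetic cohort used by the end-to-end tests.
# Simulated once per test run at a fixed seed; the reanalysis result is
# cached alongside it.

ACCEPTANCE_SEED <- 1L
ACCEPTANCE_N_FAMILIES <- 200L

acceptanceCohortDir <- function() {
  dir <- file.path(tempdir(), "rdre-acceptance-cohort")
  if (!file.exists(file.path(dir, "truth.tsv"))) {
    simulateCohort(simSpec(n_families = ACCEPTANCE_N_FAMILIES,
                           seed = ACCEPTANCE_SEED), dir)
  }
  dir
}

acceptanceRun <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- acceptanceCohortDir()
      cache <<- list(
        dir = dir,
        truth = readTruthTable(file.path(dir, "truth.tsv")),
        result = reanalyseCohort(dir)
      )
    }
    cache
  }
})

rowKeysOf <- function(rows) {
  paste(rows$case_id, rows$contig, rows$pos, rows$ref, rows$alt)
}

truthKeysOf <- function(truth) {
  paste(truth$case_id, truth$contig, truth$pos, truth$ref, truth$alt)
}
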