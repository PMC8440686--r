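## Cohort accounting: per-network and total counts, derived means and
## percentages, and the knowledge-recency year binning of causative variants
## (why was this variant missed originally? often because the gene-disease
## link or the pathogenicity assertion postdates the original analysis).

YEAR_BINS <- c(">=2017", "2015-2016", "2010-2014", "<2010", "unknown")

#' Bin causative variants by knowledge-recency year
#'
#' Two histograms over the bins `>=2017`, `2015-2016`, `2010-2014`, `<2010`
#' (`unknown` for missing years): gene level uses the year the gene was first
#' associated with disease, variant level the year the variant was first
#' asserted pathogenic/likely pathogenic. Percentages are of the
#' causative-variant total, half-up rounded to integers.
#'
#' @param solvedRows candidate data.frame restricted to causative
#'   (status `solved`) rows
#' @return data.frame with columns `level` (`gene`/`variant`), `bin`, `n`, `pct`
#' @export
yearBinCausatives <- function(solvedRows) {
  binOf <- function(year) {
    ifelse(is.na(year), "unknown",
      ifelse(year >= 2017, ">=2017",
        ifelse(year >= 2015, "2015-2016",
          ifelse(year >= 2010, "2010-2014", "<2010"))))
  }
  total <- nrow(solvedRows)
  mk <- function(level, years) {
    bins <- factor(binOf(years), levels = YEAR_BINS)
    tab <- table(bins)
    data.frame(level = level, bin = names(tab), n = as.integer(tab),
               pct = if (total) derivedPercent(as.integer(tab), total, 0) else 0,
               stringsAsFactors = FALSE)
  }
  rbind(mk("gene", solvedRows$first_association_year),
        mk("variant", solvedRows$first_plp_year))
}

#' Summarize a cohort run
#'
#' Per-network and total counts with derived statistics. Case-level status
#' follows the precedence solved > under_evaluation > het_AR_candidate >
#' unsolved: a case carries exactly one tag. Percentages are half-up rounded
#' to one decimal, means to two decimals.
#'
#' @param rows candidate data.frame (all emitted rows, statuses up to date)
#' @param registry case registry data.frame
#' @param pedigrees named list of [FamilyPedigree-class] for every analysed
#'   case (solved-skipped cases included: they count toward cohort totals)
#' @param phenotypes phenotype record data.frame (maps cases to networks)
#' @return object of class `CohortSummary`: list with `by_ern` (data.frame),
#'   `total` (named list), `year_bins` (from [yearBinCausatives()])
#' @export
summarizeCohort <- function(rows, registry, pedigrees, phenotypes) {
  caseIds <- vapply(pedigrees, indexId, character(1))
  ern <- vapply(caseIds, function(id) {
    phenotypeFor(phenotypes, id)$ern %||% NA_character_
  }, character(1))
  struct <- vapply(pedigrees, structureClass, character(1))

  caseStatus <- stats::setNames(rep("unsolved", length(caseIds)), caseIds)
  hetArCases <- unique(rows$case_id[rows$status == "het_AR_candidate"])
  caseStatus[names(caseStatus) %in% hetArCases] <- "het_AR"
  ue <- registry$case_id[registry$status == "under_evaluation"]
  caseStatus[names(caseStatus) %in% ue] <- "under_evaluation"
  caseStatus[names(caseStatus) %in% solvedCases(registry)] <- "solved"

  counted <- rows[rows$status != "rejected", , drop = FALSE]
  prioritisedRows <- rows[rows$status %in% c("prioritised", "solved"), , drop = FALSE]
  prioritisedCases <- union(
    unique(prioritisedRows$case_id),
    registry$case_id[registry$status %in% c("prioritised", "solved")])

  oneErn <- function(ids) {
    sel <- caseIds %in% ids
    r <- counted[counted$case_id %in% ids, , drop = FALSE]
    pr <- prioritisedRows[prioritisedRows$case_id %in% ids, , drop = FALSE]
    st <- caseStatus[ids]
    nCases <- sum(sel)
    nWith <- length(unique(r$case_id))
    list(
      n_cases = nCases,
      n_trio = sum(struct[sel] == "trio"),
      n_singleton = sum(struct[sel] == "singleton"),
      n_other = sum(struct[sel] == "other"),
      n_candidate_variants = nrow(r),
      n_cases_with_candidates = nWith,
      n_prioritised_variants = nrow(pr),
      n_prioritised_cases = length(intersect(prioritisedCases, ids)),
      n_solved = sum(st == "solved"),
      n_under_evaluation = sum(st == "under_evaluation"),
      n_het_ar_cases = sum(st == "het_AR"),
      n_unsolved = sum(st == "unsolved"),
      mean_candidates_per_case = derivedMean(nrow(r), nWith),
      pct_cases_with_candidates = derivedPercent(nWith, nCases),
      pct_trio = derivedPercent(sum(struct[sel] == "trio"), nCases),
      pct_singleton = derivedPercent(sum(struct[sel] == "singleton"), nCases),
      pct_other = derivedPercent(sum(struct[sel] == "other"), nCases)
    )
  }

  erns <- sort(unique(stats::na.omit(ern)))
  byErn <- do.call(rbind, lapply(erns, function(e) {
    as.data.frame(c(list(ern = e), oneErn(caseIds[!is.na(ern) & ern == e])),
                  stringsAsFactors = FALSE)
  }))
  total <- oneErn(caseIds)

  solvedRows <- rows[rows$status == "solved", , drop = FALSE]
  out <- list(by_ern = byErn, total = total,
              year_bins = yearBinCausatives(solvedRows))
  class(out) <- "CohortSummary"
  out
}

#' @export
print.CohortSummary <- function(x, ...) {
  t <- x$total
  cat("CohortSummary\n")
  cat(sprintf("  cases: %d (trio %d / singleton %d / other %d)\n",
              t$n_cases, t$n_trio, t$n_singleton, t$n_other))
  cat(sprintf("  candidate variants: %d in %d case(s) (%.1f%% of cases, mean %.2f per case)\n",
              t$n_candidate_variants, t$n_cases_with_candidates,
              t$pct_cases_with_candidates, t$mean_candidates_per_case))
  cat(sprintf("  prioritised: %d variant(s) in %d case(s)\n",
              t$n_prioritised_variants, t$n_prioritised_cases))
  cat(sprintf("  solved %d | under evaluation %d | het-AR %d | unsolved %d\n",
              t$n_solved, t$n_under_evaluation, t$n_het_ar_cases, t$n_unsolved))
  invisible(x)
}

#' Write per-network and total summary TSVs
#' @param summary a `CohortSummary`
#' @param dir output directory
#' @return the directory, invisibly
#' @export
writeCohortSummary <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(summary$by_ern, file.path(dir, "summary_by_ern.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tot <- data.frame(metric = names(summary$total),
                    value = unlist(summary$total), stringsAsFactors = FALSE)
  utils::write.table(tot, file.path(dir, "summary_total.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summary$year_bins, file.path(dir, "year_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
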