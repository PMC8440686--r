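## Case-status registry: the durable record of interpretation decisions
## across reanalysis rounds. Solved cases are excluded from subsequent rounds
## unless explicitly re-included.

#' Create an empty case registry
#' @return data.frame with columns `case_id`, `status`, `solved_keys`, `round`
#' @export
newCaseRegistry <- function() {
  data.frame(case_id = character(), status = character(),
             solved_keys = character(), round = integer(),
             stringsAsFactors = FALSE)
}

#' Record an interpretation decision for a case
#'
#' Decisions: `solved` (with the causative variant keys), `prioritised`
#' (with the prioritised keys), `under_evaluation`, `unsolved`. Solving or
#' prioritising with a variant key not among the case's candidate rows is
#' fatal. On `solved`, the named rows become `solved` and the case's other
#' rows `rejected`; on `prioritised`, the named rows become `prioritised`
#' and others keep their status.
#'
#' @param registry data.frame from [newCaseRegistry()]
#' @param rows candidate data.frame (updated statuses are returned)
#' @param case_id index-case experiment id
#' @param decision one of `solved`, `prioritised`, `under_evaluation`, `unsolved`
#' @param variant_keys keys for `solved` / `prioritised`
#' @param round reanalysis round number
#' @return list with updated `registry` and `rows`
#' @export
tagCaseStatus <- function(registry, rows, case_id,
                          decision = c("solved", "prioritised",
                                       "under_evaluation", "unsolved"),
                          variant_keys = character(), round = 1L) {
  decision <- match.arg(decision)
  caseRows <- rows$case_id == case_id
  rowKeys <- variantKey(rows$contig, rows$pos, rows$ref, rows$alt)
  if (decision %in% c("solved", "prioritised")) {
    if (!length(variant_keys)) {
      stop("decision '", decision, "' requires variant keys", call. = FALSE)
    }
    off <- setdiff(variant_keys, rowKeys[caseRows])
    if (length(off)) {
      stop("variant key(s) not among case ", case_id, "'s rows: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
  }
  if (decision == "solved") {
    rows$status[caseRows & rowKeys %in% variant_keys] <- "solved"
    rows$status[caseRows & !(rowKeys %in% variant_keys)] <- "rejected"
  } else if (decision == "prioritised") {
    rows$status[caseRows & rowKeys %in% variant_keys] <- "prioritised"
  } else if (decision == "under_evaluation") {
    rows$status[caseRows & rows$status %in% c("candidate", "prioritised")] <-
      "under_evaluation"
  }
  registry <- registry[registry$case_id != case_id, , drop = FALSE]
  registry <- rbind(registry, data.frame(
    case_id = case_id,
    status = decision,
    solved_keys = paste(variant_keys, collapse = ";"),
    round = as.integer(round),
    stringsAsFactors = FALSE
  ))
  rownames(registry) <- NULL
  list(registry = registry, rows = rows)
}

#' Case ids marked solved in a registry
#' @param registry case registry data.frame
#' @return character vector
#' @export
solvedCases <- function(registry) {
  registry$case_id[registry$status == "solved"]
}

#' Read / write the registry TSV
#' @param path TSV path
#' @return the registry data.frame ([readCaseRegistry()]) or `path`
#' @export
readCaseRegistry <- function(path) {
  if (!file.exists(path)) return(newCaseRegistry())
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character", "integer"))
}

#' @rdname readCaseRegistry
#' @param registry registry data.frame
#' @export
writeCaseRegistry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
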