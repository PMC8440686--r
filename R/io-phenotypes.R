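## Phenopacket-style JSON: an array of records, each with a subject id,
## phenotypicFeatures (HPO term objects), diseases (ORDO / OMIM term objects)
## and a metaData block carrying the submitting-network tag and the reported
## consanguinity flag.

#' Read phenotype records from phenopacket-style JSON
#'
#' Returns one row per experiment with list-columns of ontology codes.
#' HPO identifiers failing the `HP:NNNNNNN` pattern are dropped with a
#' warning; records without a subject id are skipped with a warning.
#'
#' @param path JSON file (array of phenopacket-style objects)
#' @param ern_vocabulary allowed submitting-network labels; tags outside the
#'   vocabulary raise an error
#' @return data.frame with columns `experiment_id`, `hpo` (list), `ordo`
#'   (list), `omim` (list), `ern`, `consanguinity` (logical, `NA` = unknown)
#' @export
readPhenotypeRecords <- function(path, ern_vocabulary = NULL) {
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rows <- list()
  for (r in recs) {
    eid <- r$subject$id %||% r$id
    if (is.null(eid) || !nzchar(eid)) {
      warning("phenotype record without experiment id skipped", call. = FALSE)
      next
    }
    hpo <- vapply(r$phenotypicFeatures %||% list(),
                  function(f) f$type$id %||% NA_character_, character(1))
    bad <- !grepl("^HP:[0-9]{7}$", hpo)
    if (any(bad)) {
      warning("record ", eid, ": dropped malformed HPO id(s): ",
              paste(hpo[bad], collapse = ", "), call. = FALSE)
    }
    hpo <- hpo[!bad]
    disease <- vapply(r$diseases %||% list(),
                      function(d) d$term$id %||% NA_character_, character(1))
    ordo <- disease[grepl("^(ORPHA|Orphanet):", disease)]
    omim <- disease[grepl("^OMIM:", disease)]
    ern <- r$metaData$ern %||% NA_character_
    cons <- r$metaData$consanguinity
    cons <- if (is.null(cons)) NA else isTRUE(cons)
    rows[[length(rows) + 1L]] <- list(experiment_id = eid, hpo = hpo,
                                      ordo = ordo, omim = omim, ern = ern,
                                      consanguinity = cons)
  }
  df <- data.frame(
    experiment_id = vapply(rows, `[[`, character(1), "experiment_id"),
    ern = vapply(rows, `[[`, character(1), "ern"),
    consanguinity = vapply(rows, `[[`, logical(1), "consanguinity"),
    stringsAsFactors = FALSE
  )
  df$hpo <- lapply(rows, `[[`, "hpo")
  df$ordo <- lapply(rows, `[[`, "ordo")
  df$omim <- lapply(rows, `[[`, "omim")
  if (!is.null(ern_vocabulary)) {
    off <- stats::na.omit(setdiff(df$ern, ern_vocabulary))
    if (length(off)) {
      stop("ERN tag(s) outside configured vocabulary: ",
           paste(off, collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Write phenotype records to phenopacket-style JSON
#' @param records data.frame as returned by [readPhenotypeRecords()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writePhenotypeRecords <- function(records, path) {
  objs <- lapply(seq_len(nrow(records)), function(i) {
    list(
      id = paste0("phenopacket-", records$experiment_id[i]),
      subject = list(id = records$experiment_id[i]),
      phenotypicFeatures = lapply(records$hpo[[i]], function(t) list(type = list(id = t))),
      diseases = lapply(c(records$ordo[[i]], records$omim[[i]]),
                        function(d) list(term = list(id = d))),
      metaData = list(ern = records$ern[i],
                      consanguinity = records$consanguinity[i])
    )
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}

## one-case phenotype list for a CaseBundle
phenotypeFor <- function(records, experiment_id) {
  i <- match(experiment_id, records$experiment_id)
  if (is.na(i)) {
    return(list(experiment_id = experiment_id, hpo = character(),
                ordo = character(), omim = character(),
                ern = NA_character_, consanguinity = NA))
  }
  list(experiment_id = experiment_id, hpo = records$hpo[[i]],
       ordo = records$ordo[[i]], omim = records$omim[[i]],
       ern = records$ern[i], consanguinity = records$consanguinity[i])
}
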