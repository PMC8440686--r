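## Minimal OBO handling for phenotype ontologies plus the phenotype-driven
## on-the-fly gene panels. Only the stanza fields needed for term matching
## are parsed: id, name, is_a, is_obsolete. No installed R package reads OBO,
## so the stanza scan lives here.

#' Read an ontology from an OBO file
#'
#' Parses `[Term]` stanzas (id, name, `is_a` links); obsolete terms are
#' dropped. The result is validated as an acyclic DAG with resolving parent
#' references.
#'
#' @param path OBO file
#' @param root root term id (default the HPO root `HP:0000001`)
#' @param excluded_roots branch roots excluded from phenotype matching
#'   (defaults to the HPO inheritance-mode, clinical-modifier and frequency
#'   branches)
#' @return an [HpoOntology-class]
#' @export
readObo <- function(path, root = "HP:0000001",
                    excluded_roots = c("HP:0000005", "HP:0012823", "HP:0040279")) {
  lines <- readLines(path)
  parents <- list()
  labels <- character()
  cur <- NULL
  curParents <- character()
  curLabel <- NA_character_
  obsolete <- FALSE
  inTerm <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      parents[[cur]] <<- curParents
      if (!is.na(curLabel)) labels[cur] <<- curLabel
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush()
      cur <- NULL; curParents <- character(); curLabel <- NA_character_
      obsolete <- FALSE; inTerm <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush(); cur <- NULL; inTerm <- FALSE
    } else if (inTerm) {
      if (startsWith(ln, "id: ")) cur <- sub("^id: ", "", ln)
      else if (startsWith(ln, "name: ")) curLabel <- sub("^name: ", "", ln)
      else if (startsWith(ln, "is_a: ")) {
        p <- sub("^is_a: ", "", ln)
        p <- trimws(sub("!.*$", "", p))        # strip trailing label comment
        curParents <- c(curParents, p)
      } else if (ln == "is_obsolete: true") obsolete <- TRUE
    }
  }
  flush()
  HpoOntology(parents, root = root, excluded_roots = excluded_roots,
              labels = labels)
}

#' Write an ontology to OBO format (round-trip counterpart of [readObo()])
#' @param ontology an [HpoOntology-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeObo <- function(ontology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in ontology@terms) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t), con)
    lbl <- ontology@labels[t]
    if (!is.na(lbl)) writeLines(paste0("name: ", lbl), con)
    for (p in ontology@parents[[t]] %||% character()) {
      writeLines(paste0("is_a: ", p), con)
    }
  }
  invisible(path)
}

#' Ancestor closure of a term set
#'
#' Returns the input terms together with all their ancestors, excluding the
#' ontology root. Terms absent from the ontology are dropped with a warning.
#' The closure is idempotent.
#'
#' @param terms character vector of term ids
#' @param ontology an [HpoOntology-class]
#' @return sorted character vector
#' @export
ancestorClosure <- function(terms, ontology) {
  unknown <- setdiff(terms, ontology@terms)
  if (length(unknown)) {
    warning("term(s) not in ontology dropped: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  terms <- intersect(terms, ontology@terms)
  closed <- character()
  frontier <- terms
  while (length(frontier)) {
    closed <- union(closed, frontier)
    frontier <- setdiff(
      unique(unlist(ontology@parents[frontier], use.names = FALSE)), closed)
  }
  sort(setdiff(closed, ontology@root))
}

#' Descendant closure of a term set (terms plus all descendants)
#' @param terms character vector of term ids
#' @param ontology an [HpoOntology-class]
#' @return sorted character vector
#' @export
descendantClosure <- function(terms, ontology) {
  terms <- intersect(terms, ontology@terms)
  closed <- character()
  frontier <- terms
  while (length(frontier)) {
    closed <- union(closed, frontier)
    frontier <- setdiff(
      unique(unlist(ontology@children[frontier], use.names = FALSE)), closed)
  }
  sort(closed)
}

#' Read an HPO term -> gene map from TSV
#' @param path TSV with columns `hpo_id` and `gene`
#' @param ontology optional [HpoOntology-class]; rows whose term is absent
#'   from the ontology are dropped with a warning
#' @return named list: term id -> character vector of gene symbols
#' @export
readHpoGeneMap <- function(path, ontology = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("hpo_id", "gene") %in% names(df))) {
    stop("HPO-gene map must have columns 'hpo_id' and 'gene'", call. = FALSE)
  }
  if (!is.null(ontology)) {
    off <- !df$hpo_id %in% ontologyTerms(ontology)
    if (any(off)) {
      warning(sum(off), " HPO-gene rows with terms outside the ontology dropped",
              call. = FALSE)
      df <- df[!off, , drop = FALSE]
    }
  }
  split(toupper(df$gene), df$hpo_id)
}

#' Build a phenotype-driven on-the-fly gene panel
#'
#' Each usable patient term recruits the genes annotated to the term itself
#' or (with `expand = TRUE`, the default) to any of its descendants — a
#' patient coded with a general term recruits genes annotated to its specific
#' subtypes. The ontology root and terms under excluded branches are never
#' used for matching.
#'
#' @param hpo_terms the patient's HPO term ids (e.g. the `hpo` entry of a
#'   phenotype record)
#' @param hpo_gene_map named list term -> genes, from [readHpoGeneMap()]
#' @param ontology an [HpoOntology-class]
#' @param mode `"union"` (gene set, sorted) or `"ranked"` (genes ordered by
#'   the number of distinct patient terms recruiting them, ties broken
#'   lexicographically)
#' @param expand recruit through descendant terms (default `TRUE`)
#' @param panel_id identifier for the resulting panel
#' @return a [GenePanel-class] with `source = "on-the-fly"`; empty (with a
#'   warning) when no usable term matched
#' @export
onTheFlyPanel <- function(hpo_terms, hpo_gene_map, ontology,
                          mode = c("union", "ranked"), expand = TRUE,
                          panel_id = "on-the-fly") {
  mode <- match.arg(mode)
  excluded <- descendantClosure(ontology@excluded_roots, ontology)
  usable <- setdiff(intersect(hpo_terms, ontology@terms),
                    c(ontology@root, excluded))
  dropped <- setdiff(hpo_terms, usable)
  if (length(dropped)) {
    warning("unusable patient term(s) ignored: ", paste(dropped, collapse = ", "),
            call. = FALSE)
  }
  perTerm <- lapply(usable, function(t) {
    reach <- if (expand) descendantClosure(t, ontology) else t
    sort(unique(unlist(hpo_gene_map[reach], use.names = FALSE)))
  })
  genes <- unique(unlist(perTerm))
  if (!length(genes)) {
    warning("no genes recruited from phenotype terms; on-the-fly panel is empty",
            call. = FALSE)
    return(new("GenePanel", panel_id = panel_id, source = "on-the-fly",
               genes = character()))
  }
  if (mode == "ranked") {
    counts <- table(unlist(lapply(perTerm, unique)))
    genes <- names(counts)[order(-as.integer(counts), names(counts))]
    # ranked panels keep recruitment order in the genes slot
    return(new("GenePanel", panel_id = panel_id, source = "on-the-fly",
               genes = toupper(genes)))
  }
  GenePanel(panel_id, genes, source = "on-the-fly")
}
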