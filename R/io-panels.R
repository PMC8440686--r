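#' Read a gene panel from a TSV file
#'
#' One gene symbol per line; a header line `gene` is tolerated. Symbols are
#' uppercase-normalized and de-duplicated. An empty file is fatal — curated
#' panels must be non-empty.
#'
#' @param path TSV/one-column text file of gene symbols
#' @param panel_id identifier; defaults to the file stem
#' @param source provenance (`ERN-curated` or `external`)
#' @return a [GenePanel-class]
#' @export
readGenePanel <- function(path, panel_id = NULL,
                          source = c("ERN-curated", "external")) {
  source <- match.arg(source)
  genes <- readLines(path)
  genes <- trimws(genes)
  genes <- genes[nzchar(genes)]
  genes <- genes[tolower(genes) != "gene"]
  if (!length(genes)) stop("gene panel file '", path, "' is empty", call. = FALSE)
  GenePanel(panel_id %||% tools::file_path_sans_ext(basename(path)),
            genes, source = source)
}

#' Write a gene panel to a one-column TSV
#' @param panel a [GenePanel-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeGenePanel <- function(panel, path) {
  writeLines(c("gene", panelGenes(panel)), path)
  invisible(path)
}
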