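## CNV calls arrive as a BED-dialect table with two extra columns:
##   contig  start  end  copy_state  experiment_id
## Coordinates follow BED convention (0-based half-open) in the file and are
## converted to 1-based inclusive on read, matching every other coordinate
## in the package.

#' Read CNV calls from a 5-column BED-dialect file
#'
#' @param path tab-separated file: contig, start (0-based), end (exclusive),
#'   copy_state (`deletion-het`, `deletion-hom`, `duplication`), experiment_id.
#'   A track/header line starting with `#`, `track` or `browser` is skipped.
#' @return data.frame with 1-based inclusive `start`/`end`
#' @export
readCnvCalls <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(emptyCnvTable())
  df <- utils::read.table(text = lines, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end",
                                        "copy_state", "experiment_id"))
  states <- c("deletion-het", "deletion-hom", "duplication")
  if (!all(df$copy_state %in% states)) {
    stop("unknown CNV copy_state; expected one of ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    experiment_id = df$experiment_id,
    contig = normalizeContig(df$contig),
    start = df$start + 1L,        # BED 0-based -> 1-based inclusive
    end = df$end,
    copy_state = df$copy_state,
    stringsAsFactors = FALSE
  )
  if (any(out$start > out$end)) stop("CNV interval with start > end", call. = FALSE)
  out
}

#' Write CNV calls back to the 5-column BED dialect
#' @param cnv data.frame as returned by [readCnvCalls()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeCnvCalls <- function(cnv, path) {
  lines <- paste(cnv$contig, cnv$start - 1L, cnv$end, cnv$copy_state,
                 cnv$experiment_id, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
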