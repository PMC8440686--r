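## Runs of homozygosity from exome-density genotypes, FROH-based
## consanguinity inference, and the CNV cross-check for suspect homozygous
## calls. Exome sites are sparse, so the caller combines the 1 Mb length
## floor with a site-count minimum; all three knobs are exposed in the
## filter configuration.

#' Detect runs of homozygosity in one experiment's called genotypes
#'
#' Greedy left-to-right maximal runs per contig: a run starts and ends on a
#' homozygous site, tolerates at most `max_het` heterozygous calls inside,
#' and is extended as far as possible before the next run is opened (runs
#' never overlap). Runs qualify when they contain at least `min_sites` called
#' sites and span at least `min_length_bp` (boundaries at the first and last
#' qualifying site). Two adjacent qualifying runs separated by more than
#' `max_het` heterozygous calls are never merged.
#'
#' @param sites data.frame of called sites for one experiment, columns
#'   `contig`, `pos`, `het` (logical); must be position-sorted within contig
#'   (fatal otherwise). Both homozygous-reference and homozygous-alt calls
#'   count as homozygous.
#' @param min_length_bp minimum span (default 1 Mb)
#' @param min_sites minimum number of called sites in the run (default 25)
#' @param max_het heterozygous calls tolerated per run (default 1)
#' @return data.frame: `contig`, `start`, `end`, `length_bp`, `n_sites`,
#'   `n_het_used`
#' @export
detectRoh <- function(sites, min_length_bp = 1e6, min_sites = 25L, max_het = 1L) {
  emptySeg <- data.frame(contig = character(), start = integer(), end = integer(),
                         length_bp = integer(), n_sites = integer(),
                         n_het_used = integer(), stringsAsFactors = FALSE)
  if (!nrow(sites)) return(emptySeg)
  segs <- emptySeg
  for (ctg in unique(sites$contig)) {
    s <- sites[sites$contig == ctg, , drop = FALSE]
    if (is.unsorted(s$pos)) {
      stop("genotype sites not position-sorted on contig ", ctg, call. = FALSE)
    }
    het <- s$het
    posv <- s$pos
    n <- nrow(s)
    i <- 1L
    while (i <= n) {
      if (het[i]) { i <- i + 1L; next }           # runs start on a hom site
      j <- i
      hets <- 0L
      while (j < n) {
        nxtHet <- het[j + 1L]
        if (nxtHet && hets + 1L > max_het) break
        j <- j + 1L
        hets <- hets + as.integer(nxtHet)
      }
      while (het[j]) { j <- j - 1L; hets <- hets - 1L }   # trim trailing hets
      len <- posv[j] - posv[i] + 1L
      nSites <- j - i + 1L
      if (nSites >= min_sites && len >= min_length_bp) {
        segs <- rbind(segs, data.frame(
          contig = ctg, start = posv[i], end = posv[j],
          length_bp = len, n_sites = nSites, n_het_used = hets,
          stringsAsFactors = FALSE))
      }
      i <- j + 1L
      while (i <= n && het[i]) i <- i + 1L
    }
  }
  rownames(segs) <- NULL
  segs
}

#' Homozygosity sites of one experiment from a VariantSet
#'
#' Diploid called sites only (hemizygous X and MT calls carry no
#' heterozygosity information); restricted to the given contigs.
#' @param vs a [VariantSet-class]
#' @param experiment_id sample to extract
#' @param autosomes contigs to keep (default everything but X, Y, MT)
#' @return data.frame `contig`, `pos`, `het`, position-sorted
#' @export
homozygositySites <- function(vs, experiment_id,
                              autosomes = NULL) {
  m <- variantInfo(vs)
  g <- genotypes(vs)[, experiment_id]
  p <- ploidies(vs)[, experiment_id]
  keep <- !is.na(g) & p == 2L
  if (is.null(autosomes)) {
    keep <- keep & !m$contig %in% c("X", "Y", "MT")
  } else {
    keep <- keep & m$contig %in% autosomes
  }
  out <- data.frame(contig = m$contig[keep], pos = m$pos[keep],
                    het = g[keep] == 1L, stringsAsFactors = FALSE)
  # records are (contig,pos)-sorted in a VariantSet; de-duplicate positions
  # (decomposed multi-allelics) keeping "het if any allele is het"
  if (anyDuplicated(paste(out$contig, out$pos))) {
    agg <- stats::aggregate(het ~ contig + pos, data = out, FUN = any)
    out <- agg[order(contigRank(agg$contig), agg$pos), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' FROH and consanguinity call from ROH segments
#'
#' FROH is the fraction of the autosome covered by runs of homozygosity; a
#' case at or above the threshold is called consanguineous (the default 0.03
#' corresponds to parental relatedness closer than second cousins).
#'
#' @param segments data.frame from [detectRoh()] (autosomal segments)
#' @param autosome_length total autosomal length in bp
#' @param threshold FROH threshold for the consanguinity call
#' @return list with `froh` and `consanguineous`
#' @export
inferConsanguinity <- function(segments, autosome_length, threshold = 0.03) {
  froh <- if (nrow(segments)) sum(as.numeric(segments$length_bp)) / autosome_length else 0
  list(froh = froh, consanguineous = froh >= threshold)
}

#' Cross-check homozygous candidate calls against CNV intervals
#'
#' A homozygous call sitting inside a heterozygous-deletion CNV of the same
#' experiment may in truth be hemizygous; such rows are flagged `suspect`
#' for the interpreters. With no CNV calls every variant is `clear`.
#'
#' @param contig,pos vectors describing the candidate variant positions
#' @param cnv data.frame of CNV calls (`experiment_id`, `contig`, `start`,
#'   `end`, `copy_state`, 1-based inclusive)
#' @param experiment_id the experiment whose calls to use
#' @return character vector, `"suspect"` or `"clear"`, one per variant
#' @export
cnvCrosscheck <- function(contig, pos, cnv, experiment_id) {
  flags <- rep("clear", length(pos))
  dels <- cnv[cnv$experiment_id == experiment_id &
              cnv$copy_state == "deletion-het", , drop = FALSE]
  if (!nrow(dels)) return(flags)
  varGr <- GenomicRanges::GRanges(normalizeContig(contig),
                                  IRanges::IRanges(pos, pos))
  delGr <- GenomicRanges::GRanges(dels$contig,
                                  IRanges::IRanges(dels$start, dels$end))
  hits <- GenomicRanges::findOverlaps(varGr, delGr)
  flags[unique(S4Vectors::queryHits(hits))] <- "suspect"
  flags
}
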