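## Gene-dropping simulation of the offspring of first cousins, used to
## validate FROH recovery (expected inbreeding coefficient F = 1/16).
## A human-scale autosome (22 chromosomes of 130 Mb at 1 cM/Mb) is dropped
## through the 3-generation first-cousin pedigree; markers are typed every
## 50 kb with moderately common allele frequencies so runs of homozygosity
## are detectable at exome-realistic site density without chance ROH.

#' Simulate genotypes of a first-cousin couple's child
#'
#' Founder chromosomes are labelled and dropped through the pedigree with
#' Poisson crossovers (Haldane model, 1 cM/Mb). At each marker the child is
#' identical-by-descent when the paternal and maternal copies trace to the
#' same founder chromosome; IBD markers are homozygous by construction,
#' non-IBD markers draw two independent alleles at the marker frequency.
#'
#' @param seed RNG seed
#' @param n_chrom number of autosomes (default 22)
#' @param chrom_length_bp autosome length (default 130 Mb)
#' @param marker_spacing_bp marker spacing (default 50 kb)
#' @param af_range uniform range of marker allele frequencies
#' @return list with `sites` (data.frame `contig`, `pos`, `het`, and the true
#'   `ibd` state per marker), `autosome_length` (bp) and `f_true` (realized
#'   IBD fraction of the genome)
#' @export
simulateFirstCousinOffspring <- function(seed, n_chrom = 22,
                                         chrom_length_bp = 130e6,
                                         marker_spacing_bp = 50e3,
                                         af_range = c(0.1, 0.5)) {
  set.seed(seed)
  morgans <- chrom_length_bp * 1e-8          # 1 cM/Mb
  markers <- seq(marker_spacing_bp, chrom_length_bp, by = marker_spacing_bp)

  ## transmit one recombinant haplotype from a parent's two label vectors
  transmit <- function(hap1, hap2) {
    nx <- stats::rpois(1, morgans)
    xpos <- sort(stats::runif(nx, 0, chrom_length_bp))
    phase <- (findInterval(markers, xpos) + stats::rbinom(1, 1, 0.5)) %% 2
    ifelse(phase == 0, hap1, hap2)
  }

  sites <- list()
  ibdLen <- 0
  for (chr in seq_len(n_chrom)) {
    nM <- length(markers)
    ## founders: great-grandparents G1, G2 and the two unrelated spouses U1, U2
    founder <- function(a, b) list(rep(a, nM), rep(b, nM))
    G1 <- founder(1L, 2L); G2 <- founder(3L, 4L)
    U1 <- founder(5L, 6L); U2 <- founder(7L, 8L)
    ## siblings S1, S2 (children of G1 x G2)
    S1 <- list(transmit(G1[[1]], G1[[2]]), transmit(G2[[1]], G2[[2]]))
    S2 <- list(transmit(G1[[1]], G1[[2]]), transmit(G2[[1]], G2[[2]]))
    ## the first cousins P1 (child of S1 x U1), P2 (child of S2 x U2)
    P1 <- list(transmit(S1[[1]], S1[[2]]), transmit(U1[[1]], U1[[2]]))
    P2 <- list(transmit(S2[[1]], S2[[2]]), transmit(U2[[1]], U2[[2]]))
    ## their child
    hapPat <- transmit(P1[[1]], P1[[2]])
    hapMat <- transmit(P2[[1]], P2[[2]])
    ibd <- hapPat == hapMat
    ibdLen <- ibdLen + sum(ibd) * marker_spacing_bp

    af <- stats::runif(length(markers), af_range[1], af_range[2])
    a1 <- stats::rbinom(length(markers), 1, af)
    a2 <- ifelse(ibd, a1, stats::rbinom(length(markers), 1, af))
    sites[[chr]] <- data.frame(contig = as.character(chr), pos = markers,
                               het = a1 != a2, ibd = ibd,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, sites)
  rownames(out) <- NULL
  list(sites = out,
       autosome_length = n_chrom * chrom_length_bp,
       f_true = ibdLen / (n_chrom * chrom_length_bp))
}

#' FROH recovery for simulated first-cousin offspring
#'
#' Convenience wrapper: simulate, call ROH with the given parameters, return
#' the inferred FROH alongside the realized IBD fraction.
#' @param seed RNG seed
#' @param ... passed to [simulateFirstCousinOffspring()]
#' @param min_length_bp,min_sites,max_het ROH caller parameters
#' @return list with `froh`, `f_true`, `consanguineous`
#' @export
frohFirstCousin <- function(seed, ..., min_length_bp = 1e6, min_sites = 25L,
                            max_het = 1L) {
  sim <- simulateFirstCousinOffspring(seed, ...)
  segs <- detectRoh(sim$sites[, c("contig", "pos", "het")],
                    min_length_bp = min_length_bp, min_sites = min_sites,
                    max_het = max_het)
  res <- inferConsanguinity(segs, sim$autosome_length)
  list(froh = res$froh, f_true = sim$f_true,
       consanguineous = res$consanguineous)
}
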