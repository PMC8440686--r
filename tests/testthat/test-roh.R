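# Runs of homozygosity, FROH-based consanguinity and the CNV cross-check.

homSites <- function(pos, het = FALSE, contig = "1") {
  data.frame(contig = contig, pos = pos,
             het = rep_len(het, length(pos)), stringsAsFactors = FALSE)
}

test_that("a 1.2 Mb run of 30 homozygous sites is one segment; 0.8 Mb is not", {
  pos <- seq(1e6, 2.2e6, length.out = 30)
  seg <- detectRoh(homSites(round(pos)))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_sites, 30L)
  expect_gte(seg$length_bp, 1.2e6)
  short <- detectRoh(homSites(round(seq(1e6, 1.8e6, length.out = 30))))
  expect_equal(nrow(short), 0L)
})

test_that("het tolerance: one embedded het is absorbed, two split the run", {
  pos <- round(seq(1e6, 2.5e6, length.out = 31))
  het <- rep(FALSE, 31); het[16] <- TRUE
  seg <- detectRoh(data.frame(contig = "1", pos = pos, het = het))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_het_used, 1L)
  het[10] <- TRUE                            # second het: neither half has 25 sites
  seg2 <- detectRoh(data.frame(contig = "1", pos = pos, het = het))
  expect_equal(nrow(seg2), 0L)
  expect_error(detectRoh(homSites(c(5, 1, 9))), "not position-sorted")
})

test_that("greedy segments match a brute-force window recount on random strings", {
  set.seed(314)
  # brute force with independent per-window recounting of the same definition:
  # leftmost maximal extension from each uncovered homozygous site
  bruteRoh <- function(sites, min_sites, min_len, max_het) {
    out <- list()
    for (ctg in unique(sites$contig)) {
      s <- sites[sites$contig == ctg, ]
      n <- nrow(s)
      nextStart <- 1
      while (nextStart <= n) {
        if (s$het[nextStart]) { nextStart <- nextStart + 1; next }
        best <- nextStart
        for (j in nextStart:n) {           # O(n^2): recount hets in [i, j]
          if (!s$het[j] && sum(s$het[nextStart:j]) <= max_het) best <- j
        }
        nS <- best - nextStart + 1
        len <- s$pos[best] - s$pos[nextStart] + 1
        hets <- sum(s$het[nextStart:best])
        if (nS >= min_sites && len >= min_len) {
          out[[length(out) + 1]] <- data.frame(
            contig = ctg, start = s$pos[nextStart], end = s$pos[best],
            length_bp = len, n_sites = nS, n_het_used = hets,
            stringsAsFactors = FALSE)
        }
        nextStart <- best + 1
        while (nextStart <= n && s$het[nextStart]) nextStart <- nextStart + 1
      }
    }
    if (length(out)) do.call(rbind, out) else
      detectRoh(data.frame(contig = character(), pos = integer(), het = logical()))
  }
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    sites <- data.frame(contig = sample(c("1", "2"), 1),
                        pos = sort(sample.int(3e6, n)),
                        het = runif(n) < 0.3, stringsAsFactors = FALSE)
    minS <- sample(3:10, 1); minL <- sample(c(1e5, 5e5), 1)
    maxH <- sample(0:2, 1)
    got <- detectRoh(sites, min_length_bp = minL, min_sites = minS, max_het = maxH)
    want <- bruteRoh(sites, minS, minL, maxH)
    rownames(want) <- NULL
    expect_equal(got, want, info = paste("rep", rep))
  }
})

test_that("segments never overlap and runs separated by many hets never merge", {
  set.seed(99)
  for (rep in 1:10) {
    n <- 200
    sites <- data.frame(contig = "1", pos = sort(sample.int(5e6, n)),
                        het = runif(n) < 0.25, stringsAsFactors = FALSE)
    segs <- detectRoh(sites, min_length_bp = 1e5, min_sites = 5, max_het = 1)
    if (nrow(segs) > 1) {
      expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
    }
  }
  # two qualifying runs separated by 3 hets stay separate at max_het = 1
  pos <- c(seq(1e6, 2.2e6, length.out = 30),
           seq(2.21e6, 2.25e6, length.out = 3),
           seq(2.3e6, 3.5e6, length.out = 30))
  het <- c(rep(FALSE, 30), rep(TRUE, 3), rep(FALSE, 30))
  segs <- detectRoh(data.frame(contig = "1", pos = round(pos), het = het))
  expect_equal(nrow(segs), 2L)
})

test_that("FROH definition, bounds and monotonicity", {
  none <- inferConsanguinity(detectRoh(homSites(1:3)), 20e6)
  expect_equal(none$froh, 0)
  expect_false(none$consanguineous)
  segs <- data.frame(contig = c("1", "2"), start = c(1, 1), end = c(1e6, 1e6),
                     length_bp = c(1e6, 1e6), n_sites = 30, n_het_used = 0)
  r <- inferConsanguinity(segs, 20e6)
  expect_equal(r$froh, 0.10)
  expect_true(r$consanguineous)
  # monotone in added segments
  r1 <- inferConsanguinity(segs[1, ], 20e6)
  expect_lt(r1$froh, r$froh)
  expect_true(r$froh >= 0 && r$froh <= 1)
})

test_that("first-cousin offspring FROH is recovered near F = 1/16", {
  froh <- vapply(1:6, function(s) frohFirstCousin(seed = s)$froh, numeric(1))
  expect_equal(mean(froh), 0.0625, tolerance = 0.35)   # per-genome variance is real
  expect_true(all(froh >= 0 & froh <= 1))
  # the caller tracks the realized IBD fraction closely seed by seed
  for (s in 1:3) {
    r <- frohFirstCousin(seed = 100 + s)
    expect_equal(r$froh, r$f_true, tolerance = 0.25)
  }
})

test_that("CNV cross-check flags homozygous calls under het deletions", {
  cnv <- data.frame(experiment_id = "E1", contig = "1",
                    start = 1000L, end = 2000L, copy_state = "deletion-het",
                    stringsAsFactors = FALSE)
  expect_identical(cnvCrosscheck("1", 1500, cnv, "E1"), "suspect")
  expect_identical(cnvCrosscheck("1", 2500, cnv, "E1"), "clear")
  expect_identical(cnvCrosscheck("1", 1500, cnv, "E2"), "clear")
  # no CNV calls at all -> clear
  expect_identical(cnvCrosscheck("1", 1500, cnv[0, ], "E1"), "clear")
  # hom deletions and duplications never raise the flag
  cnv$copy_state <- "deletion-hom"
  expect_identical(cnvCrosscheck("1", 1500, cnv, "E1"), "clear")
})

test_that("CNV cross-check equals a naive interval-overlap oracle at scale", {
  set.seed(2718)
  nV <- 1000; nI <- 100
  vctg <- sample(c("1", "2"), nV, replace = TRUE)
  vpos <- sample.int(5e6, nV, replace = TRUE)
  cnv <- data.frame(
    experiment_id = "E1",
    contig = sample(c("1", "2"), nI, replace = TRUE),
    start = sample.int(5e6, nI, replace = TRUE),
    copy_state = sample(c("deletion-het", "deletion-hom", "duplication"),
                        nI, replace = TRUE),
    stringsAsFactors = FALSE)
  cnv$end <- cnv$start + sample.int(2e5, nI, replace = TRUE)
  got <- cnvCrosscheck(vctg, vpos, cnv, "E1")
  for (i in seq_len(nV)) {
    hit <- FALSE
    for (j in seq_len(nI)) {
      if (cnv$copy_state[j] == "deletion-het" && cnv$contig[j] == vctg[i] &&
          cnv$start[j] <= vpos[i] && cnv$end[j] >= vpos[i]) hit <- TRUE
    }
    expect_identical(got[i], if (hit) "suspect" else "clear")
  }
})
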