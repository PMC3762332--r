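library(GenomicRanges)
library(Biostrings)

mkPeaks <- function(start, end, summit, chrom = "chrS") {
  gr <- GRanges(chrom, IRanges(start, end))
  gr$summit <- summit
  gr
}

test_that("peak length filter is strict and quantile-driven", {
  # 0-based half-open lengths {152, 300, 371, 6062}
  p <- mkPeaks(c(1, 1001, 2001, 3001),
               c(152, 1300, 2371, 9062),
               c(80, 1150, 2180, 6000))
  kept <- filterPeaks(p, maxLength = 371)
  expect_equal(width(kept), c(152, 300))
  expect_length(filterPeaks(p, quantile = 1), 4)
  expect_warning(filterPeaks(GRanges(), maxLength = 100), "empty")
})

test_that("quantile cutoff equals an independently computed percentile", {
  set.seed(19)
  len <- as.integer(round(rlnorm(1000, log(300), 0.5)))
  p <- mkPeaks(seq_along(len) * 10000L, seq_along(len) * 10000L + len - 1L,
               seq_along(len) * 10000L + len %/% 2L)
  kept <- filterPeaks(p, quantile = 0.95)
  # type-7 quantile, computed from scratch from the sorted lengths
  s <- sort(len)
  h <- (1000 - 1) * 0.95 + 1
  q95 <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(S4Vectors::metadata(kept)$max_length, q95)
  expect_true(all(width(kept) < q95))
  expect_equal(length(kept), sum(len < q95))
})

test_that("summit methylation pools read counts within the window", {
  # summit at 1-based 1000; CpGs at 0-based 950 and 1050 are inside +/-60
  meth <- data.frame(chrom = "chrS", pos = c(950, 1050, 2000),
                     strand = "+", n_meth = c(9, 7, 5),
                     n_total = c(10, 10, 5))
  p <- mkPeaks(900, 1100, 1000)
  expect_equal(summitMethylation(p, meth), 16 / 20)
  # coverage-weighted pooling differs from the unweighted mean
  meth2 <- data.frame(chrom = "chrS", pos = c(950, 1050), strand = "+",
                      n_meth = c(1, 90), n_total = c(10, 100))
  expect_equal(summitMethylation(p, meth2), 91 / 110)
  expect_equal(summitMethylation(p, meth2, pooled = FALSE),
               mean(c(0.1, 0.9)))
  # no covered CpG: undefined
  far <- mkPeaks(5000, 5200, 5100)
  expect_true(is.na(summitMethylation(far, meth)))
})

test_that("methylation categorization fractions count the stated bands", {
  f <- categorizeMethylation(c(0.9, 0.85, 0.1, 0.5))
  expect_equal(f, c(high = 0.5, mid = 0.25, low = 0.25))
  expect_equal(categorizeMethylation(rep(1, 5))[["high"]], 1)
  expect_equal(categorizeMethylation(c(0.8, 0.2))[["high"]], 0.5) # M=0.8 is high
  expect_equal(categorizeMethylation(c(0.8, 0.2))[["mid"]], 0.5)  # M=0.2 is mid
  set.seed(3)
  u <- runif(10000)
  fu <- categorizeMethylation(u)
  se <- sqrt(0.2 * 0.8 / 10000)
  expect_lt(abs(fu[["high"]] - 0.2), 2.5 * se)
  expect_lt(abs(fu[["low"]] - 0.2), 2.5 * se)
  expect_equal(sum(fu), 1)
})

test_that("foreground/background windows follow the half-open arithmetic", {
  genome <- DNAStringSet(c(chrS = paste(rep("ACGT", 200), collapse = "")))
  # 0-based half-open peak [100, 300) with summit at 0-based 200
  p <- mkPeaks(101, 300, 201)
  fb <- buildFgBg(p, genome)
  expect_equal(start(fb$fgRanges), 141)  # 0-based 140
  expect_equal(end(fb$fgRanges), 261)    # half-open end 261
  expect_equal(width(fb$fgRanges), 121)
  expect_equal(start(fb$bgRanges), 51)   # 0-based 50
  expect_equal(end(fb$bgRanges), 350)    # half-open end 350
  expect_equal(as.character(fb$fg[[1]]),
               substr(paste(rep("ACGT", 200), collapse = ""), 141, 261))
  # clipping at the chromosome start
  pc <- mkPeaks(1, 100, 21)
  # both the summit window and the extended peak clip at the start
  expect_warning(expect_warning(fbc <- buildFgBg(pc, genome), "clipped"),
                 "clipped")
  expect_equal(start(fbc$fgRanges), 1)
  expect_equal(width(fbc$fgRanges), 81)
})

test_that("unclipped foreground windows are always 121 bp", {
  set.seed(37)
  sim <- genPeaksMethylome(nSummits = 50, seed = 8)
  fb <- buildFgBg(sim$peaks, sim$genome)
  expect_true(all(width(fb$fgRanges) == 121))
})

test_that("central-CpG k-mer counts match a naive scan oracle", {
  single <- countCentralCpgKmers("AAACGCTT", collapseRC = FALSE)
  expect_equal(single[single > 0], c(AACGCT = 1L))
  both <- countCentralCpgKmers("AAACGCTT")
  expect_equal(both[["AACGCT"]], 1L)  # one double-stranded site
  # a minus-strand word maps to the same canonical site count
  expect_equal(countCentralCpgKmers("AAGCGTTT")[["AACGCT"]], 1L)
  expect_equal(sum(countCentralCpgKmers(strrep("A", 50))), 0L)
  # N-containing windows are skipped
  expect_equal(sum(countCentralCpgKmers("AANCGCTT")), 0L)

  set.seed(41)
  seqs <- vapply(1:60, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(20:80, 1), TRUE),
          collapse = ""), "")
  for (rc in c(TRUE, FALSE)) {
    got <- countCentralCpgKmers(seqs, collapseRC = rc)
    got <- got[got > 0]
    oracle <- naiveCentralKmerCount(seqs, collapseRC = rc)
    expect_equal(as.list(got), as.list(oracle))
  }
})

test_that("hypergeometric enrichment matches exact enumeration and clips", {
  # fg 60/100 vs bg 600/10000 on one k-mer
  fg <- c(AACGTT = 60L, TTCGAA = 40L)
  bg <- c(AACGTT = 600L, TTCGAA = 9400L)
  res <- kmerEnrichment(fg, bg, mTests = 256)
  r <- res[res$kmer == "AACGTT", ]
  expect_equal(r$p_raw, hyperUpperTail(60, 600, 10000, 100),
               tolerance = 1e-10)
  expect_equal(r$p_adj, min(1, r$p_raw * 256))
  # proportions equal: mass near the median, p not small
  fg2 <- c(AACGTT = 30L, TTCGAA = 70L)
  bg2 <- c(AACGTT = 3000L, TTCGAA = 7000L)
  r2 <- kmerEnrichment(fg2, bg2)
  expect_gt(r2$p_raw[r2$kmer == "AACGTT"], 0.4)
  # Bonferroni clipping at 1
  expect_true(all(kmerEnrichment(fg2, bg2)$p_adj <= 1))
  # subset consistency
  expect_error(kmerEnrichment(c(AACGTT = 10L), c(AACGTT = 5L)),
               "exceeds")
})

test_that("enrichment p-values match enumeration across random tables", {
  set.seed(43)
  for (i in 1:80) {
    N <- sample(50:2000, 1)
    K <- sample(0:min(N, 200), 1)
    n <- sample(1:min(N, 300), 1)
    k <- sample(0:min(K, n), 1)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p, hyperUpperTail(k, K, N, n), tolerance = 1e-9)
  }
})

test_that("the in vivo pipeline recovers a planted central-CpG 6-mer", {
  sim <- genPeaksMethylome(nSummits = 300, seed = 101)
  res <- enrichMethylatedKmers(sim$peaks, sim$genome, sim$methylome)
  expect_equal(res$enrichment$kmer[1], "CCCGCC")
  expect_true(res$enrichment$significant[1])
  expect_equal(consensusIUPAC(res$consensus[[1]]), "CCCGCC")
  expect_true(grepl("CCGC", consensusIUPAC(res$consensus[[1]])))
  # generated strata show up in the methylation categorization
  f <- categorizeMethylation(res$m)
  expect_lt(abs(f[["high"]] - 0.48), 3 * sqrt(0.48 * 0.52 / 300))
  expect_lt(abs(f[["low"]] - 0.38), 3 * sqrt(0.38 * 0.62 / 300))
})

test_that("an empty significant set yields no consensus, not an error", {
  expect_null(methylatedConsensusInVivo(character()))
  one <- methylatedConsensusInVivo("TACGGA")
  expect_equal(consensusIUPAC(one[[1]]), "TACGGA")
})

test_that("BED round-trip preserves intervals and summit offsets", {
  p <- mkPeaks(c(101, 1001), c(300, 1200), c(201, 1100), chrom = "chr1")
  f1 <- tempfile(fileext = ".bed")
  f2 <- tempfile(fileext = ".bed")
  writePeakBed(p, f1)
  back <- readPeakBed(f1)
  expect_equal(start(back), start(p))
  expect_equal(end(back), end(p))
  expect_equal(back$summit, p$summit)
  writePeakBed(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})
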