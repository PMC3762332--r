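# Integration of ChIP-seq binding peaks/summits with a base-resolution
# methylome, and enrichment of central-CpG k-mers in highly methylated
# summit windows. Coordinates are 1-based closed inside GRanges, 0-based
# half-open in BED files; methylome positions refer to the plus-strand C
# of each CpG (0-based in files).

#' Read peaks with summits from a BED file
#'
#' BED intervals (0-based half-open) with the summit encoded in the name
#' (4th) column as the 0-based offset of the summit from the peak start.
#' Internally the summit becomes an absolute 1-based position in the
#' `summit` metadata column.
#'
#' @param path path to the BED file.
#' @return `GRanges` with integer metadata column `summit`.
#' @export
readPeakBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name) || anyNA(suppressWarnings(as.integer(gr$name))))
    stop("BED name column must hold the 0-based summit offset")
  offset <- as.integer(gr$name)
  gr$summit <- GenomicRanges::start(gr) + offset
  gr$name <- NULL
  if (any(gr$summit < GenomicRanges::start(gr) |
          gr$summit > GenomicRanges::end(gr)))
    stop("summit outside its peak interval")
  gr
}

#' Write peaks with summits to a BED file
#'
#' Inverse of [readPeakBed()]: the name column carries the 0-based summit
#' offset from the peak start, intervals are written 0-based half-open.
#'
#' @param peaks `GRanges` with a `summit` metadata column (absolute,
#'   1-based).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(peaks, path) {
  out <- peaks
  out$name <- as.character(out$summit - GenomicRanges::start(out))
  out$summit <- NULL
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

#' Read a per-CpG methylome table
#'
#' Tab-delimited table with header columns `chrom`, `pos` (0-based
#' position of the CpG's C on the plus strand), `strand`, `n_meth`,
#' `n_total`.
#'
#' @param path path to the TSV.
#' @return validated `data.frame` with an added `level` column
#'   (`n_meth/n_total`).
#' @export
readMethylome <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "n_meth", "n_total")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("methylome table missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(tab$n_total <= 0)) stop("n_total must be > 0")
  if (any(tab$n_meth < 0 | tab$n_meth > tab$n_total))
    stop("need 0 <= n_meth <= n_total")
  tab$level <- tab$n_meth / tab$n_total
  tab
}

#' Filter peaks by length
#'
#' Retains peaks strictly shorter than a length cutoff, either given in bp
#' or as a quantile of the observed peak lengths (e.g. `quantile = 0.95`
#' keeps the 95% of peaks below the 95th length percentile, the filter
#' applied before in vivo motif analysis).
#'
#' @param peaks `GRanges`.
#' @param maxLength length cutoff in bp (exclusive). Ignored when
#'   `quantile` is given.
#' @param quantile optional quantile in \[0, 1\] from which to derive
#'   `maxLength`; `quantile = 1` retains all peaks.
#' @return the retained `GRanges`, with the cutoff used in
#'   `metadata()$max_length`.
#' @export
filterPeaks <- function(peaks, maxLength = NULL, quantile = NULL) {
  if (!length(peaks)) {
    warning("empty peak list")
    return(peaks)
  }
  len <- GenomicRanges::width(peaks)
  if (!is.null(quantile)) {
    stopifnot(quantile >= 0, quantile <= 1)
    if (quantile == 1) return(peaks)
    maxLength <- stats::quantile(len, quantile, names = FALSE)
  }
  if (is.null(maxLength)) stop("give 'maxLength' or 'quantile'")
  out <- peaks[len < maxLength]
  S4Vectors::metadata(out)$max_length <- maxLength
  out
}

#' Pooled methylation level around binding summits
#'
#' For each peak summit, pools methylome read counts over all covered
#' CpGs within `halfWindow` bp of the summit: M = sum(n_meth) /
#' sum(n_total). Coverage-weighted pooling is robust to low-coverage
#' CpGs; `pooled = FALSE` gives the unweighted mean of per-CpG levels
#' instead. Summits with no covered CpG in the window get `NA` and are
#' excluded from categorization.
#'
#' @param peaks `GRanges` with a `summit` metadata column (1-based).
#' @param methylome `data.frame` from [readMethylome()] (`pos` 0-based).
#' @param halfWindow half window size in bp (default 60).
#' @param pooled pool read counts (default) or average per-CpG levels.
#' @return numeric vector of M levels (one per peak, `NA` when no CpG is
#'   covered).
#' @export
summitMethylation <- function(peaks, methylome, halfWindow = 60L,
                              pooled = TRUE) {
  stopifnot(!is.null(peaks$summit))
  cpg <- GenomicRanges::GRanges(
    methylome$chrom,
    IRanges::IRanges(methylome$pos + 1L, width = 1L))
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(peaks),
    IRanges::IRanges(peaks$summit - halfWindow, peaks$summit + halfWindow))
  hits <- GenomicRanges::findOverlaps(win, cpg)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  m <- rep(NA_real_, length(peaks))
  if (length(q)) {
    if (pooled) {
      meth <- tapply(methylome$n_meth[s], q, sum)
      tot <- tapply(methylome$n_total[s], q, sum)
      m[as.integer(names(meth))] <- meth / tot
    } else {
      lev <- tapply(methylome$n_meth[s] / methylome$n_total[s], q, mean)
      m[as.integer(names(lev))] <- lev
    }
  }
  m
}

#' Categorize methylation levels into high / mid / low fractions
#'
#' @param levels numeric methylation levels in \[0, 1\] (`NA` dropped).
#' @param high high-methylation threshold, inclusive (default `M >= 0.8`).
#' @param low low-methylation threshold, exclusive (default `M < 0.2`).
#' @return named numeric vector `c(high, mid, low)` of fractions summing
#'   to 1.
#' @export
categorizeMethylation <- function(levels, high = 0.8, low = 0.2) {
  levels <- levels[!is.na(levels)]
  stopifnot(all(levels >= 0 & levels <= 1))
  n <- length(levels)
  if (!n) return(c(high = NA_real_, mid = NA_real_, low = NA_real_))
  hi <- sum(levels >= high)
  lo <- sum(levels < low)
  c(high = hi / n, mid = (n - hi - lo) / n, low = lo / n)
}

clipRanges <- function(gr, seqlens) {
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  maxEnd <- seqlens[as.character(GenomicRanges::seqnames(gr))]
  clipped <- st < 1L | en > maxEnd
  if (any(clipped))
    warning(sum(clipped), " interval(s) clipped at chromosome bounds")
  GenomicRanges::start(gr) <- pmax(st, 1L)
  GenomicRanges::end(gr) <- pmin(en, maxEnd)
  gr
}

#' Build foreground and background sequence sets for k-mer enrichment
#'
#' Foreground: sequences within `summitHalf` bp around each binding
#' summit (default +/-60 bp, i.e. 121 bp when unclipped). Background:
#' each full peak extended by `peakExtend` bp on both sides (default
#' +/-50 bp), which by construction contains the foreground and controls
#' for the local sequence composition of bound regions. Intervals running
#' off a chromosome end are clipped with a warning; sequences are
#' uppercased, and ambiguous bases are skipped later during k-mer
#' counting.
#'
#' @param peaks `GRanges` with a `summit` metadata column.
#' @param genome named `DNAStringSet` (one entry per chromosome).
#' @param summitHalf half-width of the summit window (default 60).
#' @param peakExtend peak extension in bp (default 50).
#' @return list with `fg`, `bg` (`DNAStringSet`) and the corresponding
#'   `fgRanges`, `bgRanges` (`GRanges`, clipped).
#' @export
buildFgBg <- function(peaks, genome, summitHalf = 60L, peakExtend = 50L) {
  stopifnot(is(genome, "DNAStringSet"), !is.null(peaks$summit))
  seqlens <- stats::setNames(Biostrings::width(genome), names(genome))
  chr <- as.character(GenomicRanges::seqnames(peaks))
  if (!all(chr %in% names(genome)))
    stop("genome does not cover chromosome(s): ",
         paste(setdiff(chr, names(genome)), collapse = ", "))
  fgR <- clipRanges(GenomicRanges::GRanges(
    chr, IRanges::IRanges(peaks$summit - summitHalf,
                          peaks$summit + summitHalf)), seqlens)
  bgR <- clipRanges(GenomicRanges::GRanges(
    chr, IRanges::IRanges(GenomicRanges::start(peaks) - peakExtend,
                          GenomicRanges::end(peaks) + peakExtend)),
    seqlens)
  extract <- function(r) {
    seqs <- Biostrings::DNAStringSet(vapply(seq_along(r), function(i) {
      toupper(as.character(Biostrings::subseq(
        genome[[as.character(GenomicRanges::seqnames(r)[i])]],
        GenomicRanges::start(r)[i], GenomicRanges::end(r)[i])))
    }, ""))
    seqs
  }
  list(fg = extract(fgR), bg = extract(bgR), fgRanges = fgR, bgRanges = bgR)
}

reverseComplementKmer <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Count central-CpG k-mers in a sequence set
#'
#' Counts every window of length `k` whose central two bases are `CG`
#' (4^(k-2) possible words for even `k`; 256 for k = 6). Because ChIP
#' fragments are strandless, strand-equivalent words are pooled by
#' default: a window's reverse complement is itself a central-CpG k-mer
#' (the central CG is its own complement), so each double-stranded site
#' is counted once under the lexicographically smaller of the k-mer and
#' its reverse complement. Counting strand readings separately instead
#' would register every site exactly twice, doubling every entry of the
#' enrichment contingency table and overstating its evidence. Windows
#' containing ambiguous bases are skipped.
#'
#' @param sequences a `DNAStringSet` (or character vector).
#' @param k even k-mer length (default 6).
#' @param collapseRC pool strand-equivalent words under the canonical key
#'   (default `TRUE`); `FALSE` counts written-strand words only, without
#'   canonicalization.
#' @return named integer vector of counts (canonical keys when
#'   `collapseRC`); the sum is the total number of central-CpG sites
#'   scanned.
#' @export
countCentralCpgKmers <- function(sequences, k = 6L, collapseRC = TRUE) {
  k <- as.integer(k)
  if (k %% 2L != 0L || k < 4L) stop("'k' must be an even integer >= 4")
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  counts <- colSums(Biostrings::oligonucleotideFrequency(sequences, k))
  central <- substr(names(counts), k %/% 2L, k %/% 2L + 1L) == "CG"
  counts <- counts[central]
  storage.mode(counts) <- "integer"
  if (!collapseRC) return(counts)
  keys <- names(counts)
  canon <- pmin(keys, reverseComplementKmer(keys))
  out <- tapply(counts, canon, sum)
  res <- as.integer(out)
  names(res) <- names(out)
  res
}

#' Hypergeometric k-mer enrichment of foreground vs background
#'
#' Tests each central-CpG k-mer for over-representation among foreground
#' windows relative to background windows: the raw p-value is the
#' upper-tail hypergeometric probability of drawing at least `fg_count`
#' occurrences of the k-mer when `fg_total` windows are drawn from a
#' population of `bg_total` windows containing `bg_count` occurrences.
#' Bonferroni correction multiplies by the full a priori hypothesis
#' family, all 4^(k-2) possible central-CpG k-mers (default), capped at 1.
#'
#' @param fgCounts,bgCounts named counts from [countCentralCpgKmers()] on
#'   the foreground and background sequence sets.
#' @param mTests number of tests for Bonferroni (default `4^(k-2)`
#'   inferred from the k-mer length).
#' @param alpha significance level on the adjusted p (default 0.01).
#' @param fgSubset is the foreground contained in the background (default
#'   `TRUE`)? If so, `fg_count > bg_count` is a consistency error.
#' @return `data.frame` sorted by `p_adj` (then `p_raw`, then `kmer`) with
#'   columns `kmer`, `fg_count`, `fg_total`, `bg_count`, `bg_total`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
kmerEnrichment <- function(fgCounts, bgCounts, mTests = NULL,
                           alpha = 0.01, fgSubset = TRUE) {
  kmers <- sort(union(names(fgCounts), names(bgCounts)))
  fg <- ifelse(is.na(fgCounts[kmers]), 0L, fgCounts[kmers])
  bg <- ifelse(is.na(bgCounts[kmers]), 0L, bgCounts[kmers])
  fgTotal <- sum(fg)
  bgTotal <- sum(bg)
  if (fgSubset && any(fg > bg))
    stop("foreground count exceeds background count for: ",
         paste(kmers[fg > bg], collapse = ", "))
  if (fgSubset && fgTotal > bgTotal)
    stop("foreground total exceeds background total")
  if (is.null(mTests)) mTests <- 4^(nchar(kmers[1L]) - 2L)
  pRaw <- stats::phyper(fg - 1, bg, bgTotal - bg, fgTotal,
                        lower.tail = FALSE)
  pAdj <- pmin(1, pRaw * mTests)
  out <- data.frame(kmer = kmers, fg_count = as.integer(fg),
                    fg_total = fgTotal, bg_count = as.integer(bg),
                    bg_total = bgTotal, p_raw = pRaw, p_adj = pAdj,
                    significant = pAdj < alpha, row.names = NULL)
  out[order(out$p_adj, out$p_raw, out$kmer), , drop = FALSE]
}

#' In vivo methylated-binding consensus from significant k-mers
#'
#' Clusters the significantly enriched central-CpG k-mers (via
#' [clusterKmers()]) and derives one consensus per group (via
#' [deriveConsensus()]), reporting the largest group first. An empty
#' significant set yields `NULL` (no consensus), not an error.
#'
#' @param significantKmers character vector of enriched k-mers.
#' @param minSimilarity clustering cutoff (default 0.75).
#' @param threshold IUPAC inclusion threshold (default 0.25).
#' @return list of [Consensus-class] objects (largest group first), or
#'   `NULL` when no k-mer is significant.
#' @export
methylatedConsensusInVivo <- function(significantKmers,
                                      minSimilarity = 0.75,
                                      threshold = 0.25) {
  if (!length(significantKmers)) return(NULL)
  groups <- clusterKmers(significantKmers, minSimilarity)
  lapply(groups, deriveConsensus, threshold = threshold)
}

#' Full in vivo central-CpG k-mer enrichment pipeline
#'
#' Chains summit methylation, high-methylation selection, foreground/
#' background construction, k-mer counting, hypergeometric enrichment and
#' consensus derivation for one set of binding peaks.
#'
#' @param peaks `GRanges` with `summit` metadata.
#' @param genome named `DNAStringSet`.
#' @param methylome methylome `data.frame` (see [readMethylome()]).
#' @param summitHalf,peakExtend window parameters (defaults 60, 50).
#' @param mHigh high-methylation cutoff for foreground summits (default
#'   `M >= 0.8`).
#' @param k,alpha,minSimilarity see the component functions.
#' @return list with `m` (per-peak methylation), `categories`,
#'   `enrichment` (data frame), `consensus` (list or `NULL`).
#' @export
enrichMethylatedKmers <- function(peaks, genome, methylome,
                                  summitHalf = 60L, peakExtend = 50L,
                                  mHigh = 0.8, k = 6L, alpha = 0.01,
                                  minSimilarity = 0.75) {
  m <- summitMethylation(peaks, methylome, summitHalf)
  highPeaks <- peaks[!is.na(m) & m >= mHigh]
  seqs <- buildFgBg(peaks, genome, summitHalf, peakExtend)
  fgSeqs <- buildFgBg(highPeaks, genome, summitHalf, peakExtend)$fg
  fgCounts <- countCentralCpgKmers(fgSeqs, k)
  bgCounts <- countCentralCpgKmers(seqs$bg, k)
  enr <- kmerEnrichment(fgCounts, bgCounts, alpha = alpha)
  cons <- methylatedConsensusInVivo(enr$kmer[enr$significant],
                                    minSimilarity)
  list(m = m, categories = categorizeMethylation(m), enrichment = enr,
       consensus = cons)
}
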