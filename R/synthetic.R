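# Seeded synthetic-data generators emulating the statistical structure of
# each pipeline input, so every stage is testable without external
# downloads: duplicate microarrays with planted binders over
# multiplicative log-normal background noise, peak/summit sets with a
# central-CpG 6-mer planted in highly methylated summit windows,
# sensorgrams from known rate constants, and bisulfite read sets with
# per-site methylation probabilities. Identical seed and parameters give
# identical output.

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate duplicate synthetic protein-microarray spot tables
#'
#' Emulates one methylated-motif competition assay probed on two replicate
#' arrays of `nProteins` proteins printed in duplicate (side-by-side
#' spots). Background normalized intensities are multiplicative log-normal
#' noise symmetric in log space around R' = 1 (which is what makes the
#' mirrored-shadow noise model estimable); planted binders are elevated by
#' `effectSdMultiple * noiseSd` on all four of their spots. Background
#' medians vary mildly around 500 fluorescence units.
#'
#' @param nProteins number of arrayed proteins (default 1536, filling a
#'   48 x 64 grid with duplicate spots).
#' @param nBinders number of planted binders (default 10).
#' @param effectSdMultiple binder elevation in units of the background
#'   noise SD (default 6).
#' @param noiseSd log-scale background noise SD (default 0.1).
#' @param seed integer seed.
#' @param nRows grid rows (default 48; columns follow as
#'   `2 * nProteins / nRows`).
#' @return list with `arrayA`, `arrayB` (spot `data.frame`s in the format
#'   of [readSpotTable()] output, plus GenePix-style columns), `truth`
#'   (planted binder protein ids) and `params`.
#' @export
genMicroarray <- function(nProteins = 1536L, nBinders = 10L,
                          effectSdMultiple = 6, noiseSd = 0.1,
                          seed = 1L, nRows = 48L) {
  stopifnot(nBinders <= nProteins,
            (2L * nProteins) %% nRows == 0L)
  nCols <- 2L * nProteins %/% nRows
  perRow <- nCols %/% 2L
  withSeed(seed, {
    prot <- sprintf("P%04d", seq_len(nProteins))
    idx <- seq_len(nProteins) - 1L
    row <- idx %/% perRow + 1L
    col1 <- 2L * (idx %% perRow) + 1L
    binders <- sort(sample(prot, nBinders))
    mkArray <- function(arrayId) {
      r <- exp(stats::rnorm(2L * nProteins, 0, noiseSd))
      elev <- rep(prot %in% binders, each = 2L) * effectSdMultiple * noiseSd
      r <- r + elev
      b <- stats::runif(2L * nProteins, 400, 600)
      data.frame(array_id = arrayId,
                 protein_id = rep(prot, each = 2L),
                 row = rep(row, each = 2L),
                 col = as.integer(rbind(col1, col1 + 1L)),
                 F = r * b, B = b, flag = "ok",
                 stringsAsFactors = FALSE)
    }
    list(arrayA = mkArray("A"), arrayB = mkArray("B"), truth = binders,
         params = list(nProteins = nProteins, nBinders = nBinders,
                       effectSdMultiple = effectSdMultiple,
                       noiseSd = noiseSd, seed = seed))
  })
}

#' Write a synthetic spot table in GenePix-results style
#'
#' @param spots spot `data.frame` from [genMicroarray()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpotTable <- function(spots, path) {
  out <- data.frame(Block = 1L, Row = spots$row, Column = spots$col,
                    Name = spots$protein_id, F_Median = spots$F,
                    B_Median = spots$B,
                    Flag = ifelse(spots$flag == "ok", 0L, -100L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic genome with peaks, summits and a methylome
#'
#' Emulates the in vivo integration input: a random genome carrying
#' `nSummits` binding peaks (152-370 bp, summits near peak centers), each
#' summit assigned to a methylation stratum (high/mid/low with
#' probabilities `fracHigh`, `fracLow` and the remainder mid, matching the
#' observed bimodal methylation of CpG-containing binding sites), a
#' per-CpG methylome with binomial read counts at the stratum methylation
#' level, and a central-CpG k-mer planted in the high-methylation summit
#' windows at `fold` times the random-background occurrence rate
#' (insertions beyond the 1x background are added, so `fold = 1` plants
#' nothing).
#'
#' @param nSummits number of peaks/summits (default 400).
#' @param fracHigh,fracLow stratum probabilities (defaults 0.48 / 0.38).
#' @param plantedKmer central-CpG k-mer to enrich (default `"CCCGCC"`).
#' @param fold foreground enrichment fold over background (default 5).
#' @param coverage methylome read coverage per CpG (default 30).
#' @param summitHalf half-width of the foreground window (default 60).
#' @param seed integer seed.
#' @return list with `genome` (`DNAStringSet`), `peaks` (`GRanges` with
#'   `summit`), `methylome` (`data.frame`), `truth` (planted k-mer,
#'   per-summit stratum and true M).
#' @export
genPeaksMethylome <- function(nSummits = 400L, fracHigh = 0.48,
                              fracLow = 0.38, plantedKmer = "CCCGCC",
                              fold = 5, coverage = 30L, summitHalf = 60L,
                              seed = 1L) {
  stopifnot(fracHigh + fracLow <= 1)
  k <- nchar(plantedKmer)
  if (substr(plantedKmer, k %/% 2L, k %/% 2L + 1L) != "CG")
    stop("planted k-mer must have CG at its central two positions")
  withSeed(seed, {
    widths <- as.integer(round(stats::runif(nSummits, 152, 370)))
    gap <- 200L
    starts <- cumsum(c(gap, widths[-nSummits] + gap))
    genomeLen <- starts[nSummits] + widths[nSummits] + gap
    seqChars <- strsplit(randomDna(genomeLen), "")[[1L]]
    summitOff <- widths %/% 2L +
      as.integer(round(stats::runif(nSummits, -10, 10)))
    summit <- starts + summitOff            # 1-based positions
    stratum <- sample(c("high", "mid", "low"), nSummits, replace = TRUE,
                      prob = c(fracHigh, 1 - fracHigh - fracLow, fracLow))
    mTrue <- ifelse(stratum == "high", stats::runif(nSummits, 0.85, 0.98),
                    ifelse(stratum == "low",
                           stats::runif(nSummits, 0.02, 0.15),
                           stats::runif(nSummits, 0.30, 0.70)))
    # plant extra copies in high-M foreground windows so that the window
    # rate is fold x the background expectation for one specific k-mer
    winLen <- 2L * summitHalf + 1L
    lambda0 <- 2 * (winLen - k + 1) / 4^k
    highIdx <- which(stratum == "high")
    plantChars <- strsplit(plantedKmer, "")[[1L]]
    for (i in highIdx) {
      nIns <- stats::rpois(1L, (fold - 1) * lambda0)
      if (nIns < 1L) next
      for (j in seq_len(nIns)) {
        off <- as.integer(stats::runif(1L, 0, winLen - k))
        at <- summit[i] - summitHalf + off
        seqChars[at:(at + k - 1L)] <- plantChars
      }
    }
    genomeSeq <- paste(seqChars, collapse = "")
    genome <- Biostrings::DNAStringSet(c(chrS = genomeSeq))
    peaks <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(starts, width = widths))
    peaks$summit <- summit
    # methylome: every CpG within the foreground windows, read counts at
    # the summit's true level
    meth <- do.call(rbind, lapply(seq_len(nSummits), function(i) {
      lo <- summit[i] - summitHalf
      hi <- summit[i] + summitHalf
      winSeq <- substr(genomeSeq, lo, hi)
      rel <- gregexpr("CG", winSeq)[[1L]]
      if (rel[1L] == -1L) return(NULL)
      pos0 <- lo + as.integer(rel) - 2L       # 0-based C position
      data.frame(chrom = "chrS", pos = pos0, strand = "+",
                 n_meth = stats::rbinom(length(pos0), coverage, mTrue[i]),
                 n_total = coverage)
    }))
    list(genome = genome, peaks = peaks, methylome = meth,
         truth = list(kmer = plantedKmer, stratum = stratum,
                      mTrue = mTrue, fold = fold))
  })
}

#' Generate a synthetic sensorgram from known rate constants
#'
#' Association then dissociation of the 1:1 Langmuir model sampled every
#' `dt` seconds (10 s by default, the label-free recording interval),
#' with multiplicative Gaussian noise. Phase durations default to six
#' characteristic times of the respective phase so both phases carry
#' curvature, capped for very slow kinetics.
#'
#' @param kOn,kOff,conc,sMax model parameters (see [modelAssociation()]).
#' @param noiseFrac multiplicative noise SD as a fraction of the signal
#'   (default 0).
#' @param dt sampling interval, s (default 10).
#' @param tAssoc,tDissoc phase durations, s (defaults: `6/k_obs` and
#'   `6/k_off`, bounded to \[300, 6000\] s).
#' @param seed integer seed.
#' @return list with `data` (`data.frame`: time_s, signal, phase),
#'   `concentration`, `tWash` and `truth` (k_on, k_off, K_D, S_max).
#' @export
genSensorgram <- function(kOn, kOff, conc, sMax = 1, noiseFrac = 0,
                          dt = 10, tAssoc = NULL, tDissoc = NULL,
                          seed = 1L) {
  stopifnot(kOn > 0, kOff > 0, conc > 0)
  kobs <- kOn * conc + kOff
  clampDur <- function(x) dt * max(30, min(600, ceiling(x / dt)))
  if (is.null(tAssoc)) tAssoc <- clampDur(6 / kobs)
  if (is.null(tDissoc)) tDissoc <- clampDur(6 / kOff)
  withSeed(seed, {
    ta <- seq(0, tAssoc, by = dt)
    sa <- modelAssociation(ta, kOn, kOff, conc, sMax)
    s0 <- modelAssociation(tAssoc, kOn, kOff, conc, sMax)
    td <- seq(dt, tDissoc, by = dt)
    sd_ <- modelDissociation(td, s0, kOff)
    sig <- c(sa, sd_)
    if (noiseFrac > 0)
      sig <- sig * (1 + stats::rnorm(length(sig), 0, noiseFrac))
    list(data = data.frame(
           time_s = c(ta, tAssoc + td),
           signal = sig,
           phase = rep(c("association", "dissociation"),
                       c(length(ta), length(td)))),
         concentration = conc, tWash = tAssoc,
         truth = list(kOn = kOn, kOff = kOff, kD = kOff / kOn,
                      sMax = sMax))
  })
}

#' Generate synthetic bisulfite read-call matrices
#'
#' Per-read Bernoulli methylation calls for an input and a ChIP sample at
#' stated per-site true levels and coverage, emulating cloned-PCR Sanger
#' bisulfite call matrices.
#'
#' @param inputLevels,chipLevels numeric true methylation levels in
#'   \[0, 1\], one per CpG site (equal lengths).
#' @param coverage reads per sample (default 20).
#' @param positions site positions (default `seq_along(inputLevels)`).
#' @param missingRate probability a call is missing (default 0).
#' @param seed integer seed.
#' @return list with `input`, `chip` (character matrices, reads x sites)
#'   and `truth`.
#' @export
genBisulfite <- function(inputLevels, chipLevels, coverage = 20L,
                         positions = NULL, missingRate = 0, seed = 1L) {
  stopifnot(length(inputLevels) == length(chipLevels),
            all(inputLevels >= 0 & inputLevels <= 1),
            all(chipLevels >= 0 & chipLevels <= 1))
  if (is.null(positions)) positions <- seq_along(inputLevels)
  withSeed(seed, {
    mk <- function(levels, prefix) {
      m <- vapply(levels, function(p)
        ifelse(stats::rbinom(coverage, 1L, p) == 1L, "M", "U"),
        character(coverage))
      m <- matrix(m, nrow = coverage)
      if (missingRate > 0) {
        drop <- matrix(stats::runif(length(m)) < missingRate, nrow(m))
        # never blank out a read completely
        keep <- apply(drop, 1L, all)
        drop[keep, 1L] <- FALSE
        m[drop] <- "."
      }
      dimnames(m) <- list(paste0(prefix, seq_len(coverage)), positions)
      m
    }
    list(input = mk(inputLevels, "in_"), chip = mk(chipLevels, "ip_"),
         truth = list(inputLevels = inputLevels, chipLevels = chipLevels,
                      coverage = coverage))
  })
}
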