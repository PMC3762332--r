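# Per-read bisulfite methylation-call analysis: per-CpG methylation
# levels, region profiles, and the binomial tail test asking whether
# immunoprecipitated (ChIP'ed) DNA is more methylated than the genomic
# input at consensus CpG sites. Call matrices hold "M" (methylated), "U"
# (unmethylated) or "." (missing) per read x per CpG position.

#' Read a per-read methylation call matrix
#'
#' Tab-delimited file: first column `read_id`, then one column per CpG
#' position (header = genomic position), values `M`, `U` or `.`.
#'
#' @param path path to the TSV.
#' @return character matrix (reads x positions) with read ids as rownames
#'   and positions as column names.
#' @export
readCallMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "read_id")
    stop("first column must be 'read_id'")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$read_id
  if (!all(m %in% c("M", "U", ".")))
    stop("calls must be 'M', 'U' or '.'")
  pos <- suppressWarnings(as.numeric(colnames(m)))
  if (anyNA(pos)) stop("column headers must be numeric CpG positions")
  if (is.unsorted(pos, strictly = TRUE))
    stop("CpG positions must be strictly increasing")
  if (any(rowSums(m != ".") < 1L))
    stop("each read needs at least one non-missing call")
  m
}

#' Write a per-read methylation call matrix
#'
#' @param calls character matrix as returned by [readCallMatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCallMatrix <- function(calls, path) {
  df <- data.frame(read_id = rownames(calls), calls, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Methylation level at one CpG site
#'
#' @param calls character vector of per-read calls (`M`/`U`/`.`) at one
#'   site; missing calls are excluded from the denominator.
#' @return list with `k` (methylated reads), `n` (informative reads) and
#'   `level` (`k/n`; `NA` when every call is missing).
#' @export
siteMethylationLevel <- function(calls) {
  k <- sum(calls == "M")
  n <- sum(calls != ".")
  list(k = k, n = n, level = if (n) k / n else NA_real_)
}

#' Per-site methylation profile of a region
#'
#' Ordered per-CpG methylation levels plus the pooled region mean (total
#' methylated calls over total informative calls).
#'
#' @param calls character matrix (reads x positions).
#' @return list with `per_site` (`data.frame`: position, k, n, level) and
#'   `region_mean` (pooled).
#' @export
regionMethylationProfile <- function(calls) {
  per <- lapply(seq_len(ncol(calls)), function(j)
    siteMethylationLevel(calls[, j]))
  df <- data.frame(position = as.numeric(colnames(calls)),
                   k = vapply(per, `[[`, 0, "k"),
                   n = vapply(per, `[[`, 0, "n"),
                   level = vapply(per, `[[`, 0, "level"))
  list(per_site = df,
       region_mean = if (sum(df$n)) sum(df$k) / sum(df$n) else NA_real_)
}

binomTail <- function(k, n, p0, alternative) {
  switch(alternative,
         greater = stats::pbinom(k - 1L, n, p0, lower.tail = FALSE),
         less = stats::pbinom(k, n, p0),
         two.sided = pmin(1, 2 * pmin(
           stats::pbinom(k - 1L, n, p0, lower.tail = FALSE),
           stats::pbinom(k, n, p0))),
         stop("unknown alternative"))
}

#' Test for methylation increase in ChIP'ed DNA vs genomic input
#'
#' At every CpG position shared by the input and ChIP call matrices,
#' computes the input methylation level (the plug-in null p0), the ChIP
#' counts, and the one-sided binomial tail probability
#' P(X >= chip_k | n = chip_n, p0) of seeing at least the observed number
#' of methylated ChIP reads if ChIP DNA were methylated at the input
#' level. Consensus and non-consensus sites are both reported so the
#' contrast (consensus sites gain methylation after ChIP, neighbors stay
#' flat) is computable. Degenerate inputs (p0 of exactly 0 or 1) get the
#' forced binomial tail and a `degenerate` flag.
#'
#' @param inputCalls,chipCalls character matrices (reads x positions).
#' @param consensusSites numeric positions inside the bound consensus.
#' @param alternative `"greater"` (default; increase after ChIP),
#'   `"less"` or `"two.sided"`.
#' @return `data.frame` with columns `position`, `input_level`, `chip_k`,
#'   `chip_n`, `chip_level`, `delta`, `p`, `in_consensus`, `degenerate`.
#' @export
compareMethylation <- function(inputCalls, chipCalls,
                               consensusSites = numeric(),
                               alternative = c("greater", "less",
                                               "two.sided")) {
  alternative <- match.arg(alternative)
  shared <- intersect(colnames(inputCalls), colnames(chipCalls))
  if (!length(shared)) stop("no shared CpG positions")
  inp <- inputCalls[, shared, drop = FALSE]
  chp <- chipCalls[, shared, drop = FALSE]
  ik <- colSums(inp == "M"); inn <- colSums(inp != ".")
  ck <- colSums(chp == "M"); cn <- colSums(chp != ".")
  keep <- inn >= 1L & cn >= 1L
  p0 <- (ik / inn)[keep]
  ck <- ck[keep]; cn <- cn[keep]
  out <- data.frame(position = as.numeric(shared[keep]),
                    input_level = p0,
                    chip_k = as.integer(ck), chip_n = as.integer(cn),
                    chip_level = ck / cn,
                    delta = ck / cn - p0,
                    p = binomTail(ck, cn, p0, alternative),
                    in_consensus = as.numeric(shared[keep]) %in%
                      consensusSites,
                    degenerate = p0 %in% c(0, 1),
                    row.names = NULL)
  if (any(out$degenerate))
    message(sum(out$degenerate),
            " site(s) with degenerate input level (0 or 1)")
  out
}
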