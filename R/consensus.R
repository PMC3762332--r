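# mCpG-centered consensus motif derivation: because the methylated CpG is
# the conserved, binding-critical position (the unmethylated counterpart
# shows no binding), bound motifs are aligned on the mCpG, reduced to
# centered k-mers, clustered by flank similarity, and each cluster is
# summarized as a PWM + IUPAC consensus.

IUPAC_BY_BASES <- c(
  "A" = "A", "C" = "C", "G" = "G", "T" = "T",
  "AC" = "M", "AG" = "R", "AT" = "W", "CG" = "S", "CT" = "Y", "GT" = "K",
  "ACG" = "V", "ACT" = "H", "AGT" = "D", "CGT" = "B", "ACGT" = "N")

#' Build a validated motif table
#'
#' @param motif_id character ids.
#' @param sequence DNA strings over A/C/G/T.
#' @param cpg_offset 0-based index of the C of the annotated CpG.
#' @param methylated logical (default `TRUE`).
#' @return `data.frame` with the four columns, validated so that
#'   `substr(sequence, cpg_offset + 1, cpg_offset + 2) == "CG"`.
#' @export
motifTable <- function(motif_id, sequence, cpg_offset, methylated = TRUE) {
  sequence <- toupper(sequence)
  if (any(grepl("[^ACGT]", sequence)))
    stop("sequences must be over A/C/G/T")
  bad <- substr(sequence, cpg_offset + 1L, cpg_offset + 2L) != "CG"
  if (any(bad))
    stop("no CpG at the annotated offset for motif(s): ",
         paste(motif_id[bad], collapse = ", "))
  data.frame(motif_id = as.character(motif_id), sequence = sequence,
             cpg_offset = as.integer(cpg_offset),
             methylated = rep_len(methylated, length(sequence)),
             stringsAsFactors = FALSE)
}

#' Extract k-mers centered on the methylated CpG
#'
#' Aligns motif sequences on the annotated CpG and cuts out the k bases
#' with the CpG occupying the two central positions. Motifs whose CpG sits
#' too close to a sequence end to supply the (k/2 - 1)-base flanks are
#' skipped with a warning. Motifs annotated at several CpGs contribute one
#' k-mer per annotation.
#'
#' @param motifs `data.frame` from [motifTable()].
#' @param k even k-mer length (default 6).
#' @return `data.frame` with columns `kmer`, `motif_id`.
#' @examples
#' extractCenteredKmers(motifTable("M197", "TCCCGCCCA", 3))  # CCCGCC
#' @export
extractCenteredKmers <- function(motifs, k = 6L) {
  k <- as.integer(k)
  if (k < 4L || k %% 2L != 0L) stop("'k' must be an even integer >= 4")
  flank <- k %/% 2L - 1L
  startPos <- motifs$cpg_offset + 1L - flank         # 1-based
  endPos <- motifs$cpg_offset + 2L + flank
  ok <- startPos >= 1L & endPos <= nchar(motifs$sequence)
  if (any(!ok))
    warning("skipping motif(s) with insufficient flank around the CpG: ",
            paste(motifs$motif_id[!ok], collapse = ", "))
  data.frame(kmer = substr(motifs$sequence[ok], startPos[ok], endPos[ok]),
             motif_id = motifs$motif_id[ok], stringsAsFactors = FALSE)
}

flankPositions <- function(k) setdiff(seq_len(k), c(k %/% 2L, k %/% 2L + 1L))

#' Pairwise flank distance between centered k-mers
#'
#' Distance = fraction of mismatching flank positions. The central CG is
#' identical in every centered k-mer by construction and carries no
#' discriminative information, so it is excluded from the comparison.
#'
#' @param a,b k-mers of equal even length with central CG.
#' @return distance in \[0, 1\].
#' @export
kmerFlankDistance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  fp <- flankPositions(nchar(a))
  av <- strsplit(a, "")[[1L]][fp]
  bv <- strsplit(b, "")[[1L]][fp]
  mean(av != bv)
}

#' Cluster centered k-mers by flank similarity
#'
#' Agglomerative average-linkage clustering of mCpG-centered k-mers on the
#' flank-mismatch distance. Merging proceeds greedily from singletons:
#' at each step the pair of groups with the smallest average pairwise
#' distance is merged, until merging would join groups whose average
#' similarity (1 - distance) falls below `minSimilarity`. The procedure is
#' deterministic: k-mers are ordered lexicographically and distance ties
#' are broken by the lexicographically smallest group representatives.
#'
#' @param kmers character vector of centered k-mers (duplicates allowed;
#'   they always co-cluster at distance 0).
#' @param minSimilarity minimum average flank similarity within a merge
#'   (default 0.75, i.e. >= 3 of 4 matching flanks for k = 6).
#' @return list of character vectors (the groups), ordered by decreasing
#'   size then lexicographically by first member.
#' @export
clusterKmers <- function(kmers, minSimilarity = 0.75) {
  if (!length(kmers)) stop("need at least one k-mer")
  kmers <- sort(as.character(kmers))
  n <- length(kmers)
  maxDist <- 1 - minSimilarity
  d <- outer(seq_len(n), seq_len(n),
             Vectorize(function(i, j) kmerFlankDistance(kmers[i], kmers[j])))
  groups <- as.list(seq_len(n))
  repeat {
    g <- length(groups)
    if (g == 1L) break
    best <- NULL
    bestD <- Inf
    bestRep <- NULL
    for (i in seq_len(g - 1L)) {
      for (j in (i + 1L):g) {
        avg <- mean(d[groups[[i]], groups[[j]]])
        rep_ij <- sort(c(kmers[groups[[i]][1L]], kmers[groups[[j]][1L]]))
        if (avg < bestD - 1e-12 ||
            (abs(avg - bestD) <= 1e-12 && !is.null(bestRep) &&
             (rep_ij[1L] < bestRep[1L] ||
              (rep_ij[1L] == bestRep[1L] && rep_ij[2L] < bestRep[2L])))) {
          bestD <- avg
          best <- c(i, j)
          bestRep <- rep_ij
        }
      }
    }
    if (bestD > maxDist + 1e-12) break
    groups[[best[1L]]] <- sort(c(groups[[best[1L]]], groups[[best[2L]]]))
    groups[[best[2L]]] <- NULL
  }
  out <- lapply(groups, function(idx) kmers[idx])
  sizes <- lengths(out)
  firsts <- vapply(out, `[`, "", 1L)
  out[order(-sizes, firsts)]
}

#' Derive the consensus of a group of centered k-mers
#'
#' Builds the per-position base-frequency PWM of the group and the IUPAC
#' consensus string: at each position, the smallest degenerate code
#' covering all bases whose frequency reaches `threshold`. For a singleton
#' group the consensus is the k-mer itself. The result is invariant to the
#' order of the group members.
#'
#' @param group character vector of k-mers of equal length.
#' @param threshold base-frequency inclusion threshold for the IUPAC code
#'   (default 0.25).
#' @return a [Consensus-class].
#' @examples
#' consensusIUPAC(deriveConsensus(c("ACCGGA", "ACCGGT")))  # "ACCGGW"
#' @export
deriveConsensus <- function(group, threshold = 0.25) {
  if (!length(group)) stop("empty k-mer group")
  k <- nchar(group[1L])
  stopifnot(all(nchar(group) == k))
  mat <- do.call(rbind, strsplit(group, ""))
  bases <- c("A", "C", "G", "T")
  pwm <- vapply(seq_len(k), function(j) {
    tab <- table(factor(mat[, j], levels = bases))
    as.numeric(tab) / length(group)
  }, numeric(4L))
  rownames(pwm) <- bases
  colnames(pwm) <- seq_len(k)
  iupac <- paste(vapply(seq_len(k), function(j) {
    sel <- bases[pwm[, j] >= threshold]
    IUPAC_BY_BASES[[paste(sel, collapse = "")]]
  }, ""), collapse = "")
  new("Consensus", pwm = pwm, iupac = iupac, members = sort(group))
}

#' Consensus motifs for one TF's bound methylated motifs
#'
#' End-to-end consensus derivation: extract mCpG-centered k-mers from the
#' motifs a TF binds, cluster them by flank similarity, and derive one
#' consensus per group. The reported (first) consensus is that of the
#' largest group, ties broken lexicographically.
#'
#' @param motifs `data.frame` from [motifTable()] restricted to the motifs
#'   bound by one TF.
#' @param k k-mer length (default 6).
#' @param minSimilarity clustering cutoff (default 0.75).
#' @param threshold IUPAC inclusion threshold (default 0.25).
#' @return list of [Consensus-class] objects, largest group first.
#' @export
tfConsensus <- function(motifs, k = 6L, minSimilarity = 0.75,
                        threshold = 0.25) {
  km <- extractCenteredKmers(motifs, k)
  if (!nrow(km)) stop("no extractable centered k-mers")
  groups <- clusterKmers(km$kmer, minSimilarity)
  lapply(groups, deriveConsensus, threshold = threshold)
}

#' Write a PWM as a tab-delimited positions x bases table
#'
#' @param consensus a [Consensus-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePWM <- function(consensus, path) {
  stopifnot(is(consensus, "Consensus"))
  df <- data.frame(position = seq_len(ncol(consensus@pwm)),
                   t(consensus@pwm), row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
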