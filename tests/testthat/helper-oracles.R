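# Independent oracles and small fixture builders used across the suite.
# Every oracle is written from first principles, separately from the
# package code paths it checks.

# ArrayGrid wrapping a plain matrix (one ok spot per cell)
gridFromMatrix <- function(m, id = "t") {
  idx <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  new("ArrayGrid", arrayId = id, values = m,
      spots = data.frame(protein_id = paste0("s", seq_len(nrow(idx))),
                         row = idx$row, col = idx$col, flag = "ok"),
      stage = "Rprime")
}

# brute-force windowed median normalization: enumerate the window cell by
# cell, truncating at the borders
bruteWindowNormalize <- function(m, window) {
  half <- (window - 1) / 2
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (is.na(m[i, j])) next
    vals <- c()
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
          !is.na(m[ii, jj]))
        vals <- c(vals, m[ii, jj])
    }
    if (length(vals)) out[i, j] <- m[i, j] / median(vals)
  }
  out
}

# exact hypergeometric upper tail by log-binomial enumeration
hyperUpperTail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  xs <- k:min(K, n)
  xs <- xs[n - xs <= N - K]
  if (!length(xs)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# exact binomial upper tail by log-binomial enumeration
binomUpperTail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  xs <- k:n
  sum(exp(lchoose(n, xs) + xs * log(p) + (n - xs) * log1p(-p)))
}

# naive per-position central-CpG k-mer scan (character arithmetic only)
rcKmer <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(x, function(s)
    paste(rev(comp[strsplit(s, "")[[1L]]]), collapse = ""), "",
    USE.NAMES = FALSE)
}
naiveCentralKmerCount <- function(seqs, k = 6, collapseRC = TRUE) {
  counts <- new.env()
  bump <- function(key) {
    cur <- mget(key, counts, ifnotfound = 0)[[1L]]
    assign(key, cur + 1, counts)
  }
  scan1 <- function(s) {
    for (i in seq_len(max(0, nchar(s) - k + 1))) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      if (substr(w, k / 2, k / 2 + 1) != "CG") next
      key <- if (collapseRC) min(w, rcKmer(w)) else w
      bump(key)
    }
  }
  # every double-stranded site appears exactly once in a plus-strand scan
  # (its minus-strand reading is the same canonical key), so one pass over
  # the written strand enumerates all sites
  for (s in as.character(seqs)) scan1(s)
  out <- unlist(as.list(counts))
  out[order(names(out))]
}

# brute-force average-linkage agglomeration over k-mer flank distance,
# smallest-representative tie-break (mirrors the documented rule but is
# coded independently of the package implementation)
bruteClusterKmers <- function(kmers, minSim) {
  kmers <- sort(kmers)
  flankDist <- function(a, b) {
    k <- nchar(a)
    fp <- setdiff(seq_len(k), c(k / 2, k / 2 + 1))
    av <- substring(a, fp, fp); bv <- substring(b, fp, fp)
    sum(av != bv) / length(fp)
  }
  groups <- lapply(seq_along(kmers), function(i) i)
  repeat {
    if (length(groups) == 1) break
    cand <- NULL
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      dd <- mean(outer(groups[[i]], groups[[j]],
                       Vectorize(function(a, b)
                         flankDist(kmers[a], kmers[b]))))
      reps <- sort(c(kmers[min(groups[[i]])], kmers[min(groups[[j]])]))
      cand <- rbind(cand, data.frame(i = i, j = j, d = dd,
                                     r1 = reps[1], r2 = reps[2]))
    }
    cand <- cand[order(cand$d, cand$r1, cand$r2), ]
    if (cand$d[1] > (1 - minSim) + 1e-12) break
    a <- cand$i[1]; b <- cand$j[1]
    groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
    groups[[b]] <- NULL
  }
  out <- lapply(groups, function(ix) kmers[ix])
  out[order(-lengths(out), vapply(out, `[`, "", 1))]
}

# exact expected unique-protein count for random motif subsets:
# E[unique] = sum_p (1 - C(M - m_p, n) / C(M, n))
exactSaturation <- function(hits, n) {
  hitTab <- hits[hits$hit, ]
  M <- length(unique(hits$motif_id))
  mp <- table(hitTab$protein_id)
  sum(1 - choose(M - as.numeric(mp), n) / choose(M, n))
}

# hit data frame with a prescribed protein x motif logical matrix
hitsFromMatrix <- function(mat) {
  data.frame(protein_id = rep(rownames(mat), ncol(mat)),
             motif_id = rep(colnames(mat), each = nrow(mat)),
             hit = as.vector(mat))
}
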