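#' Read a spot-level microarray scan table
#'
#' Parses a tab-delimited spot table in the GenePix-results style used for
#' protein microarray competition assays. The file must carry a header
#' naming the columns `Block`, `Row`, `Column`, `Name`, `F_Median`,
#' `B_Median` and `Flag`. `Name` is the arrayed protein identifier;
#' `F_Median`/`B_Median` are the foreground and background median
#' fluorescence of the spot; `Flag` marks spot quality (0 or `"ok"` keeps
#' the spot, negative values or `"excluded"` exclude it, following scanner
#' flag conventions). Excluded rows are retained but marked, so they can be
#' masked out of all downstream statistics.
#'
#' @param path path to the tab-delimited table.
#' @param arrayId identifier to attach to the measurements (defaults to the
#'   file name without extension).
#' @return `data.frame` with columns `array_id`, `protein_id`, `row`,
#'   `col`, `F`, `B`, `flag`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(
#'   data.frame(Block = 1, Row = 1:2, Column = c(1, 1), Name = "P1",
#'              F_Median = c(2000, 1000), B_Median = 500, Flag = 0),
#'   tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' readSpotTable(tf)
#' @export
readSpotTable <- function(path, arrayId = NULL) {
  if (!file.exists(path)) stop("spot table not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  required <- c("Block", "Row", "Column", "Name", "F_Median", "B_Median",
                "Flag")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("spot table is missing required column(s): ",
         paste(missing, collapse = ", "))
  flag <- tab$Flag
  excluded <- if (is.numeric(flag)) flag < 0 else flag == "excluded"
  spots <- data.frame(
    array_id = if (is.null(arrayId))
      sub("\\.[^.]*$", "", basename(path)) else arrayId,
    protein_id = as.character(tab$Name),
    row = as.integer(tab$Row),
    col = as.integer(tab$Column),
    F = as.numeric(tab$F_Median),
    B = as.numeric(tab$B_Median),
    flag = ifelse(excluded, "excluded", "ok"),
    stringsAsFactors = FALSE)
  bad <- which(spots$flag == "ok" & !(spots$B > 0))
  if (length(bad))
    stop("non-positive background (B <= 0) on ok spot at data row ",
         bad[1L])
  spots
}

#' Compute raw binding intensity ratios R = F/B on the array grid
#'
#' Converts spot measurements into an [ArrayGrid-class] of raw intensity
#' ratios: each ok spot's cell holds R = F/B (foreground over background
#' median); excluded spots become `NA` and stay masked through every later
#' stage.
#'
#' @param spots `data.frame` from [readSpotTable()] (columns `protein_id`,
#'   `row`, `col`, `F`, `B`, `flag`, optionally `array_id`).
#' @param dim optional `c(nrow, ncol)` of the grid; defaults to the maximum
#'   observed row/column.
#' @return an [ArrayGrid-class] at stage `"R"`.
#' @export
computeRawIntensity <- function(spots, dim = NULL) {
  stopifnot(is.data.frame(spots))
  key <- paste(spots$row, spots$col)
  if (anyDuplicated(key))
    stop("duplicate grid position(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (any(spots$flag == "ok" & !(spots$B > 0)))
    stop("ok spots must have B > 0")
  if (is.null(dim)) dim <- c(max(spots$row), max(spots$col))
  values <- matrix(NA_real_, dim[1L], dim[2L])
  ok <- spots$flag == "ok"
  values[cbind(spots$row[ok], spots$col[ok])] <- spots$F[ok] / spots$B[ok]
  new("ArrayGrid",
      arrayId = if ("array_id" %in% names(spots))
        as.character(spots$array_id[1L]) else "array",
      values = values,
      spots = spots[, c("protein_id", "row", "col", "flag")],
      stage = "R")
}

#' Local window-median normalization of array intensities
#'
#' Normalizes each spot's raw intensity R by the median raw intensity of
#' its neighborhood: R' = R / median(window), where the window is the
#' `window` x `window` block centered on the spot (center included),
#' truncated at grid borders. Missing (excluded) cells never enter a
#' median and stay missing. After normalization, non-binding spots scatter
#' around R' = 1 and binding spots stand out above it, which is what makes
#' the mirrored-shadow noise model estimable.
#'
#' @param grid an [ArrayGrid-class] of raw intensities.
#' @param window odd window edge length (>= 3), default 9 (a 9 x 9 block).
#' @return an [ArrayGrid-class] at stage `"Rprime"`.
#' @export
localNormalize <- function(grid, window = 9L) {
  stopifnot(is(grid, "ArrayGrid"))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("'window' must be an odd integer >= 3")
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  if (nr == 0L || nc == 0L) stop("empty grid")
  half <- window %/% 2L
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1L, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      if (is.na(v[i, j])) next
      cj <- max(1L, j - half):min(nc, j + half)
      med <- stats::median(v[ri, cj], na.rm = TRUE)
      if (is.na(med)) {
        message(sprintf("all-missing window at (%d, %d); cell set missing",
                        i, j))
        next
      }
      out[i, j] <- v[i, j] / med
    }
  }
  initialize(grid, values = out, stage = "Rprime")
}

#' Estimate the mirrored-shadow background noise distribution
#'
#' Builds the background noise model from locally normalized intensities:
#' the shadow set N1 = \{R' < 1\} (binding only ever raises R', so the
#' sub-unity side is noise) is mirrored around 1 into N2 = 2 - N1, and the
#' union N = N1 u N2 -- symmetric about 1 by construction -- yields the
#' noise mean (1, by construction) and its population standard deviation
#' (dividing by |N|: N is a constructed distribution, not a sample from
#' one). Values exactly 1 carry no deviation and are not part of N1.
#'
#' @param x an [ArrayGrid-class] at stage `"Rprime"`, or a numeric vector
#'   of normalized intensities.
#' @param minShadow minimum size of the shadow set below which the array is
#'   declared uninterpretable (default 10).
#' @return a [NoiseModel-class].
#' @examples
#' estimateNoise(c(0.8, 0.9, 0.95, 1.3, 5.0), minShadow = 3)
#' @export
estimateNoise <- function(x, minShadow = 10L) {
  v <- if (is(x, "ArrayGrid")) as.vector(x@values) else as.numeric(x)
  v <- v[!is.na(v)]
  n1 <- v[v < 1]
  if (length(n1) < minShadow)
    stop(sprintf(
      "degenerate noise: only %d value(s) below 1 (need >= %d); array uninterpretable",
      length(n1), as.integer(minShadow)))
  n <- c(n1, 2 - n1)
  m <- mean(n)
  sdN <- sqrt(mean((n - m)^2))
  new("NoiseModel", mean = m, sd = sdN, nShadow = length(n1))
}

#' Standardize normalized intensities into Z-scores
#'
#' Z = (R' - mean(N)) / sd(N) elementwise, where the mean and SD come from
#' the mirrored-shadow noise model of the same array. Missing cells
#' propagate.
#'
#' @param grid an [ArrayGrid-class] at stage `"Rprime"` (or a numeric
#'   vector/matrix of R' values).
#' @param noise a [NoiseModel-class] from [estimateNoise()].
#' @return an [ArrayGrid-class] at stage `"Z"` (or a numeric object
#'   matching the input shape).
#' @export
computeZScores <- function(grid, noise) {
  stopifnot(is(noise, "NoiseModel"))
  if (is(grid, "ArrayGrid")) {
    z <- (grid@values - noise@mean) / noise@sd
    initialize(grid, values = z, stage = "Z")
  } else {
    (grid - noise@mean) / noise@sd
  }
}

#' Call methylated-DNA binding hits from duplicate arrays
#'
#' Applies the all-four-spots rule: because each protein is printed in
#' duplicate and each motif assay is performed on two replicate arrays, a
#' protein is a positive hit only when all four of its spots produce a
#' Z-score at or above the cutoff (default 3). Proteins with any excluded
#' or missing spot are never hits. Both arrays must share the same spot
#' layout, and every protein must occupy exactly two spots per array.
#'
#' @param zA,zB [ArrayGrid-class] objects at stage `"Z"` for the two
#'   replicate arrays.
#' @param motifId identifier of the probed motif.
#' @param cutoff Z-score cutoff, inclusive (default 3).
#' @return a [HitTable-class].
#' @export
callHits <- function(zA, zB, motifId = "motif", cutoff = 3) {
  stopifnot(is(zA, "ArrayGrid"), is(zB, "ArrayGrid"))
  spA <- zA@spots
  spB <- zB@spots
  keyA <- spA[order(spA$protein_id, spA$row, spA$col),
              c("protein_id", "row", "col")]
  keyB <- spB[order(spB$protein_id, spB$row, spB$col),
              c("protein_id", "row", "col")]
  rownames(keyA) <- rownames(keyB) <- NULL
  if (!identical(keyA, keyB))
    stop("replicate arrays have mismatched spot layouts")
  if (!nrow(spA))
    return(new("HitTable", motifId = motifId,
               z = matrix(numeric(), 0L, 4L,
                          dimnames = list(character(), paste0("z", 1:4))),
               hit = logical(), cutoff = cutoff))
  counts <- table(spA$protein_id)
  if (any(counts != 2L))
    stop("protein(s) with != 2 spots per array: ",
         paste(names(counts)[counts != 2L], collapse = ", "))
  prot <- sort(unique(spA$protein_id))
  z <- matrix(NA_real_, length(prot), 4L,
              dimnames = list(prot, paste0("z", 1:4)))
  ordA <- spA[order(spA$protein_id, spA$row, spA$col), ]
  zvalA <- zA@values[cbind(ordA$row, ordA$col)]
  zvalB <- zB@values[cbind(ordA$row, ordA$col)]
  z[, 1L] <- zvalA[seq(1L, length(zvalA), by = 2L)]
  z[, 2L] <- zvalA[seq(2L, length(zvalA), by = 2L)]
  z[, 3L] <- zvalB[seq(1L, length(zvalB), by = 2L)]
  z[, 4L] <- zvalB[seq(2L, length(zvalB), by = 2L)]
  finite <- apply(z, 1L, function(r) all(is.finite(r)))
  hit <- finite & apply(z >= cutoff, 1L, function(r) all(!is.na(r) & r))
  names(hit) <- prot
  if (any(!finite))
    message(sum(!finite), " protein(s) with missing spots: never hits")
  new("HitTable", motifId = motifId, z = z, hit = hit, cutoff = cutoff)
}

#' Pearson correlation between replicate arrays
#'
#' Reproducibility check between two arrays with identical layouts:
#' Pearson correlation over jointly non-missing cells.
#'
#' @param gridA,gridB [ArrayGrid-class] objects with identical layouts.
#' @return the correlation coefficient.
#' @export
replicateCorrelation <- function(gridA, gridB) {
  stopifnot(is(gridA, "ArrayGrid"), is(gridB, "ArrayGrid"))
  if (!identical(dim(gridA@values), dim(gridB@values)))
    stop("arrays have different grid dimensions")
  a <- as.vector(gridA@values)
  b <- as.vector(gridB@values)
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 3L)
    stop("correlation undefined: fewer than 3 jointly non-missing cells")
  stats::cor(a[keep], b[keep])
}

#' Run the full duplicate-array hit-calling pipeline
#'
#' Convenience wrapper chaining [computeRawIntensity()],
#' [localNormalize()], [estimateNoise()], [computeZScores()] and
#' [callHits()] for one motif probed on two replicate arrays.
#'
#' @param spotsA,spotsB spot `data.frame`s from [readSpotTable()] (or a
#'   synthetic generator) for the two replicate arrays.
#' @param motifId identifier of the probed motif.
#' @param window local-normalization window (default 9).
#' @param cutoff Z cutoff (default 3).
#' @param minShadow minimum shadow-set size (default 10).
#' @return list with elements `hits` ([HitTable-class]), `zA`, `zB`
#'   (Z-score grids) and `noiseA`, `noiseB` ([NoiseModel-class]).
#' @export
analyzeArrayPair <- function(spotsA, spotsB, motifId = "motif",
                             window = 9L, cutoff = 3, minShadow = 10L) {
  gA <- localNormalize(computeRawIntensity(spotsA), window)
  gB <- localNormalize(computeRawIntensity(spotsB), window)
  nA <- estimateNoise(gA, minShadow)
  nB <- estimateNoise(gB, minShadow)
  zA <- computeZScores(gA, nA)
  zB <- computeZScores(gB, nB)
  list(hits = callHits(zA, zB, motifId, cutoff), zA = zA, zB = zB,
       noiseA = nA, noiseB = nB)
}

#' Export per-spot statistics and a hit table as TSV
#'
#' @param hits a [HitTable-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
  stopifnot(is(hits, "HitTable"))
  df <- data.frame(protein_id = rownames(hits@z),
                   motif_id = hits@motifId,
                   hits@z,
                   hit = hits@hit,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
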