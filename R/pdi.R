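#' Flatten hit tables into a long protein x motif data frame
#'
#' @param x a [HitTable-class] or a list of them (one per motif assay).
#' @return `data.frame` with columns `protein_id`, `motif_id`, `hit` and
#'   `z_min` (the smallest of the four Z-scores, i.e. the binding evidence
#'   that the all-four-spots rule thresholds).
#' @export
hitFrame <- function(x) {
  if (is(x, "HitTable")) x <- list(x)
  do.call(rbind, lapply(x, function(h) {
    data.frame(protein_id = rownames(h@z),
               motif_id = h@motifId,
               hit = unname(h@hit),
               z_min = suppressWarnings(apply(h@z, 1L, min)),
               row.names = NULL)
  }))
}

#' Classify protein-DNA interactions by methylation preference
#'
#' Integrates the methylated-motif competition screen with a prior
#' unmethylated-motif screen over the same proteins and motifs. Every
#' (protein, motif) pair that is a hit in at least one screen becomes a
#' PDI record with category `METH_ONLY` (binds only the methylated form),
#' `UNMETH_ONLY`, or `BOTH`.
#'
#' @param methHits,unmethHits `data.frame`s with columns `protein_id`,
#'   `motif_id`, `hit` (logical), e.g. from [hitFrame()]. The two tables
#'   must cover the same protein and motif identifier universes.
#' @return `data.frame` with columns `protein_id`, `motif_id`,
#'   `hit_meth`, `hit_unmeth`, `category`.
#' @seealso [pdiSummary()]
#' @export
classifyPDIs <- function(methHits, unmethHits) {
  for (nm in c("protein_id", "motif_id", "hit")) {
    if (!nm %in% names(methHits) || !nm %in% names(unmethHits))
      stop("hit tables need columns protein_id, motif_id, hit")
  }
  offP <- c(setdiff(methHits$protein_id, unmethHits$protein_id),
            setdiff(unmethHits$protein_id, methHits$protein_id))
  offM <- c(setdiff(methHits$motif_id, unmethHits$motif_id),
            setdiff(unmethHits$motif_id, methHits$motif_id))
  if (length(offP) || length(offM))
    stop("identifier universes differ between screens: ",
         paste(unique(c(offP, offM)), collapse = ", "))
  m <- methHits[methHits$hit, c("protein_id", "motif_id")]
  u <- unmethHits[unmethHits$hit, c("protein_id", "motif_id")]
  keyM <- paste(m$protein_id, m$motif_id, sep = "\r")
  keyU <- paste(u$protein_id, u$motif_id, sep = "\r")
  allKey <- sort(union(keyM, keyU))
  if (!length(allKey))
    return(data.frame(protein_id = character(), motif_id = character(),
                      hit_meth = logical(), hit_unmeth = logical(),
                      category = character()))
  parts <- strsplit(allKey, "\r", fixed = TRUE)
  hitM <- allKey %in% keyM
  hitU <- allKey %in% keyU
  data.frame(
    protein_id = vapply(parts, `[`, "", 1L),
    motif_id = vapply(parts, `[`, "", 2L),
    hit_meth = hitM,
    hit_unmeth = hitU,
    category = ifelse(hitM & hitU, "BOTH",
                      ifelse(hitM, "METH_ONLY", "UNMETH_ONLY")),
    row.names = NULL)
}

#' Summarize PDI categories with integer percentages
#'
#' Counts PDIs per methylation-preference category and reports percentages
#' rounded to the nearest integer percent, matching how binding-preference
#' splits are conventionally printed.
#'
#' @param pdis `data.frame` from [classifyPDIs()] (needs a `category`
#'   column).
#' @return `data.frame` with columns `category`, `count`, `percent`, rows
#'   ordered METH_ONLY, UNMETH_ONLY, BOTH.
#' @export
pdiSummary <- function(pdis) {
  lev <- c("METH_ONLY", "UNMETH_ONLY", "BOTH")
  cnt <- table(factor(pdis$category, levels = lev))
  total <- sum(cnt)
  data.frame(category = lev,
             count = as.integer(cnt),
             percent = if (total)
               as.integer(round(100 * as.integer(cnt) / total))
               else rep(NA_integer_, 3L),
             row.names = NULL)
}

#' Summarize binding coverage of a motif screen
#'
#' Distributional summaries of a hit table: how many proteins bind each
#' motif, how many motifs each protein binds, the median number of binders
#' per bound motif, and the percentage of motifs with at least one binder
#' (rounded to the nearest integer percent).
#'
#' @param hits `data.frame` with columns `protein_id`, `motif_id`, `hit`;
#'   every screened (protein, motif) pair should be present so unbound
#'   motifs are counted.
#' @return list with `per_motif` (motif_id, n_binders), `per_protein`
#'   (protein_id, n_motifs), `n_motifs`, `n_motifs_bound`,
#'   `pct_motifs_bound`, `median_binders_per_bound_motif` (`NA` when no
#'   motif is bound), `n_hit_proteins`.
#' @export
summarizeBinding <- function(hits) {
  stopifnot(all(c("protein_id", "motif_id", "hit") %in% names(hits)))
  perMotif <- stats::aggregate(hit ~ motif_id, data = hits, FUN = sum)
  names(perMotif)[2L] <- "n_binders"
  perProt <- stats::aggregate(hit ~ protein_id, data = hits, FUN = sum)
  names(perProt)[2L] <- "n_motifs"
  bound <- perMotif$n_binders >= 1L
  list(per_motif = perMotif,
       per_protein = perProt,
       n_motifs = nrow(perMotif),
       n_motifs_bound = sum(bound),
       pct_motifs_bound = as.integer(round(100 * mean(bound))),
       median_binders_per_bound_motif =
         if (any(bound)) stats::median(perMotif$n_binders[bound])
         else NA_real_,
       n_hit_proteins = sum(perProt$n_motifs >= 1L))
}

#' Hypergeometric annotation enrichment of hit proteins
#'
#' Upper-tail hypergeometric probability that the overlap between the hit
#' proteins and an annotation set (e.g. oncogenes/tumor suppressors, or
#' development genes) is at least as large as observed, drawing
#' `|hitProteins|` proteins from the arrayed universe.
#'
#' @param hitProteins character vector of hit protein ids (the draws).
#' @param members character vector of annotated protein ids (the
#'   successes); must be a subset of the universe.
#' @param universe character vector of all arrayed protein ids, or a
#'   single integer universe size (in which case `hitProteins` and
#'   `members` sizes/overlap must be consistent with it).
#' @param overlap optional observed overlap; by default
#'   `length(intersect(hitProteins, members))`.
#' @return the one-sided enrichment p-value P(X >= overlap).
#' @examples
#' annotationEnrichment(hitProteins = paste0("p", 1:4),
#'                      members = paste0("p", c(1:4, 10)),
#'                      universe = paste0("p", 1:10))  # 5/210
#' @export
annotationEnrichment <- function(hitProteins, members, universe,
                                 overlap = NULL) {
  if (length(universe) == 1L && is.numeric(universe)) {
    N <- as.integer(universe)
    K <- length(members)
    n <- length(hitProteins)
    k <- if (is.null(overlap))
      length(intersect(hitProteins, members)) else as.integer(overlap)
  } else {
    if (!all(members %in% universe))
      stop("annotation members must be a subset of the universe")
    if (!all(hitProteins %in% universe))
      stop("hit proteins must be a subset of the universe")
    N <- length(unique(universe))
    K <- length(unique(members))
    n <- length(unique(hitProteins))
    k <- length(intersect(unique(hitProteins), unique(members)))
  }
  if (k > n) stop("impossible input: overlap exceeds number of draws")
  if (k > K) stop("impossible input: overlap exceeds annotation size")
  if (k == 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Saturation curve of unique hit proteins vs motifs tested
#'
#' Estimates, for each number n of tested motifs, the expected number of
#' unique proteins hitting at least one of n randomly chosen motifs, by
#' Monte-Carlo subsampling of the observed hit table. A curve far from its
#' plateau indicates that testing more motifs would keep discovering new
#' mCpG-binding proteins.
#'
#' @param hits `data.frame` with `protein_id`, `motif_id`, `hit`.
#' @param nGrid integer vector of motif-subset sizes.
#' @param nDraws Monte-Carlo draws per size (default 100).
#' @param seed optional integer seed for the subsampling.
#' @return `data.frame` with columns `n`, `mean_unique`, `se`.
#' @export
saturationCurve <- function(hits, nGrid, nDraws = 100L, seed = NULL) {
  motifs <- unique(hits$motif_id)
  M <- length(motifs)
  if (any(nGrid > M)) stop("subset size exceeds number of motifs (", M, ")")
  if (!is.null(seed)) set.seed(seed)
  hitTab <- hits[hits$hit, c("protein_id", "motif_id")]
  byMotif <- split(hitTab$protein_id, factor(hitTab$motif_id,
                                             levels = motifs))
  res <- lapply(nGrid, function(n) {
    if (n == 0L) return(c(mean = 0, se = 0))
    u <- vapply(seq_len(nDraws), function(i) {
      sel <- sample(motifs, n)
      length(unique(unlist(byMotif[sel], use.names = FALSE)))
    }, numeric(1L))
    c(mean = mean(u), se = stats::sd(u) / sqrt(nDraws))
  })
  data.frame(n = nGrid,
             mean_unique = vapply(res, `[`, 0, "mean"),
             se = vapply(res, `[`, 0, "se"))
}

#' False-positive rate implied by orthogonal validation
#'
#' When a subset of screen hits is re-tested with an orthogonal assay
#' (e.g. EMSA), the fraction not confirmed estimates the screen's
#' false-positive rate, reported as an integer percentage.
#'
#' @param confirmed number of hits confirmed by the orthogonal assay.
#' @param tested number of hits re-tested.
#' @return integer percentage `round(100 * (1 - confirmed/tested))`.
#' @examples
#' validationFalsePositiveRate(8, 11)  # 27
#' @export
validationFalsePositiveRate <- function(confirmed, tested) {
  stopifnot(tested >= 1, confirmed >= 0, confirmed <= tested)
  as.integer(round(100 * (1 - confirmed / tested)))
}
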