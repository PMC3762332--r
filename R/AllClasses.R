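#' @import methods
NULL

#' Spatial grid of microarray spot intensities
#'
#' Container for one scanned protein microarray: a numeric matrix of
#' per-spot values (raw intensity ratios R = F/B, locally normalized
#' intensities R', or Z-scores, depending on the processing stage) plus the
#' spot annotation mapping each arrayed protein to its duplicate grid
#' positions. Cells of excluded (flagged) spots are `NA` and never enter
#' window medians, noise estimation or hit calling.
#'
#' @slot arrayId single character identifier of the array/scan.
#' @slot values numeric matrix over (row, column); `NA` marks missing.
#' @slot spots `data.frame` with columns `protein_id`, `row`, `col`,
#'   `flag` (`"ok"` or `"excluded"`); one row per printed spot.
#' @slot stage character: which quantity `values` holds
#'   (`"R"`, `"Rprime"`, or `"Z"`).
#'
#' @seealso [computeRawIntensity()], [localNormalize()], [computeZScores()]
#' @export
setClass("ArrayGrid",
  representation(arrayId = "character", values = "matrix",
                 spots = "data.frame", stage = "character"))

setValidity("ArrayGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "'values' must be a numeric matrix")
  sp <- object@spots
  need <- c("protein_id", "row", "col", "flag")
  if (!all(need %in% names(sp)))
    msg <- c(msg, sprintf("'spots' must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(sp) && (max(sp$row) > nrow(object@values) ||
                     max(sp$col) > ncol(object@values) ||
                     min(sp$row) < 1L || min(sp$col) < 1L))
      msg <- c(msg, "spot positions outside grid dimensions")
    key <- paste(sp$row, sp$col)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate grid positions in 'spots'")
    if (!all(sp$flag %in% c("ok", "excluded")))
      msg <- c(msg, "'flag' must be 'ok' or 'excluded'")
  }
  if (!object@stage %in% c("R", "Rprime", "Z"))
    msg <- c(msg, "'stage' must be one of 'R', 'Rprime', 'Z'")
  if (length(msg)) msg else TRUE
})

#' Mirrored-shadow background noise model
#'
#' The background noise distribution of a locally normalized array is
#' estimated from the "shadow" of the intensity distribution: all
#' normalized intensities R' < 1 (set N1) are reflected around 1
#' (N2 = 2 - N1) and the union N = N1 u N2 -- symmetric about 1 by
#' construction -- provides the mean and standard deviation used to
#' standardize every spot into a Z-score. Because true binders only ever
#' push R' above 1, the sub-unity side of the distribution is assumed to
#' be pure noise.
#'
#' @slot mean mean of the constructed noise set N (equals 1 by construction,
#'   up to floating point).
#' @slot sd population standard deviation of N (> 0).
#' @slot nShadow number of values in the shadow set N1.
#'
#' @seealso [estimateNoise()], [computeZScores()]
#' @export
setClass("NoiseModel",
  representation(mean = "numeric", sd = "numeric", nShadow = "integer"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (length(object@sd) != 1L || !is.finite(object@sd) || object@sd <= 0)
    msg <- c(msg, "'sd' must be a single positive finite number")
  if (length(object@mean) != 1L || !is.finite(object@mean))
    msg <- c(msg, "'mean' must be a single finite number")
  if (object@nShadow < 1L) msg <- c(msg, "'nShadow' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Hit table for one motif binding assay
#'
#' Result of probing one (methylated) DNA motif against a protein
#' microarray in duplicate: the four Z-scores per protein (2 replicate
#' arrays x 2 duplicate spots) and the hit call. A protein is a positive
#' hit only when all four of its spots reach the Z cutoff; a protein with
#' any excluded/missing spot can never be a hit.
#'
#' @slot motifId identifier of the probed motif.
#' @slot z numeric matrix, one row per protein (rownames = protein ids),
#'   columns `z1..z4` = (array A spot 1, array A spot 2, array B spot 1,
#'   array B spot 2); `NA` for excluded spots.
#' @slot hit named logical vector, `TRUE` iff all four Z-scores are finite
#'   and >= the cutoff.
#' @slot cutoff the Z cutoff used (default 3).
#'
#' @seealso [callHits()], [hitFrame()]
#' @export
setClass("HitTable",
  representation(motifId = "character", z = "matrix", hit = "logical",
                 cutoff = "numeric"))

setValidity("HitTable", function(object) {
  msg <- character()
  if (ncol(object@z) != 4L) msg <- c(msg, "'z' must have 4 columns")
  if (nrow(object@z) && is.null(rownames(object@z)))
    msg <- c(msg, "'z' must have rownames")
  if (length(object@hit) != nrow(object@z))
    msg <- c(msg, "'hit' length must match rows of 'z'")
  ok <- object@hit & !is.na(object@hit)
  if (any(ok)) {
    zh <- object@z[ok, , drop = FALSE]
    if (any(!is.finite(zh)) || any(zh < object@cutoff))
      msg <- c(msg, "hit=TRUE rows must have all four Z >= cutoff")
  }
  if (length(msg)) msg else TRUE
})

#' Consensus motif derived from a group of centered k-mers
#'
#' Position weight matrix and IUPAC string summarizing a cluster of
#' mCpG-centered k-mers. The PWM stores per-position base frequencies
#' (rows A, C, G, T; one column per position; column sums 1); the IUPAC
#' letter at each position is the smallest degenerate code covering every
#' base whose frequency reaches the inclusion threshold. The two central
#' positions are always C and G by construction.
#'
#' @slot pwm 4 x k numeric matrix, rownames `A,C,G,T`, column sums 1.
#' @slot iupac IUPAC degenerate-code string of length k.
#' @slot members character vector of the member k-mers.
#'
#' @seealso [deriveConsensus()], [clusterKmers()]
#' @export
setClass("Consensus",
  representation(pwm = "matrix", iupac = "character", members = "character"))

setValidity("Consensus", function(object) {
  msg <- character()
  if (!identical(rownames(object@pwm), c("A", "C", "G", "T")))
    msg <- c(msg, "'pwm' rownames must be A, C, G, T")
  else if (any(abs(colSums(object@pwm) - 1) > 1e-9))
    msg <- c(msg, "'pwm' columns must sum to 1")
  if (nchar(object@iupac) != ncol(object@pwm))
    msg <- c(msg, "'iupac' length must equal pwm positions")
  if (!length(object@members)) msg <- c(msg, "'members' must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Kinetic fit of a 1:1 Langmuir binding sensorgram
#'
#' Result of fitting association and dissociation phases of a label-free
#' sensorgram with the 1:1 Langmuir model: S_assoc(t) = S_eq (1 -
#' exp(-(k_on C + k_off) t)) with S_eq = S_max C / (C + K_D), and
#' S_dissoc(t) = S_0 exp(-k_off t); K_D = k_off / k_on.
#'
#' @slot kOn association rate constant, 1/(M s).
#' @slot kOff dissociation rate constant, 1/s.
#' @slot kD equilibrium dissociation constant k_off/k_on, molar.
#' @slot sMax maximal binding signal, signal units.
#' @slot concentration analyte concentration C, molar.
#' @slot rms root-mean-square residual over both phases.
#' @slot converged logical; `FALSE` marks a fit failure (e.g. no binding).
#' @slot message diagnostic text for failed fits (e.g. `"no binding"`).
#'
#' @seealso [fitSensorgram()], [averageKd()]
#' @export
setClass("KineticFit",
  representation(kOn = "numeric", kOff = "numeric", kD = "numeric",
                 sMax = "numeric", concentration = "numeric",
                 rms = "numeric", converged = "logical",
                 message = "character"))

setValidity("KineticFit", function(object) {
  msg <- character()
  if (isTRUE(object@converged)) {
    if (!is.finite(object@kOn) || object@kOn <= 0)
      msg <- c(msg, "converged fit must have k_on > 0")
    if (!is.finite(object@kOff) || object@kOff < 0)
      msg <- c(msg, "converged fit must have k_off >= 0")
    if (!isTRUE(all.equal(object@kD, object@kOff / object@kOn)))
      msg <- c(msg, "kD must equal kOff/kOn")
  }
  if (length(msg)) msg else TRUE
})
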