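# Accessor generics and show methods for the package's S4 classes.

#' @rdname ArrayGrid-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname ArrayGrid-class
#' @export
setGeneric("spotInfo", function(x) standardGeneric("spotInfo"))

#' @rdname ArrayGrid-class
#' @export
setGeneric("arrayId", function(x) standardGeneric("arrayId"))

#' @rdname NoiseModel-class
#' @export
setGeneric("noiseMean", function(x) standardGeneric("noiseMean"))

#' @rdname NoiseModel-class
#' @export
setGeneric("noiseSd", function(x) standardGeneric("noiseSd"))

#' @rdname NoiseModel-class
#' @export
setGeneric("nShadow", function(x) standardGeneric("nShadow"))

#' @rdname HitTable-class
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))

#' @rdname HitTable-class
#' @export
setGeneric("isHit", function(x) standardGeneric("isHit"))

#' @rdname HitTable-class
#' @export
setGeneric("hitProteins", function(x) standardGeneric("hitProteins"))

#' @rdname HitTable-class
#' @export
setGeneric("motifId", function(x) standardGeneric("motifId"))

#' @rdname Consensus-class
#' @export
setGeneric("consensusPWM", function(x) standardGeneric("consensusPWM"))

#' @rdname Consensus-class
#' @export
setGeneric("consensusIUPAC", function(x) standardGeneric("consensusIUPAC"))

#' @rdname Consensus-class
#' @export
setGeneric("consensusMembers", function(x) standardGeneric("consensusMembers"))

#' @rdname KineticFit-class
#' @export
setGeneric("kOn", function(x) standardGeneric("kOn"))

#' @rdname KineticFit-class
#' @export
setGeneric("kOff", function(x) standardGeneric("kOff"))

#' @rdname KineticFit-class
#' @export
setGeneric("kD", function(x) standardGeneric("kD"))

#' @rdname ArrayGrid-class
#' @export
setMethod("gridValues", "ArrayGrid", function(x) x@values)

#' @rdname ArrayGrid-class
#' @export
setMethod("spotInfo", "ArrayGrid", function(x) x@spots)

#' @rdname ArrayGrid-class
#' @export
setMethod("arrayId", "ArrayGrid", function(x) x@arrayId)

#' @rdname NoiseModel-class
#' @export
setMethod("noiseMean", "NoiseModel", function(x) x@mean)

#' @rdname NoiseModel-class
#' @export
setMethod("noiseSd", "NoiseModel", function(x) x@sd)

#' @rdname NoiseModel-class
#' @export
setMethod("nShadow", "NoiseModel", function(x) x@nShadow)

#' @rdname HitTable-class
#' @export
setMethod("zScores", "HitTable", function(x) x@z)

#' @rdname HitTable-class
#' @export
setMethod("isHit", "HitTable", function(x) x@hit)

#' @rdname HitTable-class
#' @export
setMethod("hitProteins", "HitTable", function(x) names(x@hit)[x@hit])

#' @rdname HitTable-class
#' @export
setMethod("motifId", "HitTable", function(x) x@motifId)

#' @rdname Consensus-class
#' @export
setMethod("consensusPWM", "Consensus", function(x) x@pwm)

#' @rdname Consensus-class
#' @export
setMethod("consensusIUPAC", "Consensus", function(x) x@iupac)

#' @rdname Consensus-class
#' @export
setMethod("consensusMembers", "Consensus", function(x) x@members)

#' @rdname KineticFit-class
#' @export
setMethod("kOn", "KineticFit", function(x) x@kOn)

#' @rdname KineticFit-class
#' @export
setMethod("kOff", "KineticFit", function(x) x@kOff)

#' @rdname KineticFit-class
#' @export
setMethod("kD", "KineticFit", function(x) x@kD)

#' @rdname ArrayGrid-class
#' @export
setMethod("show", "ArrayGrid", function(object) {
  v <- object@values
  cat(sprintf("ArrayGrid '%s' [%s]: %d x %d grid, %d spots (%d excluded), %d NA cells\n",
              object@arrayId, object@stage, nrow(v), ncol(v),
              nrow(object@spots), sum(object@spots$flag == "excluded"),
              sum(is.na(v))))
})

#' @rdname NoiseModel-class
#' @export
setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: mean = %.6g, sd = %.6g (n_shadow = %d)\n",
              object@mean, object@sd, object@nShadow))
})

#' @rdname HitTable-class
#' @export
setMethod("show", "HitTable", function(object) {
  cat(sprintf("HitTable for motif '%s': %d proteins, %d hits (Z >= %g on all 4 spots)\n",
              object@motifId, nrow(object@z), sum(object@hit), object@cutoff))
})

#' @rdname Consensus-class
#' @export
setMethod("show", "Consensus", function(object) {
  cat(sprintf("Consensus '%s' from %d k-mer(s): %s\n", object@iupac,
              length(object@members),
              paste(object@members, collapse = ", ")))
})

#' @rdname KineticFit-class
#' @export
setMethod("show", "KineticFit", function(object) {
  if (object@converged)
    cat(sprintf("KineticFit at C = %.3g M: k_on = %.4g 1/(M s), k_off = %.4g 1/s, K_D = %.4g M (rms %.3g)\n",
                object@concentration, object@kOn, object@kOff, object@kD,
                object@rms))
  else
    cat(sprintf("KineticFit at C = %.3g M: NOT converged (%s)\n",
                object@concentration, object@message))
})
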