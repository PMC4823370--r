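#' Marginalize a positional label distribution to mass shifts
#'
#' @param pool a [CarbonPool-class] (or an object with a label-state
#'   distribution)
#' @return a [MIDVector-class] whose fraction at M+k is the total probability
#'   of label vectors with k labeled carbons
#' @export
setGeneric("midOf", function(pool) standardGeneric("midOf"))

#' Scramble a symmetric pool end-to-end
#'
#' Succinate and fumarate are symmetric molecules: enzymes cannot distinguish
#' the two ends, so each labeling vector is averaged with its end-to-end
#' reversal. The mass isotopomer distribution is unchanged; only positional
#' information is randomized.
#'
#' @param pool a [CarbonPool-class] flagged symmetric in the network
#' @param symmetric character vector of symmetric pool names (checked)
#' @return the scrambled [CarbonPool-class]
#' @export
setGeneric("scrambleSymmetric", function(pool, symmetric) standardGeneric("scrambleSymmetric"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("nBackbone", function(x) standardGeneric("nBackbone"))

#' @rdname accessors
#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @rdname accessors
#' @export
setGeneric("correctionMatrix", function(x) standardGeneric("correctionMatrix"))

#' @rdname accessors
#' @export
setGeneric("poolProbs", function(x) standardGeneric("poolProbs"))

#' @rdname accessors
#' @export
setGeneric("poolCarbons", function(x) standardGeneric("poolCarbons"))

#' Accessors for sirmtools S4 objects
#'
#' Slot access for the core containers: `fractions()` and `nBackbone()` for
#' [MIDVector-class], `abundance()` for [IsotopePattern-class],
#' `correctionMatrix()` for [CorrectionMatrix-class], `poolProbs()` for
#' [CarbonPool-class], and `poolCarbons()` for [TracerNetwork-class].
#'
#' @param x the object
#' @return the corresponding slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("fractions", "MIDVector", function(x) x@fractions)

#' @rdname accessors
#' @export
setMethod("nBackbone", "MIDVector", function(x) x@nBackbone)

#' @rdname accessors
#' @export
setMethod("abundance", "IsotopePattern", function(x) x@abundance)

#' @rdname accessors
#' @export
setMethod("correctionMatrix", "CorrectionMatrix", function(x) x@matrix)

#' @rdname accessors
#' @export
setMethod("poolProbs", "CarbonPool", function(x) x@probs)

#' @rdname accessors
#' @export
setMethod("poolCarbons", "TracerNetwork", function(x) x@poolCarbons)
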