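NULL

#' Edge table of a network object
#'
#' @param x An \linkS4class{EdgeList}, \linkS4class{TRN},
#'   \linkS4class{PlantedNetwork} or \linkS4class{CrosstalkComponent}.
#' @return A \code{data.frame} with columns \code{source}, \code{target},
#'   \code{sign} (\code{+1} activation, \code{-1} inhibition).
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Node set of a network object
#'
#' @param x A network-bearing object.
#' @return Character vector of node symbols.
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' Network size
#'
#' The size of a regulatory network is the number of unique regulators plus
#' targets, i.e. the number of distinct nodes touched by its retained edges.
#'
#' @param x A \linkS4class{TRN}.
#' @return Integer scalar.
#' @export
setGeneric("networkSize", function(x) standardGeneric("networkSize"))

#' Boolean profile states
#'
#' @param x A \linkS4class{BooleanProfile}, \linkS4class{TRN} or
#'   \linkS4class{PlantedNetwork}.
#' @return Named integer vector of 0/1 gene states.
#' @export
setGeneric("profileStates", function(x) standardGeneric("profileStates"))

#' Planted master regulator of a synthetic network
#'
#' @param x A \linkS4class{PlantedNetwork}.
#' @return Character scalar, the root transcription factor.
#' @export
setGeneric("plantedMR", function(x) standardGeneric("plantedMR"))

#' Fraction of node states explained by the planted master regulator
#'
#' @param x A \linkS4class{PlantedNetwork}.
#' @return Numeric scalar in [0, 1].
#' @export
setGeneric("explainedFraction", function(x) standardGeneric("explainedFraction"))
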