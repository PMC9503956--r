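#' Number of residues
#' @param x an object with residues
#' @return integer count
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of chains
#' @param x an object with chains
#' @return integer count
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' One-letter residue sequence
#' @param x an object with residues
#' @return character vector of one-letter codes, one per residue
#' @export
setGeneric("residueCodes", function(x) standardGeneric("residueCodes"))

#' Reduce an all-atom structure to the 6-bead coarse-grained model
#'
#' Each residue is represented by six beads: P, C4', C2' (backbone and
#' sugar) and C2, C4, C6 (base).
#'
#' @param x a [NucleicStructure-class] in which every residue carries the
#'   six bead atoms (run [completeAtoms()] first if needed)
#' @return a [CoarseModel-class]
#' @export
setGeneric("coarseGrain", function(x) standardGeneric("coarseGrain"))

#' Secondary structure topology key
#'
#' The canonical key under which templates are indexed: the local
#' dot-bracket string itself (including \code{&} placement).  Two elements
#' have equal keys iff their local dot-bracket strings are identical.
#'
#' @param x a local dot-bracket string, an [SSE-class] or a
#'   [Template-class]
#' @return character key
#' @export
setGeneric("topologyKey", function(x) standardGeneric("topologyKey"))
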