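#' @import methods
NULL

#' Multi-chain secondary structure in extended dot-bracket notation
#'
#' Holds the per-chain dot-bracket strings of a (possibly multi-chain)
#' nucleic acid together with the derived pair table.  Positions are global,
#' 1-based, and do not count the \code{&} chain separators; chain identity is
#' recoverable from \code{breakAfter}.
#'
#' @slot chains character vector of per-chain dot-bracket strings over
#'   the alphabet \code{".()[]"}.
#' @slot pairs integer vector of length equal to the total number of
#'   nucleotides; \code{pairs[i]} is the partner of position \code{i} for
#'   round-bracket pairs, or \code{NA} if unpaired.
#' @slot pkPairs integer vector like \code{pairs} but for square-bracket
#'   (pseudoknot) pairs.
#' @slot breakAfter sorted integer vector of global positions after which a
#'   chain break occurs (length = number of chains - 1).
#'
#' @seealso [parseDotBracket()]
#' @export
setClass("DotBracket",
  representation(chains = "character", pairs = "integer",
                 pkPairs = "integer", breakAfter = "integer"))

setValidity("DotBracket", function(object) {
  n <- sum(nchar(object@chains))
  msg <- character()
  if (length(object@chains) == 0L || any(nchar(object@chains) == 0L))
    msg <- c(msg, "every chain must be non-empty")
  if (length(object@pairs) != n || length(object@pkPairs) != n)
    msg <- c(msg, "pair tables must have one entry per position")
  if (length(object@breakAfter) != length(object@chains) - 1L)
    msg <- c(msg, "number of breaks must equal number of chains - 1")
  for (tab in list(object@pairs, object@pkPairs)) {
    p <- which(!is.na(tab))
    if (any(tab[p] == p)) msg <- c(msg, "a position cannot pair with itself")
    if (!identical(tab[tab[p]], as.integer(p)))
      msg <- c(msg, "pair table must be an involution")
  }
  if (length(msg)) msg else TRUE
})

#' A smallest secondary element (SSE)
#'
#' One node of the secondary structure decomposition: a stem, or a loop of
#' kind hairpin, bulge, internal, junction, open or break.  Loop elements
#' carry \code{min(2, helix length)} boundary base pairs from each adjoining
#' helix, so that adjoining elements share up to two common base pairs used
#' as the assembly interface.
#'
#' @slot id integer element identifier (position in the decomposition).
#' @slot kind one of \code{"stem"}, \code{"hairpin"}, \code{"bulge"},
#'   \code{"internal"}, \code{"junction"}, \code{"open"}, \code{"break"}.
#' @slot positions sorted global 1-based member positions.
#' @slot pairs two-column integer matrix of the base pairs both of whose
#'   positions are members (for stems: all pairs of the helix; for loops:
#'   the boundary pairs taken from adjoining helices).
#' @slot local2d local dot-bracket string of the element, with \code{&}
#'   where a chain break falls between adjacent member positions.
#' @slot localSeq local nucleotide string (or \code{NA} when no sequence is
#'   attached).
#' @export
setClass("SSE",
  representation(id = "integer", kind = "character", positions = "integer",
                 pairs = "matrix", local2d = "character",
                 localSeq = "character"))

setValidity("SSE", function(object) {
  ok <- object@kind %in% c("stem", "hairpin", "bulge", "internal",
                           "junction", "open", "break")
  if (!ok) return("unknown SSE kind")
  if (is.unsorted(object@positions)) return("positions must be sorted")
  if (nrow(object@pairs) && !all(object@pairs %in% object@positions))
    return("all pair positions must be members")
  TRUE
})

#' Secondary structure tree of SSEs
#'
#' The decomposition of a secondary structure organised as a tree (a forest
#' when the structure has several disconnected components): stems and loops
#' are nodes, and an edge joins a stem to each adjoining loop through the
#' base pairs they share.
#'
#' @slot sses list of [SSE-class] nodes.
#' @slot edges data.frame with integer columns \code{parent} and
#'   \code{child} (indices into \code{sses}).
#' @slot root integer index of the root node (the element containing the
#'   global 5' terminus).
#' @slot dotbracket the [DotBracket-class] the tree was built from.
#' @export
setClass("SecondaryStructureTree",
  representation(sses = "list", edges = "data.frame", root = "integer",
                 dotbracket = "DotBracket"))

#' All-atom nucleic acid structure
#'
#' A light-weight container for an all-atom model: one data.frame of atoms
#' with chain, residue and atom identifiers plus coordinates in Angstrom.
#' Residues carry a structure-wide ordinal \code{rindex} (1..n in file
#' order) used as the global addressing scheme shared with [DotBracket-class]
#' positions.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{inscode}, \code{resname}, \code{elety} (atom name), \code{x},
#'   \code{y}, \code{z}, \code{rindex}.
#' @export
setClass("NucleicStructure", representation(atoms = "data.frame"))

setValidity("NucleicStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "inscode", "resname", "elety",
            "x", "y", "z", "rindex")
  if (!all(need %in% names(a))) return("missing atom table columns")
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("coordinates must be finite")
    if (anyDuplicated(paste(a$rindex, a$elety)))
      return("atom names must be unique within a residue")
    if (is.unsorted(a$rindex)) return("atoms must be grouped by rindex")
  }
  TRUE
})

#' Coarse-grained 6-bead model
#'
#' Each residue is reduced to six beads: the backbone phosphate P, the sugar
#' atoms C4' and C2', and the base atoms C2, C4 and C6.
#'
#' @slot coords numeric matrix (6 * nres) x 3 of bead coordinates, residues
#'   in structure order, beads in the order P, C4', C2', C2, C4, C6.
#' @slot resname character vector of residue names (length nres).
#' @slot chain character vector of residue chain ids (length nres).
#' @export
setClass("CoarseModel",
  representation(coords = "matrix", resname = "character",
                 chain = "character"))

setValidity("CoarseModel", function(object) {
  n <- length(object@resname)
  if (nrow(object@coords) != 6L * n) return("expected 6 beads per residue")
  if (length(object@chain) != n) return("chain vector length mismatch")
  TRUE
})

#' An SSE-shaped 3D template fragment
#'
#' A candidate 3D fragment for one secondary element, extracted from an
#' experimental structure (DNA or RNA) or built de novo from ideal geometry.
#'
#' @slot sseKind element kind the fragment was cut for.
#' @slot local2d local dot-bracket string (the topology key).
#' @slot localSeq local nucleotide string.
#' @slot fragment the [NucleicStructure-class] holding the member residues.
#' @slot sourceId identifier of the source structure.
#' @slot sourceKind one of \code{"dna"}, \code{"rna"}, \code{"denovo"}.
#' @slot resolution resolution of the source in Angstrom (\code{NA} when
#'   unknown, e.g. NMR or de novo).
#' @export
setClass("Template",
  representation(sseKind = "character", local2d = "character",
                 localSeq = "character", fragment = "NucleicStructure",
                 sourceId = "character", sourceKind = "character",
                 resolution = "numeric"))

setValidity("Template", function(object) {
  if (!object@sourceKind %in% c("dna", "rna", "denovo"))
    return("sourceKind must be dna, rna or denovo")
  nres <- nResidues(object@fragment)
  nchr <- nchar(gsub("&", "", object@local2d, fixed = TRUE))
  if (nres != nchr)
    return("fragment residue count must match local2d length")
  if (nchar(object@localSeq) != nchr)
    return("localSeq length must match local2d length")
  TRUE
})

#' Searchable library of SSE templates
#'
#' Templates indexed by element kind and secondary structure topology
#' (the local dot-bracket string, including \code{&} placement).
#'
#' @slot templates list of [Template-class] objects.
#' @slot index named list mapping \code{"<kind>|<local2d>"} to integer
#'   indices into \code{templates}.
#' @slot kind library kind, \code{"dna"} or \code{"rna"}.
#' @export
setClass("TemplateLibrary",
  representation(templates = "list", index = "list", kind = "character"))

setValidity("TemplateLibrary", function(object) {
  if (length(object@index) &&
      max(unlist(object@index)) > length(object@templates))
    return("index points past the template list")
  TRUE
})

#' Knowledge-based statistical potential
#'
#' Distance-dependent energies over binned bead-type pair distances plus
#' pseudo-torsion energies over binned backbone torsions, of the form
#' \eqn{E = -\ln((obs + c) / (ref + c))} with a quasi-chemical reference
#' (bin totals apportioned by bead-pair-type frequency).
#'
#' @slot pairEnergies numeric matrix, one row per unordered bead-type pair
#'   (21 rows), one column per distance bin.
#' @slot torsionEnergies numeric matrix with rows \code{eta} and
#'   \code{theta}, one column per 10-degree torsion bin.
#' @slot binWidth distance bin width in Angstrom.
#' @slot maxDist upper end of the binned distance range in Angstrom.
#' @slot pseudocount pseudocount used in the log-odds formula.
#' @export
setClass("EnergyModel",
  representation(pairEnergies = "matrix", torsionEnergies = "matrix",
                 binWidth = "numeric", maxDist = "numeric",
                 pseudocount = "numeric"))

setValidity("EnergyModel", function(object) {
  if (!all(is.finite(object@pairEnergies))) return("non-finite pair energies")
  if (!all(is.finite(object@torsionEnergies)))
    return("non-finite torsion energies")
  TRUE
})
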