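#' Dock a molecule against a receptor
#'
#' @param oracle a [DockingOracle-class].
#' @param molecule a [LibraryMolecule-class] or a SMILES string.
#' @param receptorId receptor/model identifier.
#' @param ... passed to methods.
#' @return a [DockingResult-class].
#' @export
setGeneric("dock", function(oracle, molecule, receptorId = "receptor", ...)
  standardGeneric("dock"))

#' Number of products a combinatorial library can form
#'
#' Closed form: the sum over usable reactions of the product of slot sizes.
#' @param x a [CombinatorialLibrary-class].
#' @return numeric (may exceed integer range for real libraries).
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' Reaction table of a library
#' @param x a [CombinatorialLibrary-class].
#' @return data.frame of reactions.
#' @export
setGeneric("libReactions", function(x) standardGeneric("libReactions"))

#' Substrate table of a library
#' @param x a [CombinatorialLibrary-class].
#' @return data.frame of substrates.
#' @export
setGeneric("libSubstrates", function(x) standardGeneric("libSubstrates"))

#' Canonical address key of a library molecule
#' @param x a [LibraryMolecule-class].
#' @return character, `"<reaction>|<sub1>+<sub2>[+<sub3>]"`.
#' @export
setGeneric("moleculeKey", function(x) standardGeneric("moleculeKey"))

#' Individuals table of a run log
#' @param x a [RunLog-class].
#' @return data.frame of all evaluated molecules (including discarded).
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' Per-generation summary of a run log
#' @param x a [RunLog-class].
#' @return data.frame of generation summaries.
#' @export
setGeneric("generations", function(x) standardGeneric("generations"))
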