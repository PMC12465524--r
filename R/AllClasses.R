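#' @import methods
NULL

#' CombinatorialLibrary: a make-on-demand chemical space
#'
#' A combinatorial library is defined implicitly by building rules (reaction
#' SMARTS with two or three components) and building blocks (substrate
#' SMILES with their allowed reaction/position usages), the way ultra-large
#' make-on-demand catalogs such as Enamine REAL are specified.  The library
#' is never enumerated on construction; products are assembled on demand
#' from (reaction, substrate tuple) addresses.
#'
#' @slot reactions data.frame with columns `reaction_id`, `smarts`, `arity`,
#'   `usable`.  A reaction is unusable when one of its slots has no valid
#'   substrate.
#' @slot substrates data.frame with columns `substrate_id`, `smiles`
#'   (as given) and `canonical` (the package-wide canonical form).
#' @slot slots named list; element `"<reaction_id>|<position>"` holds the
#'   ordered character vector of substrate ids allowed in that slot
#'   (positions are 0-based, following the building-blocks file dialect).
#' @slot parsed internal list of pre-parsed reaction templates.
#' @slot cache environment memoizing assembled products by address.
#' @export
setClass("CombinatorialLibrary",
  representation(
    reactions = "data.frame",
    substrates = "data.frame",
    slots = "list",
    parsed = "list",
    cache = "environment"
  )
)

setValidity("CombinatorialLibrary", function(object) {
  msgs <- character(0)
  rx <- object@reactions
  need <- c("reaction_id", "smarts", "arity", "usable")
  if (!all(need %in% names(rx)))
    msgs <- c(msgs, "reactions must have reaction_id, smarts, arity, usable")
  else {
    if (any(!rx$arity %in% c(2L, 3L)))
      msgs <- c(msgs, "reaction arity must be 2 or 3")
    if (anyDuplicated(rx$reaction_id))
      msgs <- c(msgs, "duplicate reaction ids")
  }
  sb <- object@substrates
  if (!all(c("substrate_id", "smiles", "canonical") %in% names(sb)))
    msgs <- c(msgs, "substrates must have substrate_id, smiles, canonical")
  for (nm in names(object@slots)) {
    ids <- object@slots[[nm]]
    if (!all(ids %in% sb$substrate_id))
      msgs <- c(msgs, paste0("slot ", nm, " references unknown substrates"))
  }
  if (length(msgs)) msgs else TRUE
})

#' LibraryMolecule: one addressable member of a combinatorial library
#'
#' The unit the evolutionary engine manipulates: a library address (which
#' reaction, which substrate per position) plus the assembled product
#' structure as canonical SMILES.
#'
#' @slot reactionId single reaction identifier.
#' @slot substrateIds ordered substrate identifiers, one per position.
#' @slot productSmiles canonical SMILES of the assembled product.
#' @export
setClass("LibraryMolecule",
  representation(
    reactionId = "character",
    substrateIds = "character",
    productSmiles = "character"
  )
)

setValidity("LibraryMolecule", function(object) {
  msgs <- character(0)
  if (length(object@reactionId) != 1L) msgs <- c(msgs, "one reactionId")
  if (length(object@substrateIds) < 2L || length(object@substrateIds) > 3L)
    msgs <- c(msgs, "substrateIds must have length 2 or 3")
  if (length(object@productSmiles) != 1L)
    msgs <- c(msgs, "one productSmiles")
  if (length(msgs)) msgs else TRUE
})

#' DockingResult: per-pose interface scores for one molecule on one receptor
#'
#' @slot moleculeKey canonical SMILES of the docked molecule.
#' @slot receptorId receptor/model identifier.
#' @slot poses data.frame with `pose_index` and `interface_delta` (REU),
#'   sorted ascending by `interface_delta` (best pose first).
#' @slot coords list of heavy-atom coordinate matrices (one per pose, may
#'   be empty when the oracle was run without geometry).
#' @export
setClass("DockingResult",
  representation(
    moleculeKey = "character",
    receptorId = "character",
    poses = "data.frame",
    coords = "list"
  )
)

setValidity("DockingResult", function(object) {
  msgs <- character(0)
  if (nrow(object@poses) < 1L) msgs <- c(msgs, "at least one pose required")
  if (is.unsorted(object@poses$interface_delta))
    msgs <- c(msgs, "poses must be sorted ascending by interface_delta")
  if (length(object@coords) &&
      length(object@coords) != nrow(object@poses))
    msgs <- c(msgs, "coords, when present, must match pose count")
  if (length(msgs)) msgs else TRUE
})

#' DockingOracle: pluggable scoring backend
#'
#' Virtual parent for anything that can produce a [DockingResult-class] for
#' a library molecule: the bundled synthetic landscape
#' ([SyntheticOracle-class]) for offline work, or score tables from an
#' external docking engine ([TableOracle-class]).
#'
#' @export
setClass("DockingOracle", representation("VIRTUAL"))

#' SyntheticOracle: deterministic pseudo-docking landscape
#'
#' Scores a molecule by chemical similarity to a planted target motif plus a
#' size reward, with optional seeded per-pose noise:
#' `base = -A * tanimoto(fp(mol), fp(motif)) - B * sqrt(heavy_atoms)`.
#' With `noise = 0` the oracle is a pure function of (molecule, receptor),
#' which makes whole pipeline runs bit-reproducible.
#'
#' @slot motif target motif SMILES (the planted optimum).
#' @slot simWeight similarity weight A (REU).
#' @slot sizeWeight size weight B (REU per sqrt(atom)).
#' @slot noise per-pose Gaussian noise scale (REU).
#' @slot nPoses poses generated per dock.
#' @slot seed base seed; per-molecule streams are derived from it so results
#'   do not depend on evaluation order.
#' @slot withCoords emit synthetic pose coordinates (motif layout + jitter).
#' @slot state internal cache environment (motif fingerprint, score cache).
#' @export
setClass("SyntheticOracle",
  contains = "DockingOracle",
  representation(
    motif = "character",
    simWeight = "numeric",
    sizeWeight = "numeric",
    noise = "numeric",
    nPoses = "integer",
    seed = "integer",
    withCoords = "logical",
    state = "environment"
  )
)

setValidity("SyntheticOracle", function(object) {
  msgs <- character(0)
  if (object@nPoses < 1L) msgs <- c(msgs, "nPoses must be >= 1")
  if (object@noise < 0) msgs <- c(msgs, "noise scale must be >= 0")
  if (is.na(canonicalSmiles(object@motif)))
    msgs <- c(msgs, "motif SMILES does not parse")
  if (length(msgs)) msgs else TRUE
})

#' TableOracle: replay externally computed docking score tables
#'
#' Wraps a set of [DockingResult-class] objects read from a score table
#' (see [readScoreTable()]) so external docking engines can drive the same
#' cascade as the synthetic oracle.
#'
#' @slot results named list of [DockingResult-class], keyed
#'   `"<moleculeKey>|<receptorId>"`.
#' @export
setClass("TableOracle",
  contains = "DockingOracle",
  representation(results = "list")
)

#' RunLog: the complete record of one evolutionary run
#'
#' Every molecule evaluated across all generations is retained, including
#' discarded ones; each distinct molecule key appears exactly once with its
#' score and provenance.
#'
#' @slot runId run identifier.
#' @slot individuals data.frame, one row per distinct evaluated molecule:
#'   `key`, `reaction_id`, `substrate_ids`, `fitness` (lid_root2),
#'   `interface_delta`, `heavy_atoms`, `generation_born`, `operator`,
#'   `parent_keys`.
#' @slot generations data.frame of per-generation summaries (`generation`,
#'   `evaluated`, `distinct_total`, `best_fitness`, `median_fitness`).
#' @slot cacheStats list with `oracle_calls`, `cache_hits`.
#' @slot valid FALSE when the run aborted (oracle failure); the partial log
#'   is retained.
#' @export
setClass("RunLog",
  representation(
    runId = "character",
    individuals = "data.frame",
    generations = "data.frame",
    cacheStats = "list",
    valid = "logical"
  )
)
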