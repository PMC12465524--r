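# chemlib: parse, validate, enumerate and sample combinatorial libraries.
#
# File dialect (both files tab-separated, UTF-8, '#' comment lines, header):
#   building rules:  reaction_id  smarts  arity
#   building blocks: substrate_id smiles  reaction_id  position   (0-based;
#                    one row per allowed usage)

.slotKey <- function(reactionId, position) paste0(reactionId, "|", position)

# '#' marks comment LINES only; SMARTS legitimately contain '#' mid-field
.readTsv <- function(path, what) {
  if (!file.exists(path)) stop("cannot open ", what, " file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop(what, " file has no data rows: ", path)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (nrow(df) == 0L) stop(what, " file has no data rows: ", path)
  df
}

#' Load a combinatorial library from building rules and building blocks
#'
#' Reads the two tab-separated files that define a make-on-demand chemical
#' space: reactions as SMARTS building rules, and substrates as SMILES with
#' their declared usages.  Substrates whose SMILES do not parse are dropped
#' with a warning; a reaction left with an empty slot (or whose declared
#' arity disagrees with its template count) is kept but marked unusable.
#' Malformed SMARTS raise an error naming every offending reaction.
#'
#' @param rulesPath path to the building-rules TSV
#'   (`reaction_id`, `smarts`, `arity`).
#' @param substratesPath path to the building-blocks TSV
#'   (`substrate_id`, `smiles`, `reaction_id`, `position`; 0-based position,
#'   one row per usage).
#' @return a validated [CombinatorialLibrary-class].
#' @seealso [assembleProduct()], [enumerateProducts()], [makeToyLibrary()]
#' @export
loadLibrary <- function(rulesPath, substratesPath) {
  rules <- .readTsv(rulesPath, "building-rules")
  blocks <- .readTsv(substratesPath, "building-blocks")
  need <- c("reaction_id", "smarts", "arity")
  if (!all(need %in% names(rules)))
    stop("building-rules file must have columns: ",
         paste(need, collapse = ", "))
  need <- c("substrate_id", "smiles", "reaction_id", "position")
  if (!all(need %in% names(blocks)))
    stop("building-blocks file must have columns: ",
         paste(need, collapse = ", "))

  rules$reaction_id <- as.character(rules$reaction_id)
  rules$arity <- as.integer(rules$arity)
  parsed <- list()
  badSmarts <- character(0)
  for (i in seq_len(nrow(rules))) {
    rx <- tryCatch(parseReactionSmarts(rules$smarts[i]), error = function(e) e)
    if (inherits(rx, "error") || rx$arity != rules$arity[i] ||
        !rules$arity[i] %in% c(2L, 3L)) {
      badSmarts <- c(badSmarts, rules$reaction_id[i])
    } else {
      parsed[[rules$reaction_id[i]]] <- rx
    }
  }
  if (length(badSmarts))
    stop("malformed reaction SMARTS (or arity mismatch) for reaction_id: ",
         paste(badSmarts, collapse = ", "))

  blocks$substrate_id <- as.character(blocks$substrate_id)
  blocks$reaction_id <- as.character(blocks$reaction_id)
  blocks$position <- as.integer(blocks$position)
  usage <- unique(blocks[, c("substrate_id", "reaction_id", "position")])
  subs <- unique(blocks[, c("substrate_id", "smiles")])
  if (anyDuplicated(subs$substrate_id))
    stop("substrate_id maps to more than one SMILES")
  subs$canonical <- canonicalSmiles(subs$smiles)
  bad <- is.na(subs$canonical)
  if (any(bad)) {
    warning("dropping ", sum(bad), " substrate(s) with unparsable SMILES: ",
            paste(utils::head(subs$substrate_id[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) ", ..." else "")
    dropped <- subs$substrate_id[bad]
    subs <- subs[!bad, , drop = FALSE]
    usage <- usage[!usage$substrate_id %in% dropped, , drop = FALSE]
  }
  unknownRx <- setdiff(usage$reaction_id, rules$reaction_id)
  if (length(unknownRx))
    stop("building blocks reference undeclared reaction(s): ",
         paste(unknownRx, collapse = ", "))
  badPos <- usage$position >= rules$arity[match(usage$reaction_id,
                                                rules$reaction_id)] |
    usage$position < 0L
  if (any(badPos))
    stop("building-block usage with position outside reaction arity: ",
         paste(utils::head(unique(usage$substrate_id[badPos]), 5L),
               collapse = ", "))

  slots <- list()
  usable <- logical(nrow(rules))
  for (i in seq_len(nrow(rules))) {
    rid <- rules$reaction_id[i]
    ok <- TRUE
    for (pos in seq_len(rules$arity[i]) - 1L) {
      ids <- usage$substrate_id[usage$reaction_id == rid &
                                usage$position == pos]
      slots[[.slotKey(rid, pos)]] <- ids
      if (length(ids) == 0L) ok <- FALSE
    }
    usable[i] <- ok
  }
  rules$usable <- usable
  rownames(rules) <- NULL
  rownames(subs) <- NULL
  methods::new("CombinatorialLibrary",
               reactions = rules, substrates = subs, slots = slots,
               parsed = parsed, cache = new.env(parent = emptyenv()))
}

#' @describeIn librarySize closed-form product count over usable reactions.
#' @export
setMethod("librarySize", "CombinatorialLibrary", function(x) {
  total <- 0
  for (i in seq_len(nrow(x@reactions))) {
    if (!x@reactions$usable[i]) next
    rid <- x@reactions$reaction_id[i]
    sizes <- vapply(seq_len(x@reactions$arity[i]) - 1L,
                    function(p) length(x@slots[[.slotKey(rid, p)]]),
                    integer(1))
    total <- total + prod(sizes)
  }
  total
})

#' @describeIn libReactions reaction table accessor.
#' @export
setMethod("libReactions", "CombinatorialLibrary", function(x) x@reactions)

#' @describeIn libSubstrates substrate table accessor.
#' @export
setMethod("libSubstrates", "CombinatorialLibrary", function(x) x@substrates)

#' Substrates allowed in one slot of a reaction
#'
#' @param library a [CombinatorialLibrary-class].
#' @param reactionId reaction identifier.
#' @param position 0-based slot position.
#' @return character vector of substrate ids (ordered as loaded).
#' @export
slotSubstrates <- function(library, reactionId, position) {
  ids <- library@slots[[.slotKey(reactionId, position)]]
  if (is.null(ids)) stop("no slot ", position, " for reaction ", reactionId)
  ids
}

setMethod("show", "CombinatorialLibrary", function(object) {
  nr <- nrow(object@reactions)
  cat("CombinatorialLibrary with", nr, "reaction(s),",
      nrow(object@substrates), "substrate(s)\n")
  cat("  usable reactions:", sum(object@reactions$usable),
      " enumerable products:", format(librarySize(object), big.mark = " "),
      "\n")
})

setMethod("moleculeKey", "LibraryMolecule", function(x)
  paste0(x@reactionId, "|", paste(x@substrateIds, collapse = "+")))

setMethod("show", "LibraryMolecule", function(object) {
  cat("LibraryMolecule", moleculeKey(object), "\n  product:",
      object@productSmiles, "\n")
})

.substrateSmiles <- function(library, substrateIds) {
  idx <- match(substrateIds, library@substrates$substrate_id)
  if (anyNA(idx)) stop("unknown substrate id(s): ",
                       paste(substrateIds[is.na(idx)], collapse = ", "))
  library@substrates$smiles[idx]
}

#' Assemble the product molecule for a library address
#'
#' Applies the reaction's SMARTS template to the ordered substrates.  The
#' result is deterministic: when the template admits several placements
#' (and hence several products), the lexicographically smallest canonical
#' SMILES is kept.  Assembled products are memoized per library object.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param reactionId reaction identifier.
#' @param substrateIds ordered substrate ids, one per slot.
#' @return a [LibraryMolecule-class].
#' @examples
#' \dontrun{
#' lib <- loadLibrary("rules.tsv", "blocks.tsv")
#' assembleProduct(lib, "r1", c("acid_1", "amine_2"))
#' }
#' @export
assembleProduct <- function(library, reactionId, substrateIds) {
  i <- match(reactionId, library@reactions$reaction_id)
  if (is.na(i)) stop("unknown reaction: ", reactionId)
  arity <- library@reactions$arity[i]
  if (length(substrateIds) != arity)
    stop("reaction ", reactionId, " has arity ", arity, ", got ",
         length(substrateIds), " substrates")
  for (p in seq_len(arity) - 1L) {
    allowed <- library@slots[[.slotKey(reactionId, p)]]
    if (!substrateIds[p + 1L] %in% allowed)
      stop("substrate ", substrateIds[p + 1L],
           " is not allowed in position ", p, " of reaction ", reactionId)
  }
  key <- paste0(reactionId, "|", paste(substrateIds, collapse = "+"))
  hit <- library@cache[[key]]
  if (!is.null(hit)) return(hit)
  products <- applyReactionSmarts(library@parsed[[reactionId]],
                                  .substrateSmiles(library, substrateIds))
  mol <- methods::new("LibraryMolecule", reactionId = reactionId,
                      substrateIds = as.character(substrateIds),
                      productSmiles = products[1])
  library@cache[[key]] <- mol
  mol
}

#' Stream every product of a combinatorial library
#'
#' Returns an iterator function so that the full space never needs to be
#' materialized (real make-on-demand libraries run to billions of members).
#' Each call on the iterator yields the next [LibraryMolecule-class], or
#' `NULL` when exhausted.  Addresses are visited reaction by reaction in
#' odometer order over the slots.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param assemble assemble product structures (set `FALSE` to stream
#'   addresses only, which skips all chemistry work).
#' @return a function: `it()` yields the next molecule or `NULL`.
#' @seealso [enumerateProducts()] for the materialized small-library view.
#' @export
productIterator <- function(library, assemble = TRUE) {
  rxs <- library@reactions[library@reactions$usable, , drop = FALSE]
  ri <- 0L
  counters <- NULL
  sizes <- NULL
  ids <- NULL
  done <- nrow(rxs) == 0L

  nextReaction <- function() {
    ri <<- ri + 1L
    if (ri > nrow(rxs)) { done <<- TRUE; return(invisible(NULL)) }
    rid <- rxs$reaction_id[ri]
    ids <<- lapply(seq_len(rxs$arity[ri]) - 1L,
                   function(p) library@slots[[.slotKey(rid, p)]])
    sizes <<- lengths(ids)
    counters <<- rep(1L, length(ids))
  }
  nextReaction()

  function() {
    if (done) return(NULL)
    rid <- rxs$reaction_id[ri]
    subIds <- vapply(seq_along(ids), function(k) ids[[k]][counters[k]],
                     character(1))
    mol <- if (assemble) assembleProduct(library, rid, subIds)
    else methods::new("LibraryMolecule", reactionId = rid,
                      substrateIds = subIds, productSmiles = NA_character_)
    # odometer increment, last position fastest
    k <- length(counters)
    repeat {
      counters[k] <<- counters[k] + 1L
      if (counters[k] <= sizes[k]) break
      counters[k] <<- 1L
      k <- k - 1L
      if (k == 0L) { nextReaction(); break }
    }
    mol
  }
}

#' Enumerate a small library into a data.frame
#'
#' Materializes the full enumeration (guarded by `maxProducts`): one row per
#' library member with its address and canonical product SMILES.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param maxProducts hard guard against accidentally enumerating a large
#'   space (default 100000).
#' @param assemble assemble product structures (default TRUE).
#' @return data.frame with `reaction_id`, `substrate_ids` (joined by `+`),
#'   `key`, `product_smiles`.
#' @export
enumerateProducts <- function(library, maxProducts = 1e5, assemble = TRUE) {
  n <- librarySize(library)
  if (n > maxProducts)
    stop("library enumerates to ", n, " products; raise maxProducts or use ",
         "productIterator()")
  it <- productIterator(library, assemble = assemble)
  rows <- vector("list", n)
  i <- 0L
  repeat {
    mol <- it()
    if (is.null(mol)) break
    i <- i + 1L
    rows[[i]] <- data.frame(
      reaction_id = mol@reactionId,
      substrate_ids = paste(mol@substrateIds, collapse = "+"),
      key = moleculeKey(mol),
      product_smiles = mol@productSmiles,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[seq_len(i)])
  rownames(out) <- NULL
  out
}

#' Draw random molecules from a combinatorial library
#'
#' Sampling follows the library's generative structure: a usable reaction is
#' drawn uniformly, then each slot's substrate uniformly — the distribution
#' is uniform over (reaction, substrate tuple) addresses within a reaction,
#' not over the pooled product space.  Driven by R's RNG; seed with
#' `set.seed()` for reproducibility.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param n number of draws.
#' @param assemble assemble product structures (default TRUE).
#' @return a list of [LibraryMolecule-class] (length `n`).
#' @export
sampleRandomMolecule <- function(library, n = 1L, assemble = TRUE) {
  rxs <- library@reactions[library@reactions$usable, , drop = FALSE]
  if (nrow(rxs) == 0L) stop("library has no usable reaction")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (nrow(rxs) == 1L) 1L else sample.int(nrow(rxs), 1L)
    rid <- rxs$reaction_id[j]
    subIds <- vapply(seq_len(rxs$arity[j]) - 1L, function(p) {
      ids <- library@slots[[.slotKey(rid, p)]]
      if (length(ids) == 1L) ids else ids[sample.int(length(ids), 1L)]
    }, character(1))
    out[[i]] <- if (assemble) assembleProduct(library, rid, subIds)
    else methods::new("LibraryMolecule", reactionId = rid,
                      substrateIds = subIds, productSmiles = NA_character_)
  }
  out
}

#' Enumerate all single-position analogs of a hit (partner expansion)
#'
#' Hit expansion over the hit's building reaction: every allowed substrate
#' replaces each position in turn while the other position(s) stay fixed.
#' The union is deduplicated by address, so the original combination appears
#' exactly once; for a two-component reaction with slot sizes m and n the
#' result has m + n - 1 entries.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param molecule a [LibraryMolecule-class] belonging to the library.
#' @param assemble assemble product structures (default TRUE).
#' @return list of [LibraryMolecule-class].
#' @export
expandPartners <- function(library, molecule, assemble = TRUE) {
  rid <- molecule@reactionId
  i <- match(rid, library@reactions$reaction_id)
  if (is.na(i)) stop("molecule's reaction is not in this library: ", rid)
  arity <- library@reactions$arity[i]
  stopifnot(length(molecule@substrateIds) == arity)
  seen <- character(0)
  out <- list()
  for (p in seq_len(arity)) {
    for (sid in library@slots[[.slotKey(rid, p - 1L)]]) {
      subIds <- molecule@substrateIds
      subIds[p] <- sid
      key <- paste0(rid, "|", paste(subIds, collapse = "+"))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <-
        if (assemble) assembleProduct(library, rid, subIds)
        else methods::new("LibraryMolecule", reactionId = rid,
                          substrateIds = subIds,
                          productSmiles = NA_character_)
    }
  }
  out
}

#' Write molecules to a SMILES file
#'
#' One line per molecule: `product_smiles<TAB>reaction_id<TAB>substrates`
#' (substrate ids joined by `+`).
#'
#' @param molecules list of [LibraryMolecule-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMoleculeFile <- function(molecules, path) {
  lines <- vapply(molecules, function(m)
    paste(m@productSmiles, m@reactionId,
          paste(m@substrateIds, collapse = "+"), sep = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
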