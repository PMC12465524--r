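# Thin bridge to OpenBabel through ChemmineR/ChemmineOB.
#
# Everything that is standard cheminformatics plumbing — SMILES
# canonicalization, logP/TPSA/MW descriptors, ECFP fingerprints, full-SMARTS
# substructure matching — is delegated here.  The exported smartsSearch_OB
# wrapper in ChemmineOB mis-dispatches its SWIG overloads in current builds,
# so the matcher below talks to the working SWIG primitives directly.

.ob_state <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

.obns <- function() getNamespace("ChemmineOB")

#' @importFrom methods new is slot validObject
#' @importFrom stats kmeans rnorm runif sd setNames cor
#' @importFrom utils read.delim write.csv head
NULL

# one OBMol per SMILES string; atom order follows order of appearance in the
# string, which the reaction engine relies on
.obMol <- function(smiles) {
  mols <- ChemmineOB::forEachMol("SMILES", smiles, identity)
  if (length(mols) == 0L) return(NULL)
  mols[[1L]]
}

#' Canonicalize SMILES strings
#'
#' Returns the OpenBabel canonical SMILES for each input; `NA` where the
#' input does not parse.  One canonical writer is used for every dedup key
#' in the package so addresses and score-cache keys are stable.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector, same length, canonical SMILES or `NA`.
#' @examples
#' canonicalSmiles(c("C(C)O", "OCC"))
#' @export
canonicalSmiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  key <- paste0("can|", smiles)
  hit <- vapply(key, function(k) !is.null(.ob_state[[k]]), logical(1))
  for (i in which(hit)) out[i] <- .ob_state[[key[i]]]
  todo <- which(!hit & !is.na(smiles) & nzchar(smiles))
  if (length(todo)) {
    src <- paste0(smiles[todo], " id", seq_along(todo), collapse = "\n")
    res <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(src, "\n")),
      error = function(e) ""
    )
    if (nzchar(res)) {
      lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
      for (ln in lines) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(parts) >= 2 && grepl("^id[0-9]+$", parts[2])) {
          j <- as.integer(sub("^id", "", parts[2]))
          out[todo[j]] <- parts[1]
        }
      }
    }
    for (j in todo) .ob_state[[key[j]]] <- out[j]
  }
  out
}

# TRUE where the SMILES parses under OpenBabel
.smilesOK <- function(smiles) !is.na(canonicalSmiles(smiles))

# Match a SMARTS pattern against one molecule.
# Returns a list of integer vectors; each vector holds 1-based atom indices
# of the molecule (in SMILES appearance order), aligned with the pattern's
# query atoms in order of appearance.
.smartsMatch <- function(smiles, smarts, uniqueMatches = TRUE) {
  ckey <- paste0("m|", smarts, "|", smiles, "|", uniqueMatches)
  cached <- .ob_state[[ckey]]
  if (!is.null(cached)) return(cached)
  ob <- .obns()
  pkey <- paste0("sp|", smarts)
  sp <- .ob_state[[pkey]]
  if (is.null(sp)) {
    sp <- get("OBSmartsPattern", ob)()
    if (!get("OBSmartsPattern_Init", ob)(sp, smarts))
      stop("invalid SMARTS pattern: ", smarts)
    .ob_state[[pkey]] <- sp
  }
  mol <- .obMol(smiles)
  if (is.null(mol)) stop("unparsable SMILES: ", smiles)
  found <- get("OBSmartsPattern_Match__SWIG_1", ob)(sp, mol)
  res <- if (!found) list() else {
    maps <- if (uniqueMatches)
      get("OBSmartsPattern_GetUMapList", ob)(sp)
    else
      get("OBSmartsPattern_GetMapList", ob)(sp)
    lapply(maps, as.integer)
  }
  get("delete_OBMol", ob)(mol)
  .ob_state[[ckey]] <- res
  res
}

# memoized parse of a SMILES string into a molecular graph
.parsedGraph <- function(smiles) {
  key <- paste0("g|", smiles)
  g <- .ob_state[[key]]
  if (is.null(g)) {
    g <- parseSmiles(smiles)
    .ob_state[[key]] <- g
  }
  g
}

# validity check for a SMARTS pattern (compiles under OpenBabel)
.smartsOK <- function(smarts) {
  ob <- .obns()
  sp <- get("OBSmartsPattern", ob)()
  ok <- isTRUE(get("OBSmartsPattern_Init", ob)(sp, smarts))
  ok
}

# propOB via ChemmineR over an SDFset built from SMILES (assumed valid);
# columns of interest: MW, logP, TPSA
.obPropTable <- function(smiles) {
  nm <- paste0("m", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, nm))
  ChemmineR::propOB(sdf)
}

# ECFP4 fingerprints as a 0/1 matrix (rows = molecules), folded to nbits.
# Uses OpenBabel's FPS writer in one batched in-process conversion; the
# per-bit accessor route through the SWIG bindings is orders of magnitude
# slower.  Unfolded rows are cached per SMILES string.
.HEXBITS <- t(vapply(0:15, function(v)
  as.integer(bitwAnd(v, c(8L, 4L, 2L, 1L)) > 0L), integer(4)))

.obEcfp4 <- function(smiles, nbits = 2048L) {
  stopifnot(length(smiles) >= 1L)
  full <- matrix(0L, length(smiles), 4096L)
  keys <- paste0("fp|", smiles)
  miss <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    hit <- .ob_state[[keys[i]]]
    if (is.null(hit)) miss[i] <- TRUE else full[i, ] <- hit
  }
  todo <- which(miss)
  if (length(todo)) {
    ns <- .obns()
    src <- paste0(paste0(smiles[todo], " id", seq_along(todo),
                         collapse = "\n"), "\n")
    inStr <- get("istreamFromString", ns)(src)
    outStr <- get("ostreamToString", ns)()
    conv <- get("OBConversion", ns)(inStr, outStr)
    if (!get("OBConversion_SetInAndOutFormats", ns)(conv, "SMI", "FPS"))
      stop("OpenBabel cannot write FPS fingerprints")
    get("OBConversion_AddOption", ns)(conv, "f", "OUTOPTIONS", "ECFP4")
    get("OBConversion_Convert", ns)(conv)
    txt <- get("stringFromOstream", ns)(outStr)
    lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    got <- logical(length(todo))
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2L || !grepl("^id[0-9]+$", parts[2])) next
      j <- as.integer(sub("^id", "", parts[2]))
      vals <- strtoi(strsplit(tolower(parts[1]), "", fixed = TRUE)[[1]],
                     16L)
      row <- as.integer(t(.HEXBITS[vals + 1L, , drop = FALSE]))
      full[todo[j], ] <- row
      .ob_state[[keys[todo[j]]]] <- row
      got[j] <- TRUE
    }
    if (!all(got))
      stop("fingerprint generation failed for: ",
           paste(smiles[todo[!got]], collapse = ", "))
  }
  m <- full
  while (ncol(m) > nbits) {
    half <- ncol(m) / 2
    m <- pmax(m[, seq_len(half), drop = FALSE],
              m[, half + seq_len(half), drop = FALSE])
  }
  m
}
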