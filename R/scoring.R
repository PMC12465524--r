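# scoring: the lid_root2 fitness currency, the score-based filters of the
# triage cascade, and the pluggable docking-oracle contract.

#' Size-normalized docking score (lid_root2)
#'
#' The ligand interface delta square-root normalized: the docking interface
#' score divided by the square root of the heavy-atom count.  The
#' normalization removes the advantage large molecules have in raw
#' interface energies; more negative remains better.
#'
#' @param interfaceDelta interface score(s), REU.
#' @param heavyAtoms heavy-atom count(s), >= 1.
#' @return `interfaceDelta / sqrt(heavyAtoms)`, REU * atoms^(-1/2).
#' @examples
#' lidRoot2(-10, 25)   # -2
#' @export
lidRoot2 <- function(interfaceDelta, heavyAtoms) {
  if (any(heavyAtoms < 1L)) stop("heavyAtoms must be >= 1")
  interfaceDelta / sqrt(heavyAtoms)
}

#' Threshold filter on lid_root2 scores
#'
#' "Better" means at or below the threshold (scores are negative-better;
#' the boundary value counts as better).  `keep_better` retains the strong
#' binders (on-target triage); `exclude_better` removes them, which is the
#' off-target counter-screen reading where predicted anti-target binders
#' are discarded.
#'
#' @param scored data.frame with a `lid_root2` column (e.g. from
#'   [scoredMolecules()] or [aggregateRuns()]).
#' @param threshold normalized score cutoff (default -3.5).
#' @param mode `"keep_better"` or `"exclude_better"`.
#' @return the kept rows of `scored`.
#' @export
scoreThresholdFilter <- function(scored, threshold = -3.5,
                                 mode = c("keep_better", "exclude_better")) {
  mode <- match.arg(mode)
  better <- scored$lid_root2 <= threshold
  keep <- if (mode == "keep_better") better else !better
  out <- scored[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Redocking consistency filter
#'
#' Compares the score a molecule earned during the evolutionary search with
#' its redocking scores: delta1 is the absolute difference between the
#' search score and the best redock pose; delta2 is the spread
#' (worst - best) across the best ten redock poses.  A molecule fails when
#' either delta exceeds `deltaMax` (set `rule = "and"` for the laxer
#' both-must-exceed reading).  Large deltas flag unstable binding modes or
#' docking artifacts rather than genuine binders.
#'
#' @param revoldScore lid_root2 from the evolutionary run.
#' @param redockTop10 1-10 redock pose scores (lid_root2), best first.
#' @param deltaMax threshold on both deltas (default 0.8).
#' @param rule `"or"` (default) or `"and"` combination of the two tests.
#' @return list with `pass`, `delta1`, `delta2`.
#' @export
redockConsistencyFilter <- function(revoldScore, redockTop10,
                                    deltaMax = 0.8,
                                    rule = c("or", "and")) {
  rule <- match.arg(rule)
  if (length(redockTop10) < 1L) stop("empty redock pose list")
  if (length(redockTop10) > 10L) stop("at most the 10 best redock poses")
  if (is.unsorted(redockTop10))
    stop("redock scores must be sorted best (most negative) first")
  delta1 <- abs(revoldScore - redockTop10[1])
  delta2 <- max(redockTop10) - min(redockTop10)
  fail <- if (rule == "or") delta1 > deltaMax || delta2 > deltaMax
          else delta1 > deltaMax && delta2 > deltaMax
  list(pass = !fail, delta1 = delta1, delta2 = delta2)
}

#' Receptor-ensemble consensus filter
#'
#' Aggregates one molecule's best lid_root2 across several receptor models
#' into a consensus (arithmetic mean) and keeps the molecule only when the
#' per-model scores agree: the population standard deviation must not
#' exceed `stdMax`.  The models are treated as the complete ensemble, hence
#' the population (not sample) standard deviation.
#'
#' @param perModelScores numeric vector (>= 2) of best lid_root2 per
#'   receptor model; names are model ids.
#' @param stdMax maximum allowed standard deviation (default 0.5).
#' @return list with `consensus`, `std`, `keep`.
#' @export
ensembleConsensusFilter <- function(perModelScores, stdMax = 0.5) {
  if (length(perModelScores) < 2L)
    stop("consensus needs at least two receptor models")
  m <- mean(perModelScores)
  s <- sqrt(mean((perModelScores - m)^2))
  list(consensus = m, std = s, keep = s <= stdMax)
}

# ---- synthetic docking oracle --------------------------------------------

# deterministic 31-adic string hash, kept below 2^31 for seed derivation
.stringSeed <- function(...) {
  s <- paste(..., sep = "|")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

# run expr under a private RNG stream, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a synthetic docking oracle
#'
#' A deterministic pseudo-docking landscape for desk-scale work: the base
#' score of a molecule is
#' `-simWeight * tanimoto(ecfp4(mol), ecfp4(motif)) - sizeWeight * sqrt(heavy_atoms)`,
#' so the planted motif is the optimum of its size class and similarity to
#' it is monotonically rewarded.  Pose `i` adds a rank offset
#' `0.05 * (i - 1)` plus seeded Gaussian noise; with `noise = 0` the oracle
#' is a pure function of (molecule, receptor), independent of evaluation
#' order, so whole pipeline runs are bit-reproducible.
#'
#' @param motif target motif SMILES (must parse).
#' @param simWeight similarity weight A, REU (default 8).
#' @param sizeWeight size weight B, REU per sqrt(atom) (default 0.4).
#' @param noise per-pose Gaussian noise scale, REU (default 0).
#' @param nPoses poses per dock (150 by default, matching routine docking
#'   practice; exploratory and redocking protocols use 200 and 600).
#' @param seed base seed for the per-molecule noise streams.
#' @param withCoords also emit synthetic pose coordinates (a deterministic
#'   motif layout plus score-dependent jitter) so pose-geometry analyses
#'   can run on oracle output.
#' @return a [SyntheticOracle-class].
#' @export
syntheticOracle <- function(motif, simWeight = 8, sizeWeight = 0.4,
                            noise = 0, nPoses = 150L, seed = 1L,
                            withCoords = FALSE) {
  obj <- methods::new("SyntheticOracle",
    motif = motif, simWeight = simWeight, sizeWeight = sizeWeight,
    noise = noise, nPoses = as.integer(nPoses), seed = as.integer(seed),
    withCoords = withCoords, state = new.env(parent = emptyenv()))
  methods::validObject(obj)
  obj@state$motifFp <- drop(.obEcfp4(canonicalSmiles(motif)))
  obj
}

.oracleSmiles <- function(molecule) {
  if (methods::is(molecule, "LibraryMolecule")) molecule@productSmiles
  else if (is.character(molecule) && length(molecule) == 1L) molecule
  else stop("molecule must be a LibraryMolecule or one SMILES string")
}

#' @describeIn dock synthetic-landscape scoring; deterministic per
#'   (molecule, receptor, seed) regardless of call order, memoized per
#'   oracle object.
#' @export
setMethod("dock", "SyntheticOracle",
          function(oracle, molecule, receptorId = "receptor", ...) {
  smi <- .oracleSmiles(molecule)
  key <- canonicalSmiles(smi)
  if (is.na(key)) stop("unparsable molecule SMILES: ", smi)
  ckey <- paste0(key, "|", receptorId)
  hit <- oracle@state[[ckey]]
  if (!is.null(hit)) return(hit)
  fp <- drop(.obEcfp4(key))
  tan <- tanimoto(fp, oracle@state$motifFp)
  heavy <- .graphCounts(key)$heavy_atoms
  base <- -oracle@simWeight * tan - oracle@sizeWeight * sqrt(heavy)
  n <- oracle@nPoses
  eps <- if (oracle@noise > 0)
    .withSeed(.stringSeed(oracle@seed, ckey),
              stats::rnorm(n, 0, oracle@noise))
  else numeric(n)
  # interface scores on the REU-like scale of the landscape
  raw <- base * sqrt(heavy) + (seq_len(n) - 1L) * 0.05 * sqrt(heavy) +
    eps * sqrt(heavy)
  ord <- order(raw)
  poses <- data.frame(pose_index = seq_len(n),
                      interface_delta = raw[ord])
  coords <- list()
  if (oracle@withCoords) {
    ref <- .motifLayout(heavy, .stringSeed(oracle@seed, key))
    coords <- lapply(seq_len(n), function(i) {
      jit <- .withSeed(.stringSeed(oracle@seed, ckey, i),
                       matrix(stats::rnorm(heavy * 3L, 0,
                                           0.15 * (i - 1L) + 0.01),
                              ncol = 3L))
      ref + jit
    })
  }
  res <- methods::new("DockingResult", moleculeKey = key,
                      receptorId = receptorId, poses = poses,
                      coords = coords)
  oracle@state[[ckey]] <- res
  oracle@state$calls <- c(oracle@state$calls, ckey)
  res
})

# deterministic pseudo-3D layout: heavy atoms on a helix
.motifLayout <- function(nAtoms, seed) {
  t <- seq_len(nAtoms)
  cbind(2.2 * cos(t), 2.2 * sin(t), 0.9 * t)
}

#' @describeIn dock replay a stored score table; errors on molecules the
#'   table does not contain.
#' @export
setMethod("dock", "TableOracle",
          function(oracle, molecule, receptorId = "receptor", ...) {
  key <- canonicalSmiles(.oracleSmiles(molecule))
  res <- oracle@results[[paste0(key, "|", receptorId)]]
  if (is.null(res))
    stop("score table has no entry for ", key, " on ", receptorId)
  res
})

setMethod("show", "SyntheticOracle", function(object) {
  cat("SyntheticOracle: motif", object@motif, "\n  A =", object@simWeight,
      " B =", object@sizeWeight, " noise =", object@noise,
      " poses =", object@nPoses, "\n")
})

setMethod("show", "DockingResult", function(object) {
  cat("DockingResult", object@moleculeKey, "on", object@receptorId, ":",
      nrow(object@poses), "poses, best interface_delta",
      format(object@poses$interface_delta[1], digits = 4), "REU\n")
})

#' Summarize docking results into a scored-molecule table
#'
#' @param results list of [DockingResult-class].
#' @param provenance label for the stage that produced the scores
#'   (`"evolve"`, `"redock"`, `"offtarget"`, ...).
#' @return data.frame with `key`, `receptor_id`, `heavy_atoms`,
#'   `best_interface_delta`, `lid_root2`, `provenance`.
#' @export
scoredMolecules <- function(results, provenance = "evolve") {
  rows <- lapply(results, function(r) {
    heavy <- .graphCounts(r@moleculeKey)$heavy_atoms
    best <- r@poses$interface_delta[1]
    data.frame(key = r@moleculeKey, receptor_id = r@receptorId,
               heavy_atoms = heavy, best_interface_delta = best,
               lid_root2 = lidRoot2(best, heavy),
               provenance = provenance, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- external score-table adapter ----------------------------------------

#' Read a docking score table into DockingResult objects
#'
#' Expected CSV columns: `molecule_key`, `receptor_id`, `pose_index`,
#' `interface_delta`.  Rows failing to parse are reported as warnings; the
#' call errors only when nothing parses.  Poses are sorted best-first per
#' (molecule, receptor).
#'
#' @param path CSV file.
#' @return named list of [DockingResult-class], keyed
#'   `"<moleculeKey>|<receptorId>"`.
#' @seealso [tableOracle()], [writeScoreTable()]
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stop("cannot open score table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_key", "receptor_id", "pose_index", "interface_delta")
  if (!all(need %in% names(df)))
    stop("score table must have columns: ", paste(need, collapse = ", "))
  df$interface_delta <- suppressWarnings(as.numeric(df$interface_delta))
  bad <- is.na(df$interface_delta) | !nzchar(df$molecule_key)
  if (any(bad)) {
    warning(sum(bad), " malformed score-table row(s) skipped")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no parsable rows in score table: ", path)
  out <- list()
  for (grp in split(df, paste0(df$molecule_key, "|", df$receptor_id))) {
    grp <- grp[order(grp$interface_delta), , drop = FALSE]
    key <- grp$molecule_key[1]
    out[[paste0(key, "|", grp$receptor_id[1])]] <-
      methods::new("DockingResult", moleculeKey = key,
                   receptorId = grp$receptor_id[1],
                   poses = data.frame(pose_index = grp$pose_index,
                                      interface_delta = grp$interface_delta),
                   coords = list())
  }
  out
}

#' Write DockingResult objects as a score table CSV
#'
#' @param results list of [DockingResult-class].
#' @param path output CSV.
#' @return invisibly, the path.
#' @export
writeScoreTable <- function(results, path) {
  rows <- lapply(results, function(r)
    data.frame(molecule_key = r@moleculeKey, receptor_id = r@receptorId,
               pose_index = r@poses$pose_index,
               interface_delta = r@poses$interface_delta,
               stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Wrap stored docking results as an oracle
#'
#' @param results named list from [readScoreTable()], or a path to a score
#'   table CSV.
#' @return a [TableOracle-class].
#' @export
tableOracle <- function(results) {
  if (is.character(results)) results <- readScoreTable(results)
  methods::new("TableOracle", results = results)
}
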