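# site: structural post-processing of docked ligand clouds — residue
# contact consensus maps, fixed-correspondence ligand RMSD, and RMSD-score
# funnel tables.
#
# Conventions: heavy atoms only on both sides (docked structures vary in
# protonation); contacts are counted per compound using its best-scored
# pose; RMSD uses identity atom correspondence without re-superposition,
# since all poses share the receptor frame.

#' Read a receptor structure from a PDB file
#'
#' Keeps heavy atoms of ATOM/HETATM records (first altLoc only), grouped by
#' residue with author numbering and insertion codes preserved.
#'
#' @param path PDB file.
#' @return a `ReceptorStructure`: list with `sourceId` and `residues`
#'   (data.frame: chain, resno, insert, resid, and a coordinate matrix per
#'   residue in `coords`).
#' @export
readReceptorPdb <- function(path) {
  if (!file.exists(path)) stop("cannot open PDB file: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  keep <- at$elety != "H" & !grepl("^[0-9]*H", at$elety)
  at <- at[keep, , drop = FALSE]
  if (!nrow(at)) stop("no heavy atoms in PDB file: ", path)
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  rkey <- paste(at$chain, at$resno, ins, sep = "|")
  keys <- unique(rkey)
  residues <- data.frame(
    chain = vapply(strsplit(keys, "|", fixed = TRUE), `[`, character(1), 1L),
    resno = as.integer(vapply(strsplit(keys, "|", fixed = TRUE), `[`,
                              character(1), 2L)),
    insert = vapply(strsplit(keys, "|", fixed = TRUE), function(x)
      if (length(x) >= 3L) x[3] else "", character(1)),
    resid = at$resid[match(keys, rkey)],
    stringsAsFactors = FALSE)
  coords <- lapply(keys, function(k) {
    sel <- rkey == k
    m <- cbind(at$x[sel], at$y[sel], at$z[sel])
    if (any(!is.finite(m))) stop("non-finite coordinates in ", path)
    m
  })
  structure(list(sourceId = basename(path), residues = residues,
                 coords = coords),
            class = "ReceptorStructure")
}

#' @export
print.ReceptorStructure <- function(x, ...) {
  cat("ReceptorStructure", x$sourceId, ":", nrow(x$residues),
      "residue(s),", sum(vapply(x$coords, nrow, integer(1))),
      "heavy atoms\n")
  invisible(x)
}

#' Read ligand poses from an SDF file
#'
#' One molecule record per pose.  Score fields are taken from the SDF data
#' block (`molecule_key`, `interface_delta`, optional `pose_index`); heavy
#' atoms only are kept, in file order.
#'
#' @param path SDF file.
#' @return data.frame with `molecule_key`, `pose_index`,
#'   `interface_delta`, and coordinate matrices in the `coords` list
#'   column.
#' @export
readPoseSdf <- function(path) {
  if (!file.exists(path)) stop("cannot open SDF file: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  n <- length(sdf)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    mol <- sdf[[i]]
    ab <- mol@atomblock
    elem <- gsub("_.*$", "", rownames(ab))
    heavy <- toupper(elem) != "H"
    coords <- unname(ab[heavy, c("C1", "C2", "C3"), drop = FALSE])
    db <- mol@datablock
    key <- if ("molecule_key" %in% names(db)) db[["molecule_key"]]
           else mol@header[["Molecule_Name"]]
    score <- if ("interface_delta" %in% names(db))
      as.numeric(db[["interface_delta"]]) else NA_real_
    pidx <- if ("pose_index" %in% names(db))
      as.integer(db[["pose_index"]]) else i
    rows[[i]] <- list(molecule_key = key, pose_index = pidx,
                      interface_delta = score, coords = coords)
  }
  out <- data.frame(
    molecule_key = vapply(rows, `[[`, character(1), "molecule_key"),
    pose_index = vapply(rows, `[[`, integer(1), "pose_index"),
    interface_delta = vapply(rows, `[[`, numeric(1), "interface_delta"),
    stringsAsFactors = FALSE)
  out$coords <- lapply(rows, `[[`, "coords")
  out
}

#' Residue contact consensus map of a docked compound cloud
#'
#' For each receptor residue, counts the number of distinct compounds with
#' at least one heavy atom within `cutoff` of any residue heavy atom — one
#' count per compound regardless of how many atoms touch.  Counts are
#' binned for visualization (half-open, descending: >500, (400,500],
#' (200,400], (100,200], <=100).
#'
#' @param receptor a `ReceptorStructure` from [readReceptorPdb()].
#' @param poses data.frame as from [readPoseSdf()], expected to hold one
#'   (best) pose per compound.
#' @param cutoff contact distance, Angstrom (default 4.0).
#' @return data.frame: chain, resno, insert, resid, count, bin.
#' @export
residueContactMap <- function(receptor, poses, cutoff = 4.0) {
  if (nrow(poses) == 0L) stop("no poses supplied")
  nres <- nrow(receptor$residues)
  counts <- integer(nres)
  for (r in seq_len(nres)) {
    rc <- receptor$coords[[r]]
    touched <- vapply(poses$coords, function(pc) {
      d2 <- outer(rowSums(pc^2), rowSums(rc^2), `+`) -
        2 * (pc %*% t(rc))
      any(d2 <= cutoff^2 + 1e-12)
    }, logical(1))
    counts[r] <- length(unique(poses$molecule_key[touched]))
  }
  out <- receptor$residues
  out$count <- counts
  out$bin <- cut(counts, breaks = c(-Inf, 100, 200, 400, 500, Inf),
                 labels = c("<=100", "100-200", "200-400", "400-500",
                            ">500"))
  out
}

#' Ligand RMSD between two poses of the same molecule
#'
#' Root-mean-square deviation over heavy atoms under identity
#' correspondence, without superposition: the poses live in the shared
#' receptor frame, so rigid displacement is signal, not noise.
#'
#' @param coordsA,coordsB n x 3 coordinate matrices in identical atom
#'   order.
#' @return RMSD in Angstrom.
#' @export
ligandRmsd <- function(coordsA, coordsB) {
  if (!all(dim(coordsA) == dim(coordsB)))
    stop("atom count mismatch between poses")
  sqrt(mean(rowSums((coordsA - coordsB)^2)))
}

#' RMSD-score funnel table for one molecule's pose set
#'
#' The best pose is the lowest-scoring one; every pose with an interface
#' score at or below `scoreFloor` gets its RMSD to the best pose, poses
#' above the floor carry `NA` (they are too poorly scored to be
#' informative about convergence).  A funnel — RMSD growing as scores
#' worsen — indicates a converged binding mode.
#'
#' @param poses data.frame as from [readPoseSdf()] restricted to one
#'   molecule (needs `pose_index`, `interface_delta`, `coords`, and
#'   optionally `heavy_atoms`).
#' @param scoreFloor interface-score floor in REU (default -10): poses
#'   scoring worse are excluded from RMSD computation.
#' @return data.frame sorted by score: pose_index, interface_delta,
#'   lid_root2, rmsd_to_best.
#' @export
funnelTable <- function(poses, scoreFloor = -10) {
  stopifnot(nrow(poses) >= 1L)
  if (length(unique(poses$molecule_key)) > 1L)
    stop("funnelTable expects poses of a single molecule")
  ord <- order(poses$interface_delta)
  poses <- poses[ord, , drop = FALSE]
  heavy <- nrow(poses$coords[[1]])
  best <- poses$coords[[1]]
  rmsd <- rep(NA_real_, nrow(poses))
  eligible <- poses$interface_delta <= scoreFloor
  for (i in which(eligible)) rmsd[i] <- ligandRmsd(poses$coords[[i]], best)
  data.frame(pose_index = poses$pose_index,
             interface_delta = poses$interface_delta,
             lid_root2 = lidRoot2(poses$interface_delta, heavy),
             rmsd_to_best = rmsd)
}
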