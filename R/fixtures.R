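# fixtures: synthetic-data generators that make every stage testable
# offline — toy combinatorial libraries in the loader's TSV dialect,
# planted-optimum scoring landscapes, and toy receptor/pose systems with
# known ground truth.
#
# Substrate pools are curated, reliably-reactive templates (carboxylic
# acids, primary amines, sulfonyl chlorides, 1,2-diamines) so that test
# signal isolates engine behavior from chemistry edge cases.

.aromDecor <- c("C", "CC", "F", "Cl", "Br", "I", "OC", "C(C)C", "CO",
                "C(F)(F)F", "CCC", "CCCC", "OCC", "C(C)(C)C", "SC")

.acidPool <- function() {
  arom <- c(sprintf("OC(=O)c1ccc(%s)cc1", .aromDecor),
            sprintf("OC(=O)c1cccc(%s)c1", .aromDecor))
  alip <- c("CC(=O)O", "CCC(=O)O", "CCCC(=O)O", "CC(C)C(=O)O",
            "CC(C)(C)C(=O)O", "OC(=O)C1CC1", "OC(=O)C1CCC1",
            "OC(=O)C1CCCC1", "OC(=O)CC1CC1", "CCCCC(=O)O")
  list(aromatic = arom, aliphatic = alip)
}

.aminePool <- function() {
  arom <- c(sprintf("NCc1ccc(%s)cc1", .aromDecor),
            sprintf("NCc1cccc(%s)c1", .aromDecor))
  alip <- c("CN", "CCN", "CCCN", "CCCCN", "CC(C)N", "CC(C)CN",
            "NC1CC1", "NC1CCC1", "NC1CCCC1", "NC1CCCCC1", "NCC1CC1",
            "CC(C)(C)N")
  list(aromatic = arom, aliphatic = alip)
}

.sulfonylPool <- function() {
  list(aromatic = c("O=S(=O)(Cl)c1ccccc1", "O=S(=O)(Cl)c1ccc(C)cc1",
                    "O=S(=O)(Cl)c1ccc(F)cc1", "O=S(=O)(Cl)c1ccc(Cl)cc1"),
       aliphatic = c("CS(=O)(=O)Cl", "CCS(=O)(=O)Cl", "CCCS(=O)(=O)Cl",
                     "O=S(=O)(Cl)C1CC1"))
}

.diaminePool <- function() {
  list(aromatic = character(0),
       aliphatic = c("NCCN", "CC(N)CN", "NCC(C)N", "CC(N)C(C)N",
                     "NCC(CC)N", "CC(C)(N)CN"))
}

.TOY_REACTIONS <- list(
  amide = list(
    smarts = "[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]",
    arity = 2L, pools = c("acid", "amine")),
  sulfonamide = list(
    smarts = "[S:1](=O)(=O)Cl.[NX3;H2:2]>>[S:1](=O)(=O)[N:2]",
    arity = 2L, pools = c("sulfonyl", "amine")),
  diamide = list(
    smarts = paste0("[C:1](=O)[OH].[NX3;H2:2][CX4:3][CX4:4][NX3;H2:5].",
                    "[C:6](=O)[OH]>>",
                    "[C:1](=O)[N:2][C:3][C:4][N:5][C:6]=O"),
    arity = 3L, pools = c("acid", "diamine", "acid"))
)

.poolFor <- function(name, family) {
  pool <- switch(name, acid = .acidPool(), amine = .aminePool(),
                 sulfonyl = .sulfonylPool(), diamine = .diaminePool())
  out <- switch(family,
                mixed = as.vector(rbind(
                  c(pool$aromatic, rep(NA, max(0, length(pool$aliphatic) -
                                                 length(pool$aromatic)))),
                  c(pool$aliphatic, rep(NA, max(0, length(pool$aromatic) -
                                                  length(pool$aliphatic)))))),
                aromatic = pool$aromatic,
                aliphatic = pool$aliphatic)
  out[!is.na(out)]
}

#' Generate a toy combinatorial library on disk
#'
#' Writes building-rules and building-blocks TSV files in the
#' [loadLibrary()] dialect, emulating the shape of a make-on-demand
#' library specification at desk scale.  Reactions come from a curated set
#' (`"amide"`, `"sulfonamide"`, two components; `"diamide"`, three
#' components); substrates are drawn from reliably-reactive pools.  Files
#' are byte-identical under the same arguments and seed.
#'
#' @param dir output directory (created if needed).
#' @param slotSizes named list: reaction type -> integer vector of slot
#'   sizes (one per position), e.g. `list(amide = c(3, 4))`.  Repeat a
#'   type under names like `amide2` for several instances.
#' @param family substrate family: `"mixed"` (default), `"aromatic"` or
#'   `"aliphatic"` — the two pure families give structurally separable
#'   products for clustering tests.
#' @param seed RNG seed for the (deterministic) pool shuffling.
#' @param invalidSubstrate also emit one unparsable substrate row
#'   (exercises load-time validation).
#' @return list with `rulesPath`, `blocksPath`.
#' @export
makeToyLibrary <- function(dir, slotSizes = list(amide = c(3L, 4L)),
                           family = c("mixed", "aromatic", "aliphatic"),
                           seed = 1L, invalidSubstrate = FALSE) {
  family <- match.arg(family)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  total <- sum(vapply(slotSizes, prod, numeric(1)))
  if (total > 1e5)
    stop("toy library would enumerate to ", total,
         " products; keep it below 1e5")
  rules <- list(); blocks <- list(); subSeen <- list()
  subId <- function(type, smiles) {
    key <- paste0(type, "|", smiles)
    id <- subSeen[[key]]
    if (is.null(id)) {
      id <- sprintf("%s_%02d", type,
                    sum(startsWith(names(subSeen) %||% character(0),
                                   paste0(type, "|"))) + 1L)
      subSeen[[key]] <<- id
      blocks[[length(blocks) + 1L]] <<-
        data.frame(substrate_id = id, smiles = smiles,
                   reaction_id = NA_character_, position = NA_integer_,
                   stringsAsFactors = FALSE)
    }
    id
  }
  usage <- list()
  for (i in seq_along(slotSizes)) {
    nm <- names(slotSizes)[i]
    type <- sub("[0-9]+$", "", nm)
    rxn <- .TOY_REACTIONS[[type]]
    if (is.null(rxn)) stop("unknown toy reaction type: ", nm)
    sizes <- as.integer(slotSizes[[i]])
    if (length(sizes) != rxn$arity)
      stop(nm, " needs ", rxn$arity, " slot sizes")
    rid <- paste0("r_", nm)
    rules[[length(rules) + 1L]] <- data.frame(
      reaction_id = rid, smarts = rxn$smarts, arity = rxn$arity,
      stringsAsFactors = FALSE)
    for (p in seq_len(rxn$arity)) {
      pool <- .poolFor(rxn$pools[p], family)
      if (sizes[p] > length(pool))
        stop("slot size ", sizes[p], " exceeds the ", rxn$pools[p],
             " pool (", length(pool), ") for family ", family)
      picked <- .withSeed(.stringSeed(seed, rid, p),
                          pool[sample.int(length(pool), sizes[p])])
      for (s in picked) {
        usage[[length(usage) + 1L]] <- data.frame(
          substrate_id = subId(rxn$pools[p], s), smiles = s,
          reaction_id = rid, position = p - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  usageDf <- do.call(rbind, usage)
  stopifnot(!anyNA(canonicalSmiles(unique(usageDf$smiles))))
  if (invalidSubstrate) {
    usageDf <- rbind(usageDf, data.frame(
      substrate_id = "broken_01", smiles = "C1CC",
      reaction_id = usageDf$reaction_id[1], position = 0L,
      stringsAsFactors = FALSE))
  }
  rulesDf <- do.call(rbind, rules)
  rulesPath <- file.path(dir, "building_rules.tsv")
  blocksPath <- file.path(dir, "building_blocks.tsv")
  .writeTsv(rulesDf, rulesPath,
            "# toy building rules (reaction SMARTS, tab-separated)")
  .writeTsv(usageDf, blocksPath,
            "# toy building blocks (one row per allowed usage)")
  list(rulesPath = rulesPath, blocksPath = blocksPath)
}

.writeTsv <- function(df, path, comment) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(vapply(df[i, ], as.character, character(1)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Plant a similarity landscape on a library
#'
#' Picks a motif molecule from the library (seeded random, or a given
#' address), builds the matching [syntheticOracle()], and records the full
#' brute-force ranking of the enumerated library under the noiseless
#' landscape formula — computed here by direct enumeration, independently
#' of the oracle object, so searches can be validated against it.
#'
#' @param library an enumerable [CombinatorialLibrary-class].
#' @param seed RNG seed (motif choice).
#' @param simWeight,sizeWeight,noise,nPoses oracle parameters (see
#'   [syntheticOracle()]).
#' @param motifKey optional library address key `"rid|s1+s2"` to use as
#'   motif instead of a random pick.
#' @return list with `motif` ([LibraryMolecule-class]), `oracle`
#'   ([SyntheticOracle-class]), and `ranking` (data.frame: key,
#'   product_smiles, heavy_atoms, score, rank — best first).
#' @export
makePlantedLandscape <- function(library, seed = 1L, simWeight = 8,
                                 sizeWeight = 0.4, noise = 0,
                                 nPoses = 20L, motifKey = NULL) {
  enum <- enumerateProducts(library)
  motifRow <- if (is.null(motifKey)) {
    .withSeed(.stringSeed(seed, "motif"),
              enum[sample.int(nrow(enum), 1L), , drop = FALSE])
  } else {
    hit <- enum[enum$key == motifKey, , drop = FALSE]
    if (nrow(hit) == 0L) stop("motifKey not in library: ", motifKey)
    hit
  }
  motif <- methods::new("LibraryMolecule",
                        reactionId = motifRow$reaction_id,
                        substrateIds = strsplit(motifRow$substrate_ids,
                                                "+", fixed = TRUE)[[1]],
                        productSmiles = motifRow$product_smiles)
  oracle <- syntheticOracle(motif@productSmiles, simWeight = simWeight,
                            sizeWeight = sizeWeight, noise = noise,
                            nPoses = nPoses, seed = seed)
  # brute-force ranking by the landscape formula, via direct enumeration
  fps <- fingerprintMolecules(enum$product_smiles)
  motifFp <- drop(fingerprintMolecules(motif@productSmiles))
  sims <- vapply(seq_len(nrow(fps)),
                 function(i) tanimoto(fps[i, ], motifFp), numeric(1))
  heavy <- vapply(enum$product_smiles,
                  function(s) .graphCounts(canonicalSmiles(s))$heavy_atoms,
                  integer(1))
  score <- -simWeight * sims - sizeWeight * sqrt(heavy)
  ord <- order(score, enum$key)
  ranking <- data.frame(key = enum$key[ord],
                        product_smiles = enum$product_smiles[ord],
                        heavy_atoms = heavy[ord], score = score[ord],
                        rank = seq_along(ord), stringsAsFactors = FALSE)
  list(motif = motif, oracle = oracle, ranking = ranking)
}

# ---- toy receptor / pose systems -----------------------------------------

.writePdb <- function(residues, path) {
  con <- file(path, "w")
  on.exit(close(con))
  serial <- 0L
  atomNames <- c("CA", "CB", "CG")
  for (r in seq_len(nrow(residues))) {
    xyz <- residues$coords[[r]]
    for (a in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      writeLines(sprintf(
        "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial, atomNames[(a - 1L) %% 3L + 1L], residues$resid[r],
        residues$chain[r], residues$resno[r],
        xyz[a, 1], xyz[a, 2], xyz[a, 3], 1.00, 0.00, "C"), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

.writePoseSdf <- function(poses, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(poses))) {
    xyz <- poses$coords[[i]]
    writeLines(c(poses$molecule_key[i], "  evoscreen", ""), con)
    nb <- max(0L, nrow(xyz) - 1L)           # chain bonds keep readers happy
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(xyz), nb), con)
    for (a in seq_len(nrow(xyz)))
      writeLines(sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        xyz[a, 1], xyz[a, 2], xyz[a, 3], "C"), con)
    for (a in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", a, a + 1L, 1L), con)
    writeLines("M  END", con)
    writeLines(c(">  <molecule_key>", poses$molecule_key[i], "",
                 ">  <pose_index>", as.character(poses$pose_index[i]), "",
                 ">  <interface_delta>",
                 sprintf("%.4f", poses$interface_delta[i]), "",
                 "$$$$"), con)
  }
  invisible(path)
}

#' Generate a toy receptor and docked-pose system with known ground truth
#'
#' Builds a small PDB receptor (three heavy atoms per residue, residues
#' spaced well apart), a best-pose SDF for `nCompounds` compounds with a
#' planted residue-contact plan, a multi-pose SDF for one compound with
#' `"funnel"` (coordinate jitter growing as scores worsen) or `"scatter"`
#' (score-independent jitter) geometry, and a ground-truth contact-count
#' CSV.  Everything is reproducible bit-for-bit under the seed.
#'
#' @param dir output directory.
#' @param nResidues,nCompounds system size.
#' @param geometry `"funnel"` or `"scatter"` for the multi-pose set.
#' @param nPoses poses in the multi-pose set (default 30).
#' @param seed RNG seed.
#' @param contactDensity probability a compound touches a residue
#'   (default 0.3).
#' @return list with `receptorPath`, `posesPath`, `funnelPath`,
#'   `truthPath`, `contactPlan` (logical matrix), `truth` (data.frame).
#' @export
makeToyReceptorAndPoses <- function(dir, nResidues = 8L, nCompounds = 10L,
                                    geometry = c("funnel", "scatter"),
                                    nPoses = 30L, seed = 1L,
                                    contactDensity = 0.3) {
  geometry <- match.arg(geometry)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spacing <- 24
  residues <- data.frame(chain = "A", resno = seq_len(nResidues),
                         resid = "ALA", stringsAsFactors = FALSE)
  residues$coords <- lapply(seq_len(nResidues), function(r)
    rbind(c(spacing * r, 0, 0), c(spacing * r + 1.4, 0.4, 0),
          c(spacing * r, 1.4, 0.6)))
  receptorPath <- file.path(dir, "receptor.pdb")
  .writePdb(residues, receptorPath)

  plan <- .withSeed(.stringSeed(seed, "plan"), {
    m <- matrix(stats::runif(nCompounds * nResidues) < contactDensity,
                nrow = nCompounds)
    m[, 1] <- TRUE    # keep the map non-degenerate
    m
  })
  atomsPer <- max(4L, max(rowSums(plan)) + 1L)
  poseRows <- lapply(seq_len(nCompounds), function(j) {
    touch <- which(plan[j, ])
    xyz <- matrix(NA_real_, nrow = atomsPer, ncol = 3L)
    k <- 0L
    for (r in touch) {
      k <- k + 1L
      xyz[k, ] <- c(spacing * r, 0, 3.0)      # 3 A from residue atom 1
    }
    far <- .withSeed(.stringSeed(seed, "far", j),
                     matrix(stats::runif((atomsPer - k) * 3L, 400, 500),
                            ncol = 3L))
    xyz[(k + 1L):atomsPer, ] <- far
    list(molecule_key = sprintf("cmpd_%02d", j), pose_index = 1L,
         interface_delta = -12 - j * 0.1, coords = xyz)
  })
  poses <- data.frame(
    molecule_key = vapply(poseRows, `[[`, character(1), "molecule_key"),
    pose_index = vapply(poseRows, `[[`, integer(1), "pose_index"),
    interface_delta = vapply(poseRows, `[[`, numeric(1),
                             "interface_delta"),
    stringsAsFactors = FALSE)
  poses$coords <- lapply(poseRows, `[[`, "coords")
  posesPath <- file.path(dir, "poses.sdf")
  .writePoseSdf(poses, posesPath)

  # multi-pose set for RMSD-score funnel analysis
  base <- .motifLayout(8L, 0L)
  scores <- seq(-15, -8, length.out = nPoses)
  funnelRows <- lapply(seq_len(nPoses), function(i) {
    scale <- if (geometry == "funnel") 0.02 + 0.25 * (i - 1L) else 1.5
    jit <- .withSeed(.stringSeed(seed, geometry, i),
                     matrix(stats::rnorm(length(base), 0, scale),
                            ncol = 3L))
    list(molecule_key = "funnel_mol", pose_index = i,
         interface_delta = scores[i], coords = base + jit)
  })
  funnel <- data.frame(
    molecule_key = "funnel_mol",
    pose_index = vapply(funnelRows, `[[`, integer(1), "pose_index"),
    interface_delta = vapply(funnelRows, `[[`, numeric(1),
                             "interface_delta"),
    stringsAsFactors = FALSE)
  funnel$coords <- lapply(funnelRows, `[[`, "coords")
  funnelPath <- file.path(dir, "funnel_poses.sdf")
  .writePoseSdf(funnel, funnelPath)

  truth <- data.frame(resno = seq_len(nResidues), count = colSums(plan))
  truthPath <- file.path(dir, "contact_truth.csv")
  utils::write.csv(truth, truthPath, row.names = FALSE)
  list(receptorPath = receptorPath, posesPath = posesPath,
       funnelPath = funnelPath, truthPath = truthPath,
       contactPlan = plan, truth = truth)
}
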