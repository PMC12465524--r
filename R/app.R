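# app: end-to-end pipeline composition mirroring the two campaign rounds,
# with a manifest that records every stage's input/output counts, plus the
# campaign-statistics report helpers.

#' Pipeline configuration
#'
#' Houses the campaign constants in one place: the evolutionary settings,
#' the first-filter bounds, the lid_root2 cutoff (-3.5), the redock
#' consistency threshold (0.8), the ensemble consensus band (0.5), the
#' redock budget, clustering k and the purchase budget.  All randomness
#' derives from the single `seed`.
#'
#' @param rulesPath,blocksPath library file paths.
#' @param oracle a [DockingOracle-class].
#' @param round campaign round (1 or 2; selects the HBA hard bound).
#' @param receptors character vector of receptor ids to run against.
#' @param offTargetReceptor optional anti-target receptor id; when set, an
#'   off-target counter screen (exclude-better at `scoreThreshold`) runs
#'   after redocking.
#' @param nRuns independent evolutionary runs (default 2).
#' @param evolution an [evolutionConfig()]; its seed is re-derived per run
#'   from `seed`.
#' @param filter a [filterConfig()]; defaults to `filterConfig(round)`.
#' @param scoreThreshold lid_root2 cutoff (default -3.5).
#' @param consistencyMax redock consistency threshold (default 0.8).
#' @param consensusStdMax ensemble consensus band (default 0.5).
#' @param redockTop how many top compounds to redock (default 50).
#' @param redockPoses poses per redock (default 600).
#' @param clusterK diversity clusters (default 100, reduced to the
#'   candidate count when larger).
#' @param nTarget purchase budget after pruning (default 150).
#' @param seed global seed.
#' @param outDir output directory for reports and the manifest.
#' @return config list for [runScreen()] / [runExpand()].
#' @export
pipelineConfig <- function(rulesPath, blocksPath, oracle, round = 1L,
                           receptors = "receptor",
                           offTargetReceptor = NULL, nRuns = 2L,
                           evolution = evolutionConfig(),
                           filter = NULL, scoreThreshold = -3.5,
                           consistencyMax = 0.8, consensusStdMax = 0.5,
                           redockTop = 50L, redockPoses = 600L,
                           clusterK = 100L, nTarget = 150L, seed = 1L,
                           outDir = tempfile("evoscreen_run")) {
  list(rulesPath = rulesPath, blocksPath = blocksPath, oracle = oracle,
       round = as.integer(round), receptors = receptors,
       offTargetReceptor = offTargetReceptor, nRuns = as.integer(nRuns),
       evolution = evolution,
       filter = if (is.null(filter)) filterConfig(round) else filter,
       scoreThreshold = scoreThreshold, consistencyMax = consistencyMax,
       consensusStdMax = consensusStdMax,
       redockTop = as.integer(redockTop),
       redockPoses = as.integer(redockPoses),
       clusterK = as.integer(clusterK), nTarget = as.integer(nTarget),
       seed = as.integer(seed), outDir = outDir)
}

.stageRecord <- function(manifest, stage, nIn, nOut, detail = NULL) {
  manifest$stages[[length(manifest$stages) + 1L]] <-
    c(list(stage = stage, n_in = nIn, n_out = nOut),
      if (!is.null(detail)) list(detail = detail))
  manifest
}

.redockOracle <- function(config) {
  o <- config$oracle
  if (methods::is(o, "SyntheticOracle"))
    syntheticOracle(o@motif, simWeight = o@simWeight,
                    sizeWeight = o@sizeWeight, noise = o@noise,
                    nPoses = config$redockPoses,
                    seed = o@seed + 1L, withCoords = o@withCoords)
  else o
}

#' Run the full screening pipeline
#'
#' Composes the campaign stages in their fixed order: independent
#' evolutionary runs, aggregation, first-stage property/traffic-light/PAINS
#' filter, top-N selection, redocking, lid_root2 cutoff, redock consistency
#' filter, optional ensemble consensus (several receptors), optional
#' off-target counter screen, diversity clustering, and budget pruning.
#' Every stage appends its input/output counts to a JSON manifest; with the
#' synthetic oracle at zero noise the run is deterministic under `seed`.
#'
#' @param config a [pipelineConfig()].
#' @return list with `manifest`, `selection` (final scored data.frame),
#'   `candidates`, `clusters`, `runLogs`, `library`; the manifest is also
#'   written to `<outDir>/manifest.json` and the selection to
#'   `<outDir>/selection.csv`.
#' @export
runScreen <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), seed = config$seed,
                   round = config$round)
  lib <- loadLibrary(config$rulesPath, config$blocksPath)
  manifest$library_size <- librarySize(lib)

  # stage: evolutionary runs (one per run id x lead receptor)
  runLogs <- list()
  for (r in seq_len(config$nRuns)) {
    ev <- config$evolution
    ev$seed <- .stringSeed(config$seed, "evolve", r)
    runLogs[[r]] <- runEvolution(lib, config$oracle, ev,
                                 receptorId = config$receptors[1],
                                 runId = sprintf("run%02d", r))
  }
  merged <- aggregateRuns(runLogs)
  manifest <- .stageRecord(manifest, "evolve",
                           nIn = manifest$library_size,
                           nOut = nrow(merged),
                           detail = list(runs = config$nRuns))

  # stage: first filter (hard properties + traffic lights + PAINS)
  ff <- firstFilter(merged$product_smiles, config$filter)
  surv <- merged[ff$audit$stage == "pass", , drop = FALSE]
  manifest <- .stageRecord(manifest, "first_filter", nrow(merged),
                           nrow(surv),
                           detail = as.list(table(ff$audit$stage)))

  # stage: top-N by lid_root2 for redocking
  surv <- surv[order(surv$lid_root2, surv$key), , drop = FALSE]
  top <- utils::head(surv, config$redockTop)
  manifest <- .stageRecord(manifest, "redock_selection", nrow(surv),
                           nrow(top))

  # stage: redock + score threshold + consistency
  redocker <- .redockOracle(config)
  kept <- list()
  for (i in seq_len(nrow(top))) {
    perModel <- numeric(0)
    for (rec in config$receptors) {
      res <- dock(redocker, top$product_smiles[i], rec)
      heavy <- top$heavy_atoms[i]
      scores <- lidRoot2(res@poses$interface_delta, heavy)
      perModel[rec] <- scores[1]
      if (rec == config$receptors[1]) {
        cons <- redockConsistencyFilter(top$lid_root2[i],
                                        utils::head(scores, 10L),
                                        config$consistencyMax)
        lead <- scores[1]
      }
    }
    consensus <- if (length(config$receptors) >= 2L)
      ensembleConsensusFilter(perModel, config$consensusStdMax)
    else list(consensus = lead, std = 0, keep = TRUE)
    row <- top[i, , drop = FALSE]
    row$redock_lid_root2 <- lead
    row$consensus <- consensus$consensus
    row$consensus_std <- consensus$std
    row$consistency_pass <- cons$pass
    row$consensus_pass <- consensus$keep
    kept[[i]] <- row
  }
  redocked <- do.call(rbind, kept)
  manifest <- .stageRecord(manifest, "redock", nrow(top), nrow(redocked))

  scored <- redocked
  scored$lid_root2 <- scored$redock_lid_root2
  afterCut <- scoreThresholdFilter(scored, config$scoreThreshold,
                                   "keep_better")
  manifest <- .stageRecord(manifest, "score_threshold", nrow(scored),
                           nrow(afterCut))
  afterCons <- afterCut[afterCut$consistency_pass, , drop = FALSE]
  manifest <- .stageRecord(manifest, "redock_consistency", nrow(afterCut),
                           nrow(afterCons))
  if (length(config$receptors) >= 2L) {
    afterCons2 <- afterCons[afterCons$consensus_pass, , drop = FALSE]
    manifest <- .stageRecord(manifest, "ensemble_consensus",
                             nrow(afterCons), nrow(afterCons2))
    afterCons <- afterCons2
  }

  # stage: off-target counter screen
  if (!is.null(config$offTargetReceptor) && nrow(afterCons) > 0L) {
    ot <- vapply(seq_len(nrow(afterCons)), function(i) {
      res <- dock(redocker, afterCons$product_smiles[i],
                  config$offTargetReceptor)
      lidRoot2(res@poses$interface_delta[1], afterCons$heavy_atoms[i])
    }, numeric(1))
    keepOt <- !(ot <= config$scoreThreshold)   # exclude predicted binders
    manifest <- .stageRecord(manifest, "offtarget", nrow(afterCons),
                             sum(keepOt))
    afterCons <- afterCons[keepOt, , drop = FALSE]
  }

  # stage: clustering + budget pruning
  candidates <- afterCons
  rownames(candidates) <- NULL
  clusters <- NULL
  selection <- candidates
  if (nrow(candidates) > 0L) {
    k <- min(config$clusterK, nrow(candidates))
    clusters <- clusterCompounds(candidates$product_smiles, k = k,
                                 scores = candidates$lid_root2,
                                 seed = .stringSeed(config$seed, "cluster"))
    manifest <- .stageRecord(manifest, "cluster", nrow(candidates),
                             clusters$k)
    if (nrow(candidates) > config$nTarget) {
      pr <- similarityBudgetPrune(
        data.frame(key = candidates$product_smiles,
                   lid_root2 = candidates$lid_root2,
                   stringsAsFactors = FALSE),
        config$nTarget)
      selection <- candidates[candidates$product_smiles %in%
                                pr$kept$key, , drop = FALSE]
      manifest <- .stageRecord(manifest, "budget_prune", nrow(candidates),
                               nrow(selection))
    }
  }
  rownames(selection) <- NULL
  utils::write.csv(selection, file.path(config$outDir, "selection.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, selection = selection,
       candidates = candidates, clusters = clusters, runLogs = runLogs,
       library = lib)
}

#' Run the hit-expansion pipeline
#'
#' Mirrors the second-round flow: partner enumeration of the hit, docking
#' of the expansion, lid_root2 cutoff, then seeded evolutionary runs whose
#' initial populations draw from the surviving pool, followed by the
#' standard cascade of [runScreen()].
#'
#' @param config a [pipelineConfig()] (set `round = 2L` and several
#'   `receptors` for the full round-2 behavior).
#' @param hit a [LibraryMolecule-class] belonging to the library.
#' @return as [runScreen()], plus `expansion` (scored expansion table)
#'   and `seededPool`.
#' @export
runExpand <- function(config, hit) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  lib <- loadLibrary(config$rulesPath, config$blocksPath)
  expansion <- expandPartners(lib, hit)
  results <- lapply(expansion, function(m)
    dock(config$oracle, m, config$receptors[1]))
  expScored <- scoredMolecules(results, provenance = "expand")
  expScored$molecule <- expansion
  kept <- scoreThresholdFilter(expScored, config$scoreThreshold,
                               "keep_better")
  pool <- kept$molecule
  config$evolution$seededPool <- pool
  out <- runScreen(config)
  out$manifest$stages <- c(
    list(list(stage = "expand", n_in = 1L,
              n_out = length(expansion)),
         list(stage = "expand_score_filter", n_in = length(expansion),
              n_out = length(pool))),
    out$manifest$stages)
  jsonlite::write_json(out$manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$expansion <- expScored[, setdiff(names(expScored), "molecule")]
  out$seededPool <- pool
  out
}

# ---- campaign report statistics ------------------------------------------

#' Campaign hit rate
#'
#' @param hits confirmed hits.
#' @param tested compounds tested.
#' @param digits decimals in the percentage (default 2).
#' @return percentage, rounded.
#' @examples
#' hitRate(3, 138)   # 2.17
#' @export
hitRate <- function(hits, tested, digits = 2L) {
  stopifnot(tested > 0L, hits >= 0L)
  round(100 * hits / tested, digits)
}

#' Sampled fraction of a chemical space
#'
#' @param sampled distinct molecules evaluated.
#' @param librarySize enumerable size of the space.
#' @param sigDigits significant digits of the percentage (default 2).
#' @return percentage (tiny for ultra-large spaces), at `sigDigits`
#'   significant digits.
#' @examples
#' sampledFraction(358713, 19548368812)   # 0.0018
#' @export
sampledFraction <- function(sampled, librarySize, sigDigits = 2L) {
  stopifnot(librarySize > 0)
  signif(100 * sampled / librarySize, sigDigits)
}

#' Stage pass rate
#'
#' @param passed,total counts.
#' @return whole-number percentage.
#' @examples
#' passRate(628, 757)   # 83
#' @export
passRate <- function(passed, total) {
  stopifnot(total > 0L)
  round(100 * passed / total)
}

#' Summarize a screening run directory
#'
#' Reads the manifest written by [runScreen()] and emits the campaign
#' statistics: per-stage pass rates, the sampled fraction of the library,
#' and (when hit counts are supplied) the hit rate.
#'
#' @param runDir directory holding `manifest.json`.
#' @param hits,tested optional experimental outcome counts.
#' @return list with `stages` (data.frame: stage, n_in, n_out,
#'   pass_rate_pct), `sampled_fraction_pct`, and optionally
#'   `hit_rate_pct`.
#' @export
reportScreen <- function(runDir, hits = NULL, tested = NULL) {
  path <- file.path(runDir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json under ", runDir)
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  stages <- do.call(rbind, lapply(manifest$stages, function(s)
    data.frame(stage = s$stage, n_in = as.numeric(s$n_in),
               n_out = as.numeric(s$n_out),
               pass_rate_pct = passRate(as.numeric(s$n_out),
                                        max(1, as.numeric(s$n_in))),
               stringsAsFactors = FALSE)))
  evolveStage <- stages[stages$stage == "evolve", , drop = FALSE]
  sampled <- if (nrow(evolveStage))
    sampledFraction(evolveStage$n_out[1],
                    as.numeric(manifest$library_size)) else NA_real_
  out <- list(stages = stages, sampled_fraction_pct = sampled)
  if (!is.null(hits) && !is.null(tested))
    out$hit_rate_pct <- hitRate(hits, tested)
  out
}
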