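# evolve: the evolutionary search over library addresses.
#
# Populations are data.frames (one row per individual) holding the library
# address, the assembled product, the lid_root2 fitness and provenance
# (operator, parents, generation born).  The engine never re-docks a
# genotype it has already scored: results are cached by canonical product
# SMILES + receptor, while the run log still records every evaluated
# molecule including discarded ones.

#' Evolution run configuration
#'
#' Defaults mirror the published campaign protocol: 200 random seed
#' molecules reduced to 50 survivors by rank-based selection, 30 iterative
#' cycles growing the population by several hundred offspring per cycle.
#' Operator mixture weights, elitism and the seeded-start sizes are
#' exposed; the mixture must sum to 1.
#'
#' @param seedSize initial random population (default 200).
#' @param survivors population size after selection (default 50).
#' @param generations number of cycles (default 30).
#' @param offspringPerGeneration children per cycle (default 300).
#' @param pMutSubstrate,pMutReaction,pCrossover,pImmigrant operator mixture
#'   weights (defaults 0.45 / 0.10 / 0.35 / 0.10).
#' @param elitismCount best-by-fitness kept deterministically (default 5).
#' @param seededPool optional list of [LibraryMolecule-class] used instead
#'   of a random start.
#' @param seededPick draws without replacement from the pool (default 200).
#' @param seededRandomExtra random molecules added to a seeded start
#'   (default 50).
#' @param seed RNG seed for the run.
#' @return config list consumed by [runEvolution()].
#' @export
evolutionConfig <- function(seedSize = 200L, survivors = 50L,
                            generations = 30L,
                            offspringPerGeneration = 300L,
                            pMutSubstrate = 0.45, pMutReaction = 0.10,
                            pCrossover = 0.35, pImmigrant = 0.10,
                            elitismCount = 5L,
                            seededPool = NULL, seededPick = 200L,
                            seededRandomExtra = 50L, seed = 1L) {
  w <- c(pMutSubstrate, pMutReaction, pCrossover, pImmigrant)
  if (abs(sum(w) - 1) > 1e-9) stop("operator mixture weights must sum to 1")
  if (survivors > seedSize) stop("survivors must not exceed seedSize")
  if (generations < 1L) stop("generations must be >= 1")
  list(seedSize = as.integer(seedSize), survivors = as.integer(survivors),
       generations = as.integer(generations),
       offspringPerGeneration = as.integer(offspringPerGeneration),
       weights = stats::setNames(w, c("mutation_substrate",
                                      "mutation_reaction", "crossover",
                                      "immigrant")),
       elitismCount = as.integer(elitismCount),
       seededPool = seededPool, seededPick = as.integer(seededPick),
       seededRandomExtra = as.integer(seededRandomExtra),
       seed = as.integer(seed))
}

.popRow <- function(mol, fitness = NA_real_, interfaceDelta = NA_real_,
                    heavy = NA_integer_, generation = 0L,
                    operator = "seed", parents = "") {
  data.frame(key = moleculeKey(mol), reaction_id = mol@reactionId,
             substrate_ids = paste(mol@substrateIds, collapse = "+"),
             product_smiles = mol@productSmiles, fitness = fitness,
             interface_delta = interfaceDelta, heavy_atoms = heavy,
             generation_born = generation, operator = operator,
             parent_keys = parents, stringsAsFactors = FALSE)
}

.rowMolecule <- function(row) {
  methods::new("LibraryMolecule", reactionId = row$reaction_id,
               substrateIds = strsplit(row$substrate_ids, "+",
                                       fixed = TRUE)[[1]],
               productSmiles = row$product_smiles)
}

# evaluate rows lacking fitness through the oracle (cache-aware via a
# ledger environment); returns list(pop, ledger stats)
.evaluate <- function(pop, oracle, receptorId, ledger) {
  todo <- which(is.na(pop$fitness))
  for (i in todo) {
    key <- canonicalSmiles(pop$product_smiles[i])
    cached <- ledger$scores[[key]]
    if (is.null(cached)) {
      res <- dock(oracle, pop$product_smiles[i], receptorId)
      heavy <- .graphCounts(res@moleculeKey)$heavy_atoms
      cached <- list(fitness = lidRoot2(res@poses$interface_delta[1], heavy),
                     interface = res@poses$interface_delta[1],
                     heavy = heavy)
      ledger$scores[[key]] <- cached
      ledger$calls <- ledger$calls + 1L
    } else {
      ledger$hits <- ledger$hits + 1L
    }
    pop$fitness[i] <- cached$fitness
    pop$interface_delta[i] <- cached$interface
    pop$heavy_atoms[i] <- cached$heavy
  }
  pop
}

#' Initial population for an evolutionary run
#'
#' Random mode draws `seedSize` random molecules.  Seeded mode (when
#' `config$seededPool` is set) draws `seededPick` pool members without
#' replacement — or the whole pool when it is smaller — and adds
#' `seededRandomExtra` random molecules from the full library, mirroring a
#' hit-expansion restart.  All individuals are evaluated through the
#' oracle.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param config an [evolutionConfig()].
#' @param oracle a [DockingOracle-class].
#' @param receptorId receptor to dock against.
#' @return evaluated population data.frame.
#' @export
initPopulation <- function(library, config, oracle,
                           receptorId = "receptor") {
  ledger <- new.env(parent = emptyenv())
  ledger$scores <- list(); ledger$calls <- 0L; ledger$hits <- 0L
  .withSeed(config$seed, .initPopulation(library, config, oracle,
                                         receptorId, ledger))
}

.initPopulation <- function(library, config, oracle, receptorId, ledger) {
  pool <- config$seededPool
  mols <- if (is.null(pool)) {
    sampleRandomMolecule(library, config$seedSize)
  } else {
    if (length(pool) == 0L) stop("seededPool is empty")
    take <- min(config$seededPick, length(pool))
    picked <- pool[sample.int(length(pool), take)]
    extra <- if (config$seededRandomExtra > 0L)
      sampleRandomMolecule(library, config$seededRandomExtra) else list()
    c(picked, extra)
  }
  pop <- do.call(rbind, lapply(mols, .popRow))
  pop <- pop[!duplicated(pop$key), , drop = FALSE]
  rownames(pop) <- NULL
  .evaluate(pop, oracle, receptorId, ledger)
}

#' Mutate a library molecule
#'
#' Substrate mutation picks one slot uniformly and replaces its substrate
#' with a different allowed one.  Reaction mutation moves the individual to
#' a different reaction chosen uniformly; each slot keeps its substrate
#' when the new reaction allows it there and is resampled uniformly
#' otherwise.  When no alternative exists (singleton library) the parent is
#' returned flagged unchanged.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param molecule parent [LibraryMolecule-class].
#' @param kind `"substrate"` or `"reaction"`.
#' @return list with `molecule` (unevaluated child), `operator`,
#'   `changed`.
#' @export
mutateMolecule <- function(library, molecule,
                           kind = c("substrate", "reaction")) {
  kind <- match.arg(kind)
  rid <- molecule@reactionId
  subIds <- molecule@substrateIds
  if (kind == "substrate") {
    arity <- length(subIds)
    slots <- sample.int(arity, arity)        # try slots in random order
    for (p in slots) {
      alt <- setdiff(library@slots[[.slotKey(rid, p - 1L)]], subIds[p])
      if (length(alt)) {
        subIds[p] <- if (length(alt) == 1L) alt
                     else alt[sample.int(length(alt), 1L)]
        child <- assembleProduct(library, rid, subIds)
        return(list(molecule = child, operator = "mutation_substrate",
                    changed = TRUE))
      }
    }
    return(list(molecule = molecule, operator = "mutation_substrate",
                changed = FALSE))
  }
  rxs <- library@reactions[library@reactions$usable &
                           library@reactions$reaction_id != rid, ,
                           drop = FALSE]
  if (nrow(rxs) == 0L)
    return(list(molecule = molecule, operator = "mutation_reaction",
                changed = FALSE))
  j <- if (nrow(rxs) == 1L) 1L else sample.int(nrow(rxs), 1L)
  newRid <- rxs$reaction_id[j]
  newArity <- rxs$arity[j]
  newSubs <- character(newArity)
  for (p in seq_len(newArity)) {
    allowed <- library@slots[[.slotKey(newRid, p - 1L)]]
    keepOld <- p <= length(subIds) && subIds[p] %in% allowed
    newSubs[p] <- if (keepOld) subIds[p]
                  else if (length(allowed) == 1L) allowed
                  else allowed[sample.int(length(allowed), 1L)]
  }
  child <- assembleProduct(library, newRid, newSubs)
  list(molecule = child, operator = "mutation_reaction", changed = TRUE)
}

#' Recombine two library molecules
#'
#' Parents sharing a reaction swap the substrate of one uniformly chosen
#' slot, yielding the two recombinants.  Parents on different reactions
#' cannot exchange substrates meaningfully, so each undergoes a substrate
#' mutation instead (keeping the offspring budget full).
#'
#' @param library a [CombinatorialLibrary-class].
#' @param parentA,parentB parent [LibraryMolecule-class] objects.
#' @return list of two child lists (as in [mutateMolecule()]).
#' @export
crossoverMolecules <- function(library, parentA, parentB) {
  if (parentA@reactionId != parentB@reactionId) {
    return(list(mutateMolecule(library, parentA, "substrate"),
                mutateMolecule(library, parentB, "substrate")))
  }
  rid <- parentA@reactionId
  arity <- length(parentA@substrateIds)
  p <- if (arity == 1L) 1L else sample.int(arity, 1L)
  subA <- parentA@substrateIds; subB <- parentB@substrateIds
  tmp <- subA[p]; subA[p] <- subB[p]; subB[p] <- tmp
  changed <- !identical(subA, parentA@substrateIds)
  list(
    list(molecule = assembleProduct(library, rid, subA),
         operator = "crossover", changed = changed),
    list(molecule = assembleProduct(library, rid, subB),
         operator = "crossover", changed = changed))
}

#' Rank-based survivor selection
#'
#' The `elitismCount` best individuals by fitness are kept
#' deterministically; the remaining survivors are drawn without replacement
#' with probability proportional to `N - rank + 1` (linear ranking, rank 1
#' = best).  Fitness ties break by molecule key so selection is
#' reproducible.
#'
#' @param population evaluated population data.frame.
#' @param k number of survivors.
#' @param elitismCount deterministic elite size (default 5).
#' @return the selected rows.
#' @export
rankSelect <- function(population, k, elitismCount = 5L) {
  n <- nrow(population)
  if (k > n) stop("cannot select ", k, " from ", n)
  ord <- order(population$fitness, population$key)
  pop <- population[ord, , drop = FALSE]
  elite <- seq_len(min(elitismCount, k))
  rest <- setdiff(seq_len(n), elite)
  need <- k - length(elite)
  pick <- if (need > 0L) {
    w <- (n - rest + 1)
    rest[.sampleWithoutReplacement(length(rest), need, w)]
  } else integer(0)
  out <- pop[c(elite, sort(pick)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# weighted sampling without replacement (successive draws)
.sampleWithoutReplacement <- function(n, k, w) {
  idx <- seq_len(n)
  out <- integer(k)
  for (i in seq_len(k)) {
    j <- if (length(idx) == 1L) 1L
         else sample.int(length(idx), 1L, prob = w)
    out[i] <- idx[j]
    idx <- idx[-j]; w <- w[-j]
  }
  out
}

#' Run one evolutionary optimization
#'
#' The generation loop: survivors produce `offspringPerGeneration` children
#' through the operator mixture (immigrants are fresh random molecules),
#' children are evaluated cache-aware through the oracle, and rank-based
#' selection reduces the population back to `survivors`.  After
#' `generations` cycles the complete [RunLog-class] is returned — every
#' distinct molecule ever evaluated, including discarded ones.  A fixed
#' seed yields a bit-identical log.
#'
#' @param library a [CombinatorialLibrary-class].
#' @param oracle a [DockingOracle-class].
#' @param config an [evolutionConfig()].
#' @param receptorId receptor to dock against.
#' @param runId label stored in the log.
#' @return a [RunLog-class].
#' @export
runEvolution <- function(library, oracle, config = evolutionConfig(),
                         receptorId = "receptor", runId = "run1") {
  .withSeed(config$seed,
            .runEvolution(library, oracle, config, receptorId, runId))
}

.runEvolution <- function(library, oracle, config, receptorId, runId) {
  ledger <- new.env(parent = emptyenv())
  ledger$scores <- list(); ledger$calls <- 0L; ledger$hits <- 0L
  aborted <- FALSE
  pop <- tryCatch(
    .initPopulation(library, config, oracle, receptorId, ledger),
    error = function(e) e)
  if (inherits(pop, "error")) stop(pop)
  all <- pop
  gens <- vector("list", config$generations)
  for (g in seq_len(config$generations)) {
    parents <- rankSelect(pop, min(config$survivors, nrow(pop)),
                          config$elitismCount)
    kids <- tryCatch(
      .offspring(library, parents, config, g),
      error = function(e) e)
    if (inherits(kids, "error")) { aborted <- TRUE; break }
    kids <- tryCatch(.evaluate(kids, oracle, receptorId, ledger),
                     error = function(e) e)
    if (inherits(kids, "error")) { aborted <- TRUE; break }
    newKeys <- !(kids$key %in% all$key) & !duplicated(kids$key)
    all <- rbind(all, kids[newKeys, , drop = FALSE])
    pool <- rbind(parents, kids)
    pool <- pool[!duplicated(pool$key), , drop = FALSE]
    pop <- pool
    gens[[g]] <- data.frame(
      generation = g, evaluated = nrow(kids), distinct_total = nrow(all),
      best_fitness = min(pop$fitness),
      median_fitness = stats::median(pop$fitness))
  }
  gensDf <- do.call(rbind, gens[!vapply(gens, is.null, logical(1))])
  if (is.null(gensDf))
    gensDf <- data.frame(generation = integer(0), evaluated = integer(0),
                         distinct_total = integer(0),
                         best_fitness = numeric(0),
                         median_fitness = numeric(0))
  rownames(all) <- NULL
  methods::new("RunLog", runId = runId, individuals = all,
               generations = gensDf,
               cacheStats = list(oracle_calls = ledger$calls,
                                 cache_hits = ledger$hits),
               valid = !aborted)
}

.offspring <- function(library, parents, config, generation) {
  n <- config$offspringPerGeneration
  ops <- sample(names(config$weights), n, replace = TRUE,
                prob = config$weights)
  rows <- vector("list", n)
  i <- 1L
  while (i <= n) {
    op <- ops[i]
    pick <- function() .rowMolecule(
      parents[sample.int(nrow(parents), 1L), , drop = FALSE])
    if (op == "crossover" && nrow(parents) >= 2L) {
      ij <- sample.int(nrow(parents), 2L)
      kids <- crossoverMolecules(library,
                                 .rowMolecule(parents[ij[1], , drop = FALSE]),
                                 .rowMolecule(parents[ij[2], , drop = FALSE]))
      pk <- paste(parents$key[ij], collapse = ",")
      for (k in kids) {
        if (i > n) break
        rows[[i]] <- .popRow(k$molecule, generation = generation,
                             operator = k$operator, parents = pk)
        i <- i + 1L
      }
    } else if (op == "immigrant") {
      mol <- sampleRandomMolecule(library, 1L)[[1]]
      rows[[i]] <- .popRow(mol, generation = generation,
                           operator = "immigrant")
      i <- i + 1L
    } else {
      parent <- parents[sample.int(nrow(parents), 1L), , drop = FALSE]
      kind <- if (op == "mutation_reaction") "reaction" else "substrate"
      k <- mutateMolecule(library, .rowMolecule(parent), kind)
      rows[[i]] <- .popRow(k$molecule, generation = generation,
                           operator = k$operator, parents = parent$key)
      i <- i + 1L
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @describeIn individuals accessor.
#' @export
setMethod("individuals", "RunLog", function(x) x@individuals)

#' @describeIn generations accessor.
#' @export
setMethod("generations", "RunLog", function(x) x@generations)

setMethod("show", "RunLog", function(object) {
  cat("RunLog", object@runId, ":", nrow(object@individuals),
      "distinct molecules over", nrow(object@generations),
      "generations\n  best fitness:",
      format(min(object@individuals$fitness), digits = 4),
      " oracle calls:", object@cacheStats$oracle_calls,
      " cache hits:", object@cacheStats$cache_hits, "\n")
  if (!object@valid) cat("  [partial log: run aborted]\n")
})

#' Merge several run logs into one scored-molecule table
#'
#' Union of all evaluated molecules across runs, keeping the best (lowest)
#' fitness per molecule with the contributing run ids, sorted best-first.
#'
#' @param runLogs list of [RunLog-class].
#' @return data.frame with `key`, `reaction_id`, `substrate_ids`,
#'   `product_smiles`, `lid_root2`, `heavy_atoms`, `runs`.
#' @export
aggregateRuns <- function(runLogs) {
  if (length(runLogs) == 0L) stop("need at least one run log")
  rows <- do.call(rbind, lapply(runLogs, function(log) {
    df <- log@individuals
    df$run_id <- log@runId
    df
  }))
  best <- list()
  for (i in seq_len(nrow(rows))) {
    k <- rows$key[i]
    cur <- best[[k]]
    if (is.null(cur)) {
      best[[k]] <- list(row = rows[i, , drop = FALSE],
                        runs = rows$run_id[i])
    } else {
      best[[k]]$runs <- union(cur$runs, rows$run_id[i])
      if (rows$fitness[i] < cur$row$fitness)
        best[[k]]$row <- rows[i, , drop = FALSE]
    }
  }
  out <- do.call(rbind, lapply(best, function(b) {
    data.frame(key = b$row$key, reaction_id = b$row$reaction_id,
               substrate_ids = b$row$substrate_ids,
               product_smiles = b$row$product_smiles,
               lid_root2 = b$row$fitness,
               heavy_atoms = b$row$heavy_atoms,
               runs = paste(sort(b$runs), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$lid_root2, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
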