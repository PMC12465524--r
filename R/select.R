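# select: ECFP4 fingerprints, Tanimoto similarity, diversity clustering and
# the greedy similarity budget pruning that reduces a candidate list to a
# purchasable set.

#' ECFP4 fingerprints for molecules
#'
#' Extended-connectivity (circular, diameter 4) hashed fingerprints as a
#' 0/1 matrix, one row per molecule.  Deterministic: identical canonical
#' SMILES yield identical rows.
#'
#' @param smiles character vector of SMILES.
#' @param nbits fingerprint length (default 2048; the unfolded hash is
#'   folded down by OR-ing halves).
#' @return integer 0/1 matrix, `length(smiles)` x `nbits`.
#' @export
fingerprintMolecules <- function(smiles, nbits = 2048L) {
  can <- canonicalSmiles(smiles)
  if (anyNA(can))
    stop("unparsable SMILES: ", paste(smiles[is.na(can)], collapse = ", "))
  .obEcfp4(can, nbits = nbits)
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; the empty-vs-empty case is defined as 0.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) 0 else inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param fp fingerprint matrix (rows = molecules).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
tanimotoMatrix <- function(fp) {
  m <- fp %*% t(fp)                       # intersections
  card <- rowSums(fp)
  uni <- outer(card, card, `+`) - m
  sim <- ifelse(uni == 0, 0, m / uni)
  diag(sim) <- 1
  sim
}

#' Cluster compounds into diversity groups
#'
#' Groups molecules by fingerprint similarity into (at most) `k` clusters.
#' The default runs k-means on the raw ECFP4 bit vectors; `"kmedoids"`
#' performs PAM under 1 - Tanimoto distance, the literal-metric
#' alternative.  When per-molecule scores are supplied, each cluster's
#' representative is its best-scoring (lowest lid_root2) member.
#'
#' @param smiles character vector of SMILES (or a precomputed fingerprint
#'   matrix via `fp`).
#' @param k number of clusters (default 100; reduced with a warning when
#'   it exceeds the number of distinct molecules).
#' @param scores optional numeric vector of lid_root2 scores.
#' @param method `"kmeans"` or `"kmedoids"`.
#' @param fp optional fingerprint matrix overriding `smiles`.
#' @param seed RNG seed for the clustering initialization.
#' @return list with `assignment` (data.frame: smiles, cluster), `clusters`
#'   (data.frame: cluster, size, representative, best_score), `k`.
#' @export
clusterCompounds <- function(smiles, k = 100L, scores = NULL,
                             method = c("kmeans", "kmedoids"),
                             fp = NULL, seed = 1L) {
  method <- match.arg(method)
  if (is.null(fp)) fp <- fingerprintMolecules(smiles)
  n <- nrow(fp)
  stopifnot(n >= 1L, k >= 1L)
  nDistinct <- nrow(unique(fp))
  if (k > nDistinct) {
    warning("k = ", k, " exceeds ", nDistinct,
            " distinct molecules; using k = ", nDistinct)
    k <- nDistinct
  }
  cl <- .withSeed(seed, {
    if (method == "kmeans") {
      if (k == n) seq_len(n)
      else stats::kmeans(fp, centers = k, nstart = 5L, iter.max = 200L,
                         algorithm = "Lloyd")$cluster
    } else {
      d <- stats::as.dist(1 - tanimotoMatrix(fp))
      if (k == n) seq_len(n) else cluster::pam(d, k = k,
                                               cluster.only = TRUE)
    }
  })
  assignment <- data.frame(smiles = smiles, cluster = as.integer(cl),
                           stringsAsFactors = FALSE)
  reps <- lapply(split(seq_len(n), cl), function(idx) {
    best <- if (is.null(scores)) idx[1]
            else idx[order(scores[idx], smiles[idx])[1]]
    data.frame(cluster = cl[best], size = length(idx),
               representative = smiles[best],
               best_score = if (is.null(scores)) NA_real_
                            else min(scores[idx]),
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, reps)
  clusters <- clusters[order(clusters$cluster), , drop = FALSE]
  rownames(clusters) <- NULL
  list(assignment = assignment, clusters = clusters,
       k = length(unique(cl)))
}

#' Greedy similarity budget pruning
#'
#' Reduces a scored candidate set to exactly `nTarget` members: repeatedly
#' find the currently most similar pair (pairwise Tanimoto over ECFP4) and
#' remove its worse-scoring member (higher lid_root2), until the budget is
#' reached.  Similarity ties break by molecule key order; score ties keep
#' the earlier key.  The most-similar pair is recomputed after every
#' removal.
#'
#' @param scored data.frame with `key` (SMILES) and `lid_root2`.
#' @param nTarget number of molecules to keep.
#' @param fp optional precomputed fingerprint matrix (rows follow
#'   `scored`).
#' @return list with `kept` (data.frame subset, original order) and
#'   `audit` (data.frame of removals: step, removed_key, paired_with,
#'   similarity).
#' @export
similarityBudgetPrune <- function(scored, nTarget, fp = NULL) {
  n <- nrow(scored)
  if (n < nTarget) stop("input (", n, ") smaller than target ", nTarget)
  if (is.null(fp)) fp <- fingerprintMolecules(scored$key)
  sim <- tanimotoMatrix(fp)
  diag(sim) <- -1
  alive <- rep(TRUE, n)
  audit <- list()
  while (sum(alive) > nTarget) {
    idx <- which(alive)
    sub <- sim[idx, idx, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)
    # deterministic pair choice on similarity ties: the pair whose sorted
    # key pair is lexicographically smallest
    pairs <- unique(t(apply(best, 1L, function(r)
      sort(c(idx[r[1]], idx[r[2]])))))
    keyPairs <- t(apply(pairs, 1L, function(r)
      sort(scored$key[r])))
    keyOrd <- order(keyPairs[, 1], keyPairs[, 2])
    pair <- pairs[keyOrd[1], ]
    i <- pair[1]; j <- pair[2]
    # remove the worse-scoring member (higher lid_root2); ties keep the
    # earlier key
    drop <- if (scored$lid_root2[i] > scored$lid_root2[j]) i
            else if (scored$lid_root2[j] > scored$lid_root2[i]) j
            else if (scored$key[i] <= scored$key[j]) j else i
    alive[drop] <- FALSE
    audit[[length(audit) + 1L]] <- data.frame(
      step = length(audit) + 1L, removed_key = scored$key[drop],
      paired_with = scored$key[if (drop == i) j else i],
      similarity = sim[i, j], stringsAsFactors = FALSE)
  }
  auditDf <- if (length(audit)) do.call(rbind, audit)
             else data.frame(step = integer(0), removed_key = character(0),
                             paired_with = character(0),
                             similarity = numeric(0))
  kept <- scored[alive, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, audit = auditDf)
}
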