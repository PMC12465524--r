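# Fingerprints, Tanimoto, clustering, budget pruning.

test_that("fingerprints are deterministic and discriminate structures", {
  f1 <- fingerprintMolecules(c("c1ccccc1", "c1ccccc1", "Cc1ccccc1"))
  expect_identical(f1[1, ], f1[2, ])
  expect_equal(tanimoto(f1[1, ], f1[1, ]), 1)
  t12 <- tanimoto(f1[1, ], f1[3, ])
  expect_gt(t12, 0)
  expect_lt(t12, 1)
  expect_true(all(rowSums(f1) >= 1))
  # same molecule, different SMILES spelling
  f2 <- fingerprintMolecules(c("C(C)O", "OCC"))
  expect_identical(f2[1, ], f2[2, ])
})

test_that("tanimoto matches hand counts and is a bounded symmetric sim", {
  a <- integer(8); a[c(1, 2, 3)] <- 1L
  b <- integer(8); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)            # 2 / 4
  expect_equal(tanimoto(a, integer(8)), 0)
  expect_equal(tanimoto(integer(8), integer(8)), 0)
  expect_equal(tanimoto(a, a), 1)
  expect_error(tanimoto(a, b[1:4]), "mismatch")
  set.seed(10)
  for (i in 1:20) {
    x <- as.integer(runif(32) < 0.4)
    y <- as.integer(runif(32) < 0.4)
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_gte(tanimoto(x, y), 0)
    expect_lte(tanimoto(x, y), 1)
  }
  # matrix form agrees with the pairwise definition
  fp <- rbind(a, b, a)
  m <- tanimotoMatrix(fp)
  expect_equal(m[1, 2], 0.5)
  expect_equal(m[1, 3], 1)
  expect_equal(m, t(m))
})

test_that("clustering separates two structural families perfectly", {
  dirA <- file.path(tempdir(), "famA")
  dirB <- file.path(tempdir(), "famB")
  pa <- makeToyLibrary(dirA, list(amide = c(4L, 4L)), family = "aromatic",
                       seed = 3L)
  pb <- makeToyLibrary(dirB, list(amide = c(4L, 4L)),
                       family = "aliphatic", seed = 3L)
  prodA <- enumerateProducts(loadLibrary(pa$rulesPath, pa$blocksPath))
  prodB <- enumerateProducts(loadLibrary(pb$rulesPath, pb$blocksPath))
  smiles <- c(prodA$product_smiles, prodB$product_smiles)
  truth <- rep(c("A", "B"), c(nrow(prodA), nrow(prodB)))
  cl <- clusterCompounds(smiles, k = 2L, method = "kmeans", seed = 5L)
  tab <- table(cl$assignment$cluster, truth)
  # every k-means cluster is pure: one family per cluster
  expect_true(all(apply(tab, 1, function(r) sum(r > 0) == 1L)))
  # the PAM/Tanimoto alternative recovers the families to high purity
  # (medoid choice is less crisp on heterogeneous hashed fingerprints)
  clm <- clusterCompounds(smiles, k = 2L, method = "kmedoids", seed = 5L)
  tabm <- table(clm$assignment$cluster, truth)
  purity <- sum(apply(tabm, 1, max)) / length(smiles)
  expect_gte(purity, 0.8)
  # degenerate cases
  one <- clusterCompounds(smiles[1:5], k = 1L, seed = 2L)
  expect_equal(one$k, 1L)
  distinct <- unique(smiles)[1:6]
  own <- clusterCompounds(distinct, k = 6L, seed = 2L)
  expect_equal(own$k, 6L)
  expect_warning(clusterCompounds(distinct, k = 50L, seed = 2L),
                 "exceeds")
})

test_that("cluster representatives are the best-scoring members", {
  smiles <- enumerateProducts(tinyLibrary())$product_smiles
  scores <- seq(-5, -5 + 0.1 * (length(smiles) - 1), by = 0.1)
  cl <- clusterCompounds(smiles, k = 3L, scores = scores, seed = 4L)
  for (i in seq_len(nrow(cl$clusters))) {
    members <- cl$assignment$smiles[cl$assignment$cluster ==
                                      cl$clusters$cluster[i]]
    best <- members[which.min(scores[match(members, smiles)])]
    expect_equal(cl$clusters$representative[i], best)
    expect_equal(cl$clusters$best_score[i],
                 min(scores[match(members, smiles)]))
  }
})

test_that("budget pruning removes the worse member of the closest pair", {
  smiles <- enumerateProducts(plantedCampaign()$library)$product_smiles
  # planted near-duplicate pair: same molecule under two spellings would
  # collapse, so take two homologs and check the first removal
  scored <- data.frame(key = c("CCCCCCCCO", "CCCCCCCCCO", "c1ccccc1",
                               "CC(=O)Nc1ccccc1"),
                       lid_root2 = c(-4.0, -3.0, -4.5, -4.2),
                       stringsAsFactors = FALSE)
  pr <- similarityBudgetPrune(scored, 3L)
  expect_equal(nrow(pr$kept), 3L)
  # the octanol/nonanol pair is by far the most similar; the worse-scoring
  # nonanol (-3.0) goes first
  expect_equal(pr$audit$removed_key[1], "CCCCCCCCCO")
  expect_true("CCCCCCCCO" %in% pr$kept$key)
  # exact output size and subset/audit consistency on a larger input
  scored2 <- data.frame(key = smiles[1:40],
                        lid_root2 = seq(-6, -2.1, length.out = 40),
                        stringsAsFactors = FALSE)
  pr2 <- similarityBudgetPrune(scored2, 25L)
  expect_equal(nrow(pr2$kept), 25L)
  expect_true(all(pr2$kept$key %in% scored2$key))
  expect_setequal(c(pr2$kept$key, pr2$audit$removed_key), scored2$key)
  expect_error(similarityBudgetPrune(scored, 10L), "smaller")
})

test_that("pruning equals an independent greedy simulation on small sets", {
  smiles <- unique(enumerateProducts(plantedCampaign()$library)$product_smiles)
  bruteGreedy <- function(keys, scores, fp, nTarget) {
    alive <- seq_along(keys)
    while (length(alive) > nTarget) {
      bestSim <- -Inf; bestPair <- NULL
      for (x in seq_along(alive)) for (y in seq_along(alive)) {
        if (x >= y) next
        i <- alive[x]; j <- alive[y]
        s <- tanimoto(fp[i, ], fp[j, ])
        pick <- FALSE
        if (s > bestSim) pick <- TRUE
        else if (s == bestSim) {
          cand <- sort(c(keys[i], keys[j]))
          cur <- sort(c(keys[bestPair[1]], keys[bestPair[2]]))
          if (cand[1] < cur[1] ||
              (cand[1] == cur[1] && cand[2] < cur[2])) pick <- TRUE
        }
        if (pick) { bestSim <- s; bestPair <- c(i, j) }
      }
      i <- bestPair[1]; j <- bestPair[2]
      drop <- if (scores[i] > scores[j]) i
              else if (scores[j] > scores[i]) j
              else if (keys[i] <= keys[j]) j else i
      alive <- setdiff(alive, drop)
    }
    keys[alive]
  }
  set.seed(6)
  for (trial in 1:4) {
    pickN <- sample(5:8, 1)
    keys <- sample(smiles, pickN)
    scores <- round(runif(pickN, -6, -2), 2)
    nTarget <- sample(2:(pickN - 1), 1)
    fp <- fingerprintMolecules(keys)
    mine <- similarityBudgetPrune(
      data.frame(key = keys, lid_root2 = scores,
                 stringsAsFactors = FALSE), nTarget, fp = fp)
    brute <- bruteGreedy(keys, scores, fp, nTarget)
    expect_setequal(mine$kept$key, brute)
  }
})
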