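# lid_root2 normalization, score filters, oracle contract and score tables.

test_that("lid_root2 divides by the square root of the heavy-atom count", {
  expect_equal(lidRoot2(-10, 25), -2)
  expect_equal(lidRoot2(0, 17), 0)
  expect_equal(round(lidRoot2(-12.3, 24), 4), -2.5107)
  expect_error(lidRoot2(-5, 0), "heavyAtoms")
  # size penalty: same interface energy, bigger molecule, score closer to 0
  expect_gt(lidRoot2(-10, 40), lidRoot2(-10, 20))
})

test_that("threshold filter treats the boundary as better and partitions", {
  scored <- data.frame(key = c("a", "b", "c"),
                       lid_root2 = c(-3.6, -3.4, -3.5))
  kept <- scoreThresholdFilter(scored, -3.5, "keep_better")
  expect_setequal(kept$key, c("a", "c"))
  excl <- scoreThresholdFilter(scored, -3.5, "exclude_better")
  expect_setequal(excl$key, "b")
  expect_setequal(c(kept$key, excl$key), scored$key)
})

test_that("redock consistency fails when either delta exceeds the bound", {
  ok <- redockConsistencyFilter(-4.0, c(-3.9, -3.8, -3.7))
  expect_true(ok$pass)
  expect_equal(ok$delta1, 0.1)
  expect_equal(round(ok$delta2, 10), 0.2)
  bad1 <- redockConsistencyFilter(-5.0, c(-4.0, -3.9))
  expect_false(bad1$pass)
  expect_equal(bad1$delta1, 1.0)
  bad2 <- redockConsistencyFilter(-4.4, seq(-4.5, -3.6, length.out = 10))
  expect_false(bad2$pass)              # spread 0.9 fails regardless of d1
  expect_equal(round(bad2$delta2, 10), 0.9)
  # the laxer AND rule passes the spread-only case
  expect_true(redockConsistencyFilter(-4.4, seq(-4.5, -3.6,
                                                length.out = 10),
                                      rule = "and")$pass)
  expect_error(redockConsistencyFilter(-4, numeric(0)), "empty")
})

test_that("ensemble consensus uses mean and population sd", {
  r <- ensembleConsensusFilter(c(m1 = -4.0, m2 = -4.2, m3 = -4.4))
  expect_equal(r$consensus, -4.2)
  expect_equal(round(r$std, 3), 0.163)
  expect_true(r$keep)
  r2 <- ensembleConsensusFilter(c(m1 = -3.0, m2 = -4.5, m3 = -3.9))
  expect_equal(round(r2$std, 3), 0.616)
  expect_false(r2$keep)
  r3 <- ensembleConsensusFilter(c(a = -4, b = -4, c = -4))
  expect_equal(r3$std, 0)
  expect_true(r3$keep)
  # invariant under receptor relabeling
  r4 <- ensembleConsensusFilter(c(x = -4.4, y = -4.0, z = -4.2))
  expect_equal(r4$std, r$std)
  expect_equal(r4$consensus, r$consensus)
  expect_error(ensembleConsensusFilter(c(a = -4)), "two")
})

test_that("synthetic oracle rewards motif similarity and penalizes size", {
  lib <- tinyLibrary()
  enum <- enumerateProducts(lib)
  motif <- enum$product_smiles[5]
  oracle <- syntheticOracle(motif, noise = 0, nPoses = 10L, seed = 2L)
  scores <- vapply(enum$product_smiles, function(s) {
    r <- dock(oracle, s)
    lidRoot2(r@poses$interface_delta[1],
             computeProperties(s)$heavy_atoms)
  }, numeric(1))
  heavy <- computeProperties(enum$product_smiles)$heavy_atoms
  sameSize <- which(heavy == heavy[5])
  expect_equal(unname(which.min(scores[sameSize])),
               unname(which(sameSize == 5)))
  # monotone in similarity at fixed size
  fps <- fingerprintMolecules(enum$product_smiles)
  motifFp <- fps[5, ]
  sims <- apply(fps, 1, tanimoto, b = motifFp)
  for (i in sameSize) for (j in sameSize) {
    if (sims[i] > sims[j]) expect_lt(scores[i], scores[j])
  }
})

test_that("synthetic oracle is bit-reproducible under its seed", {
  motif <- enumerateProducts(tinyLibrary())$product_smiles[1]
  probe <- enumerateProducts(tinyLibrary())$product_smiles[7]
  o1 <- syntheticOracle(motif, noise = 0.4, nPoses = 25L, seed = 99L)
  o2 <- syntheticOracle(motif, noise = 0.4, nPoses = 25L, seed = 99L)
  r1 <- dock(o1, probe, "recX")
  r2 <- dock(o2, probe, "recX")
  expect_identical(r1@poses, r2@poses)
  expect_true(!is.unsorted(r1@poses$interface_delta))
  # per-molecule streams: call order must not matter
  o3 <- syntheticOracle(motif, noise = 0.4, nPoses = 25L, seed = 99L)
  invisible(dock(o3, motif, "recX"))
  r3 <- dock(o3, probe, "recX")
  expect_identical(r1@poses, r3@poses)
})

test_that("score tables round-trip and preserve sorted poses", {
  motif <- enumerateProducts(tinyLibrary())$product_smiles[1]
  oracle <- syntheticOracle(motif, noise = 0.2, nPoses = 600L, seed = 5L)
  probes <- enumerateProducts(tinyLibrary())$product_smiles[1:3]
  results <- lapply(probes, function(s) dock(oracle, s, "rec1"))
  path <- file.path(tempdir(), "scores.csv")
  writeScoreTable(results, path)
  back <- readScoreTable(path)
  expect_length(back, 3L)
  for (r in results) {
    b <- back[[paste0(r@moleculeKey, "|", r@receptorId)]]
    expect_equal(nrow(b@poses), 600L)
    expect_equal(b@poses$interface_delta, r@poses$interface_delta)
    expect_true(!is.unsorted(b@poses$interface_delta))
  }
  # table oracle replays stored results and rejects unknown molecules
  to <- tableOracle(path)
  expect_equal(dock(to, probes[1], "rec1")@poses$interface_delta,
               results[[1]]@poses$interface_delta)
  expect_error(dock(to, "CCCCCCCC", "rec1"), "no entry")
  # empty file is a file-level error
  empty <- file.path(tempdir(), "empty.csv")
  writeLines("molecule_key,receptor_id,pose_index,interface_delta", empty)
  expect_error(readScoreTable(empty), "no parsable rows")
})
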