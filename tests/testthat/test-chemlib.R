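# Combinatorial library loading, product assembly, enumeration, sampling
# and partner expansion.

test_that("library loads with the closed-form product count", {
  lib <- tinyLibrary()
  expect_s4_class(lib, "CombinatorialLibrary")
  expect_equal(librarySize(lib), 12)          # 3 x 4
  expect_equal(librarySize(mixedLibrary()), 20)  # 12 + 2*2*2
})

test_that("substrates with invalid SMILES are dropped with a warning", {
  dir <- file.path(tempdir(), "lib_invalid")
  paths <- makeToyLibrary(dir, list(amide = c(3L, 4L)), seed = 7L,
                          invalidSubstrate = TRUE)
  expect_warning(lib <- loadLibrary(paths$rulesPath, paths$blocksPath),
                 "unparsable")
  expect_false("broken_01" %in% libSubstrates(lib)$substrate_id)
  expect_equal(librarySize(lib), 12)
})

test_that("malformed SMARTS errors name the offending reaction", {
  dir <- file.path(tempdir(), "lib_badsmarts")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("reaction_id\tsmarts\tarity",
               "r_bad\t[C:1](=O[OH].[N:2]>>[C:1][N:2]\t2"),
             file.path(dir, "rules.tsv"))
  writeLines(c("substrate_id\tsmiles\treaction_id\tposition",
               "s1\tCC(=O)O\tr_bad\t0", "s2\tCN\tr_bad\t1"),
             file.path(dir, "blocks.tsv"))
  expect_error(loadLibrary(file.path(dir, "rules.tsv"),
                           file.path(dir, "blocks.tsv")),
               "r_bad")
})

test_that("amide coupling template reproduces N-methylacetamide", {
  products <- evoscreen:::applyReactionSmarts(
    "[C:1](=O)O.[N;H2:2]>>[C:1](=O)[N:2]", c("CC(=O)O", "CN"))
  expect_equal(products, canonicalSmiles("CC(=O)NC"))
})

test_that("assembly is deterministic and validates its preconditions", {
  lib <- tinyLibrary()
  acids <- slotSubstrates(lib, "r_amide", 0)
  amines <- slotSubstrates(lib, "r_amide", 1)
  ref <- evoscreen:::applyReactionSmarts(
    lib@parsed[["r_amide"]],
    evoscreen:::.substrateSmiles(lib, c(acids[1], amines[1])))[1]
  for (i in 1:25) {
    again <- evoscreen:::applyReactionSmarts(
      lib@parsed[["r_amide"]],
      evoscreen:::.substrateSmiles(lib, c(acids[1], amines[1])))[1]
    expect_identical(again, ref)
  }
  mol <- assembleProduct(lib, "r_amide", c(acids[1], amines[1]))
  expect_identical(mol@productSmiles, ref)
  # wrong arity
  expect_error(assembleProduct(lib, "r_amide", c(acids[1], amines[1],
                                                 amines[2])), "arity")
  # substrate not allowed in the slot
  expect_error(assembleProduct(lib, "r_amide", c(amines[1], acids[1])),
               "not allowed")
})

test_that("enumeration yields each address once and matches brute force", {
  lib <- tinyLibrary()
  enum <- enumerateProducts(lib)
  expect_equal(nrow(enum), 12)
  expect_equal(anyDuplicated(enum$key), 0L)
  # independent nested-loop oracle over the raw templates
  acids <- slotSubstrates(lib, "r_amide", 0)
  amines <- slotSubstrates(lib, "r_amide", 1)
  brute <- character(0)
  for (a in acids) for (b in amines) {
    brute <- c(brute, evoscreen:::applyReactionSmarts(
      "[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]",
      evoscreen:::.substrateSmiles(lib, c(a, b)))[1])
  }
  expect_equal(sort(enum$product_smiles), sort(brute))
})

test_that("round trip: enumerate then re-assemble reproduces products", {
  lib <- mixedLibrary()
  enum <- enumerateProducts(lib)
  for (i in seq_len(nrow(enum))) {
    subIds <- strsplit(enum$substrate_ids[i], "+", fixed = TRUE)[[1]]
    again <- assembleProduct(lib, enum$reaction_id[i], subIds)
    expect_identical(again@productSmiles, enum$product_smiles[i])
  }
})

test_that("random sampling is seeded, uniform per slot, and total", {
  lib <- tinyLibrary()
  set.seed(42)
  a <- vapply(sampleRandomMolecule(lib, 20, assemble = FALSE),
              moleculeKey, character(1))
  set.seed(42)
  b <- vapply(sampleRandomMolecule(lib, 20, assemble = FALSE),
              moleculeKey, character(1))
  expect_identical(a, b)
  # uniform over the 12 addresses of the single reaction
  set.seed(11)
  draws <- vapply(sampleRandomMolecule(lib, 6000, assemble = FALSE),
                  moleculeKey, character(1))
  tab <- table(factor(draws, levels = sort(unique(
    enumerateProducts(lib, assemble = FALSE)$key))))
  expect_length(tab, 12L)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("empty or singleton sampling degenerates correctly", {
  dir <- file.path(tempdir(), "lib_singleton")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("reaction_id\tsmarts\tarity",
               "r1\t[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]\t2"),
             file.path(dir, "rules.tsv"))
  writeLines(c("substrate_id\tsmiles\treaction_id\tposition",
               "s1\tCC(=O)O\tr1\t0", "s2\tCN\tr1\t1"),
             file.path(dir, "blocks.tsv"))
  lib1 <- loadLibrary(file.path(dir, "rules.tsv"),
                      file.path(dir, "blocks.tsv"))
  set.seed(1)
  keys <- vapply(sampleRandomMolecule(lib1, 5), moleculeKey, character(1))
  expect_length(unique(keys), 1L)
})

test_that("reactions with an empty slot are unusable and contribute 0", {
  dir <- file.path(tempdir(), "lib_emptyslot")
  dir.create(dir, showWarnings = FALSE)
  writeLines(c("reaction_id\tsmarts\tarity",
               "r1\t[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]\t2",
               "r2\t[S:1](=O)(=O)Cl.[NX3;H2:2]>>[S:1](=O)(=O)[N:2]\t2"),
             file.path(dir, "rules.tsv"))
  writeLines(c("substrate_id\tsmiles\treaction_id\tposition",
               "s1\tCC(=O)O\tr1\t0", "s2\tCN\tr1\t1",
               "s3\tCS(=O)(=O)Cl\tr2\t0"),   # r2 slot 1 left empty
             file.path(dir, "blocks.tsv"))
  lib <- loadLibrary(file.path(dir, "rules.tsv"),
                     file.path(dir, "blocks.tsv"))
  rx <- libReactions(lib)
  expect_false(rx$usable[rx$reaction_id == "r2"])
  expect_equal(librarySize(lib), 1)
  expect_equal(nrow(enumerateProducts(lib)), 1L)
})

test_that("partner expansion matches the closed form and brute force", {
  lib <- tinyLibrary()
  set.seed(3)
  hit <- sampleRandomMolecule(lib, 1)[[1]]
  exp2 <- expandPartners(lib, hit)
  expect_length(exp2, 3 + 4 - 1)
  keys <- vapply(exp2, moleculeKey, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true(moleculeKey(hit) %in% keys)
  # brute-force per-position substitution with dedup
  brute <- character(0)
  for (p in 1:2) for (sid in slotSubstrates(lib, "r_amide", p - 1L)) {
    s <- hit@substrateIds; s[p] <- sid
    brute <- c(brute, paste0("r_amide|", paste(s, collapse = "+")))
  }
  expect_setequal(keys, unique(brute))
  # subset of the full enumeration
  expect_true(all(keys %in% enumerateProducts(lib, assemble = FALSE)$key))
  # three-component reaction: m + n + k - (arity - 1)
  lib3 <- mixedLibrary()
  d0 <- slotSubstrates(lib3, "r_diamide", 0)
  d1 <- slotSubstrates(lib3, "r_diamide", 1)
  d2 <- slotSubstrates(lib3, "r_diamide", 2)
  hit3 <- assembleProduct(lib3, "r_diamide", c(d0[1], d1[1], d2[1]))
  expect_length(expandPartners(lib3, hit3), 2 + 2 + 2 - 2)
  # unknown reaction
  alien <- methods::new("LibraryMolecule", reactionId = "nope",
                        substrateIds = c("a", "b"),
                        productSmiles = "CC")
  expect_error(expandPartners(lib, alien), "not in this library")
})
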