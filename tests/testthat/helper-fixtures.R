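# Shared fixtures, memoized for the whole test run: libraries are generated
# programmatically and cached so each file pays the chemistry cost once.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  v <- .fixtureCache[[name]]
  if (is.null(v)) {
    v <- builder()
    .fixtureCache[[name]] <- v
  }
  v
}

# 3 x 4 amide toy library (12 products)
tinyLibrary <- function() fixture("tiny", function() {
  dir <- file.path(tempdir(), "evoscreen_tiny")
  paths <- makeToyLibrary(dir, list(amide = c(3L, 4L)), seed = 7L)
  loadLibrary(paths$rulesPath, paths$blocksPath)
})

# amide 3x4 plus diamide 2x2x2 (12 + 8 = 20 products)
mixedLibrary <- function() fixture("mixed", function() {
  dir <- file.path(tempdir(), "evoscreen_mixed")
  paths <- makeToyLibrary(dir, list(amide = c(3L, 4L),
                                    diamide = c(2L, 2L, 2L)), seed = 7L)
  loadLibrary(paths$rulesPath, paths$blocksPath)
})

# 30 x 40 amide library (1200 products) with its planted landscape
plantedCampaign <- function() fixture("planted", function() {
  dir <- file.path(tempdir(), "evoscreen_planted")
  paths <- makeToyLibrary(dir, list(amide = c(30L, 40L)), seed = 7L)
  lib <- loadLibrary(paths$rulesPath, paths$blocksPath)
  landscape <- makePlantedLandscape(lib, seed = 3L)
  list(paths = paths, library = lib, landscape = landscape)
})

# hand-written two-reaction library sharing identical slot lists
sharedSlotLibrary <- function() fixture("sharedslots", function() {
  dir <- file.path(tempdir(), "evoscreen_shared")
  dir.create(dir, showWarnings = FALSE)
  rules <- file.path(dir, "rules.tsv")
  blocks <- file.path(dir, "blocks.tsv")
  writeLines(c("reaction_id\tsmarts\tarity",
               "rA\t[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]\t2",
               "rB\t[C:1](=O)[OH].[NX3;H2:2]>>[C:1](=O)[N:2]\t2"),
             rules)
  subs <- c(acid_1 = "CC(=O)O", acid_2 = "CCC(=O)O",
            amine_1 = "CN", amine_2 = "CCN")
  rows <- c("substrate_id\tsmiles\treaction_id\tposition")
  for (rid in c("rA", "rB")) {
    rows <- c(rows,
              sprintf("%s\t%s\t%s\t0", c("acid_1", "acid_2"),
                      subs[c("acid_1", "acid_2")], rid),
              sprintf("%s\t%s\t%s\t1", c("amine_1", "amine_2"),
                      subs[c("amine_1", "amine_2")], rid))
  }
  writeLines(rows, blocks)
  loadLibrary(rules, blocks)
})

# published reference binders of the WDR40 campaign, built from their
# printed names (1-methyl-4-phenyl-triazolylmethyl / methylsulfanyl-benzyl
# anilines carrying a 1H-tetrazol-1-yl group)
COMPOUND_A <- "Cn1nnc(-c2ccccc2)c1CNc1cccc(-n2cnnn2)c1"
COMPOUND_D <- "CSc1ccc(CNc2cccc(-n3cnnn3)c2)cc1"
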