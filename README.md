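# evoscreen

Evolutionary screening of ultra-large combinatorial compound libraries, and
the complete hit-triage cascade that follows it.

Make-on-demand chemical catalogs (Enamine REAL and its peers) define
billion-member compound spaces implicitly: reaction templates ("building
rules", reaction SMARTS with two or three components) combined with
reactant lists ("building blocks", SMILES with declared usages).  Screening
such a space by docking every member is impossible.  evoscreen implements
the strategy used in ultra-large library screening campaigns such as the
CACHE challenge on the WDR40 domain of LRRK2: a genetic algorithm that
searches the space of library *addresses* — (reaction, substrate tuple) —
using a size-normalized docking score as fitness, followed by a staged
triage that reduces hundreds of thousands of scored molecules to a
purchasable selection.

The fitness and filtering currency throughout is **lid_root2**, the docking
interface score divided by the square root of the heavy-atom count:

    lid_root2 = interface_delta / sqrt(heavy_atoms)     [REU · atoms^(-1/2)]

more negative is better, and the square-root normalization removes the size
advantage of large molecules.  The cascade stages, each exposed as a
package function and composed by `runScreen()` / `runExpand()`:

1. independent evolutionary runs over the library (`runEvolution()`,
   mutation of substrates/reactions, crossover, linear-rank selection with
   elitism, complete run logging including discarded molecules);
2. hard physicochemical filters, the 0/1/2 traffic-light property banding
   (total > 2 removed), and PAINS substructure screening (`firstFilter()`);
3. redocking filters: lid_root2 cutoff at −3.5, redock-consistency deltas
   bounded by 0.8, receptor-ensemble consensus with standard deviation
   ≤ 0.5 (`scoreThresholdFilter()`, `redockConsistencyFilter()`,
   `ensembleConsensusFilter()`);
4. ECFP4/Tanimoto diversity clustering into 100 groups and greedy
   similarity pruning to an exact purchase budget (`clusterCompounds()`,
   `similarityBudgetPrune()`);
5. hit expansion by partner enumeration (`expandPartners()`), off-target
   counter screening, and binding-site post-processing: per-residue
   contact consensus maps at 4 Å and RMSD-score funnel tables
   (`residueContactMap()`, `funnelTable()`).

Docking itself is behind a pluggable oracle contract: the bundled
`syntheticOracle()` (a planted similarity landscape, deterministic under a
seed) makes every stage runnable and testable offline, and `tableOracle()`
replays score tables produced by an external engine such as RosettaLigand.
Chemistry plumbing (canonical SMILES, logP/TPSA/MW, ECFP4, SMARTS matching)
is delegated to OpenBabel via Bioconductor's ChemmineR/ChemmineOB; reaction
product assembly from atom-mapped templates is implemented in the package.

## Worked example

A desk-scale campaign on a generated 120-product amide library with a
planted-optimum oracle:

```r
library(evoscreen)

lib_files <- makeToyLibrary("demo", list(amide = c(10L, 12L)), seed = 1L)
lib <- loadLibrary(lib_files$rulesPath, lib_files$blocksPath)
lib
#> CombinatorialLibrary with 1 reaction(s), 22 substrate(s)
#>   usable reactions: 1  enumerable products: 120

landscape <- makePlantedLandscape(lib, seed = 1L)
cfg <- evolutionConfig(seedSize = 20L, survivors = 8L, generations = 8L,
                       offspringPerGeneration = 24L, elitismCount = 2L,
                       seed = 1L)
log <- runEvolution(lib, landscape$oracle, cfg, runId = "demo")
log
#> RunLog demo : 73 distinct molecules over 8 generations
#>   best fitness: -9.789  oracle calls: 73  cache hits: 138

head(generations(log)[, c("generation", "evaluated", "best_fitness",
                          "median_fitness")], 4)
#>   generation evaluated best_fitness median_fitness
#> 1          1        24    -8.309221      -5.710581
#> 2          2        24    -9.788854      -5.941107
#> 3          3        24    -9.788854      -5.955521
#> 4          4        24    -9.788854      -7.279839
```

The best fitness is monotone (elitism) and plateaus once the planted
optimum is found.  The run evaluated 73 of 120 products; checking the
search result against the recorded brute-force ranking:

```r
best <- individuals(log)[which.min(individuals(log)$fitness), ]
best$key
#> [1] "r_amide|acid_01+amine_06"
landscape$ranking$rank[landscape$ranking$key == best$key]
#> [1] 1
```

First-stage triage of some evaluated molecules, with full audit:

```r
ff <- firstFilter(head(individuals(log)$product_smiles, 5))
ff$audit[, c("mw", "logp", "hbd", "hba", "rotb", "total", "stage")]
#>         mw   logp hbd hba rotb total         stage
#> 1 231.3333 3.4463   1   2    4     1          pass
#> 2 332.2349 4.7225   1   2    5     3 traffic_light
#> 3 329.1767 3.7446   1   2    2     1          pass
#> 4 287.0970 2.5743   1   2    2     1          pass
#> 5 283.3648 3.4523   2   3    6     2          pass
```

Row 2 carries a traffic-light total of 3 (logP band 2 plus an Fsp³ band)
and is removed; a total of exactly 2 survives.  The descriptor conventions
reproduce the printed profiles of the campaign's published binders — e.g.
`computeProperties()` on the 332.4 Da triazole/tetrazole aniline returns
MW 332.4, one H-bond donor, eight acceptors (Lipinski N+O), five rotatable
bonds.

The end-to-end pipeline with manifest, clustering and budget pruning:

```r
cfg <- pipelineConfig(lib_files$rulesPath, lib_files$blocksPath,
                      oracle = landscape$oracle, nRuns = 2L,
                      redockTop = 15L, clusterK = 5L, nTarget = 8L,
                      seed = 1L, outDir = "demo/run1")
out <- runScreen(cfg)    # writes demo/run1/manifest.json, selection.csv
```

A command-line front end over the same functions ships in
`inst/cli/evoscreen.R` (`enumerate`, `evolve`, `filter`, `cluster`,
`prune`, `site-map`, `funnel`, `fixtures`, `report`).

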