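---
title: "Methods: evolutionary screening of combinatorial libraries and the hit-triage cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolutionary screening of combinatorial libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoscreen)
```

# The problem

Make-on-demand chemical catalogs define their compound space implicitly: a
few thousand reaction templates (building rules, as reaction SMARTS with two
or three components) combined with reactant lists (building blocks, as
SMILES with declared usages) enumerate to tens of billions of products.
Exhaustive docking of such a space is impossible; evoscreen implements the
alternative used in ultra-large library screening campaigns against the
WDR40 domain of LRRK2: an evolutionary (genetic) search over library
*addresses* — (reaction, substrate tuple) — with a docking score as fitness,
followed by a multi-stage triage cascade that turns hundreds of thousands of
scored molecules into a purchasable candidate list.

The package covers the complete computational pipeline at desk scale:
library parsing and product assembly, the evolutionary engine, the
physicochemical triage, fingerprint clustering and budget pruning, hit
expansion, off-target counter screening, and structural post-processing of
docked poses.  Physics-based docking itself is outside the package; it is
abstracted behind a docking-oracle contract so that either the bundled
synthetic landscape or score tables from an external engine (RosettaLigand
or similar) drive the cascade.

# Product assembly from reaction SMARTS

`assembleProduct()` turns an address into a structure by applying the
reaction template to the ordered substrates.  OpenBabel (through
ChemmineR/ChemmineOB) performs the reactant-template substructure matching,
so the full SMARTS vocabulary is available on the reactant side; the product
construction itself is graph surgery on the package's own molecular graphs:

* mapped template atoms survive with their out-of-template substituents;
* matched but unmapped reactant atoms are deleted (leaving groups), along
  with any fragments this disconnects;
* unmapped product-template atoms are created fresh;
* bonds among product atoms are exactly those the product template writes;
* hydrogen counts at the reaction center are recomputed from standard
  valence rules unless the product template pins them (`[NH:2]`).

Two dialect restrictions keep the engine predictable and are enforced with
clear errors: recursive SMARTS (`$(...)`) is not accepted inside reaction
templates, and the product side must be SMILES-like (bracket atoms with
optional H count, charge and atom map).  Both restrictions are irrelevant
for the coupling-style chemistry that combinatorial catalogs are built
from (amide/sulfonamide couplings, di-substitutions on a core).

When a template matches a substrate in several places, each placement yields
a product; the lexicographically smallest canonical SMILES is kept.  This is
a determinism device, not a chemical claim: without reaction conditions
there is no principled way to prefer one site, and a fixed total order makes
every address reproducible.  All canonicalization and deduplication in the
package go through one writer (OpenBabel canonical SMILES), so address
caches, score caches and cross-run merges agree on molecule identity.

# The fitness currency: lid_root2

Docking interface energies scale with molecular size, so raw scores favor
large molecules.  The pipeline's fitness and filtering currency is the
interface score divided by the square root of the heavy-atom count
(`lidRoot2()`), in REU per square root atom.  All thresholds in the cascade
are expressed in this unit: the selection cutoff (−3.5), the redocking
consistency bound (0.8), and the ensemble consensus band (0.5).  "Better"
always means *at or below* a threshold: scores are negative-better, ties at
a boundary are kept, which makes boundary behavior testable and removes
dependence on floating-point coincidence.

# The evolutionary engine

`runEvolution()` follows the campaign protocol: a 200-molecule random seed
population reduced to 50 survivors by rank-based selection, then 30 cycles
in which survivors produce several hundred offspring.  Defaults (all
config-exposed in `evolutionConfig()`):

| parameter | default | role |
|---|---|---|
| seedSize | 200 | random initial population |
| survivors | 50 | population after selection |
| generations | 30 | cycles |
| offspringPerGeneration | 300 | children per cycle |
| p(substrate mutation) | 0.45 | local optimization |
| p(reaction mutation) | 0.10 | scaffold hops |
| p(crossover) | 0.35 | recombination of promising compounds |
| p(immigrant) | 0.10 | fresh random exploration |
| elitismCount | 5 | deterministic survival of the best |

The operator mixture is a design choice: the protocol this mirrors states
only that operator rates balance local optimization, escape from local
minima, and exploration.  The defaults realize those three roles and are
deliberately ordinary; nothing in the package depends on their exact
values, and the tests exercise the engine at much smaller settings.

Selection is linear ranking: after sorting by fitness (ties broken by
molecule key, so selection is reproducible), individual at rank r is drawn
without replacement with weight N − r + 1; the `elitismCount` best survive
deterministically, which makes the per-generation best fitness monotone —
the observed behavior of converging score trajectories.  Crossover between
parents of different reactions is undefined (their slot lists are
incompatible); those pairs fall back to substrate mutation so the offspring
budget stays full.

Every evaluated genotype is logged, including discarded ones, but a
genotype is never docked twice: scores are cached by canonical product
SMILES and receptor.  Distinct addresses occasionally collapse to the same
product (symmetric substrates), so oracle calls can be fewer than logged
addresses; the run log records both counts.

# The synthetic docking oracle

Offline testing needs a landscape whose optimum is known.
`syntheticOracle()` scores a molecule as

```
base = -A * tanimoto(ecfp4(mol), ecfp4(motif)) - B * sqrt(heavy_atoms)
```

with A = 8 REU (similarity weight) and B = 0.4 REU per √atom (size reward),
per-pose rank offsets, and optional seeded Gaussian noise.  The planted
motif is the optimum of its size class by construction, and similarity to
it is monotonically rewarded — the property the engine's recovery tests
rely on.  Noise streams are derived per (molecule, receptor) from the
oracle seed, so results are independent of evaluation order and whole
pipeline runs are bit-identical under one seed.  `makePlantedLandscape()`
additionally records the full brute-force ranking of an enumerable library,
computed by direct enumeration rather than through the oracle object, so
searches are validated against an independently produced ground truth.

What the synthetic landscape deliberately does not emulate: docking-score
noise correlated with chemotype, receptor-dependent pose physics, and the
scoring-function exploitation that real sampling-based docking invites.
Passing the recovery tests therefore demonstrates correctness of the
search and triage machinery, not virtual-screening performance on real
targets.

# First-stage triage

`firstFilter()` applies three gates in a fixed, audited order:

1. **Hard property bounds** — MW 150–500 Da, logP −1 to 5, rotatable bonds
   ≤ 10, H-bond donors ≤ 5, acceptors ≤ 12 (round 1) or ≤ 10 (round 2).
   PSA and Fsp³ are computed but never hard-filtered.
2. **Traffic lights** — each of logP, MW, PSA, rotatable bonds and Fsp³ is
   banded 0/1/2 and summed; totals above 2 are removed (a total of exactly
   2 survives).  The published scheme's K_D and solubility columns are
   experimental quantities and are represented as absent, not zero.
3. **PAINS** — any match in the substructure catalog rejects the molecule,
   reported by pattern name.

Descriptor conventions are fixed so the two published reference binders of
the WDR40 campaign reproduce their printed values exactly (MW 332.4 / 297.4
Da, HBD 1/1, HBA 8/5, rotatable bonds 5/5): acceptors are the Lipinski N+O
atom count (sulfur never counts), donors are hydrogens on N or O, and a
rotatable bond is an acyclic single bond between two non-terminal heavy
atoms with amide C–N excluded.  logP (Crippen-type) and topological PSA
come from OpenBabel; printed logP values are treated as approximate (the
original campaign used a different toolkit), and the tests accept ±0.5.

The banding scheme's printed boundaries are open ("<3", ">4"), leaving the
boundary values undefined; they are resolved half-open with the *worse*
band winning at an edge (logP exactly 3 scores 1, exactly 4 scores 2; MW
400/500, PSA 120/140 likewise; Fsp³ scores 0 above 0.3, 1 in (0.2, 0.3], 2
at or below 0.2).  Choosing the stricter band is conservative for a
desirability penalty and is asserted by tests so the policy cannot drift.

The bundled PAINS catalog is a compact set of the classic interference
substructure classes (quinones, catechols, rhodanines, hydrazone phenols,
azo aryls, isothiazolones, alkylidene barbiturates, ...) written as this
package's own SMARTS; it is intentionally small and documented as such.
Production screening should supply a full published catalog via
`painsScreen(catalogPath = ...)` in the same two-column TSV format — the
same mechanism accepts any custom SMARTS blocklist.

# Score-based filters

* `scoreThresholdFilter()` — keep-better mode retains molecules at or below
  the cutoff (on-target triage); exclude-better removes them, which is the
  off-target counter screen: candidates predicted to bind the anti-target
  well are discarded.
* `redockConsistencyFilter()` — two deltas per molecule: |search score −
  best redock score| and the spread across the ten best redock poses.  The
  molecule fails when *either* exceeds 0.8.  The OR reading is the
  conservative resolution of an ambiguous rule ("a difference in both
  calculations"); the laxer AND variant is available via `rule = "and"`.
* `ensembleConsensusFilter()` — consensus is the arithmetic mean of
  per-model best scores (mean chosen over best-of: it uses all models and
  is the usual consensus-docking aggregate), and molecules are kept only
  when the population standard deviation across models is ≤ 0.5.  The
  population form is used because the receptor models are the complete
  ensemble, not a sample from one.

# Clustering and budget pruning

Diversity grouping into k = 100 clusters uses ECFP4 fingerprints (hashed
circular substructures, diameter 4; 4096-bit OpenBabel hash folded to a
configurable 2048 bits).  "k-means based on Tanimoto similarity" is
internally inconsistent — k-means needs a vector mean, Tanimoto is a set
similarity — so the default runs k-means (Lloyd) on the raw bit vectors,
and a k-medooid alternative (`method = "kmedoids"`, PAM under 1 − Tanimoto)
provides the literal-metric reading.  Both are seeded and reproducible;
which variant produced the original campaign's clusters is unknowable from
the outside, and on constructed two-family fixtures k-means separates the
families perfectly while PAM is slightly less crisp.

`similarityBudgetPrune()` reduces a candidate list to an exact purchase
budget: repeatedly find the most similar pair and drop its worse-scoring
member, recomputing the most similar pair after every removal (the literal
reading of the published procedure; O(n²) per step is irrelevant at a few
hundred candidates).  Similarity ties resolve by lexicographic key pair,
score ties keep the earlier key, and the removal audit trail is returned so
the operation is fully replayable.

# Structural post-processing

`residueContactMap()` counts, per receptor residue, the number of distinct
compounds with any heavy atom within 4 Å of any residue heavy atom — one
count per compound, using its best-scored pose.  Hydrogens are ignored on
both sides (docked structures vary in protonation).  Counts are binned for
visualization; the published bin edges overlap at their boundaries, so they
are implemented half-open descending (>500, (400,500], (200,400],
(100,200], ≤100).

`ligandRmsd()` is the fixed-correspondence heavy-atom RMSD without
re-superposition: poses share the receptor frame, so rigid displacement is
binding-mode signal.  Graph-symmetry-aware RMSD is out of scope.
`funnelTable()` assembles the RMSD-versus-score table against the
best-scoring pose, computing RMSD only for poses with interface score at or
below −10 REU (poses above the floor carry NA — they are too poorly scored
to inform convergence).  A positive rank correlation between RMSD and score
is the funnel signature of a converged binding mode.

# Fixtures and problem sizes

The synthetic-data module generates everything the tests consume:

* toy libraries in the loader's TSV dialect, built from curated
  reliably-reactive substrate pools (carboxylic acids, primary amines,
  sulfonyl chlorides, 1,2-diamines) so test signal isolates engine behavior
  from chemistry edge cases; aromatic-only and aliphatic-only families give
  structurally separable products for clustering tests;
* planted landscapes with recorded brute-force rankings;
* toy receptor/pose systems (minimal PDB + SDF) with planted residue
  contacts and funnel or scatter pose geometry.

The test suite and the acceptance script run the engine on a 1200-product
library (30 × 40 amide space) with populations of 40, 12 survivors, 30
offspring and 10 generations — sizes chosen so the whole suite exercises
every stage, including five independent search seeds, in about a minute of
CPU.  At these settings the search recovers the brute-force optimum on all
tested seeds while evaluating roughly 15 % of the library; the full-scale
protocol defaults remain 200/50/300/30.

# Known limitations

* The synthetic oracle is a similarity landscape; it cannot surface
  scoring-function pathologies of real docking engines.
* Reaction templates with recursive SMARTS or non-SMILES product sides are
  rejected rather than supported.
* Stereochemistry is not enumerated; stereo descriptors in input SMILES are
  accepted but ignored in product assembly.
* The bundled PAINS catalog is a representative subset; campaign-grade
  screening should load a full published list.
* Manual steps of the original campaign (expert hit picking, visual pose
  inspection) are represented by their decision-support products — cluster
  sheets, top-pose tables, funnel tables — not automated away.
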