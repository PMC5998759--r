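# rwrDTI

Drug-target interaction (DTI) prediction with network-weighted features.

Identifying which proteins a small-molecule drug binds is central to drug
discovery, and experimental screening is slow and expensive. rwrDTI is for
computational chemists and bioinformaticians who want to predict candidate
drug-target pairs from three widely available ingredients: a
protein-protein interaction (PPI) network with confidence scores, known
drug-target pairs (from which a shared-target drug-drug interaction (DDI)
network is derived), and per-entity feature vectors — 1024-bit molecular
fingerprints for drugs and a 1287-dimensional primary-structure descriptor
for proteins (amino acid/dipeptide composition, normalized Moreau-Broto,
Moran and Geary autocorrelations, and composition/transition/distribution
statistics).

## Method

Raw features ignore the interactome. The package smooths them with a
random walk with restart (RWR) on each network before training. For a seed
node with indicator vector *q*, the walk

&nbsp;&nbsp;&nbsp;&nbsp;r ← (1 − c) Ã r + c q

converges to the seed's affinity distribution over the network, where Ã is
the column-stochastic normalized adjacency matrix and c ∈ (0, 1] the
restart probability (default 0.25). Stacking the fixed points of all seeds
gives the affinity matrix W (every row sums to 1, diagonal ≥ c), and
weighted features are the matrix product W·F: each entity's smoothed
features are an affinity-weighted convex mixture of the features of the
entities around it — unlike one-hop "guilt-by-association" averaging
(included as the baseline `gbaWeighting()`), the walk sees the whole
topology while always retaining at least a c fraction of the entity's own
signal.

Each (drug, protein) pair becomes a 2311-dimensional vector (drug block ++
protein block), positives are balanced against replicate random negative
sets (20 by default), and pairs are classified with a k-nearest-neighbour
model under the cubic distance d(x, y) = (Σ|xᵢ − yᵢ|³)^(1/3). Evaluation
is threshold-free ROC/AUC, reported as mean ± sd across negative sets,
with paired t-tests between weighting schemes and a restart-probability
sweep utility.

## Worked example

Everything below is runnable offline: the synthetic-data generator builds
a modular interactome in which drugs acting in the same module share
targets and carry correlated fingerprints — the structure the weighting
exploits.

```r
library(rwrDTI)

## the restart walk on a worked two-node example (c = 0.5)
net <- interactionNetwork("A", "B")
rwr(net, "A", rwrConfig(restartC = 0.5))
#>         A         B
#> 0.6666667 0.3333333

## a seeded synthetic world: block-model PPI, planted DTIs, DDI cliques
w <- generateWorld(rngSeed = 1)
w
#> SyntheticWorld
#>   PPI: 100 proteins, 386 edges
#>   DDI: 20 drugs, 40 edges
#>   DTI: 60 training pairs, 20 held-out pairs

protF <- proteinDescriptorMatrix(w@sequences)   # 100 x 1287

res <- runPipeline(w@dti, w@testDti, w@fingerprints, protF, w@ddi, w@ppi,
                   weighting = "rwr", config = rwrConfig(restartC = 0.25),
                   nSets = 20, rngSeed = 1)
raw <- runPipeline(w@dti, w@testDti, w@fingerprints, protF, w@ddi, w@ppi,
                   weighting = "none", nSets = 20, rngSeed = 1)
sprintf("RWR-weighted : %.3f (+/- %.3f)", res$meanAuc, res$sdAuc)
#> "RWR-weighted : 0.925 (+/- 0.033)"
sprintf("unweighted   : %.3f (+/- %.3f)", raw$meanAuc, raw$sdAuc)
#> "unweighted   : 0.473 (+/- 0.058)"
pairedTTest(res$aucPerNegativeSet, raw$aucPerNegativeSet)$p
#> 1.5e-17
```

The weighted model separates held-out positives from negatives (AUC 0.925
averaged over 20 negative sets) while the same pipeline on raw features
sits at chance (0.473): the protein sequences are random, so all module
signal in the protein block is injected by the network weighting.

Real data drop in the same way: `readPPI()` (TSV edge list with a strict
confidence threshold, e.g. `> 800` on the 0-1000 scale), `readDTI()` (TSV
pair list), `readFingerprints()` (CSV), `readSequences()` (FASTA), then
`buildDDISharedTarget()` and the same calls as above. A thin command-line
wrapper with `simulate`, `evaluate` and `sweep-c` subcommands is installed
at `inst/scripts/rwr-dti.R`.

See the vignette (`vignettes/network-weighted-dti.Rmd`) for the model
assumptions, parameter choices and the limits of the synthetic benchmark.

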