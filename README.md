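# slnet

Synthetic-lethality (SL) screening of cancer gene pairs on protein–protein
signaling networks, with drug-target annotation and validation.

## The problem

Two genes are synthetic-lethal when a cell tolerates the loss of either one
but dies when both are lost. If a tumor already carries an inactivating
mutation in a cancer gene *m*, a drug inhibiting an SL partner gene *n*
should kill tumor cells while sparing normal cells — which makes the
*non-cancer* partner of an SL pair a candidate anticancer drug target.
`slnet` predicts such pairs computationally, treating the human signaling
network as a proxy for the cell: gene pairs whose joint knockout
disproportionately disrupts network communication are SL candidates.

## The method

For a network with average shortest path length

$$D = \frac{1}{\tfrac{1}{2}N(N-1)} \sum_{i>j} d_{ij},$$

each (cancer gene *m*, non-cancer gene *n*) pair receives a **stability
score**

$$S = \frac{2D_{m,n} - D_m - D_n}{D_0},$$

where $D_0$ is the intact network's value and $D_m$, $D_n$, $D_{m,n}$ are the
values after deleting $\{m\}$, $\{n\}$ and $\{m,n\}$. $S$ isolates the
*pair-specific* destabilization: a change caused by one hub alone cancels
out. Significance comes from an empirical p-value against 1000
degree-preserving edge-swap randomizations,
$p = \#\{S_\mathrm{random} > S_\mathrm{obs}\}/1000$. Significant pairs then
pass three screens:

1. **Distance** — keep pairs no farther apart than the (floored) mean
   cancer/non-cancer pair distance;
2. **Frequency** — keep non-cancer genes in the shortest prefix carrying 50%
   of all cancer↔non-cancer shortest-path traversals;
3. **Function** — hypergeometric gene-set enrichment (BH-adjusted); a pair
   survives only if both genes sit in a significantly enriched set.

Surviving non-cancer genes are annotated with drug–target records and
validated through three channels: overlap with an SL reference
(SynLethDB-style pair tables), drug-sensitivity support (a cell line mutated
in the SL partner is highly sensitive, log-IC50 < 0, to a drug hitting the
target), and a literature hypergeometric test
$P = 1 - \sum_{i=0}^{x-1}\binom{M}{i}\binom{N-M}{K-i}/\binom{N}{K}$.

## Worked example

The package ships a seeded generator that builds a scale-free network with
planted "bridge" pairs — a cancer gene and a non-cancer gene engineered to be
the two short bridges between a node group and the rest of the network, the
topological signature the stability score is designed to detect:

```r
library(slnet)
bundle <- synthBundle(seed = 1)   # 200 nodes, 20 cancer genes, 5 planted pairs
writeFixtureBundle(bundle, "bundle")
cfg <- pipelineConfig("bundle", "out", nRandom = 100, seed = 1)
mf  <- runPipeline("all", cfg)
str(mf$counts)
```

```
 $ candidate_pairs       : int 1080
 $ pairs_scored          : int 1080
 $ pairs_network_distance: int 50
 $ pairs_frequency       : int 34
 $ pairs_final           : int 8
 $ targets_annotated     : int 5
 $ targets_triple        : int 4
```

1080 candidate pairs (top-30% non-cancer genes × 20 cancer genes) shrink to
50 after the network + distance screen, 34 after the frequency screen and 8
final SL pairs; all 5 planted pairs are among them. The 5 planted non-cancer
genes carry drug-target records and 4 pass all three validation channels —
matching the fractions the generator wired into the reference and
sensitivity tables. Stage outputs are plain TSV under `out/`
(`scored_pairs.tsv`, `final_pairs.tsv`, `targets.tsv`, `validation.json`).

A thin command-line wrapper is installed at `inst/scripts/slnet.R`:

```sh
Rscript inst/scripts/slnet.R synth --out demo --seed 1 --n-random 100
```

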