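---
title: "Network-stability screening for synthetic-lethal drug targets: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-stability screening for synthetic-lethal drug targets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slnet)
```

## Model and assumptions

`slnet` treats the human signaling network as a functional proxy for the
cell: communication between proteins runs along short paths, and the average
shortest path length

$$D = \frac{1}{\tfrac12 N(N-1)}\sum_{i>j} d_{ij}$$

summarizes how efficiently the network communicates. A synthetic-lethal
(SL) interaction between a mutated cancer gene $m$ and a non-cancer gene $n$
should show up as a *pair-specific* loss of communication: deleting both
nodes degrades $D$ far more than deleting either alone. The stability score

$$S = \frac{2D_{m,n} - D_m - D_n}{D_0}$$

captures exactly that contrast. Writing $\Delta_x = D_x - D_0$, the score is
$(\Delta_{m,n} - \Delta_m) + (\Delta_{m,n} - \Delta_n)$ over $D_0$: the
excess of the joint effect over each single effect. A hub whose removal
alone stretches paths contributes equally to $D_{m,n}$ and to its own
$D_m$, so it cannot inflate $S$ by itself — that is the point of
subtracting the single removals.

The assumptions worth stating: the network is undirected and unweighted
(distances are hop counts); topology is a meaningful stand-in for function;
and the graph is treated as one fixed snapshot — no tissue specificity, no
expression conditioning.

Raw significance thresholds on $S$ would confound pair structure with node
degree, so each pair's score is calibrated against a degree-preserving null:
random simple graphs with the identical degree sequence, generated by
repeated double edge swaps (swaps creating self-loops or multi-edges are
rejected; 10 attempted swaps per edge by default). The empirical p-value is
the strict-exceedance ratio $p = \#\{S_\mathrm{random} >
S_\mathrm{obs}\}/k$ over $k$ randomized networks.

## The three screens

1. **Network screen.** Keep pairs with $p < \alpha$ (default 0.05,
   $k = 1000$ randomizations), then drop pairs whose hop distance exceeds a
   threshold — by default the floor of the mean distance over *all*
   candidate pairs. The rationale is biological: close proteins share
   processes, and an SL partnership across half the network is implausible.
2. **Frequency screen.** Every non-cancer gene is scored by the number of
   (cancer, non-cancer) pairs for which it is interior to at least one
   shortest path. Genes in the shortest count-descending prefix carrying
   50% of the total traversal mass are kept; the same statistic, at the
   top-30% rank cutoff, selects which non-cancer genes enter the candidate
   pairing in the first place.
3. **Function screen.** Hypergeometric over-representation of the surviving
   genes in a gene-set collection (upper tail $P[X \ge k]$, BH-adjusted
   across sets at $q < 0.05$), with the whole cleaned network as the
   default background. A pair survives only if **both** genes belong to at
   least one significant set — the stricter of the two plausible rules, and
   the one consistent with the screen's purpose of keeping pairs that act
   inside cancer-relevant processes.

## Numerical and convention choices

* **Disconnection.** The $\tfrac12 N(N-1)$ denominator presumes a connected
  graph, but node removal can disconnect it. $D$ is therefore computed as
  the mean over *reachable* pairs; a strict mode errors on disconnection
  instead. Removals that leave no reachable pair mark the record degenerate
  and exclude it downstream. The reachable-pairs convention means that
  stranding a small group *removes* long pairs from the mean — a score can
  legitimately fall after a disconnecting removal — which is why the
  synthetic fixture plants bridge structures that reroute rather than
  disconnect (below).
* **Null normalizer.** For the null scores, $D_0$ is each random network's
  own average path length (the score formula applied self-consistently); a
  flag switches to reusing the observed network's $D_0$.
* **Ties and p = 0.** The strict `>` in the empirical p-value means a pair
  whose score ties the entire null (e.g. on a complete graph, where every
  $S = 0$) gets $p = 0$ and passes — a documented pathology of the
  exceedance ratio as defined. An optional $(r+1)/(k+1)$ pseudocount is
  available but off by default.
* **Caching.** Single-removal averages $D_m$, $D_n$ are pair-independent
  and cached per network; tests pin the contract that cached and uncached
  evaluation agree. The kernel itself is a masked breadth-first search in
  C++ over a CSR adjacency, cross-checked in the test suite against both
  igraph and a Floyd–Warshall oracle.
* **Frequency counting.** A node is credited at most once per (cancer,
  non-cancer) pair when it is interior to *some* shortest path — not once
  per path — because the screen asks which genes traffic passes through,
  not how many alternative routes exist. Endpoints are never credited.
* **Rank cutoffs.** The top-fraction rule uses a ceiling on the gene count;
  all orderings break count ties lexicographically so every output is
  deterministic. Percentages in validation reports are rounded half-up to
  two decimals.
* **Leaf pruning.** "Peripheral" cleanup is interpreted as a single,
  non-iterative pass removing degree-1 nodes, off by default; orphan and
  self-loop removal plus duplicate-edge collapse always run, and cleaning
  is idempotent.
* **Seeds.** One global seed drives every stochastic component through
  per-component sub-seeds derived from the component name, so adding a
  component never perturbs the draws of another, and two runs with the same
  seed produce byte-identical outputs.

## The synthetic fixture

Real inputs for this screen are large curated resources. To make every
stage testable offline, `synthBundle()` builds a seeded universe: a
Barabási–Albert network (signaling networks are heavy-tailed; an
Erdős–Rényi variant exists for null calibration), a random cancer-gene
subset, and *planted bridge pairs*. For each planted pair, a node group is
carved out of the ambient network and re-attached through exactly two short
bridges — the cancer gene $m$ and a non-cancer gene $n$ — plus one long
backup chain. Removing $m$ or $n$ alone reroutes through the other bridge
(small $\Delta$); removing both forces all group traffic through the chain
($D_{m,n} \gg \max(D_m, D_n)$) without disconnecting anything. The two
bridges share a group neighbor, so planted pairs sit at distance 2 and
survive the distance screen by construction. The non-cancer bridge is drawn
from the highest-degree free nodes so that it carries realistic
shortest-path traffic, as genuine bridge genes do — otherwise a freshly
wired bridge would be invisible to the frequency screen that real
high-traffic genes pass.

The companion tables encode the ground truth with controlled coverage:
defaults put 80% of planted pairs in the SL reference, give 80% sensitive
(log-IC50 $\in [-3, -0.5]$) cell-line records, cover all planted non-cancer
genes with drug-target rows, and give planted genes elevated
literature counts ($x/K$ far above the global rate $M/N = 0.1$ for the
cancer context and $0.01$ for the SL context) against flat decoys. One
shared gene set co-annotates all planted genes, among 20 random decoy sets.

What passing tests show — and what they do not: the fixture demonstrates
that the implementation detects the topological signature the score is
defined by, that the null is calibrated (empirical p-values are
approximately uniform on an unstructured Erdős–Rényi graph), and that the
plumbing is deterministic end to end. It does not show that real SL pairs
look like planted bridges, that signaling-network topology suffices to
predict synthetic lethality, or how the screen behaves under the noise,
bias and incompleteness of curated interactomes.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `topFraction` | 0.30 | non-cancer genes entering the pairing, by traversal rank |
| `nRandom` | 1000 | randomized networks behind each p-value |
| `alphaNetwork` | 0.05 | empirical-p cutoff of the network screen |
| `distanceMode` | `"auto"` | hop cutoff = floor of mean candidate distance |
| `massFraction` | 0.50 | cumulative traversal mass kept by the frequency screen |
| `alphaEnrich` | 0.05 | BH q-value cutoff of the function screen |
| `ic50Cut` | 0 | log-IC50 below which a cell line counts as sensitive |
| `swapsPerEdge` | 10 | edge-swap intensity per randomization |

The test suite and the acceptance script run the screen at reduced problem
sizes chosen as representative rather than exhaustive: the default bundle
(200 nodes, 20 cancer genes, 5 planted pairs) with 100 randomizations for
end-to-end recovery, 200 randomizations and 50 pairs for the uniformity
check, and 1000 randomizations of a 200-node network for degree-sequence
preservation.

## Known limitations

* The distance filter's published description is ambiguous between "strictly
  below the mean" and "at most the floored mean"; `slnet` implements the
  floored-mean rule and exposes an explicit integer threshold as well.
* An alternative reading of the frequency statistic equates it with node
  degree; `slnet` implements the shortest-path traversal count, which on
  scale-free graphs correlates with degree but is not identical to it.
* Gene identifiers are normalized only by case and whitespace; alias
  resolution is deliberately out of scope and must happen upstream.
* Directed screening is supported mechanically (distances become directed),
  but the published semantics — and all defaults and tests — are
  undirected.
* With the no-pseudocount convention, `nRandom` bounds the resolution of
  p-values (multiples of `1/nRandom`); at small `nRandom` the network
  screen is correspondingly coarse.
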