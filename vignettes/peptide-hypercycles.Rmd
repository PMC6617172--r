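---
title: "Simulating prebiotic peptide chemistry and detecting hypercycles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prebiotic peptide chemistry and detecting hypercycles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepcycle)
```

## The model

`pepcycle` simulates a well-mixed pool of oriented peptides (read N- to
C-terminus; a reversed sequence is a different species) built from the six
amino acids with plausible prebiotic synthesis routes — A, V, G, E, D and S —
supplied at fixed "chemostat" copy numbers (38 A, 4 D, 11 E, 100 G, 1 S,
10 V by default). Time is discrete. One **generation** is:

1. **Synthesis sweep.** All molecule instances are shuffled and paired
   (an odd molecule idles). A pair with sequences $s_1, s_2$ of lengths
   $L_1, L_2$ ligates with probability
   $$P = \begin{cases} c(L_1)\,c(L_2) & L_1 \le 3 \text{ and } L_2 \le 3\\
   c(L_1)\,c(L_2)\,\mathrm{simil}(s_1,s_2) & \text{otherwise,}\end{cases}$$
   where $c(L)$ is a length-dependent interaction coefficient
   (tabulated for $L \le 10$, logistic $1/(1+e^{-0.8(L-4)})$ beyond) and
   `simil` is a normalized local-alignment similarity (below). On
   acceptance the first-drawn molecule becomes the N-terminal part of the
   concatenated product and one copy of each reactant is consumed.
2. **Fragmentation sweep.** Every multi-residue *species* is tested once
   with probability $\min(1, L/\theta)$, $\theta$ the fragmentation
   threshold; on success **one occurrence** is cut at a uniformly random
   internal bond. Testing species rather than instances means an abundant
   cluster risks at most one copy per generation — this differential
   stability of abundant species is, together with similarity-gated
   ligation, what lets clusters persist and act as a dynamic memory.
3. **Replenishment.** Monomer counts are restored up to their initial
   values (the amino-acid reservoir). Residue mass is conserved exactly
   through steps 1–2; only step 3 adds mass.

The similarity factor is the model's core feedback: similar long peptides
ligate at nearly full interaction strength, so a population of mutually
similar sequences catalyses its own growth — the operational analogue of
an autocatalytic hypercycle.

## Similarity scoring

Each residue carries a physico-chemical coefficient $S_r$ (from side-chain
polarity and solvation free energy; the package treats the 20 tabulated
values as ground-truth constants). Two residues score
$S_{ij} = 10/(10+|S_i-S_j|) \in (0,1]$. Sequence pairs are scored by a
Smith–Waterman local alignment with linear gap penalty $d = 2$:
$$H_{i,j} = \max\{0,\; H_{i-1,j-1}+S_{ij},\; H_{i-1,j}-d,\; H_{i,j-1}-d\}$$
with zero boundaries. Because $\max S_{ij} = 1 < d$, gapped paths are never
optimal under the defaults; the gap branches are nevertheless implemented
(the recursion is the standard one, and a user can lower `gap`). Two
normalizations of $\mathrm{maxH}$ are exposed:

* `simil` = $\min(1, \mathrm{maxH}/\min(L_1,L_2))$ — used in the synthesis
  probability. Self-similarity is exactly 1 (the diagonal accumulates
  exact 1.0 terms, so no floating-point slack is needed).
* `cluster_distance` = $1 - \min(1, \mathrm{maxH}/\max(L_1,L_2))$ — used
  for clustering and cross-run cluster matching.

The min-normalized score makes a peptide *identical* (distance 0) to every
longer peptide that locally contains it. That is the right notion for
reactivity (a short template can seed a long product) but it is unusable
as a clustering distance: monomers would be at distance ~0 from almost
everything and single linkage would chain the entire pool into one
cluster. Normalizing by the longer length makes the distance sensitive to
both composition and length — "clustered by length and similarity" — while
preserving the defining property that identical sequences have distance 0
and the conventional cutoff value 0.300.

## Epochs and clustering

After every `generations_per_epoch` generations (default 400) the
generated polymers are reduced: sequences are clustered on pairwise
`cluster_distance` with a hierarchical cut at 0.300, each cluster keeping
one representative (highest occurrence count; ties to the shorter, then
lexicographically smaller sequence) that inherits the summed occurrences.
The reduced pool seeds the next epoch; 20 epochs of 400 generations
(8000 generations) is the default protocol.

Three clustering choices deserve justification because the underlying
procedure they replace (multiple alignment plus model-based distances in
an external GUI tool) leaves them open:

* **Linkage.** The default is *complete* linkage. Under single linkage the
  populated "length ladder" chains: $d(L, L+1) = 1 - L/(L+1) \le 0.3$ for
  every $L \ge 3$, so all polymers merge into one cluster whose
  representative (the most abundant, hence shortest member) replaces
  them — every epoch would reset the pool to trimers and length could
  never accumulate. Complete linkage yields compact clusters coherent in
  length and composition. `linkage = "single"` remains available and is
  tested against a connected-components oracle.
* **Monomer exemption.** The protocol clusters the polymer sub-pool only;
  the monomer food set passes through epochs untouched. Aligning length-1
  sequences is degenerate, and merging distinct amino acids (A, V, S sit
  within 0.3 of G) would convert the food inventory into glycine at every
  epoch boundary while replenishment re-injects the originals — a runaway
  glycine pump that, in practice, swamps the pool with monomers and caps
  polymer length. `cluster_pool()` itself still partitions whatever pool
  it is given, monomers included.
* **Representative rule.** Count-first with deterministic ties; the
  alternative (e.g. longest member) would bias length upward with no
  physical justification, since the representative stands for the
  cluster's reactive mass.

## Perturbation experiments

* **Knockout / restart** (`knockout_and_restart`): zero one cluster at an
  epoch boundary (default epoch 4) and replay the remaining epochs. Each
  epoch has its own seed drawn once from the master seed, so the baseline
  and knockout runs are identical up to the knockout and the replay is
  bit-exact for a null knockout (deleting nothing). Baseline
  representatives seen after the knockout epoch that match no knockout-run
  representative within 0.300 form the **co-extinct set** — the signature
  that they depended on the deleted cluster. The target's own cluster
  counts as co-extinct when it fails to re-form; if it is rebuilt de novo
  it is reported in a separate `reformed` field. Target selection
  (`select_knockout_target`) mirrors experimental practice: among polymer
  clusters whose pre-knockout trajectory is non-monotone, take the longest
  (most developed); rules `"longest"` and `"abundant"` are also provided.
* **Oscillation detection** (`detect_oscillations`): counts strict sign
  changes in the first differences of each cluster trajectory (zero
  differences skipped; clusters are tracked across epochs by
  threshold-matching representatives, so identity survives representative
  drift). Two or more direction changes flag an oscillation candidate.
  Periodic abundance is a necessary but not sufficient hypercycle
  signature, and the two-change criterion is an operationalization — it is
  configurable, not canonical.
* **Hypercycle membership** (`hypercycle_membership`): knockout targets
  whose co-extinct sets overlap are grouped (with the union of their
  co-extinct sets) into one inferred hypercycle; the grouping is
  order-independent.
* **Glycine sweep** (`glycine_sweep`): one full protocol per initial
  glycine count (75–124 by default, i.e. 50 conditions), condition $i$
  seeded with `seed + i`. Final-epoch clusters are matched across
  conditions at the clustering threshold and summarised as mean ±
  standard deviation of per-condition occurrences (absent conditions
  count 0).

## Numerical and reproducibility choices

* One R RNG stream drives everything, consumed in a fixed documented
  order (pairing shuffle, per-pair acceptance draws, per-species
  fragmentation draws, cut sites); per-epoch seeds are drawn once from
  the master seed, keeping any derived seed below $2^{31}$.
* Scores are kept as doubles; no rounding of $S_{ij}$. Distances of
  exactly 0.300 fall inside the cluster (the cut is inclusive).
* The fragmentation threshold defaults to 60: it must exceed the longest
  representative the model is expected to support (50+ residues), and at
  60 a 30-mer still fragments with probability 0.5 per tested generation.
* Degenerate inputs error early: empty pools and sequences, monomer
  fragmentation, unknown residue codes (reported by letter), thresholds
  below 2.

## What the synthetic experiments do and do not show

The package's tests run desk-scale protocols (typically 3–8 epochs of
20–200 generations from the standard 164-molecule pool; the acceptance
suite uses 6 × 50 with ten seeds) rather than the full 20 × 400 protocol.
At that scale the model reproduces the qualitative phenomenology:
polymers accumulate, length-banded clusters coexist, trajectories are
non-monotone in essentially every seeded run, and null knockouts replay
exactly.

Co-extinction after a real knockout is a much weaker signal at desk
scale. The six-letter alphabet puts four residues (A, V, G, S) within
pairwise similarity 0.81–0.97 of each other, so at threshold 0.300 any
two clusters in the same length band match across runs; a knockout can
then only be detected as a loss of the length frontier, and within a
short post-knockout window both runs usually repopulate the same bands.
A finer distance (the replaced external pipeline's model-based distances)
or longer runs would sharpen the signal; the package reports the
machinery and its honest desk-scale behaviour rather than forcing the
outcome.

Nothing here models spatial structure, surfaces, wet–dry cycling,
chirality, folding or continuous-time kinetics; "hypercycle" claims are
operational (oscillation plus co-extinction), not chemical-kinetic proof
of autocatalysis.

## A worked desk-scale run

```{r example, eval = FALSE}
cfg <- protocol_config(epochs = 6, generations_per_epoch = 50)
h <- run_protocol(cfg, seed = 1, verbose = TRUE)
h$stats                       # per-epoch cluster counts and event totals
occurrence_matrix(h)[1:5, ]   # abundance trajectories
target <- select_knockout_target(h, epoch = 4)
knockout_and_restart(h, target, epoch = 4)
```
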