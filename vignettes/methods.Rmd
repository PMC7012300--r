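---
title: "Methods: stability and reproducibility of gene-family trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stability and reproducibility of gene-family trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `treestab`, the
meaning and defaults of every tuning parameter, the numerical choices that
make results deterministic, and the limitations of the approach.

## 1. The problem

A bootstrap proportion on a single branch (Pb) answers a local question:
how often does this one bipartition reappear under resampling? It does not
answer the question users usually care about: *is the tree as a whole
right?* A tree can carry moderate support on every branch and still almost
never be reproduced in full, because the probability of jointly recovering
all branches decays multiplicatively.

`treestab` therefore works at the level of whole (sub)tree topologies:

- **Ps (stability)** asks how concentrated the bootstrap distribution of a
  clade's rooted topology is on its mode.
- **Pr (reproducibility)** asks whether an *independent* dataset — the
  paralogous gene family created by the same duplication — recovers the
  same topology.

High Ps with low Pr is the signature of consistent bias (e.g. long-branch
effects reproduced by resampling but not by independent data); low Ps means
the data simply cannot resolve the clade.

## 2. Tree inference: NJp

Trees are built by neighbor joining on the proportion of differing sites
(p-distance), the combination usually called **NJp**. Rationale: the
bootstrap loop re-estimates a tree thousands of times, and under the
simple substitution regimes where these statistics are interpretable,
p-distance NJ is fast, consistent, and free of model-fitting failures on
resampled data (a maximum-likelihood replicate can fail to converge; NJp
cannot).

Details that matter for exactness:

- **Deletion mode.** `deletion = "complete"` (default) drops every column
  containing `-` or `N` in *any* sequence, so all pairs are compared on the
  same sites; `"pairwise"` keeps, per pair, the columns complete in that
  pair. Complete deletion is the default because the bootstrap resamples
  columns, and pairwise deletion makes the effective alignment differ per
  pair within one replicate. A pair (or alignment) with zero comparable
  columns is an error (`treestab_data_error`), not a silent `NaN`.
- **Tie-breaking.** When two joins tie on the Q-criterion (within a
  relative tolerance of `1e-12`), the join whose clusters have the
  lexicographically smallest representative labels (C-locale order) wins.
  This makes the inferred tree a pure function of the labelled distance
  matrix — independent of input record order.
- **Negative branch lengths.** NJ algebra can produce small negative
  branch lengths. They are clamped to zero *in the written tree only*; the
  internal distance updates use the unclamped values, so the topology is
  the textbook NJ topology.

## 3. Canonical topology keys

Two topologies are "the same" exactly when their **canonical keys** are
equal. A key is built by walking the tree as an undirected graph,
collapsing unary nodes, recursively rendering each internal node as
`(child, child, ...)` with children sorted in C-locale (`radix`) order:

- *Outgroup-rooted* key (used by Ps and Pr): the tree is rooted on the
  outgroup leaf and the outgroup itself is omitted, leaving the rooted
  ingroup topology.
- *Rooted* key: rendered from the root as-is.
- *Unrooted* key: anchored at the lexicographically smallest leaf, which
  fixes one representative among the otherwise equivalent rootings.

Radix sorting everywhere means keys do not depend on the session locale.
The test suite verifies that key equality coincides exactly with
Robinson–Foulds distance zero on hundreds of random trees.

## 4. The statistics

Let an alignment be resampled `R` times (columns drawn with replacement,
same length), and let each replicate yield an NJp tree.

**Pb.** Each interior branch of the point-estimate tree defines a leaf
bipartition, encoded as the sorted labels of the side *not* containing the
smallest leaf. Pb is `100 × (replicates containing that bipartition) / R`.

**Ps.** For a clade (ingroup) plus an outgroup — supplied, or chosen as
the non-ingroup sequence with the smallest mean p-distance to the ingroup
(`closest_outgroup()`, ties broken lexicographically) — the analysis is run
on the *reduced* alignment of ingroup + outgroup. Each replicate tree is
keyed outgroup-rooted; Ps is the modal key's percentage. Ps is undefined
for 2-leaf ingroups (only one rooted topology exists); this raises
`treestab_stability_undefined`. Note the number of rooted topologies grows
as `(2n − 3)!!`, so for large ingroups even excellent data spread some mass
off the mode.

**Pr.** Families A and B are linked by a label map (species-level pairing,
e.g. built from the trailing `_species` token by `build_species_map()`).
T2, family B's point-estimate topology, is transported into A's label
universe through the map; Pr1 is the percentage of A's bootstrap replicates
whose key equals the transported T2. Pr2 is the converse; Pr is exactly
their mean. Because Ps and Pr1 consume the *same* replicate stream (the
RNG is re-seeded with `config$seed` at the start of each stream), Pr1 ≤ Ps
always holds, as it must: no single topology can beat the mode.

**Topology source for T1/T2.** Two defensible definitions exist:
`"subtree"` (default) keys the ingroup subtree of the NJp tree built from
the *reduced* alignment, matching how the bootstrap replicates themselves
are computed, so point estimate and replicates are exchangeable;
`"full-tree"` builds the NJp tree from the *entire* alignment and extracts
the ingroup subtree, which uses all sequences to place the root but makes
the point estimate methodologically different from the replicates. Both
are implemented (`topology_source =`), and `"given"` lets the caller
supply fixed topologies.

## 5. Defaults

| Parameter | Default | Rationale |
|---|---|---|
| `n_replicates` | 1000 | resolves percentages to 0.1; standard practice |
| `seed` | 1 | explicit, so every published number is reproducible |
| `deletion` | `"complete"` | identical site set for all pairs and replicates |
| `topology_source` | `"subtree"` | point estimate exchangeable with replicates |
| `n_sites` (simulator) | 1000 | typical gene-length alignment |
| rounding (`pairwise_pr`) | half-up to 1 d.p. | matches how such tables are reported; half-up avoids banker's-rounding surprises |

## 6. The simulator

`evolve_jc69()` evolves sequences down a tree under Jukes–Cantor:
each site changes along a branch of length `b` with probability
`0.75 (1 − e^{−4b/3})`, uniformly to one of the other three bases, giving
the closed-form expected p-distance `0.75 (1 − e^{−4d/3})` at divergence
`d` (verified at 10,000 sites in the acceptance tests).

`make_family_pair()` emulates a gene or genome duplication: two families
(`A_`/`B_` prefixes) evolve on the same species tree, either on identical
topologies (`agree = TRUE`) or with family B's tree perturbed by one
nearest-neighbor interchange (`nni_perturb()`). The NNI branch should be
chosen explicitly for discordance studies: an NNI across the root-adjacent
branch merely re-roots the tree and is *neutral* once trees are re-rooted
on the outgroup, so a randomly drawn branch can yield a "discordant" pair
with Pr = 100.

What the simulator does **not** emulate: rate variation across sites or
lineages, unequal base frequencies, transition/transversion bias,
insertions/deletions, gene conversion between paralogs, and alignment
error. It is a fixture generator for validating the statistics, not a
realistic sequence evolution model.

## 7. Determinism

Every stochastic routine takes an explicit integer seed and re-seeds at
the start of each replicate stream; all label sorting is C-locale; NJ ties
are broken deterministically. Consequence: the full pipeline — simulation,
bootstrap, all statistics, CLI outputs, `scripts/acceptance.R` JSON — is
bit-identical across runs, platforms, and locales for a fixed seed.

## 8. Problem sizes and limitations

The implementation is exercised up to ~30 sequences and a few thousand
sites with 1,000 replicates (seconds to a minute). NJ is `O(n³)` per
replicate, so hundreds of sequences with thousands of replicates will be
slow. Other limitations:

- p-distance underestimates divergence at saturation; NJp is intended for
  the moderate-divergence regime where these statistics are interpretable.
- Ps compares *rooted* topologies, so everything is conditional on the
  outgroup choice; `closest_outgroup()` is a heuristic, and a misleading
  outgroup misleads Ps and Pr equally.
- Pr assumes a one-to-one species map between families; missing or extra
  paralogs must be resolved by the caller before mapping.

## 9. Worked numeric example

With a tally of 850/100/50 over the three rooted topologies of a 3-leaf
ingroup across 1,000 replicates:

```{r}
ft <- frequency_table(c("((A,B),C)", "((B,C),A)", "((A,C),B)"),
                      c(850, 100, 50))
compute_ps(ft)$ps            # 85  (modal percentage)
compute_pr1(ft, "((B,C),A)") # 10  (frequency of a named alternative)
```

See the README for a full simulate → Ps/Pb/Pr session with its printed
output, and `scripts/acceptance.R` for the end-to-end reproduction script.
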