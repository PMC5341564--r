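---
title: "Scoring drug–disease overlap by network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug–disease overlap by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rwrpharm)
```

## The model

`rwrpharm` treats both a disease and a drug as perturbations of a
weighted protein–protein interaction (PPI) network and asks how much the
two perturbations overlap. The propagation engine is the random walk
with restart (RWR),

$$x^{(t+1)} = (1 - r)\,P\,x^{(t)} + r\,x^0,$$

where $P$ is the column-normalized weighted adjacency matrix
($p_{ij} = w_{ij} / \sum_k w_{kj}$), $x^0$ the seed preference vector
and $r$ the restart probability. For $0 < r \le 1$ the map is a
contraction with factor $1 - r$ in the $L_1$ norm, so the iteration
converges geometrically to the unique fixed point
$x = r\,(I - (1-r)P)^{-1} x^0$ on any connected undirected network. The
fixed point scores each node's proximity to the seed set: restart
continually re-injects mass at the seeds, and the walk spreads it along
high-confidence edges, so scores decay with network distance.

The drug–disease **effect score** is the inner product
$S = \langle x_{disease},\, x_{drug} \rangle$: large when the two
propagated distributions concentrate on the same nodes, i.e. when the
drug-influenced sub-network overlaps the disease-affected one.
Significance is assessed by a permutation null: the same walk is run for
size-matched target sets drawn uniformly from the network, and
$Z = (S - \bar S_r)/\Delta S_r$ with the sample (n−1) standard
deviation. $Z > 3$ is flagged significant by default (a configurable
convention, not a hard-coded rule). Pathway-level effects come from
projecting $x$ onto a gene-set collection: genes absent from the
network count zero, each pathway takes the mean over its full member
list, and the top 5% of pathways per entity is selected.

## Assumptions

* Interactions are undirected and their confidence weights are
  meaningful on a common $[0,1]$ scale; the walk uses them directly in
  the normalization.
* The network is connected enough that propagation reaches all nodes;
  isolated nodes are rejected at normalization time and the network
  builder never produces them.
* Identifiers match exactly (case-sensitive, whitespace-trimmed); no
  alias resolution is attempted, and seed genes that fail to map are
  reported rather than guessed.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.9 | confidence cutoff for background-network edges (dimensionless, $[0,1]$) |
| `r` | 0.3 | restart probability; larger values localize scores near the seeds. 0.3 is the value established for disease-gene prioritization |
| `per_target` | 0.01 | drug seed value per target; a fixed weak preference motivated by the modest per-target potency of natural-product ingredients. The walk is linear in $x^0$ and the null uses the same value, so it cancels in $Z$ |
| `n_perm` | 1000 | random counterpart sets in the permutation null |
| `tol`, `max_iter` | 1e−10, 1000 | $L_1$ convergence tolerance and iteration cap; with $r = 0.3$ the contraction factor is 0.7, so $\sim$70 iterations reach 1e−10, far below any score difference of interest |
| `top_fraction` | 0.05 | pathway selection fraction; the count is **floored** (4722 sets → 236 selected) |
| fold thresholds | 4, 0.25 | strict inequalities: a ratio of exactly 4.0 is not differentially expressed |

## Design choices where the design was open

* **Adaptive network inclusion.** Lowering the threshold "per gene" is
  made concrete as: admit the missing gene's raw edges in descending
  weight order and stop at the first edge that attaches it to the
  existing filtered network. This adds the fewest, most-confident edges.
  If none of the gene's neighbours is in the network, only its single
  highest-weight edge is kept and the gene enters as a satellite
  component; genes with no raw edges at all are reported as unmapped.
* **`m` in the disease seed `1/m`** counts *mapped* disease genes, so
  the disease vector is always a probability distribution over the
  network; unmapped genes are reported separately.
* **Expression weighting.** "Normalized differential expression ratio"
  is implemented as $|\log_2 \text{ratio}|$ rescaled to sum 1, treating
  k-fold induction and repression symmetrically; a raw-ratio mode is
  available behind `weighting = "raw"` for sensitivity analysis.
* **Seed scale is never silently renormalized.** The drug vector sums to
  $0.01 k$, not 1; conservation of mass therefore holds only for
  probability seeds, and the scale invariance of $Z$ is covered by a
  test rather than assumed.
* **Null sampling** draws nodes uniformly, not degree-matched, matching
  the stated protocol of size-matched random target sets.
* **Ties and rounding.** Pathway ties at the selection cutoff break by
  lexicographic name; reported percentages round half-up at the printed
  precision; sample (n−1) SD in the null (negligible vs population SD at
  n = 1000).
* **Duplicate edges** keep the maximum confidence; self-edges are
  dropped (they would distort column normalization and carry no
  interaction information).

## Numerical notes

The transition matrix is held sparse (`Matrix::dgCMatrix`); the
iterative walk is the production path, and a dense closed-form solve
(`rwr_closed_form`, guarded to ≤ 2000 nodes) serves as an independent
oracle — the test suite requires $L_1$ agreement within 1e−8 on random
graphs up to 200 nodes. Permutation nulls are propagated as columns of
one matrix; columns never interact, so the result equals one-at-a-time
runs (also verified by test) at a fraction of the cost. All sampling
goes through an internal seeded-RNG scope that restores the caller's
`.Random.seed`, which is what makes file-level outputs byte-identical
under a fixed seed.

## What the synthetic fixtures emulate — and what they don't

The generator grows connected scale-free networks by preferential
attachment (heavy-tailed degrees, as in PPI data), assigns edge
confidences uniformly on `[0.9, 1]` (a high-confidence background
build), and plants a densified module standing in for a
disease-affected sub-network. Synthetic pathway collections mark a
known fraction of sets as module-enriched; synthetic expression tables
plant a known set of genes outside the (0.25, 4) ratio band. Defaults —
500 nodes, 30-node module at density 0.5, 100 permutations in tests —
keep the suite fast while leaving clear signal margins; the acceptance
script runs the same conditions with 1000 permutations.

These fixtures validate the machinery: calibration of the null
($Z$ of random "drugs" has mean ≈ 0, SD ≈ 1), recovery of planted
modules ($Z > 3$ for module-drawn targets, not for random ones), and
enrichment recovery in the pathway projection. They do **not**
reproduce STRING's evidence-channel structure, real pathway topology,
gene-family redundancy, or literature bias in disease-gene lists — so
green tests demonstrate correctness of the algorithms, not biological
performance on real data. Full-scale analyses require the real inputs
(a STRING release, curated disease genes and targets, an MSigDB
collection) fed through the same entry points.

## A minimal run

```{r example, eval = FALSE}
spec <- fixture_spec(n_nodes = 300, module_size = 20, rng_seed = 11)
fx  <- generate_network(spec)
fx  <- plant_disease_module(fx, 20, 0.5, rng_seed = 12)
net <- build_background_network(fx$edges, threshold = 0.9)
res <- assess_drug_disease(net, fx$disease_genes, fx$disease_genes[1:8],
                           n_perm = 1000, rng_seed = 42)
res

coll <- generate_pathway_collection(net$nodes, n_pathways = 100,
                                    module_genes = fx$disease_genes,
                                    enriched_fraction = 0.2, rng_seed = 13)
select_top_fraction(score_pathways(res$x_disease, coll), 0.05)
```

## Known limitations

* Uniform (not degree-matched) null sampling means hub-heavy target
  sets can inherit significance from degree alone; the optional
  degree-aware analysis is left to the user via custom seed sets.
* Exact-identifier matching pushes all namespace harmonization upstream.
* The inner-product score is unnormalized; compare $Z$ values, not raw
  $S$, across networks or seed-set sizes.
* The closed-form oracle is dense and deliberately capped; for large
  networks only the iterative path applies.
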