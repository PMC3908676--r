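---
title: "Robustness-based detection of overlapping protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness-based detection of overlapping protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robcomplex)
```

## The model

Protein complexes are groups of physically associated proteins. In a PPI
network — an undirected simple graph of proteins and observed
interactions — complexes appear as locally dense subgraphs. Two
properties distinguish a credible complex from a density artifact in
noisy interaction data:

1. **Internally corroborated edges.** An interaction whose endpoints share
   no other partners is weakly supported; within a real complex, members
   interact with each other's partners. We quantify this with the Jaccard
   edge weight $w_{uv} = |\Gamma(u) \cap \Gamma(v)| / |\Gamma(u) \cup
   \Gamma(v)|$ and require every edge kept inside a cluster to have
   $w_{uv} \ge \gamma$.
2. **Robustness.** Functionally associated proteins are linked by many
   alternative paths. The robustness degree $R(K) = n/|K|$ measures how
   many members (always the current highest-degree one) can be removed
   before the induced subgraph disconnects or empties. A clique tolerates
   every removal ($R = 1$); a hub-and-spokes star collapses immediately
   ($R = 1/(k+1)$). Clusters must maintain $R \ge \theta$ as they grow.

Each cluster grows greedily from a seed — the unvisited node with the
highest *node weight*, i.e. the average degree of its neighbourhood graph
after degree-1 pruning. Expansion priority among frontier nodes is the
modified Czekanovski–Dice distance

$$d(v, K) = \frac{|K| - m}{|K|} +
  \frac{OUT(K) + OUT(v)}{\deg(K) + \deg(v) - 2m + |K|},$$

whose first term rewards direct edges from $v$ into $K$ and whose second
term rewards shared neighbourhood: external edges of $K$ and $v$ that lead
to their common neighbours are excluded from $OUT(\cdot)$, so a candidate
embedded in the cluster's periphery scores a small distance even with few
direct edges. Finished clusters are merged into the collection when their
neighbour affinity $NA(A,B) = |A \cap B|^2 / (|A||B|)$ with the closest
existing cluster reaches the merge threshold; otherwise they are appended.
Because the visited flag gates only *seeding*, members of earlier clusters
remain eligible expansion candidates and the output may overlap — the
behaviour real complexes show (shared subunits).

## Parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `theta` | 0.5 | fraction in [0,1] | minimum robustness degree during growth; 0.5 demands that half the members can be stripped before disconnection |
| `gamma` | 0.1 | Jaccard weight in [0,1] | minimum internal edge weight; filters corroboration-free edges beyond the automatic removal of weight-0 edges |
| `min_size` | 3 | count | smallest reported cluster; smaller clusters are still generated and mark their members visited |
| `merge_threshold` | 0.5 | affinity in (0,1] | neighbour-affinity cutoff for absorbing a new cluster into its closest existing one |
| `omega` (evaluation) | 0.2 | affinity in (0,1] | prediction–reference match threshold, the field's convention |

No experimental values of $\theta$ and $\gamma$ are available for the
original comparative study, so the defaults are this package's choice:
$\theta = 0.5$ is the natural midpoint at which a cluster must survive
losing half its nodes, and $\gamma = 0.1$ keeps the weight constraint
active without dominating the robustness constraint. Both are exposed on
every interface.

## Numerical and procedural choices

Several points of the procedure admit more than one reading; the package
fixes them as follows.

* **Degree-1 pruning is a single simultaneous pass** using degrees in the
  unpruned neighbourhood graph, not an iterative core-peel. Iterating
  would alter the node weight on simple motifs (e.g. a triangle with a
  pendant chain) and the removal of degree-1 nodes is described as one
  act.
* **$\deg(K)$ counts edges with exactly one endpoint in $K$** (external
  degree only, including edges to $v$). With $2m$ subtracted in the
  denominator this reproduces the union-size structure of the classical
  Czekanovski–Dice distance. The alternative reading (internal edges
  counted twice and added) cannot be ruled out textually but breaks that
  correspondence.
* **Common neighbours of $K$ and $v$** exclude members of $K$ and $v$
  itself, so the categories member / candidate / common neighbour /
  other are disjoint when counting $OUT(\cdot)$.
* **Edge weights are computed once on the raw graph**; deleting the
  zero-weight edges does not trigger recomputation. Recomputing after
  deletion could cascade (new zero-weight edges appear) and in sparse
  graphs empty the network entirely.
* **Seed weights are computed on the filtered network**, since
  initialization strictly precedes seed selection in the pipeline.
* **Rejected candidates are blacklisted** for the remainder of that
  cluster's growth. Re-admitting them after later growth is conceivable
  but unstated, and the blacklist guarantees termination: each expansion
  step either adds or permanently rejects a node, so a cluster performs
  at most $|V|$ additions plus $|V|$ rejections, and each outer iteration
  marks at least the seed visited.
* **Merging is single-shot.** A new cluster is compared once against the
  current collection; a merged union is not re-merged and the
  $\theta$/$\gamma$ constraints are not re-checked on it (the union of
  two qualifying clusters sharing most members typically still qualifies,
  but this is not enforced). The detection log records which output
  clusters absorbed a merge so audits can separate the two cases.
* **All tie-breaks are lexicographic on the protein ID** (byte order,
  locale-independent): seed selection, expansion candidates, robustness
  removals. Combined with canonical output ordering (size descending,
  then first member) this makes runs byte-identical.
* **Degenerate inputs.** An empty network yields an empty complex set; a
  network of isolated nodes terminates immediately (best node weight 0);
  a single-node cluster has robustness 1 (one removal empties it); a
  complex with no localization-annotated member is skipped by the
  co-localization aggregate, and a complex with no tabulated protein pair
  is skipped by the GO aggregate.

## The synthetic benchmark generator

Real benchmark corpora (curated complex catalogues, localization atlases,
GO similarity matrices) are not redistributable here, so the package
ships a planted-complex generator that emulates the structural assumption
the detector rests on: dense groups in a sparse background.
`synthetic_config()` plants `n_complexes` groups (default 5 of size 5),
joins each internal pair with probability `p_within` (default 0.9,
re-sampling a group until internally connected so ground truth is
well-defined), optionally lets consecutive complexes share exactly one
node, adds `n_background` extra proteins (default 20, ≈4 per complex —
enough background to create spurious attachments without swamping the
25 complex members), and joins every cross pair with probability
`p_background` (default 0.01). The shared node of an overlapping pair is
drawn from the predecessor's not-previously-shared members so overlaps
stay pairwise. Everything derives from `rng_seed`; the caller's RNG state
is untouched.

What the generator does *not* emulate: the heavy-tailed degree
distribution of real PPI networks, experiment-specific false-negative
structure (bait–prey asymmetry), and complexes of heterogeneous density.
Passing the recovery tests therefore shows the pipeline is correct and
well-behaved under its own model assumptions — it does not certify
performance on any particular real interactome.

## Validation problem sizes

The test suite validates the distance measure against a naive
enumeration oracle on 1000 random graphs of up to 12 nodes, the
robustness identity on complete graphs up to $K_8$ and stars up to 6
leaves, and end-to-end recovery on the default benchmark scale (45-node
networks, 5 planted complexes, 10 seeds for the noisy regime). These
sizes exercise every code path of the per-candidate scoring loop; the
algorithms themselves are polynomial (the expansion loop is bounded by
$|V|$ additions plus $|V|$ rejections per cluster) and run on networks of
thousands of nodes, though no optimisation work has been done for that
scale.

## Known limitations

* Recall is structurally modest on sparse real networks: the robustness
  and weight constraints deliberately trade recall for precision, and
  complexes that are not densely connected in the observed network (e.g.
  binary-interaction chains) cannot pass $\theta = 0.5$.
* Input confidence scores are ignored; the Jaccard weight is the only
  edge-weight source.
* GO semantic similarity is consumed as a precomputed pairwise table;
  computing term-level similarity from the ontology DAG is out of scope.
* Complexes smaller than `min_size` are never reported, including true
  heterodimers.
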