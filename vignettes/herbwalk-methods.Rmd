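---
title: "Methods: diffusion-based herb and compound prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-based herb and compound prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbwalk)
```

## The multiscale network

`herbwalk` models the cellular context as a typed, undirected, unweighted
multilayer graph: a protein–protein interaction (PPI) layer, a
protein→biological-function annotation layer, and a function–function
hierarchy. Herbs, compounds, and the disease enter the graph as explicit
entity nodes wired to their target proteins, rather than as seed sets
spread over the proteins: this keeps each walk's restart mass on a single
node, makes the entity's "reach" emerge from its degree, and lets mechanism
subnetworks display the direct entity→target edges. Six edge classes are
distinguished (`ppi`, `protein_function`, `function_hierarchy`,
`herb_target`, `compound_target`, `disease_gene`); edge classes are
validated against endpoint node classes at construction, duplicate records
collapse to one edge, and isolated nodes are reported rather than dropped.

Gene symbols are normalized to uppercase ASCII by the file readers; no
alias or identifier resolution is attempted, which is a documented
limitation — two symbols for the same protein remain two nodes.

## The biased random walk with restart

From node $u$ the walker steps to neighbor $v$ with probability
$w_{c(u,v)} / \sum_{v' \in N(u)} w_{c(u,v')}$, where $c(u,v)$ is the class
of the joining edge and $w$ is a positive per-class weight. Raising
`class_weights["protein_function"]` shifts transition probability toward
biological-function nodes, which is the "bias" in the method's name; with
all weights equal the walk is the ordinary uniform neighbor walk. With
restart probability $\alpha$ the diffusion profile of seed $s$ solves

$$ r = \alpha\, e_s + (1 - \alpha)\, M r, $$

with $M$ the column-stochastic biased transition operator. Nodes with no
neighbors receive a self-loop so $M$ stays stochastic; the walk never
teleports except to its seed.

**Parameters and defaults.** `restart_prob = 0.5`, all class weights `1`,
L1 tolerance `1e-10`, `max_iter = 500`. The restart probability and bias
weights are genuinely free parameters of this family of methods and no
single published value fits every network, so the package ships neutral
defaults (a half-and-half mix of restart and diffusion, no class bias) and
exposes every knob through `walk_params()` and the YAML `walk:` block.
Results in any analysis should state the values used; nothing in the
scoring code hard-codes them. The tolerance/iteration pair was chosen so
that power iteration agrees with the exact dense solve to better than
`1e-8` maximum absolute difference with margin (the suite sweeps 50 random
graphs), and convergence failure is flagged on the returned profile rather
than silently accepted.

**Numerical conventions.** Profiles are renormalized to sum exactly to 1
before return (power iteration preserves the simplex up to rounding);
top-$k$ selection breaks frequency ties lexicographically on node id so
runs are bit-reproducible; the dense verification solver
(`diffusion_profile_exact()`) refuses graphs above 2,000 nodes.

## Scoring and selection

The similarity between an entity and the disease is the Pearson correlation
of their diffusion profiles over the protein and function nodes. Entity
nodes are excluded from the correlation vector so an entity's own restart
mass cannot inflate its score; Spearman and log-frequency variants are
available (`method=`, `log_freq=`). All profiles compared are computed on
one shared network with every entity attached, so the vectors are aligned
and every walk sees the same topology.

Target overlap is assessed with the one-sided hypergeometric tail
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ and summarized as
fold enrichment $(k/n)/(K/N)$. The background universe $N$ defaults to the
proteins of the network and is configurable: with real annotation
databases the natural universe (all assayed proteins vs. all annotated
targets) is ambiguous, and the enrichment scale moves with it, so the
package never bakes an inferred value in. p-values are reported raw at the
herb level (matching how such tables are usually printed); BH adjustment is
available through `p.adjust` on the returned column.

Herb selection applies three rules with these defaults: overlap
p < 0.05, at least 5 active compounds, top 10 by correlation (ties by
ascending p, then id). An "active" compound is, by default, one with at
least one network-mapped target (`active_rule = "network_mapped"`); the
stricter alternative — at least one target inside the disease gene set — is
exposed as `"disease_target"`. The permissive default is the coherent one:
compound-level rankings can legitimately retain a single significant
compound for a herb that passed the 5-compound rule, which would be
impossible if "active" already required disease-target hits. Herb target
sets default to the union of compound targets capped at the top 50 by
simple pathway count (the number of herb→compound→target paths per
target); the full union is available with `limit = Inf`.

## Enrichment statistics

`enrich_sets()` is a self-contained over-representation test: per term a
2×2 table against the background, one-sided hypergeometric p, BH adjustment
across the library, odds ratio with Haldane's +0.5 correction when any cell
is zero. The z-score follows the rank-deviation construction: `n_random`
(default 200, seeded, isolated from the caller's RNG) random queries of the
same size are drawn from the background, each term's p-value rank is
recorded, and the z-score is the term's observed-rank deviation from its
random expectation in rank standard deviations. The combined score is
$|z \cdot \ln p|$, which is 0 whenever $p = 1$. Because the z-score depends
on a simulated background, its exact values vary with the library, the
background, and `n_random`; it is a ranking aid, not a calibrated
statistic. When the pipeline has no external GMT library it uses the
network's own protein→function annotations as the gene-set library, one set
per function node.

## Mechanism subnetworks

A compound's mechanism subnetwork is the induced subgraph over the top-$k$
(default 20) protein/function nodes of the compound profile and of the
disease profile, plus both entity nodes. How the two top-$k$ sets should be
joined into one displayed network is genuinely open; the package takes the
minimal reproducible option: induce all parent edges first, then, while the
subgraph is disconnected, add an unweighted shortest path through the
parent network between the compound-side component and the nearest other
component, tagging interior path nodes `connector`. This guarantees
connectivity (whenever the parent graph allows it), adds as few nodes as
possible, and is deterministic. Every non-connector, non-entity node is in
at least one top-$k$ list; growing $k$ never removes nodes. Restricting
function nodes to enrichment-significant ones is deliberately *not* the
default — the raw top-$k$ is what the profiles actually say — but the node
table carries both profiles' frequencies so callers can filter.

Compounds with no network-mapped target cannot seed a walk and are
excluded throughout (`herbwalk_unlinked` condition), at attachment, in
ranking, and in mechanism extraction.

## The synthetic world

`generate_world()` emulates the *structure* of the real inputs, not their
marginals: a preferential-attachment PPI layer (scale-free degrees, 2 edges
per new protein), a uniform random rooted tree as the function hierarchy
with Poisson(1) protein annotations onto its leaves, herbs with 2–8
compounds each (so some herbs genuinely fall below the 3-ingredient
floor), compounds with 1–5 targets, and a disease module taken as a
breadth-first ball of 20 proteins around the highest-degree protein —
propagation methods assume disease genes cluster, and a hub-centred ball is
the simplest connected realization. Defaults: 200 proteins, 50 functions,
10 herbs. These sizes keep a full pipeline run in seconds while leaving
room for 20-seed replication experiments; they are roughly 1% of the real
databases' scale, so absolute correlation values are not comparable to
production runs — only rank behavior is.

One herb is *planted*: a fraction `planted_herb_proximity` (default 0.9) of
its target draws comes from the disease module and its 1-hop ring, half the
proximal mass on the module itself and half on the ring. The 50/50 split
encodes that a genuinely active herb hits disease genes directly as well as
their immediate interactors; drawing uniformly from the pooled
module + ring would dilute direct hits on larger rings and make the
"planted signal" depend on ring size rather than on the proximity
parameter. The planted herb always receives at least 5 compounds so that
it is eligible under both selection rules (3-ingredient floor,
5-active-compound rule) — a planted positive that the pipeline's own
filters remove would make end-to-end recovery untestable. Decoy herbs draw
targets uniformly from non-disease proteins. The generator is a pure
function of config + seed, and `write_world()` emits byte-identical TSV/GMT
bundles for a fixed config.

What passing the planted-recovery experiments does **not** show: robustness
to annotation noise and database bias, to shared compounds between herbs
(synthetic herbs have disjoint compound sets), to hub-target confounding in
real PPI networks, or to the identifier-mapping problems of real catalogs.
The function layer is a tree plus optional cross edges, not a full GO DAG;
the walk code is tested to tolerate non-tree hierarchies but the generator
does not emit them by default.

`overlap_toy()` is a separate deterministic micro-fixture: ten herb target
sets with fixed overlap patterns (2/50, 5/50, 2/27, 2/26, 2/38, 1/11,
4/50 ×3, 3/50) in a universe of 4,227 genes containing 10 disease genes,
so the background fraction is exactly 10/4227. It exercises the
cross-herb consistency of the fold-enrichment statistic: one shared
background calibration must reproduce every herb's enrichment from its
k/n alone.

## Orchestration and reproducibility

`run_pipeline()` chains build → filter → diffuse → prioritize → enrich →
mechanisms, writing TSV rankings, an enrichment table, GraphML/SIF
subnetworks for the passing compounds of the top herb, a `run.log`, and a
`manifest.json` with the config hash and seed. Re-running with identical
inputs and config reproduces identical result files; the only stochastic
stage (the enrichment z background) is driven by the config seed. The
selection thresholds, walk parameters, and seed round-trip through a YAML
config (`config_as_yaml()` / `read_pipeline_config()`).

## Known limitations

- No pharmacokinetics: absorption, metabolism, and bioavailability of
  compounds are outside the model, so a high-ranking compound is a
  network hypothesis, not a drug candidate.
- No identifier mapping or alias resolution; inputs must share one symbol
  namespace.
- Correlation between diffusion profiles is dominated by high-frequency
  hub nodes; the Spearman and log-frequency options mitigate but do not
  remove this.
- The enrichment z-score and combined score depend on the simulated random
  background and the library version; only the hypergeometric p and BH
  adjustment are exactly reproducible across environments.
- Herb-level p-values are reported without multiple-testing correction by
  default, mirroring common practice in candidate tables; treat them as
  ranking scores rather than confirmatory tests.
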