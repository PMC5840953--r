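---
title: "Inferring constantly activated and inhibited signaling subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring constantly activated and inhibited signaling subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustsig)
library(dplyr)
```

## The model

A persistent extracellular stimulus — chronic inflammation is the motivating
case — keeps some intracellular signaling routes switched on (or off) for
long periods. If the stimulus is sustained, its footprint should be visible
in steady-state transcriptomes: the receptors and ligands that sense it are
differentially expressed, and so are the transcription factors (TFs) at the
downstream end of the affected pathways. `sustsig` reconstructs the routes
in between.

The inputs are deliberately minimal:

* a **signed directed interactome**: curated signaling interactions with a
  direction of signal flow and a sign (+1 activation, -1 inhibition), as
  exported from resources such as OmniPath or ReactomeFI;
* **booleanized differential expression**: per-region up/down calls,
  discretized to +1 / -1, with every other gene 0. Upstream statistics
  (normalization, fold-change cutoffs) are out of scope — the calls arrive
  precomputed;
* **role lists**: which symbols are TFs, receptors, and membrane/secreted
  ligands.

Because the stimulus itself is unobserved, it is modeled as a dummy node
(`ROOT`) wired to every receptor/ligand upregulated in the phenotype being
analyzed. Any explanation of the TF pattern must therefore enter the cell
through an upregulated sensor — that constraint is structural, not a
penalty, and `validate_solution()` re-checks it on every solution.

Each interactome edge then gets one of two fixed probabilities: `p_high`
(default 0.9) when the edge's sign is compatible with the booleanized
states of its endpoints in this phenotype, `p_low` (default 0.1) otherwise.
With costs `-ln(weight)`, maximizing the product of edge probabilities
becomes minimizing additive cost, and the question "what is the most
plausible wiring from the stimulus to all differentially expressed TFs?"
becomes a **rooted directed Steiner problem**: find the minimum-cost
arborescence rooted at `ROOT` covering every differentially expressed TF
(the terminals). Running the same machinery twice — once oriented to the
disease phenotype, once to the control — yields the *constantly activated*
and *constantly inhibited* subnetworks of a region.

## What "compatible" means: two shipped schemes

The compatibility notion admits two readings, and both are implemented
(`weight_params(scheme = ...)`); `weight_table()` prints the full 18-case
decision table for either.

* `differential_activity` (default): an edge scores `p_high` iff the source
  is differentially expressed, the target is **upregulated** in the
  phenotype, and the sign agrees (`sign * state_src == +1`). This encodes
  "the target is more active in this phenotype than in the other": an
  activating edge between two genes that are both *down* in the phenotype is
  evidence for the other phenotype, not this one, so it scores low here. Two
  of the 18 cases score high. The scheme is antisymmetric by construction:
  no doubly differential edge can score high in both orientations.
* `sign_consistency`: an edge scores `p_high` iff both endpoints are
  differentially expressed and `sign * state_src == state_tgt` — plain
  agreement between the regulatory sign and the two states, regardless of
  which direction the target moved. Four of 18 cases score high, and the
  scheme is invariant under flipping the sign together with the target
  state.

The difference only matters for edges whose target is downregulated in the
analyzed phenotype. `differential_activity` is the default because the
analysis asks for routes that keep their targets *more active* under the
stimulus; `sign_consistency` is the natural scoring when pathways are
defined by sign-consistent propagation (it is what the synthetic generator
plants, so the recovery experiments use it).

Non-differentially-expressed genes stay in the network: their incident
edges simply score `p_low`, which lets the solver pass through a
non-differential kinase or adapter when topology demands it — such linkers
are reported in the output but carry no claim of differential activity.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `p_high` / `p_low` | 0.9 / 0.1 | probability | the two-valued weighting; only their ratio matters for the optimum, the values are conventional |
| `root_edge_weight` | `p_high` | probability | root-to-sensor edges are uniformly cheap so receptor choice is decided by downstream topology, not by the artificial hop |
| `root_children` | `"receptors+ligands"` | — | ligands are pooled with receptors as stimulus sensors (the inclusive reading); `"receptors"` restores the narrow one |
| `max_terminals` | 12 | count | exact solver budget: the subset DP is exponential in the terminal count |
| `max_edges` | 18 | count | brute-force oracle budget |
| `pc_penalty` | `NULL` | cost units | optional prize-collecting relaxation: per-terminal exclusion penalty; default is mandatory terminals with a hard error on unreachability |

The cost transform `-ln(weight)` is a presentation choice: for two-valued
weights any strictly decreasing transform yields the same optima.

## Solvers, determinism, numerics

* `exact_steiner()` — dynamic programming over terminal subsets on the
  all-pairs shortest-path metric (the directed Dreyfus–Wagner recursion:
  split each terminal set at a merge node, then relax by shortest paths).
  Provably optimal; practical to about a dozen terminals.
* `brute_force_steiner()` — the independent testing oracle: exhaustive
  enumeration of per-node in-edge assignments (an edge set in which some
  node has two in-edges can never be an arborescence, so the enumeration is
  complete), with sound cost-bound pruning. Never used for analysis, only
  for cross-checking.
* `heuristic_steiner()` — repeatedly attaches the terminal with the
  cheapest shortest path from the current tree, then prunes non-terminal
  leaves. Admissible-by-construction bound: never below the exact optimum,
  equal to it on disjoint-path instances; intended for networks beyond the
  exact terminal budget.

All three are fully deterministic without any seed: ties — equal-cost
frontier nodes, equal-cost predecessors, equal-cost DP splits — are broken
by lexicographic order of node symbols. Floating-point cost comparisons use
an absolute 1e-12 tolerance (the costs in a default run are small integer
combinations of `-ln 0.9` and `-ln 0.1`, so genuine ties are exact at
machine precision and the tolerance is only a guard). Reported costs must
recompute from the edge table to within 1e-9, which `validate_solution()`
asserts.

Degenerate inputs are contracts, not surprises: zero terminals yield the
empty tree at cost 0; an unreachable terminal is a hard error naming the
terminal unless `pc_penalty` (or the pipeline's `on_unreachable = "drop"`)
says otherwise; a phenotype orientation with no upregulated sensor skips
that run with the reason recorded. Parallel opposite-sign edges between the
same gene pair are both kept (only exact duplicates are collapsed at parse
time), and the arborescence in-degree rule means a tree uses at most one of
them. Self-loops can never extend a tree, so they need no special handling.

## What the synthetic generator emulates

`generate_instance()` builds a random signed interactome with designated
receptor / ligand / TF / intermediate pools, plants `k_planted`
node-disjoint pathways (receptor → interior chain → one or more TFs), and
propagates states down each pathway as `state(target) = sign *
state(source)` from a receptor state of +1 — i.e., each planted pathway is
a concrete constantly-activated route whose expression pattern is exactly
sign-compatible. Up/down calls are then emitted from the final states, so
the pipeline is exercised through the same booleanization step real data
would use.

Two choices make recovery a well-posed test rather than a lottery:

* **Identifiability of the truth.** A random background edge whose two
  endpoints both lie on planted pathways could, by chance, be
  sign-compatible and create a second cheap route into a planted TF — the
  "ground truth" would then be genuinely ambiguous. The generator therefore
  forces such edges to the incompatible sign. Background edges touching any
  non-planted (state 0) gene are left alone; they score `p_low` anyway.
* **Node-disjoint planting.** Pathways share no receptor, interior node, or
  TF, so under zero noise the planted forest is the unique optimum and
  receptor recovery has an unambiguous target.

Noise enters through two independent dials: `noise_flip_rate` sets
non-planted genes to spurious ±1 calls (creating decoy sensors and decoy
terminals), and `planted_corrupt_rate` zeroes planted states (missed
calls — the harder failure mode, since a corrupted receptor loses its root
edge and its TFs may become unreachable; the recovery experiment drops
unreachable terminals and records how many, mirroring the prize-collecting
fallback).

The default scale — 60 genes, 120 background edges, 3 planted pathways of
interior length 1–3 with 1–2 TFs each — keeps every replicate inside both
the exact solver's and the brute-force oracle's budgets, which is what lets
the test suite cross-check all three solvers on the same instances. The
suite runs 50 random solver-comparison networks and 20-replicate recovery
experiments at this scale; at zero noise the experiments recover the
planted receptors with precision and recall 1.0, and under 5% planted-state
corruption mean recall stays above 0.9 (both recomputed by the tests on
every run).

What the generator does **not** emulate — and hence what passing tests do
not certify about real data: scale-free degree structure (background edges
are uniform random), correlated noise between neighboring genes, the
~20-fold larger size of curated human interactomes, post-translational
signaling invisible to mRNA (a known blind spot of the expression-only
approach), and any identifier-mapping noise (symbols are compared exactly
after whitespace trimming; harmonization is the caller's job).

## Reading the output

`decompose_by_receptor()` splits a solution tree at its root children: each
mediator (receptor or ligand chosen by the solver) heads one subtree, and
the TFs it controls are counted up/down **always in disease-vs-control
orientation**, also for the control-oriented run — otherwise the inhibited
subnetworks' counts would be silently negated. The run's phenotype maps to
the interpretation label: case → `constantly_activated`, control →
`constantly_inhibited`. `compare_regions()` is plain set algebra over
mediators (shared vs region-specific, plus all non-empty overlap classes
for up to 6 regions), and `summarize_run()` emits the two deterministic
report tables. Intermediates inside the subtrees are serialized (GraphML,
SIF) but not ranked: the method's claim is about the sensors and the
existence of a cheap compatible route, not about ordering kinases.

## Known limitations

* One tree per (region, phenotype) run: equally cheap alternative optima
  exist in principle and only the deterministic tie-break picks among them;
  the manifest records the rule so runs are reproducible.
* The exact solver's terminal budget (default 12) is real; regions with
  many differentially expressed TFs need the heuristic, which carries no
  optimality certificate beyond the admissibility bound.
* Mandatory-terminal semantics treat every differentially expressed TF as
  equally important; the `pc_penalty` relaxation is a blunt, uniform way to
  soften that.
* Two-valued weights discard expression magnitude by design; genes just
  under the upstream calling threshold look identical to unchanged genes.

```{r session}
sessionInfo()
```
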