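---
title: "Time-consistent reconciliation of event-labeled gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-consistent reconciliation of event-labeled gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtrecon)
```

## The problem

A gene family evolves inside a species phylogeny through speciations,
duplications, horizontal gene transfers (HGT) and losses.  When the gene
tree `T` comes with *event labels* — each internal vertex marked as a
speciation, duplication or transfer, each gene assigned by `sigma` to the
species it resides in, and the out-edges of transfer vertices flagged —
reconciling it with a species tree `S` means choosing a map `mu` from
gene-tree vertices to positions in `S` (vertices for speciations and
leaves, edges for duplications and transfers) that preserves the
ancestral order inside the transfer-free parts of `T`.

Such a map may still be biologically impossible: transfers couple the
timing of distant parts of `S`, and a set of transfers can force a gene
to travel back in time.  This package implements the complete decision
theory for that question: given `(T; t, sigma)` and `S`, does a
*time-consistent* reconciliation exist, and if so, construct one.

## Observability conditions

Losses can erase all evidence of an event, so the theory is developed
for gene trees that could in principle be inferred from data:

* **O1** — every internal vertex has at least two children (the root at
  least two as well): unary events leave no trace.
* **O2** — every transfer vertex keeps at least one transfer and one
  non-transfer out-edge: otherwise either the recipient or the donor
  lineage left no surviving descendant and the vertex would not be
  recognizable as a transfer.
* **Sigma1** — a speciation vertex has two children whose transfer-free
  species sets are disjoint.
* **Sigma2** — the two sides of a transfer edge have disjoint
  transfer-free species sets.

`check_O1()`, `check_O2()`, `check_sigma1()` and `check_sigma2()`
implement these; the last two return violating vertices/edges for
diagnostics.  A stronger geometric condition on true scenarios (that the
donor and recipient lineages of a transfer be incomparable species at
the transfer time) cannot be checked on a labeled tree alone; Sigma1 and
Sigma2 are its checkable consequences, and they are what the algorithms
require.

## Reconciliation maps and the lca-map

`lca_map()` computes, bottom-up over non-transfer edges, the lowest
possible position `ell(u) = lca_S(sigma_TE(u))` of every gene vertex,
where `sigma_TE(u)` is the set of species of the transfer-free leaf
descendants of `u`.  Every valid map satisfies `mu(u) >= ell(u)`.
`canonical_reconciliation()` places every vertex at this lower bound:
speciations and leaves on `ell(u)` itself, duplications and transfers on
the species edge immediately above it.  `validate_reconciliation()`
checks the axioms (M1), (M2i–iii) and (M3); (M3) is verified along the
parent–child pairs of the transfer-free forest plus the global lower
bound, which implies the condition for all comparable pairs by
transitivity of the order.

The species tree is always used in *augmented* form
(`augment_species_root()`): a planted root above the crown provides the
edge to which duplications and transfers predating the first speciation
are mapped.

## Time maps and the auxiliary graph

A *time map* assigns strictly decreasing real times towards the root.  A
reconciliation is *time-consistent* if time maps `tau_T`, `tau_S` exist
with (C1) speciations/leaves simultaneous with their images and (C2)
duplications/transfers strictly inside the time span of their image
edge.  We anchor the time axis at `tau_T(root of T) = 0` and
`tau_S(planted root of S) = -1`.

All timing constraints can be collected into a directed *auxiliary
graph* on the union of the two vertex sets
(`build_auxiliary_graph()`):

* **A1** gene-tree edges, with speciation/leaf endpoints replaced by
  their images (this encodes C1 by merging);
* **A2** species-tree edges;
* **A3** each duplication/transfer vertex `u` precedes `ell(u)`;
* **A4** the joint lca of a transfer edge's species sets precedes the
  transfer vertex;
* **A5** a duplication/transfer vertex lies strictly between the
  endpoints of its image edge.

The graph with rules A1, A2, A5 is acyclic exactly when the *given* map
is time-consistent (`is_time_consistent_map()`); the graph with rules
A1–A4 is acyclic exactly when *some* time-consistent map exists
(`exists_time_consistent_map()`).  The latter graph only involves the
forced images of speciations and leaves, so the verdict does not depend
on which valid anchor map is supplied — a property the test suite checks
explicitly.

`reconcile()` composes the whole pipeline: observability checks,
lca-map, canonical map, A2-mode decision, explicit time maps from a
topological order (`derive_time_maps()`), and relocation of every
duplication/transfer vertex onto the unique species edge whose time span
contains its time (`relocate_map()`).  On refusal it returns a
machine-checkable certificate: one cycle of the auxiliary graph, with
the edge classes that produced each arc.

## DTL-scenarios

For fully resolved binary trees the classical DTL formalism maps every
gene vertex to a species *vertex*.  `validate_dtl()` checks its axioms
(leaf anchoring, descendant conditions, transfer edges exactly at
incomparable images, and the per-event placement rules), and
`mu_to_gamma()` / `gamma_to_mu()` convert between the two formalisms:
an edge image `(x, y)` projects to its child endpoint `y`, and a
duplication/transfer vertex lifts back to the edge above its DTL image.
On binary instances a valid DTL-scenario exists exactly when a valid
reconciliation map exists; the test suite verifies this equivalence by
double brute force on an enumerated family.

## Numerical and algorithmic choices

* **LCA queries** use binary lifting built once per tree; trees are
  immutable after construction.
* **Edges are addressed by their child endpoint** everywhere (unique
  because every vertex has one parent).
* **Topological orders** come from Kahn's algorithm with lexicographic
  tie-breaking on namespaced vertex ids (`S:` for species, `T:` for
  gene vertices), with the planted species root taken first; this makes
  `reconcile()` fully deterministic.  Any topological order would be
  correct.
* **Time values** are the 0-based topological ranks, with
  speciation/leaf vertices inheriting the rank of their image and an
  affine rescale to the anchors.  Using distinct integer ranks instead
  of epsilon-perturbed reals guarantees the strict inequalities of (C2)
  without floating-point fragility, and makes the relocation edge
  unique.
* **Self-loops and 2-cycles** in the auxiliary graph count as cycles
  and are certified like any other cycle.
* **Cycle certificates** are extracted from a strongly connected
  component, walking smallest-successor-first from the smallest vertex,
  so refusals are deterministic too.
* The stated `O(|V(T)| log |V(S)|)` cost of the relocation loop assumes
  the species-tree height is logarithmic; for caterpillar species trees
  the walk is linear in the height.  We implement the stated procedure
  and do not attempt to improve the bound.

## The scenario simulator

`simulate_scenario()` draws a dated species tree (uniform ranked
topology, splits at times `i/n`, contemporary leaves, planted root at
time −1) and evolves one gene lineage forward.  On entering a species
edge a lineage suffers at most one event — duplication, transfer or
loss, with the configured per-edge-traversal probabilities (children
restart the draw, so several events per edge do occur); at species
vertices the gene is copied into every daughter lineage.  Transfer
recipients are drawn uniformly from the species edges that overlap the
event time and are incomparable to the donor edge.  Extinct lineages
are pruned and unary vertices suppressed, which enforces O1 and O2 on
the observable tree.

Default rates (duplication 0.2, transfer 0.2, loss 0.1 per edge
traversal, six species, at most 64 nodes) were chosen once to produce
small gene families in which roughly every second family carries at
least one transfer — enough to exercise every code path without making
brute-force oracles intractable.

Two deliberate properties of this observability operationalization:

* A transfer whose donor-side lineage leaves no survivors would, after
  pruning, look like a vertical edge that secretly crosses species
  lineages ("hidden transfer"); the true positions of its ancestors
  then violate the reconciliation axioms.  Such scenarios are rejected
  and resampled, so the emitted ground truth `mu` and event times are
  always a valid, time-consistent reconciliation — which is what makes
  the simulator usable as a test oracle.
* A retained speciation always keeps children in distinct daughter
  species, so the Sigma1 repair (relabeling a speciation as a
  duplication) can never actually trigger here; the code path exists
  as a defensive rejection.

What the simulator does *not* emulate: realistic rate calibration,
replacement transfers, within-edge rate variation, sequence evolution,
and inference noise in the event labels.  Passing tests on simulated
data therefore show correctness of the combinatorial machinery on
observable scenarios, not robustness to mislabeled input.

## The enumerated instance family

`enumerate_small_instances()` generates *every* binary observable
instance within its limits (gene leaves, species count, transfer count),
with `sigma` surjective, deduplicated up to isomorphism including
species relabeling, in a deterministic order.  The verification suites
run on the family with 4 gene leaves, 3 species and 2 transfers
(434 instances) plus the named fixtures and seeded simulator instances;
these sizes keep the double-brute-force oracles (all candidate maps ×
all rank assignments) exhaustive yet fast.  The guard accepts limits up
to 6 leaves / 4 species / 2 transfers, but the family grows very
quickly; the crossing-transfer fixture `G2S1` (6 leaves, 4 species) is
included explicitly so that both verdicts of the existence question are
exercised.

## Worked example

```{r example}
fx <- named_fixture("G1S0")
r <- reconcile(fx$gene, fx$species)
r$status
r$mu
round(r$tau$tau_T, 2)
round(r$tau$tau_S, 2)

fx2 <- named_fixture("G2S1")
r2 <- reconcile(fx2$gene, fx2$species)
r2$status
r2$cycle
```

The refusal certificate above is the 4-cycle `X -> v1 -> Y -> v2 -> X`:
the first transfer forces its vertex `v1` below the speciation `X` and
above the recipient subtree rooted at `Y`, the second forces `v2` below
`Y` and above `X` — no global time axis can satisfy both.

## Known limitations

* Event labels and `sigma` are taken as given; inferring them from
  orthology or sequence data is out of scope.
* No costs are optimized and the (possibly exponential) set of valid
  maps is never enumerated outside the brute-force test oracles.
* The species tree is fixed; searching for a species tree that admits a
  time-consistent reconciliation is an open problem.
* Dated (ultrametric) species trees and branch lengths are ignored;
  only the topological timing constraints are used.
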