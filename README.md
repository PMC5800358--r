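# hgtrecon

Time-consistent reconciliation of event-labeled gene trees with
horizontal gene transfer.

## What this package does

Genes evolve inside species through speciations (•), duplications (□),
horizontal gene transfers (△) and losses.  When the gene tree
`(T; t, σ)` is *event-labeled* — every internal vertex carries its event
type, every gene is assigned by `σ` to the species it resides in, and
the out-edges of transfer vertices are flagged — reconciling it with a
species tree `S` means finding a map

```
μ : V(T) → V(S) ∪ E(S)
```

that sends leaves to their species (M1), speciations to
`lca_S(σ_TĒ(u))` — the lca of the species below `u` in the transfer-free
forest `T_Ē` (M2i) — duplications and transfers to species-tree edges
(M2ii) with incomparable images at the two ends of each transfer edge
(M2iii), and preserves the ancestor order inside the components of `T_Ē`
(M3).

A valid `μ` can still require a gene to travel back in time: transfers
tie the timing of distant parts of `S` together.  `μ` is
**time-consistent** when time maps `τ_T`, `τ_S` exist with
`τ_T(u) = τ_S(μ(u))` for speciations and leaves (C1) and
`τ_S(x) < τ_T(u) < τ_S(y)` for duplications/transfers mapped to the edge
`(x, y)` (C2).  Both the check for a given `μ` and the existence question
for *some* `μ` reduce to acyclicity of a small directed constraint graph
on `V(T) ∪ V(S)`, which this package builds and decides in
`O(|V(T)| log |V(S)|)`; in the positive case it constructs `μ` and the
time maps explicitly, in the negative case it returns one cycle of the
constraint graph as a refusal certificate.

The package is aimed at researchers working on gene-family histories and
orthology inference who need a fast, certified feasibility check (or
counterexample) for event-labeled trees, e.g. downstream of
orthology/xenology inference and ahead of any cost-based reconciliation.

Also included: validators for the observability conditions (O1, O2,
Σ1, Σ2), the classical binary DTL-scenario formalism and conversions to
and from it, gene-family aggregation under an artificial duplication
root, a forward scenario simulator with ground truth, an exhaustive
small-instance enumerator, Newick/NHX + TSV file formats, and a command
line interface.

## Worked example

```r
library(hgtrecon)

fx <- named_fixture("G1S0")     # one transfer; species tree ((A,B)X,C)R
r  <- reconcile(fx$gene, fx$species)
r$status
#> [1] "consistent"
r$mu
#> <recon_map on 5 gene vertices>
#>   gene   kind species
#> 1    r vertex       X
#> 2    v   edge       B
#> 3    a vertex       A
#> 4    b vertex       B
#> 5    c vertex       C
r$tau$tau_T
#>   r   v   a   b   c
#> 0.0 1.0 0.5 1.5 2.0
r$tau$tau_S
#>    R    X    C    A    B  RHO
#> -0.5  0.0  2.0  0.5  1.5 -1.0
```

The speciation root `r` is simultaneous with its image `X` (time 0); the
transfer vertex `v` sits on the species edge `(X, B)` strictly between
the times of `X` (0) and `B` (1.5), as (C2) requires.  `RHO` is the
planted species root anchored at time −1.

With two crossing transfers no global time axis exists and the package
refuses with a certificate:

```r
fx2 <- named_fixture("G2S1")
r2  <- reconcile(fx2$gene, fx2$species)
r2$status
#> [1] "inconsistent"
r2$cycle$vertex
#> [1] "X"  "v1" "Y"  "v2"
```

## Command line

```sh
inst/exec/hgtrecon reconcile gene.nhx species.nwk --out-dir out/
inst/exec/hgtrecon validate-tree gene.nhx --json
inst/exec/hgtrecon check-exists gene.nhx species.nwk
```

Exit codes: 0 success/consistent, 3 valid trees but no time-consistent
reconciliation, 4 invalid trees or map, 2 usage error.  Gene trees are
Newick with NHX tags (`ev=spe|dup|hgt|leaf`, `trans=0|1` on the edge to
the parent; `σ` from an `S=` tag, a `gene_SPECIES` leaf-name suffix, or
a TSV).

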