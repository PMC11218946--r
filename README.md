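# rnatangle

Topological artifact detection in predicted 3D RNA structures.

Computational RNA 3D structure predictors — especially deep-learning
methods — sometimes emit models whose geometry no folding chain could
reach: the backbone ties a knot, or one structural element spears through
another. Experimentally determined RNA structures essentially never show
these conformations, so their presence in a predicted model flags a
modelling artifact. `rnatangle` audits models (PDB/mmCIF) for both classes
of defect and is aimed at structure predictors and assessors who want an
automated topology check before publishing or ranking models.

## What it computes

**Backbone knots.** The sugar-phosphate backbone (atoms P, O5′, C5′, C4′,
C3′, O3′) is an open curve, so knotting is assessed under stochastic chain
closure: both endpoints are projected onto a large sphere and connected
through random points (200 closures by default). Each closed curve is
simplified by KMT reduction, projected to a knot diagram, and identified
via its Alexander polynomial Δ(t) — computed exactly from the determinant
of the Alexander matrix and matched against the prime knots through 7
crossings (3₁ … 7₇). A chain is *knotted* when fewer than 50% of closures
are unknots; chains whose diagrams stay too complex are flagged TTC ("too
tangled to check"), and chains with duplicated atom coordinates are
rejected as invalid.

**Entanglements of structure elements.** The secondary structure (detected
geometrically from canonical A-U/G-C/G-U pairs, or read from a layered
dot-bracket) decomposes each chain into loops (L), dinucleotide steps (D),
and single strands (S). Every closed element is spanned by a triangulated
surface; punctures of that surface by other elements and pairwise Gauss
linking numbers classify each conflict into the nine subclasses
L&L, L&D, D&D (interlaces, linking number ≠ 0) and L(S), L(D), L(L), D(S),
D(D), D(L) (lassos). Lassos formed by loops get a depth — the number of
nucleotides a strand is threaded beyond the puncture — with depth ≤ 5
called shallow and depth > 5 deep. Interlaces, D(\*) lassos, and deep L(\*)
lassos are flagged as artifacts.

## Worked example

Build a hairpin whose 3′ tail threads the loop, then audit it:

```r
library(rnatangle)

fx <- make_hairpin_lasso(loop_size = 6, depth = 6)   # ground-truth fixture
ss <- annotate_base_pairs(fx$model, "dotbracket", dotbracket = fx$dotbracket)
entanglement_table(detect_all(fx$model, ss))
#>   subclass element_x element_y n_intersections lk depth depth_class artifact
#> 1     L(S)   L[3-10]  S[12-28]               1 NA     6        deep     TRUE
```

One L(S) lasso: the loop closed by pair 3–10 is pierced once by the
single strand 12–28, six nucleotides from its free end — a deep lasso,
hence an artifact. Knot assessment on an opened trefoil curve:

```r
cur <- make_knot_curve("torus", 2, 3, n_points = 200, open_fraction = 0.05)
assess_knot(cur$points, n_closures = 200, seed = 42)
#> <knot_assessment>  knotted: 3_1
#>   closures: 3_1=200
#>   direct closure: 3_1
```

All 200 random closures identify the trefoil, so the chain is called
knotted with dominant label 3₁ and an agreeing direct closure.

Batch audits run from the shell via the installed `exec/rnatangle` script:

```sh
rnatangle scan --input models/ --closures 200 --seed 1 --out audit/
rnatangle knots model.pdb
rnatangle synth hairpin_lasso --depth 7 --out lasso.pdb
```

`scan` writes per-model JSON reports, a flat entanglement CSV, a summary
CSV with the columns Models / Interlaces / Lassos / Trefoils / Other knots
/ TTC stratified by target or method class, and a run manifest.

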