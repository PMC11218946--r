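---
title: "Auditing predicted 3D RNA structures for topological artifacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing predicted 3D RNA structures for topological artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnatangle)
```

## The problem

RNA folds hierarchically: secondary structure forms first and the tertiary
fold arranges the resulting helices and loops in space. That history
constrains what geometries are reachable. A chain that would have to pass
through an already-closed loop, or tie its backbone into a knot, faces a
topological barrier that folding essentially never crosses — which is why
high-resolution experimental RNA structures are, with marginal exceptions,
unknotted and unentangled. Structure *predictors*, however, do not fold;
they guess a final conformation directly, and nothing in a coordinate
regression penalizes an impossible topology. `rnatangle` makes the two
relevant classes of defect measurable: backbone knots, and entanglements
of structure elements.

## Entanglements of structure elements

### Elements

Given canonical base pairs (Watson–Crick A-U and G-C, wobble G-U), each
chain decomposes into three element kinds:

* **Loops (L)** — closed cycles alternating backbone arcs with
  hydrogen-bond edges: a closing pair plus its directly enclosed pairs.
  Hairpin, internal, and multibranch cycles are all spanned; whether a
  junction cycle should count was genuinely open, and we span all loop
  cycles because a threading through any closed cycle is equally
  unreachable by ordered folding.
* **Dinucleotide steps (D)** — the quadrilateral of two stacked pairs
  (i, j), (i+1, j−1); helix interiors are covered by their steps, not
  emitted as two-pair "loops".
* **Single strands (S)** — maximal unpaired runs not enclosed by any pair
  (dangling ends and inter-domain linkers), extended by their flanking
  paired anchors so that threading near a strand end is still seen; depth
  counting uses the unpaired residues only. Unpaired residues *inside* a
  pair span already belong to that loop's cycle and are not re-reported as
  strands.

Element curves traverse the six backbone atoms per residue; hydrogen-bond
edges are single straight segments between per-residue anchor points (C1′
when present, C4′ for backbone-only fixtures). Pseudoknot pairs are
assigned to crossing-free layers and close loops exactly like nested
pairs.

### Surfaces, punctures, and linking

Each closed element is spanned by a triangle fan from its boundary
centroid, refined by three rounds of midpoint subdivision with Laplacian
relaxation of interior vertices (boundary fixed). The surface is a
combinatorial device: the topological verdict must not depend on it, and
the tests check that one vs three refinement rounds never changes a label.
Punctures are segment–triangle intersections (absolute tolerance 1e-6 Å;
hits closer than 0.1 Å along the piercing element are merged, as happens
when a segment grazes a shared triangle edge), each carrying a sign from
the surface orientation. Linking numbers are computed exactly for
polygonal curves as Gauss solid-angle sums, no projection involved. For a
closed piercer the signed punctures must total the linking number — an
identity the test suite checks on every linked fixture.

Classification of a pair (X closed, Y any, sharing no residue):
linking ≠ 0 gives an interlace (L&L, L&D, D&D); linking 0 with punctures
gives a lasso X(Y). Interlaces and D(\*) lassos are always artifacts.
L(\*) lassos carry a depth: with a single puncture by a strand, the number
of the strand's unpaired nucleotides beyond the crossing segment toward
each chain end, minimized over the two directions; with two punctures, the
nucleotides strictly between the crossing segments. Depth ≤ 5 is shallow
(such lassos can plausibly slip out during folding and are not flagged),
depth > 5 is deep and counts as an artifact. The counting convention —
residues strictly beyond the crossing-adjacent residue — is fixed by the
worked 69-nt example in the package's validation suite, where a strand
spanning residues 36–69 pierced between residues 62 and 63 has depth 6.

## Backbone knots

### Protocol

The backbone polyline of each chain (P, O5′, C5′, C4′, C3′, O3′ per
residue, in that order; a missing 5′-terminal phosphate is tolerated, any
other incomplete residue is skipped with a warning) is an *open* curve.
Knot type is therefore a distribution, not a single value:

1. **KMT reduction** deletes any interior vertex whose neighbour triangle
   no other chain segment crosses, iterated to a fixed point. Endpoints
   are never deleted. Coplanar segment/triangle incidences are resolved by
   an exact 2D clip, so planar regions reduce correctly.
2. **Two-point stochastic closure**, 200 times: both endpoints are pushed
   radially onto a sphere centred at the chain centroid with radius 10×
   the chain extent, then joined through a random point on the far
   hemisphere along great-circle arcs (15° steps). The connecting path
   stays an order of magnitude outside the chain, so only the closure
   randomness — not the connecting geometry — decides the knot type.
   Per-closure RNG streams derive deterministically from the master seed
   and closure index, making histograms bit-for-bit reproducible.
3. **Diagram and invariant**: each closed curve is projected along a
   random direction, redrawn (up to 100 times) if the projection violates
   general position; crossings give the Alexander matrix, whose reduced
   determinant is computed exactly over ℤ[t] by fraction-free (Bareiss)
   elimination and normalized to ±t^k with positive constant term. Labels
   come from a table of the prime knots through 7 crossings, where the
   polynomial is a complete separator. Unmatched polynomials (composites,
   8+ crossings) report `"unknown"`.

A chain is **knotted** when strictly fewer than 50% of completed closures
are unknots. The dominant label is the most frequent non-trivial one. A
single **direct closure** (straight end-to-end segment) is also
classified; probabilistically-knotted chains whose direct closure is an
unknot are flagged `ambiguous` and can be discarded with an option rather
than silently.

### Failure modes as categories

Two situations end an assessment without a knot label, and both are
reported as data rather than errors: models with duplicated atom
coordinates (within 0.01 Å across residues) are status
`invalid-coordinates`, and chains whose diagrams still exceed the crossing
budget (default 50) after reduction in more than 20% of closures — or that
repeatedly fail general position — are TTC, *too tangled to check*. The
TTC operationalization is a package decision: the category is real in
practice (absurdly dense models exist) but has no standard quantitative
definition; a crossing budget after reduction is cheap, monotone in
density, and the 20% margin keeps isolated bad projections from
reclassifying a model.

## Synthetic ground truth

Every detector is validated against generators whose truth is fixed by
construction, not by the detector:

* **Torus knots** T(2,3), T(2,5), T(2,7) from the standard
  parametrization; their Alexander polynomials have a closed form, used as
  the independent oracle.
* **Twist knots** (3₁, 4₁, 5₂, 6₁, 7₂) as polygonal templates: a
  double-helix loop with m half-twists whose top lobe threads the bottom
  lobe. The template's knot types were calibrated once against the
  closed-form twist-knot Alexander polynomials and then frozen.
* **Entanglement fixtures** with 6 backbone atoms per residue at an
  idealized 5.9 Å virtual P–P spacing: a clean hairpin; a hairpin whose 3′
  tail pierces the loop with *programmed* depth (the crossing segment is
  placed between two specific tail residues, so depth recovery must be
  exact, not approximate); interlocked hairpin loops with linking number
  ±1; a dinucleotide step threaded by a strand; and untangled controls
  where the same tail is routed outside.
* **Degenerate fixtures**: a dense confined random walk (1,500 steps in a
  15 Å box) for the TTC pathway, and a hairpin with a copied phosphate for
  the invalid-coordinates pathway.

What the fixtures do *not* emulate: real base geometry (only the idealized
helix carries donor/acceptor atoms), thermodynamically plausible folds,
atom clashes, or the noisy, partially malformed files of real prediction
archives. Passing tests therefore demonstrate correctness of the
topological machinery on well-formed inputs, and the file-level
sanitization (CASP header stripping, heteroatom removal, incomplete
residues) is tested separately on constructed corruptions — but
correctness on any particular prediction archive also depends on the
base-pair annotation used, which is the main source of divergence between
annotation tools.

## Numerical choices

* Geometric pair detection accepts A-U/G-C/G-U when all canonical
  donor–acceptor distances fall in 2.4–3.5 Å and C1′–C1′ in 10–11 Å; each
  residue keeps its best-scoring partner. These are conventional
  canonical-pair ranges; the upstream annotation a given archive was
  scored with may differ, so a layered dot-bracket can be supplied
  instead.
* Segment–triangle tests use absolute tolerance 1e-9 (KMT) and 1e-6 Å
  (punctures); projections reject crossings within 1e-7 of a vertex or
  tangency and depth separations below 1e-7.
* Bareiss elimination keeps Alexander coefficients exact in double
  precision for every diagram within the crossing budget; the budget (50)
  also bounds the determinant's size far below the 2^53 integer limit.
* The closure sphere's radius factor (10×) guarantees the closing arcs
  clear the chain's convex hull; arc discretization at 15° adds ≤ 24
  vertices per closure, which KMT removes again immediately.

## Problem sizes

The shipped validation runs at desk scale by choice: knot fixtures of
150–240 vertices, entanglement fixtures of 14–40 residues, 200 closures
for protocol-level checks and 40–100 for batch tests, and a six-model
cohort through the full pipeline. The same code paths take full-size
prediction archives; a 41-group CASP-style cohort is a matter of wall
time, not of different machinery.

## Known limitations

* Knot labels stop at 7 crossings; beyond that the report is honest but
  coarse (`"unknown"`), matching the practical need to separate trefoils
  from "more complex".
* The Alexander polynomial cannot distinguish a knot from its mirror
  image, and distinct knots share polynomials from 8+ crossings onward.
* Inter-chain entanglements are detected, but the element decomposition
  assumes pairs within a chain; inter-chain base pairs are not annotated.
* Geometric pair detection requires base atoms; backbone-only models must
  supply a dot-bracket.
* The radial closure geometry is one faithful realization of two-point
  sphere closure; closure histograms from other implementations may
  differ in the tails even when the knotted/unknotted verdict agrees.
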