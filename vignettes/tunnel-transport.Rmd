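---
title: "Tunnel detection and ligand transport: methods and parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tunnel detection and ligand transport: methods and parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tunnelr)
```

This vignette is the package's account of what it computes, which
assumptions it makes, and where the genuinely open design choices were
decided.

## The geometric model

A protein structure is reduced to a set of spheres: atom centres with van
der Waals radii (Bondi values by default — H 1.20, C 1.70, N 1.55, O 1.52,
S 1.80, P 1.80, halogens 1.47/1.75/1.85/1.98, default 1.70 Å; the table is
user-replaceable in `assign_radii()`). Hydrogens are used if present and
never added; only blank/'A' alternate locations are kept; coordinates stay
in the input frame.

`build_network()` computes the 3D Delaunay tessellation of the considered
atom centres (Bowyer–Watson incremental insertion, implemented in C++ in
this package). Voronoi vertices are circumcentres of the finite tetrahedra;
Voronoi edges connect circumcentres of facet-adjacent tetrahedra. We use
the ordinary Voronoi diagram of atom *centres* and make the geometry
van-der-Waals aware through the clearance function — the distance from a
point to the nearest atom *surface* — rather than constructing a weighted
(additively or power-) diagram. For near-uniform radii (protein heavy atoms
span 1.5–2.0 Å) the two constructions agree closely; the approximation can
shift bottleneck positions by a fraction of the radius spread, which is why
bottlenecks on real structures should be read with ±0.2 Å scepticism.

Numerical robustness: input points receive a deterministic hash jitter of
about 1e-9 of the bounding-box diagonal before tessellation, which removes
exactly-cospherical degeneracies (lattice fixtures additionally jitter
their atoms by 5% of the lattice constant for the same reason). Points
whose insertion would still create a degenerate cell are skipped with a
warning if they exceed 0.1% of the input; tessellation output is fully
deterministic for identical input.

### Edge costs

Each edge is sampled at its endpoints plus interior points (at least
`edge_samples = 3`, and at least one per 0.5 Å for long edges, capped at
64: long Voronoi edges through open space would otherwise hide narrow
passages from both the probe filter and the cost). Segment costs are
`seg_len / clearance(midpoint)^2`; a segment whose midpoint clearance is
non-positive makes the edge impassable (infinite cost). The per-edge
minimum clearance is the minimum over all sampled points and is the
quantity the probe filter tests.

### Bulk, surface, interior

`label_bulk()` marks as **bulk** the vertices where a probe of
`shell_radius` (default 3 Å) fits *and* that communicate with the unbounded
exterior through edges the same probe can pass, seeded at the tessellation
hull. The connectivity requirement is deliberate: a wide, fully enclosed
cavity — exactly where tunnel searches start — is not bulk solvent, and a
pure clearance threshold would label it so, leaving no valid starting
vertex. Non-bulk vertices within `shell_depth` (default 4 Å, path length
along edges) of bulk are **surface**; the rest are **interior**. A
`shell_depth` of 0 disables the surface layer.

### Tunnel search

`find_tunnels()` restricts the graph to edges whose minimum clearance is at
least `probe_radius` (default 0.9 Å) with finite cost, removes bulk
vertices, and runs Dijkstra (via igraph) from the starting vertex. Goal
vertices are non-bulk vertices with a probe-passable edge into bulk; among
neighbouring goals only local cost minima are kept, which collapses the
many near-duplicate mouths of a single opening before clustering. Each
path is truncated at its first bulk-adjacent vertex and then continued
along that vertex's cheapest passable exit edge until the shell probe first
fits — that point is "the protein surface" for the purposes of tunnel
length. The centerline is resampled at 0.5 Å and `r(l)` is recomputed as
the true clearance at each resampled point (not interpolated vertex
clearance), so a narrow passage inside a long exit edge is measured, not
skipped.

Properties follow from the centerline: length `L`, bottleneck `min r(l)`,
curvature `L / ‖start − end‖`, cost as the trapezoidal integral of
`r(l)^-2`, throughput `exp(-cost)`. Clustering uses the mean Euclidean
distance between centerlines resampled at 20 equal arc-length fractions,
average linkage, cut at `clustering_threshold` (default 3.5 Å of that
metric — the metric is defined here precisely because dendrogram units are
otherwise ambiguous). Ties anywhere are broken by vertex/tunnel id.

### Starting points and pockets

Four modes produce the raw point: explicit coordinates; the unweighted mean
over selected residues of their mass-weighted centres; the mass-weighted
centre of a bound ligand; or the residue-centre mean of a detected pocket.
`snap_to_vertex()` then snaps it to the nearest non-bulk vertex within
`maximal_distance` (default 3 Å, hard) whose clearance reaches
`desired_radius` (default 5 Å, soft); if none qualifies the
largest-clearance vertex in range is used with a warning.

`detect_pockets()` admits Voronoi vertices whose touching-sphere radius —
measured to atom centres, the usual alpha-sphere convention — lies in
[`alpha_min` = 3, `alpha_max` = 6] Å, that are collision-free, not bulk at
the pocket scale (bulk is relabelled at `shell_radius = alpha_max` here,
since the tunnel-scale 3 Å shell would swallow any open pocket), and that
pass a burial test: the mean of the unit directions to the sphere's contact
atoms must be shorter than 0.7. The burial test is what separates a genuine
pocket sphere (contacts on several sides cancel) from a sphere floating
just outside the surface (contacts in a one-sided cone); without it, every
convex body grows spurious "pockets" a few ångströms above its surface.
Spheres are single-linkage clustered at `cluster_dist` = 4.5 Å, clusters
below `min_spheres` = 10 are dropped as packing noise, and pockets are
ranked by a Monte-Carlo union-of-spheres volume (20 000 samples, fixed
internal seed, hence deterministic; ties broken by centroid order).
Catalytic flagging is reduced to matching a user-supplied residue list —
database lookups are out of scope. Note that the residue-centre starting
point of a bowl-shaped pocket can land marginally inside the bowl's wall;
the subsequent snap always restores a collision-free vertex.

## Ligand transport

`discretize()` places discs along the centerline at arc lengths `0, delta,
2·delta, …` plus the end (default `delta` = 0.3 Å); the disc normal is the
local tangent and the disc radius is `r(l) + disc_margin` (default 1 Å —
the margin lets the anchor explore off-centre positions; it is exposed
because no canonical value exists).

The pose score is a capped 12-6 potential: for each ligand/receptor atom
pair within 8 Å, `e = 0.2 · ((s/d)^12 − 2 (s/d)^6)` with `s` the sum of the
vdW radii, capped at +10 per pair. It is a *steric* score: energies are
dimensionless, not comparable to any docking or force-field scale, and
charges present in input files are ignored. Only the shape of a profile
and the ordering of barriers carry meaning. Receptor flexibility is
excluded by design; the ligand is rigid.

`optimize_on_disc()` minimizes the score over 2 in-plane + 3 rotational
degrees of freedom: `n_starts` = 24 seeded random starts (uniform over the
disc, axis-angle rotations up to π) plus the base pose, each refined by a
deterministic Nelder–Mead (150 iterations, constraint violations penalized
quadratically, final pose projected into the feasible set and re-scored
without penalty). For a single-atom ligand the rotational degrees are
vacuous and any rotation restraint is dropped, which makes the two bound
modes agree exactly there.

The **lower bound** optimizes discs independently — entries are independent
of their neighbours by construction. The **upper bound** walks the discs in
trajectory order, restricting each step's rotation to `max_rotation` = 10°
from the previous pose; if the result exceeds the lower bound at that disc
by more than `energy_slack` = 2.0, it backtracks up to `backtrack_window` =
5 discs with fresh seeded restarts, and reports `status = "failed"` when
the budget is exhausted — failure is a legal outcome meaning no continuous
passage was found at this rotation budget, not an error. These three
control parameters are parameterized stand-ins, not claims about any
reference implementation's internals. Any feasible pose the constrained
pass discovers that beats the unconstrained per-disc minimum also updates
the lower-bound profile (best-found-incumbent semantics), which both
sharpens the lower bound and guarantees the documented upper ≥ lower
ordering at shared seeds.

Direction `"in"` iterates discs from mouth to active site. Barrier
extraction (`barrier_analysis()`): `E_B` is the minimum over the 20% of
discs nearest the site end, `E_S` the minimum over the 20% nearest the
mouth, `E_MAX` the maximum between those two minima; `Ea = E_MAX − E_S`
("in") or `E_MAX − E_B` ("out"), `ΔE_bind = E_B − E_S`. Explicit indices
(site-to-mouth order, 1-based) override the automatic rules.

Determinism: every random draw comes from a per-disc stream derived from
`(seed, disc index, backtrack attempt)`; identical inputs and seed give
bit-identical profiles.

## The synthetic fixtures, and what passing them shows

`make_shell_channel()` builds a hollow shell of carbon pseudo-atoms on a
jittered cubic lattice and drills straight channels of known radius;
`make_dented_shell()` builds a *solid* ball with hemispherical surface
dents (solid deliberately: a hollow ball's enclosed cavity would itself be
a legitimate pocket and would confound pocket counting). Ground truth —
axis clearance profiles, bottleneck value and position, the closed-form
cost integral — is recorded by brute-force geometry at generation time and
consumed by the tests directly, so no expected value is hard-coded.

Test problem sizes were chosen as the smallest that keep the analytic
channels well resolved: unit-test shells use lattice spacing 0.8–1.0 Å
(2 000–3 500 atoms); the cylinder-recovery check runs one 49 000-atom shell
at 0.5 Å spacing. The transport co-location fixture places its constriction
(drilled radius 0.6 Å, probe lowered to 0.7 Å accordingly) near the tunnel
mouth: with a dense pseudo-atom wall the attractive tail of the 12-6 score
rises smoothly toward the mouth, and a constriction must clash sterically —
and sit where the residual attractive rise beyond it is small — for its
spike to be the global maximum. That is a property of real profiles too:
shallow constrictions near a buried end can be masked by the binding well.

What the fixtures do *not* emulate: chemical heterogeneity (all
pseudo-atoms are carbons), realistic packing density (the lattice is
denser than protein interiors, which inflates the attractive baseline),
side-chain texture of tunnel walls, conformational flexibility, and
electrostatics. Passing these tests therefore demonstrates geometric and
algorithmic correctness — not that the steric score predicts measured
transport kinetics.

## Known limitations

* Ordinary Voronoi of centres (not a power diagram): small bottleneck bias
  where radii vary strongly, e.g. around sulphur or bound ions.
* The steric score has no electrostatics, desolvation or torsional terms;
  absolute energies and even relative depths between different ligands are
  not meaningful beyond ordering.
* Upper-bound failure depends on the rotation budget and backtracking
  window; a failure is evidence of difficulty, not impossibility.
* Single-model, single-conformer analysis; no trajectory support.
* Pocket ranking is by estimated volume only; druggability-style scores are
  intentionally not computed.
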