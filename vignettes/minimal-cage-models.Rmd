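---
title: "Minimalistic bead models of cage self-assembly: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimalistic bead models of cage self-assembly: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicage)
```

## The model

Self-assembled cage molecules — porous organic cages, metal–organic cages —
form when ditopic ("linker") and tritopic or tetratopic ("node") building
blocks condense into a closed polyhedral architecture. Which topology
(Tri4Di6, Tet6Di12, ...) actually forms depends strongly on a handful of
geometric parameters of the building blocks, above all the ditopic ligand's
bite angle and the pyramidalisation of the node. `minicage` implements a
deliberately minimal bead model of this problem: each building block is a
handful of beads with harmonic bonds and angles, cages are assembled on
idealised topology graphs, and a cage's *geometric* stability is read off
the residual strain energy of its best conformer.

### Building blocks

Three block types are built from five bead classes:

* **ditopic** `a–c–a`: three collinear beads; the two `a` beads are the
  binders. The internal b–a–c angle target `theta0` (set at assembly, when
  the partner `b` bead exists) defines the bite angle through
  `theta_bite = 2 (theta0 - 90)`, valid when the backbone is straight and
  the b–a–a–b torsion is near zero. The block therefore carries an a–c–a
  angle term at 180 degrees; without a straight backbone the bite angle
  would be undefined. This term can be switched off.
* **tritopic** `n + 3b`: the three binders sit on a cone about the local
  z axis at polar angle `alpha = acos(sqrt((2 cos(theta) + 1) / 3))`, the
  unique placement making all three pairwise b–n–b angles equal the target
  `theta` (120 degrees = planar).
* **tetratopic** `m + 4b`: four binders on a cone at
  `alpha = acos(sqrt(cos(theta)))`, which makes the four adjacent b–m–b
  angles equal `theta` and the two opposite angles `2 alpha`
  (90 degrees = square planar, opposite angle 180). The opposite-angle
  closure follows from the square-pyramid construction; it is the only
  symmetric completion once the adjacent angle is fixed.

Blocks are emitted at exact internal equilibrium (zero internal strain),
which the test suite verifies by measuring angles directly from the
coordinates. Bond targets come from the Lorentz mixing rule
`r0(i, j) = (r_i + r_j) / 2`. Defaults: bond radius 2 A for every class,
`sigma` 1 A, `epsilon` 10 kJ/mol. The 2 A radius is a configurable
placeholder — phase maps are reported in angle space, which is the axis of
interest, and the angle-space results are insensitive to a uniform radius
choice.

### Topologies

A topology graph types each vertex by required arity and fixes an ideal
unit-scale position (centred, unit circumradius). The registry covers the
eleven standard graphs: midpoint constructions (polyhedron vertices for the
nodes, edge midpoints for the linkers) for Tri4Di6 (tetrahedron), Tri6Di9
(equilateral trigonal prism), Tri8Di12 (cube), Tet6Di12 (octahedron),
Tet8Di16 (equal-edge square antiprism), Tet12Di24 (cuboctahedron); polar
constructions for Tri2Di3 and Tet2Di4; the octahedron-plus-cube
Tet6Tri8 with its 24 node–node contacts; and the double-bridged tetrahedra
Tri4_2Di6 and Tet4_2Di8. For the two subscript variants the literature
graph was not available in detail, so documented fallback constructions are
used: a tetrahedron of nodes with two doubled bridges completing the
degree requirement. The registry is open — custom graphs can be registered
from vertex/edge tables and are validated (degree = arity, handshake,
connectivity, no ditopic binding one partner twice).

### Assembly

Each block is rigidly moved onto its scaled vertex position with the
rotation that best superposes its binder directions onto its incident edge
directions (orthogonal Procrustes per binder-to-edge assignment; the
assignment itself is chosen by enumerating the at most 4! permutations).
Mirror-degenerate alignments are broken deterministically: permutations are
visited in lexicographic order and only strict improvements are accepted,
so the lowest-index binder pairs with the lowest-index edge. The assembly
scale is the smallest multiplier for which every edge accommodates the two
block extents plus the new bond, grown by 10% steps until no inter-block
bead pair is closer than 1.2 sigma; the procedure is deterministic.

Assembly then enumerates every force-field term:

* one constructed bond per topology edge, between the binder beads
  assigned to that edge;
* a b–a–c angle at each ditopic binder, at the block's stored target;
* centre–binder–partner "straightness" angles (n–b–a, m–b–a, and n–b–b /
  m–b–b in Tet6Tri8) at 180 degrees, so that the b–a–c angle controls the
  geometry the way the bite-angle picture assumes (configurable off);
* with the torsion restriction **on**, one b–a–a–b quadruple per ditopic
  block. The torsion is *alchemical*: the two `a` beads are not mutually
  bonded (they connect through `c`), but the dihedral of the four
  positions in that order is exactly the quantity that distinguishes both
  binding sites facing the same direction (0 degrees) from opposite
  directions (180). With `E = k (1 + cos(p phi - phi0))`, `p = 1` and
  `phi0 = 180` the minimum sits at `phi = 0` with `E = 0` and the barrier
  at 180 is `2 k = 100` kJ/mol.

Excluded-volume interactions are omitted for bead pairs separated by two
or fewer bonds (the conventional bond-cutoff exemption); everything else
interacts.

## Force field and units

`E = E_bond + E_angle + E_torsion + E_excl_vol` with harmonic bond and
angle terms in the 1/2-convention, the cosine torsion above, and a purely
repulsive excluded-volume term
`sqrt(eps_i eps_j) (sigma_ij / r)^12`, `sigma_ij = (sigma_i + sigma_j)/2`,
truncated and shifted to zero at `3 sigma_ij`. A purely repulsive form is
the right choice for a good-solvent model: collapse should be driven by
geometric frustration, not by attraction between beads. Defaults:
`k_bond` 1e5 kJ/mol/nm^2 (= 1e3 kJ/mol/A^2 — the unit conversion is
exactly a factor 100), `k_angle` 1e2 kJ/mol/rad^2, `k_torsion` 50 kJ/mol.
Angles are degrees at every user interface and radians inside the energy
kernel. Coordinates are Angstrom, energies kJ/mol.

The kernel (bond/angle/torsion/excluded-volume energies and their analytic
gradient) is compiled C++; the gradient is verified against central finite
differences to relative error below 1e-5 in the test suite, and energy
invariance under rigid motion to below 1e-8 kJ/mol. Numerical guards: a
coincident non-exempt pair contributes a large finite penalty rather than
overflowing, and the angle gradient is skipped within 1e-8 of the
0/180-degree singularities of `acos` (where the harmonic restoring force
vanishes for the 180-degree terms anyway).

## Conformer search

One local minimisation from the construction geometry is not enough: the
assembled cage can sit on the wrong side of a barrier (typically collapsed
or partially inverted states). The search runs seven stages:

1. constrained minimisation with every intra-block bond stiffly restrained
   at its current length — the freshly constructed inter-block bonds relax
   first;
2. full minimisation;
3. softened-potential stochastic dynamics: overdamped Brownian steps with
   `k_bond` and `k_angle` scaled by 0.1, `kBT = 2.5` kJ/mol, 2000 steps,
   8 evenly spaced frames kept (the model neglects temperature; these are
   search parameters only, chosen so the soft trajectory crosses angle
   barriers in a few thousand steps while remaining stable at
   `dt = 0.005`);
4. full minimisation of every frame;
5. outward shift of all beads from the bead centroid by factors 1.25, 1.5
   and 2 — an anti-collapse restart;
6. full minimisation of each shifted start;
7. a tighter final minimisation of the best candidate.

The lowest-energy candidate wins, and the result can never be worse than
stage 2 alone (best-of-candidates). The whole sequence is reproducible
from one integer seed. Minimisation uses L-BFGS-B on the analytic
gradient. Gradient tolerances are 1e-2 kJ/mol/A for the search stages and
1e-3 for the final polish: in double precision the line search stalls at a
maximum gradient component around 4e-4 kJ/mol/A for these systems (energy
scale set by `k_bond` = 1e3), so demanding much tighter values would flag
fully converged structures as unconverged. At these tolerances the
residual energy resolution is orders of magnitude below the 0.3 kJ/mol
stability threshold.

The stability score is `E_b`, the optimised total energy divided by the
number of building blocks, comparable across topologies of different size.

## Phase space and self-sorting

A scan crosses each topology with the angle grid restricted to the block
types it needs (ditopic 90–180 in 5-degree steps, tritopic 50–120 and
tetratopic 50–90 in 10-degree steps by default) and both torsion states if
requested. Every phase point gets a seed derived deterministically from
the master seed and the point identity, so results are independent of
evaluation order and scans are resumable. An optional repeat count records
the seed-to-seed spread of `E_b` per point (`E_b_spread`), surfacing
optimiser instability rather than hiding it.

A structure is *accessible* when `E_b <= 0.3` kJ/mol. The threshold is a
model-dependent choice (the energy scale is alchemical); it is exposed as
a parameter everywhere and the percent-selected curve shows how the degree
of self-sorting depends on it. Per building-block combination and torsion
state the outcome is **unstable** (no stable topology), **selective**
(exactly one — self-sorting is assumed to occur), or **mixed** (two or
more compete); the smallest stable topology by block count is recorded as
the likely kinetic product. Accessible topology maps arrange these
outcomes on the rectangular angle grid, with missing points labelled
`unknown` rather than dropped.

Two structural invariants of the machinery are tested: stable sets are
monotone in the threshold, and relaxing the torsion restriction never
destabilises a phase point (flexibility can only help, within optimiser
noise).

## Shape measures and pore radius

The continuous shape measure of an n-point set against a reference
polyhedron is `100 * min` over vertex labelling, rotation, translation and
isotropic scale of the normalised squared deviation. Rotation and scale
are closed-form per labelling (singular value decomposition with the
determinant sign correction); the labelling minimum is exact, found by
depth-first assignment with an upper bound from pairing the remaining
radius products in sorted order — a valid bound since each matched pair
can contribute at most the product of its distances from the centroid.
The pruned search is verified against exhaustive permutation enumeration.
Measures are computed on building-block centroids (unweighted over each
block's beads): e.g. the six tetratopic centroids of Tet6Di12 against the
octahedron OC-6, the eight tritopic centroids of Tet6Tri8 against the cube
CU-8. References are the regular polygon/polyhedron for TP-3, SP-4, T-4,
OC-6, CU-8, the equilateral trigonal prism for TPR-6 and the equal-edge
square antiprism for SAPR-8; the registry is data-driven so alternative
reference geometries can be swapped in. Centroid sets with 12 or more
vertices (Tet12Di24) are skipped — factorial enumeration is the cost
driver — and report an empty map.

The pore radius is the simplest centroid-to-surface definition:
`max(0, min_i(|x_i - centroid| - sigma_i / 2))`. It is a rough cavity
proxy, not a probe-based cavity algorithm; window sizes and guest
accessibility are out of scope.

## What the defaults emulate, and what they do not

The default bead set, angle grids and search configuration are the study
conditions of the package: they emulate a discretised scan over symmetric,
single-size building blocks in a good solvent. Passing tests demonstrate
that the *geometric* logic of cage design — bite-angle/topology matching,
double-well stability surfaces, the drastic stabilisation from backbone
flexibility, ideal-shape recovery for stable rigid cages — emerges from
bead-scale harmonic terms alone. They do not show anything about
temperature, solvent, ions, metal stereochemistry and twist,
inter-building-block attraction, kinetics of assembly, or asymmetric /
mixed-size building blocks: none of these are modelled. Self-sorting
outcomes here are geometric accessibility statements and will produce
false positives relative to experiment.

## Problem sizes and runtime choices

The test suite and the acceptance script keep the published protocol at
sizes that finish in minutes on one CPU: the bite-angle scans run the full
18-point ditopic grid on Tet6Di12 (66 beads) and Tet12Di24 (132 beads);
the double-walled tetrahedron instability check uses a 5 x 5 sub-grid of
the default angle space; the flexibility comparison a 3 x 3 sub-grid over
three topologies and both torsion states. These are the package's own
reproducibility conditions; the full default grids are available through
`scan_phase_space()` and the command-line `scan` subcommand for larger
studies.

## Known limitations

* `Tri4_2Di6` and `Tet4_2Di8` use fallback graph constructions (documented
  above); their ideal ditopic placements are offset midpoints, which is a
  heuristic.
* The optimiser is a local-search heuristic; no global-optimality claim is
  made, and isolated phase points can land in the wrong well. The
  `repeats` option quantifies this.
* The shape-measure topology mapping covers centroid sets with 3–8
  vertices only.
* The alchemical torsion is defined on (b, a, a, b); if a convention
  including the centre bead were preferred, the phase would need
  re-deriving.
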