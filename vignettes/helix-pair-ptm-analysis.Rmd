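---
title: "Helix-pair motif geometry and PTM solvent accessibility: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helix-pair motif geometry and PTM solvent accessibility: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixptm)
```

This vignette is the package's account of its methods: the geometric
model of a helix-pair super-secondary motif, the classification of
α-α-corner versus L/V packings, the construction of modification
moieties, the solvent-accessibility measures, and the trajectory-level
stability statistics — together with the numerical choices behind each
and what the synthetic validation does and does not demonstrate.

## The coordinate model

Structures are held as a flat heavy-atom table plus one coordinate
matrix per model (the multi-model PDB convention; ensembles and
pseudo-trajectories are simply structures with several models).
Hydrogens in input files are discarded and backbone amide hydrogens are
rebuilt geometrically where needed, which makes every downstream
quantity independent of whether a deposited structure happens to
include hydrogens. Alternate locations collapse to the
highest-occupancy conformer (ties to altloc A); waters and ligands are
dropped by default. Van der Waals radii are fixed Bondi values (C 1.70,
N 1.55, O 1.52, S 1.80, P 1.80 Å): fixing the table is what makes the
solvent-accessibility numbers reproducible across machines and runs.

Residues are addressed two ways: 0-based half-open index ranges into a
chain's residue list (gap-safe, used by every algorithm) and author
residue numbers (used in all reported loci). Selenomethionine maps to
`M` for sequence search by default, since MSE is pervasive in X-ray
entries.

## Secondary structure

Assignment follows the Kabsch–Sander hydrogen-bond method. The amide H
is placed at 1.0 Å from N along the reversed carbonyl direction of the
preceding residue; prolines and chain-initial residues get none, and a
C(i−1)–N(i) distance above 2.5 Å is treated as a chain break (the
fragment is split for the bond search). The bond energy is the
electrostatic model

$$E = 0.084 \cdot 332 \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}}
      - \frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right)\ \text{kcal/mol},$$

accepted strictly below −0.5 kcal/mol; any of the four distances below
0.5 Å is a clash and never a bond. Two consecutive i→i+4 turns give H,
two consecutive i→i+3 turns give G, inter-strand bridge patterns give
E, everything else is C, with priority H > E > G on conflict. Only
these four states are assigned; bends, turns and π-helices are not
needed by any downstream step. Helix segments entering motif analysis
are maximal H runs of at least 5 residues (the shortest helix the
survey must represent is 5 residues); 3₁₀ runs can be merged in by
flag, off by default since corner geometry is defined on α-helices.

On generated ideal helices (φ/ψ = −57°/−47°) the assignment labels all
interior residues H; on hen lysozyme (the `bio3d` example entry, used
as an independent real-structure check) it recovers the canonical
helices at their literature positions.

## Helix axes and the six descriptors

The axis of a helix segment is the least-squares (first principal
component) line through the centroids of sliding four-residue Cα
windows, oriented N→C. Window centroids suppress the helical wobble
(for an ideal helix of Cα radius 2.3 Å the centroids lie within
~0.26 Å of the true axis), and the PCA line through them is exact for
ideal geometry and noise-robust otherwise. The segment length is the
span of the centroid projections; the mean Cα distance to the line is
reported as the local radius (~2.3 Å).

For two fitted segments the package computes:

- **d**, the distance between the infinite axis lines (for parallel
  lines, the ordinary parallel distance);
- **r**, the minimum distance between the finite segments (clamped
  closest-approach); `d ≤ r` always, and `d = r` exactly when the
  closest-approach parameters are interior to both segments — the
  operational meaning of "the axes intersect in projection";
- **θ**, the signed dihedral between the direction vectors about their
  common perpendicular. The perpendicular is oriented from the first
  helix's line towards the second's, and the angle is right-handed
  about it; with this convention θ is invariant under swapping the two
  helices, and the generator's crossing construction at distance
  d > 0 yields θ = −φ. Since the original sign convention of the
  torsion angle cannot be established from a single reported value,
  comparisons should use |θ| (the magnitude is convention-free);
- **φ**, the unsigned planar angle arccos |â·b̂| ∈ [0°, 90°];
- **S** and **P**, the area and perimeter of the convex intersection
  of the two projected rectangles.

For the projection, both helices are projected along the common
perpendicular onto the plane spanned by the two axis directions; each
helix becomes a finite rectangle of length equal to its fitted segment
and width 2·radius. The projection radius defaults to **5.0 Å** — the
side-chain envelope of an α-helix, distinct from the 2.3 Å Cα fit
radius. With width 10 Å, two long strips crossing at φ = 66° intersect
in a parallelogram of area 100/sin 66° ≈ 109.5 Å², which is the
worked-example value the pipeline reproduces; this consonance is what
fixed the default. The intersection itself is computed by successive
half-plane (Sutherland–Hodgman) clipping of one rectangle against the
other; an empty intersection reports S = P = 0. Finite rectangles
(rather than infinite strips) were chosen because segment truncation
is the only way the perimeter can fall below the strip closed form
2(w₁+w₂)/sin φ, as the reference perimeter value does. Near-parallel
pairs (φ < 1°) are projected along the common normal of the pair
instead; this is a generator-driven design choice, as the convention
for parallel axes has no unique natural definition.

All six descriptors are invariant under rigid motion of the complex
(validated to 1e−6), and d, r, φ, S, P are symmetric under swapping
the helices.

## Motif blocks and classification

Candidate blocks are anchored on ordered helix pairs (i, j), i < j, of
a chain: the block's locus runs from the start of helix i to the end of
helix j, and `n_helix` counts the helices lying fully inside. A block
is retained when the first and last helices are in contact,
**d ≤ 14 Å**. Classification uses two thresholds chosen so that the
worked corner example classifies correctly while random skew pairs do
not: the crossing test |d − r| ≤ 0.1 Å (axis-fit noise on ideal
helices is well below this) and the "zero or close to zero" area bound
S ≤ 1 Å² (clipping noise is orders of magnitude smaller). Pairs with
crossing axes and substantial area are α-α-corners; pairs with
non-crossing axes (d < r) and near-zero area are L/V-structures;
anything else is reported as unclassified rather than forced into a
bin. The chain-length cap used when selecting subunits for simulation
(< 200 residues) is available as an optional filter flag, off by
default, because it is a tractability constraint rather than a
geometric one.

## PTM notation and moiety construction

Annotated peptides use hyphen-delimited tokens inside the one-letter
sequence: `P(X)` phosphorylation (X ∈ S/T/Y), `AC(X)` acetylation
(lysine anywhere; any leading token denotes position 1, covering
N-terminal acetylation) and `GG(K)` the Gly-Gly ubiquitylation
remnant. Exactly one token per peptide is accepted; incompatible
token/residue combinations are notation errors.

Moieties are built at idealised internal coordinates on the anchor
atom — P–O 1.6 Å tetrahedral PO₃ on the S/T/Y hydroxyl oxygen, a
trigonal C(=O)CH₃ with C–N 1.33 Å on lysine NZ or the backbone N, and
an eight-heavy-atom Gly-Gly dipeptide remnant on NZ via an isopeptide
bond. The single attachment torsion is scanned in 30° steps and the
rotation minimising Σ 1/d² to neighbouring heavy atoms (within 6 Å) is
kept: a deterministic, clash-avoiding placement that makes the
solvent-accessibility numbers identical run-to-run. Remaining contacts
below 1.5 Å raise a warning, not an error. Phosphate carries no
protons and no moiety hydrogens are ever added, consistent with the
heavy-atom accessibility model; no charge assignment or energy
minimisation is attempted, so the builder is a geometric stand-in whose
adequacy is judged at the level of accessibility changes, not
energetics. Pre-existing atoms are never moved; the residue is renamed
(SEP/TPO/PTR/ALY/KGG) so the modification survives PDB round trips,
and those residue names map back to the parent one-letter codes so the
underlying sequence is unchanged.

## Solvent accessibility and the active environment

SASA is Shrake–Rupley on heavy atoms: each atom's sphere of radius
r_vdw + 1.4 Å is sampled with a deterministic 960-point Fibonacci
lattice, and the accessible fraction times the expanded-sphere area is
the atom's contribution. 960 points keep the isolated-sphere error
below 0.5% and the cluster-total error below 1% of a 10⁵-point dense
sampling, at a cost that lets the survey run interactively. Per-residue
areas are sums over the residue's atoms; moiety atoms count with their
residue, so the modified-residue area (VM) includes the added group.

The *active environment* of a modification is the set of residues,
excluding the modified one, whose per-residue SASA changes by more than
ε = 0.1 Å² between the native and modified structures — just above the
sampling noise of the 960-point lattice, so membership is driven by
real occlusion, not quadrature jitter. The survey over a set of
structures containing a peptide averages occurrences within each
structure first, then across structures, and reports VN/VM (target
residue before/after) and UN/UM (target plus active environment
before/after).

## Trajectories, clustering, stability

Pseudo-trajectories are multi-model structures (binary trajectory
formats are out of scope; converters exist). RMSD uses Kabsch
superposition with the reflection-corrected SVD rotation, on Cα by
default (backbone N/CA/C by flag). GROMOS clustering is the greedy
neighbour rule: the frame with the most neighbours within the cutoff
(self included) becomes a cluster centre and is removed with its
neighbours; ties go to the lowest frame index; cluster sizes are
non-increasing by construction, and the largest cluster is exposed
directly. Descriptor series re-fit both axes in every frame, store
frame 1 as the "stat" reference, and stability summaries report
per-descriptor mean, **sample (n−1)** standard deviation and the
maximum absolute deviation from the reference; the stat/nmd/mod
comparison table juxtaposes the initial values with the native and
modified series.

## The synthetic generator: what it emulates, and what not

`build_peptide` constructs peptides from canonical bond lengths/angles
by NeRF chaining; `build_ideal_helix` places backbone atoms on coaxial
helical tracks derived from the canonical α-helix (rise 1.5 Å/residue,
twist 100°, Cα radius 2.3 Å) and then rigidly corrects the structure so
its *fitted* axis coincides exactly with the requested line — which is
what makes the generator's target geometry an exact ground truth for
the measurement pipeline rather than an approximate one.
`build_helix_pair` places two helices at a requested axis distance and
crossing angle, with the closest approach interior (d = r) or slid
along the second axis to make r > d by a known amount, and returns the
analytic expectations alongside the structure. Gaussian
pseudo-trajectories add i.i.d. coordinate noise of a stated σ per
frame, deterministically from a seed.

The parameter-recovery suite samples crossing angles in [45°, 90°] and
helices of 21–26 residues: that is the regime in which the intersection
parallelogram lies fully inside both finite rectangles, so the strip
closed form w₁w₂/sin φ is the exact expected area. At shallower angles
or with shorter helices the rectangles truncate the parallelogram and
the closed form ceases to be the correct reference (the clipped area is
then validated against a Monte-Carlo point-sampling oracle instead).

What passing these tests shows: the measurement pipeline recovers known
geometry essentially exactly, the clipping and quadrature match
independent oracles, and every descriptor is rigid-motion invariant.
What it does not show: agreement with any particular crystal
structure's absolute solvent accessibilities (which depend on the real
packing environment), force-field realism of the pseudo-trajectories
(the noise model has no physics), or the original torsion-angle sign
convention. The two worked examples bundled with the analysis scripts
are therefore explicitly *synthetic stand-ins* built at the reported
motif geometry — the geometric quantities are re-measured honestly from
atoms, but the SASA magnitudes are properties of the stand-in, not of
the original crystal environment.

## Problem sizes and determinism

The bundled analyses use two-helix structures of ~48 residues,
30-frame pseudo-trajectories, 25–50 random pair specifications, 960
(fast) versus 10⁵ (dense) sphere points and 10⁶-point Monte-Carlo area
oracles; these sizes give oracle agreement well inside the stated
tolerances while keeping the whole suite interactive. Every stochastic
step takes an explicit seed; generators, torsion scans and quadrature
are otherwise fully deterministic.

## Known limitations

- Kinked helices are treated as single segments as assigned; no
  curvature model.
- β-sheet output is limited to the E state; no ladder/sheet topology.
- The moiety builder is geometric only: no pKa, charge, rotamer
  library or minimisation.
- mmCIF and binary trajectory formats are not read.
- The θ sign convention is internal; only |θ| should be compared
  across software.
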