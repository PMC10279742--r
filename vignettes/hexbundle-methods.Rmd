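---
title: "Models and methods behind hexbundle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hexbundle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexbundle)
```

# The system

The six-helix DNA bundle (6HB) is an archetypal DNA nanostructure: six
B-form duplexes of 21 base pairs arranged on a hexagon, joined at top and
bottom by single-stranded poly-thymidine loops, with a single-stranded
nick in the midsection of each duplex. Three alternating duplexes carry a
cholesterol anchor at the nick (residue 14), which lets the hollow barrel
insert into lipid bilayers and act as a membrane nanopore. The questions
that motivate the analyses in this package are structural and functional:
how far does the real ensemble deviate from the designed symmetric barrel
(duplex kinking at the nick, breathing, fraying, lumen widening), how
does membrane insertion and salt concentration change that picture, and
what ionic current does the inserted pore carry.

`hexbundle` implements the analysis layer for such studies on
coarse-grained bead ensembles: geometry (kink angles, lumen profile,
height/width, RMSD/RMSF, base-pair breakage, conformational clustering),
replica/bootstrap statistics, ion/water density profiles, and
computational-electrophysiology post-processing. It deliberately does
*not* run molecular dynamics. Instead, a synthetic-data module generates
6HB-like ensembles, ion fields and ion-swap ledgers with fully controlled
ground truth, so that every estimator can be validated by parameter
recovery at desk scale.

# The bead model

Each paired nucleotide is reduced to two beads: a *backbone* bead on a
helical path of radius 9.4 Å about the duplex axis (the B-DNA phosphate
radius) with a rise of 3.4 Å/bp and twist of 34.3°/bp, and a *base* bead
at 3 Å from the axis. The two strands of a duplex are antiparallel, with
the second backbone offset by 140° (the minor groove). Paired base beads
are placed antipodally about the duplex axis, so each base-pair midpoint
lies exactly on the axis. This last choice is deliberate: if base beads
instead follow their own backbone's phase, the base-pair midpoints trace
a narrow helix and a principal-component fit of a short (7-bp) segment
tilts by several degrees, which would contaminate every kink measurement.
With axial midpoints, segment axis fits are exact and an imposed hinge
rotation is recovered to numerical precision.

Residue numbering runs 1–25 per strand: 21 paired residues plus a
4-residue poly-T loop (the designed loop length is not fixed by the
architecture, so it is a parameter; 4 gives the conventional 25-residue
numbering). Residue 1 sits at the top of the helix; the nick at residue
14 splits each helix into a "top" (1–14) and "bottom" (15–25) region,
and the split index is a parameter everywhere it is used. Loops are
assigned role `loop` and never participate in pairing or in
height/width/lumen measurements — in real maps they are the most
disordered part of the structure, and including them would let floppy
linkers dominate rigid-body metrics.

# The kinematic ensemble generator

`generate_ensemble()` replaces force-field dynamics with an imposed,
fully recoverable motion model. Per frame, in order:

1. **Kink** — the below-nick segment of each helix is rigidly rotated
   about a hinge on the helix axis at the nick height, about a
   tangential axis, by the per-helix angle (degrees, in [0°, 180°)).
2. **Breathing** — the hexagon circumradius is scaled sinusoidally with
   the configured amplitude (Å) and period (ns), moving each helix
   rigidly along its radial direction.
3. **Fraying** — each targeted base pair independently breaks with
   probability `fray_prob` per frame; a broken pair's base bead is
   displaced 10 Å away from its partner, safely beyond the breakage
   cutoff.
4. **Global tilt/twist** — a rigid tilt plus a time-linear rotation
   about the vertical axis.
5. **Noise** — isotropic Gaussian displacement of every bead
   (`noise_sigma`, Å).

All randomness derives from a single master seed through per-replica
streams (`seed + 1000003 * replica`, mod 2^31 − 1), so replica *r* is
bit-identical regardless of how many replicas are requested, and the
whole ensemble is reproducible from `(parameters, seed)`.

What this emulates — and what it does not: the generator reproduces the
*observables* of a 6HB ensemble (kink statistics, breathing of the
cross-section, terminal fraying rates, global diffusion-like noise) with
exactly known ground truth, which is what validating estimators
requires. It does not model forces, correlated collective modes beyond
breathing, salt-dependent electrostatics, or lipid dynamics; a test that
passes on synthetic data therefore certifies the *estimator*, not any
claim about real trajectories.

# Geometry conventions

* **Helix axes** are principal axes of base-pair midpoint positions,
  oriented from residue 1 toward the strand end so that the two segment
  directions of a straight duplex coincide. The **kink angle** is the
  angle between the top (pairs 1–14) and bottom (pairs 15–21) segment
  axes: 0° for a straight duplex, range [0°, 180°).
* The **lumen profile** splits the 21 bp into three slabs of 7 (top,
  centre, bottom). For each slab and each pair of opposing helices —
  fixed to (1,4), (2,5), (3,6), the hexagonal antipodes — the minimum
  backbone bead-centre distance within the slab is taken, and the
  reported width is the mean over the three pairs. Distances are centre
  to centre with no bead-surface correction; comparisons against models
  using van der Waals surfaces must state that convention.
* **Height** is the extent of the duplex backbone beads projected on
  the bundle axis; **outer width** is the diameter of the smallest
  enclosing circle of backbone beads projected on the orthogonal plane.
  The bundle axis is the sign-aligned mean of the six helix-axis
  directions rather than a point-cloud principal component: when the
  bundle breathes wide enough that its lateral variance exceeds the
  axial one, a PCA axis flips into the plane while the mean helix
  direction stays the barrel axis. An optional `bead_radius` adds a
  surface correction at both extremes.
* **RMSD** uses Kabsch superposition (rotation + translation, no
  reflection). **RMSF** is computed per replica about the time-mean
  structure and then ensemble-averaged; with `align = TRUE` (default)
  frames are first superposed onto the replica mean (two passes), which
  removes global rigid motion. Both conventions are reported because
  they answer different questions and can differ by an order of
  magnitude when a structure drifts; published per-residue RMSF values
  for this system (~39–42 Å against an ~80 Å object) are only
  compatible with an alignment-free convention, and the package does
  not attempt to reproduce any specific value.
* **Base-pair breakage** declares a pair broken in a frame when its
  base-bead distance exceeds a cutoff, default 8 Å — comfortably above
  the 6 Å paired distance of the bead model and below the ≥15 Å frayed
  separation. No published criterion exists for the bead scale, so the
  cutoff is an explicit parameter.
* **Clustering** follows the classic greedy neighbour-count
  (GROMOS-style) rule on pairwise superposed RMSDs, with ties broken by
  the lowest frame index, making the result deterministic. The RMSD
  cutoff has no defensible default and must be given explicitly.

# Ensemble statistics

The estimate of any scalar observable is the unweighted mean of
per-replica time means; its uncertainty is the bootstrap standard error
over replicas (default B = 1000, seeded). The replica is the resampling
unit because replicas are the independent realisations of the ensemble
protocol; frames within a replica are time-correlated and would make a
frame-level bootstrap overconfident. Class-average statistics are
deliberately unweighted by class population. `convergence_curve()`
recomputes the SE on nested prefixes of replicas or duration, which is
how one verifies that an ensemble is large enough that adding one more
replica would not change the answer.

The exhaustive bootstrap (`exhaustive = TRUE`, n ≤ 8) enumerates all
n^n resamples and returns the exact SD of the resample-mean
distribution; it exists to validate the Monte-Carlo bootstrap.

# Ion fields and density profiles

The synthetic ion field places Na⁺/Cl⁻/water beads uniformly at the bulk
number density implied by the NaCl concentration (1 M = 0.6022 nm⁻³ per
species; water beads default to 8.3 nm⁻³, the bulk density of 4-to-1
mapped polarisable coarse-grained water), plus Poisson-distributed extra
beads inside a lumen cylinder to realise a configured enhancement in
nm⁻³. The default box is 160 × 160 × 180 Å and the default lumen
cylinder has radius 9 Å (the designed 18 Å pore lumen) over a 100 Å
axial window; the published analyses do not state the torus/lumen region
geometry, so both are parameters.

`number_density_z()` bins along the fixed box z axis (the membrane
normal), averages over frames and converts to nm⁻³; by construction the
binned densities conserve the mean particle count exactly.
`region_density_difference()` reports the mean density inside a region
minus a disjoint bulk reference region — the lumen-enhancement
estimator.

# Computational electrophysiology

In a double-bilayer ion-swap protocol, the raw data are ledgers of
ion/water swap events between the two compartments. The per-slice
current is

I = Σᵢ (qᵢ · nᵢ) / (2 Δt),

with nᵢ the directed swap count of species i (A→B positive), qᵢ its
charge, Δt the slice length (default 20 ns), and the factor 2 for the
two pores of the double bilayer; 1 e/ns = 160.2 pA is applied in exactly
one place. Slices with |V| > 100 mV are excluded (the usable voltage
window of nanopore recordings) and logged. The conductance is the
least-squares IV slope in nS; the default fit is constrained through the
origin because an ohmic pore passes zero current at zero bias and the
zero-imbalance replicas pin that point, with the free-intercept fit
reported alongside. Uncertainty is a bootstrap over IV points. The
per-slice conductance distribution (G = I/V for |V| ≥ 10 mV, the floor
avoiding division blow-up near zero bias) exposes sub-conductance
states as separate modes.

The ledger generator inverts the estimator: for a slice at voltage V it
draws Poisson swap counts whose means combine a current-neutral baseline
(2 events per species and direction per slice) with a directed component
chosen so that E[I] = G·V, shared equally between Na⁺ moving with the
field and Cl⁻ against it. The default schedule reproduces the published
design: 30 replicas of 100 ns in 20-ns slices, ten replicas each at
charge imbalances of 0, 2 and 4 e holding ≈0, 50 and 100 mV, with a
25 mV per-slice jitter emulating the sharp potential fluctuations of
swap enforcement — which also reproduces the reported feature that a
fraction of high-bias slices fall outside ±100 mV, leaving roughly 100
usable IV points.

# Coarse-graining utilities

`boltzmann_invert()` converts a histogram of a bonded coordinate into an
effective potential U(x) = −k_B T ln P(x) (kcal/mol, minimum shifted to
zero, empty bins undefined), the standard route from reference
simulations to coarse-grained bonded terms; a Gaussian histogram yields
the harmonic curvature k_B T/σ² exactly. `radius_of_gyration()` and
`rg_percent_difference()` support the conventional check that a
coarse-grained group reproduces the compactness of its reference
representation within a few percent (threshold configurable, default
5%).

# Problem sizes and numerical choices

The test-suite and acceptance runs use desk-scale problem sizes chosen
so that Monte-Carlo error is small against the tolerances being checked:
kink recovery on a single noise-free frame (it is deterministic),
base-pair breakage on 1000 frames (binomial SE ≈ 0.22% at p = 0.302
with 42 pairs/frame), conductance recovery on the full 30-replica
schedule (≈120–130 usable IV points, bootstrap SE ≈ 0.04 nS), density
recovery on 500 independent frames (Poisson SE ≈ 0.008 nm⁻³ on the
lumen cylinder), and clustering/RMSD oracles on ≤10 frames where
exhaustive search is feasible. The demo pipeline (3 replicas × 20
frames) runs in seconds; the full stage set scales linearly in frames
and replicas.

Numerical conventions worth knowing: angle fits clamp dot products to
[−1, 1] before `acos`; the axis-fit residual clamps tiny negative
variances to zero; the smallest enclosing circle reduces to the convex
hull and scans two- and three-point support candidates exactly;
clustering and generator tie-breaks are by lowest index; and all
delimited output is tab-separated UTF-8 with mandatory headers, written
deterministically so reruns are byte-identical.

# Known limitations

* The motion model is kinematic; it cannot exhibit emergent behaviour
  (e.g. salt-dependent expulsion from the membrane) and is not meant
  to.
* The membrane mode is geometric: a lipid-bead slab with a cylindrical
  cavity standing in for the toroid. Lipid self-assembly, leaflet
  structure and membrane mechanics are out of scope.
* Base-pair/base-step helical parameters (shear, stretch, roll, ...)
  belong to dedicated nucleic-acid tools and are not computed here.
* The two-bead nucleotide cannot represent sugar puckers or groove
  geometry; analyses that need them require a finer representation.
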