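---
title: "Hydrophobic gating analysis: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrophobic gating analysis: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poregate)
library(dplyr)
```

poregate analyses molecular-dynamics trajectories of hexameric ion channels
built like CRAC/Orai: six identical subunits, four transmembrane helices
each, arranged in three concentric layers with the TM1 helices lining a
central pore. The questions it is built to answer are the ones that decide
whether such a channel is open or closed and how the gating signal travels:
is the pore geometrically wide enough for water, is it nevertheless
functionally occluded by a vapour bubble in its hydrophobic constriction,
do the pore helices rotate or merely translate, and in what order do
inter-helix contacts break as the conformational wave propagates from the
peripheral helices to the pore. This vignette records the models behind
each analysis, the conventions and defaults, and what the validation
strategy does and does not establish.

## Coordinate conventions and channel annotation

All analyses assume the pore-axis convention: the C6 symmetry axis is the
z axis, z grows toward the extracellular side (the glutamate ring at high
z), and the pore centre is at the xy origin. `align_pore_axis()` establishes
this once per trajectory by a principal-component fit of the pore-helix
(TM1) Cα atoms of a reference frame, orienting the axis so the E-ring sits
above the basic region, and applies the same rigid transform to every
frame. A straight axis is appropriate here because the sixfold symmetry of
the channel keeps the pore essentially straight; curved-axis profiling is
deliberately out of scope.

Channel annotation is a `channel_topology`: six chain labels *in ring
order* (subunit n and n+1 are physical neighbours — this ordering is what
gives "inter-subunit n/n+1" its meaning in the contact analysis), helix
residue intervals, marker-ring residues, and the gate residue. Residue
numbering follows the input PDB with no renumbering; the defaults use Orai
numbering (E178, F171 markers, H206 gate). Axial regions are slabs bounded
by the mean z of the six Cα atoms of the marker rings: the basic region
between the R155 and K163 ring planes, the hydrophobic region between the
L167 and V174 planes extended by a padding (default 1 Å) on both sides, the
E-ring a ±padding slab about E178, and the whole pore from the basic lower
bound to the E-ring upper bound. The source data never state slab widths
for these regions, so the padding is an explicit parameter echoed into all
output metadata, and degenerate geometry (ring planes out of order,
overlapping regions) is an error rather than something silently reordered.

## Pore radius by maximal inscribed spheres

At each z of a grid (default spacing 0.5 Å) the pore radius is

$$ r(z) \;=\; \max_{c \in \mathbb{R}^2} \; \min_i \big( \lVert (c, z) - x_i
\rVert - r_{\mathrm{vdW},i} \big), $$

the radius of the largest sphere centred in the plane that touches no
atom's van der Waals surface. Atoms within `max(vdW) + 3 Å` of the slice
plane participate (spheres feel atoms outside the exact plane); slices with
no atoms in reach are reported missing, never zero. The in-plane
maximisation is a Nelder–Mead search seeded from the previous slice's
centre plus five seeded random restarts, with a soft constraint keeping the
centre within `max_center_offset` (default 5 Å) of the axis — necessary
because for open geometries the objective is unbounded as the centre
escapes the atom cloud. A dense-grid brute force (`method = "grid"`) is
kept as an independent oracle; the test suite requires agreement within
0.05 Å on channel slabs. Van der Waals radii come from an embedded
Bondi-style element table (overridable); unknown elements fall back to
1.7 Å with a warning.

Radii are classified against a water probe radius of 1.15 Å (the HOLE
colour-code convention): below one probe radius the pore is sterically
closed, up to two probe radii it can hold at most a single water file,
beyond that multiple waters. The water-counting and PMF analyses are
independent of this choice. Whether trajectory-averaged profiles include
side chains is a flag stored in the output attributes; the default includes
them, and the backbone-only variant exists because comparing the two
separates rotation-driven from displacement-driven radius change (see the
radius–rotation PMF below). Excluding atoms can only widen the pore, and
the suite asserts that monotonicity pointwise.

## Hydration, dewetting and PMFs

A water counts toward a region when its z lies inside the region slab and
its in-plane distance from the axis is at most `radial_cutoff` (default
10 Å — generous enough to cover the pore lumen; recorded in outputs).
Dewetting (bubble) intervals are maximal runs with count ≤ 1 lasting at
least 1 ns by default: the count threshold of 1 tolerates the occasional
single-molecule intrusion at the region boundaries without declaring the
bubble broken, and the persistence requirement suppresses single-frame
flickers. Detection is idempotent and unaffected by appending wet frames.

Occupancy PMFs are Boltzmann inversions,
$F = -k_B T \ln(\rho/\rho_{\mathrm{bulk}})$ with
$k_B = 0.0019872$ kcal/(mol·K) and T = 300 K by default, on 1 Å axial bins
(cylinder volumes) or (z, r) bins (cylindrical-shell volumes
$\pi (r_{out}^2 - r_{in}^2)\,\Delta z$). Bins devoid of samples would
diverge; they are instead assigned the maximal finite free energy of the
grid — the value of the least-occupied non-empty bin — so no emitted grid
contains infinities, at the cost of an artificially flat region near the
maximum. The (pore radius, helix rotation) PMF has no meaningful bulk
reference, so it is referenced to its most-populated bin
(`min_referenced`: the minimum over non-empty bins is exactly zero);
default bins are 0.25 Å × 2°. Its diagnostic logic: if rotation causes the
radius change through side-chain displacement, the low-free-energy valley
is slanted with side chains included and flat without them; if rotation and
dilation are merely simultaneous, the valley stays slanted either way.

The pore-wall hydropathy profile assigns each pore-lining (TM1) residue its
scale value at the mean z of its six Cα atoms and takes a sliding-window
mean (window 3 Å) along z. The shipped scale is the Wimley–White
*interfacial* scale with the sign flipped so that positive means
hydrophobic; the octanol variant or any other residue→value map can be
passed instead, since the sources that use such profiles rarely state the
variant. The hydrophobic constriction of the synthetic channel shows up as
the expected single positive peak flanked by negative (charged/polar)
stretches.

## Helix kinematics

Rotation angles deliberately use only Cα positions, so they remain
meaningful even against low-resolution experimental structures without
side-chain coordinates. Each pore helix gets a per-frame axis (first
principal direction of its centroid-removed Cα cloud, oriented toward +z);
the rotation at an axial level is the signed angle between the in-plane
components (⊥ the helix's own axis) of the axis→marker-Cα vector at frame t
and at the reference, positive counter-clockwise viewed from the
extracellular side. The four levels default to the E178, F171, K163 and
R155 rings; the difference between levels of one helix is its twist, which
is precisely what distinguishes twisting from rigid-body rotation. The
reference direction may be averaged over a window of frames
(`reference_frames`), which removes the jitter of a single-frame zero
point. Two numerical facts worth knowing: the principal axis of a finite
discrete helix is tilted from the true axis by a small residual
(about 0.4° for a 20-residue helix, vanishing roughly quadratically with
length), so even noiseless recoveries are exact only to a few hundredths of
a degree; and with per-atom jitter of σ = 0.3 Å a single-frame, six-helix
mean angle has a standard deviation of about 3° (lever arm 2.3 Å), which is
why recoveries average over plateaus — 40-frame reference and measurement
windows bring the estimator below 1°.

SASA uses Shrake–Rupley quadrature on a Fibonacci sphere lattice (default
960 points, probe 1.4 Å), with every heavy atom of the supplied structure
occluding. Accuracy was checked against the closed-form two-sphere lens
area and a 10⁵-point reference (default resolution agrees within 1%);
because the point lattice is lab-fixed, rotation invariance holds only to
quadrature precision, while translation invariance is exact.

Inter-helix analyses use Cα centres of mass of configurable residue
subranges ("lower part" defaults to the cytosolic half). Displacements from
the reference frame are projected onto the unit vector toward the partner's
reference COM, so a positive value always reads "approach"; using the pore
COM as the pseudo-partner turns the same projection into a
centripetal(+)/centrifugal(−) measure. χ1 is the standard N–CA–CB–γ
dihedral in (−180°, 180°], with an explicit error for residues lacking a γ
heavy atom. The atom-contact density around the gate residue counts heavy
atoms of other residues within 7.5 Å of any heavy atom of the residue — the
quantity that drops when the helices around the steric brake move apart and
its side chain gains room to swing.

## Contact dynamics

Two residues are in contact when at least two distinct side-chain
heavy-atom pairs are closer than 5.0 Å. "Distinct pairs" counts pairs, not
atoms: one atom may participate in both qualifying pairs. That is the
permissive reading of the pair criterion, chosen because the criterion
constrains pairs, and it is pinned by a unit test. Glycine, having no
side-chain heavy atoms, can never be in contact. The neighbour search is a
padded cell list validated against the all-pairs computation by exact set
equality on every fixture.

Event extraction smooths each pair's presence series by absorbing runs
shorter than `persistence` (default 5 frames) into the preceding state,
then reports pairs present at the start and absent at the end as *broken*
at the last present→absent transition, the reverse as *formed*, and pairs
present throughout as *stable*. The six-fold consensus rule groups events
across the symmetry-related copies by (residue pair, kind, class): groups
seen in ≥ 3 subunits are emitted at the arithmetic mean of the per-subunit
times, averaging over exactly the subunits that show the event (the
narrower of the two readings of "averaged their times"). Inter-subunit
pairs are oriented along the ring (first residue on subunit n, second on
n+1) before grouping, and pairs between non-adjacent subunits — which a
C6 ring geometry should not produce — are discarded with a warning.

## Structure metrics and targeted MD

RMSD series superpose each frame on the reference by Kabsch least squares
over an alignment selection, then evaluate the RMSD over a possibly
different measurement selection (named presets: all backbone, TM4
backbone, pore-helix backbone; backbone is {N, CA, C, O}, explicitly
excluding CB). Block averaging splits a series into contiguous equal blocks
(remainder dropped from the end) and reports sd(block means)/√n_blocks;
with one point per block this reproduces the plain SEM.

The targeted-MD utilities encode the standard biasing scheme: a linear
target-RMSD schedule ρ(t) from the initial inter-state RMSD to zero, and
the harmonic bias U = (k/2N)(RMSD − ρ)². The rendered form of this formula
in the literature is typographically ambiguous ("1/2 k N" vs "k/(2N)"); the
per-atom convention k/(2N) is adopted because N is described as the number
of biased atoms and the bias should stay intensive in system size. With the
canonical inputs (13.94 Å initial RMSD; k = 10⁵ kcal/mol/Å²) the schedule
gives drift rates of 0.1394 Å/ns over 100 ns and 0.02788 Å/ns over 500 ns.

## The synthetic channel and what validation shows

The generator builds an idealized channel: ideal α-helices (rise 1.5 Å,
twist 100°/residue, Cα radius 2.3 Å) carrying N/CA/C/O backbone sites and
two heavy pseudo-side-chain sites (CB, CG) reaching `sidechain_extent`
(default 3 Å) from the helix axis; six four-helix subunits at layer radii
8/14/20 Å (TM1 / TM2–TM3 / TM4, with TM4ext between the outer layers);
subunits B–F are exact 60°-rotated copies of A, so C6 symmetry is exact to
machine precision. The TM1 phase is chosen so the hydrophobic marker ring
points straight at the pore axis, which makes the geometric pore radius at
that level exactly `8 − 3 − 1.7 = 3.3 Å` — a closed-state-like constriction
known in closed form. TM1 carries a realistic sequence pattern (basic
rings, a leucine/valine/phenylalanine block, the glutamate ring) so the
hydropathy profile has structure; all pseudo-residues carry a γ atom, so
χ1 is defined everywhere including the HIS gate residue.

Gating scripts impose, per frame: a per-level TM1 twist (interpolated
linearly in z between the four marker planes — the paper-style "twisting,
not rigid rotation" pattern), a radial TM1 dilation, a step-like outward
bend of TM4ext about its cytosolic end (breaking its TM3 contacts at a
known frame), a gate-residue χ1 swing of exactly the scripted amplitude at
a known frame, and Gaussian per-atom jitter added last. Water is modelled
as single-site pseudo-particles — every analysis here uses only water
positions — placed uniformly at a bulk density of 0.0334 Å⁻³ (ambient
water; a generator parameter, not a literature value) in a pore cylinder
plus a bulk slab, with the hydrophobic slab excluded during the scripted
bubble interval. The particle count is Poisson-drawn once and held fixed
(trajectories need constant atom counts); positions are resampled every
frame. The preset scripts run 200 frames with a 20% hold, 60% linear ramp,
20% hold shape; the holds exist so that recovered quantities can be
time-averaged over stationary windows, and the opening preset's final
twists (2° at the E-ring, 11° at the hydrophobic ring, 14°/16° in the
basic region) follow the observed pattern of small extracellular and large
cytosolic rotations.

Everything the generator imposes is emitted as ground truth, and the test
suite closes the loop: water counts are recovered exactly; bubble endpoints
to the frame; contact-breakdown times to the scripted frame with all six
subunits agreeing; χ1 histories exactly; per-level twists within 0.5°
noiseless and within 2° under 0.3 Å jitter; the analytic pore radius
exactly at the marker level.

What this does *not* show: the generator has no force field, no
thermodynamics of dewetting, no membrane, ions or hydrogen atoms, and its
waters do not interact with anything. Passing recovery tests therefore
demonstrates that the *measurement machinery* is correct — not that any
physical claim about a real channel would be reproduced. Real-trajectory
headline numbers (equilibrium pore water around two hundred molecules,
rotation magnitudes from biased transitions, contact-event sequences over
hundreds of nanoseconds) require the original hundreds-of-nanoseconds
all-atom trajectories and are outside what synthetic data can certify.

## Numerical choices and problem sizes

Degenerate inputs are errors, not guesses: empty selections, missing marker
rings, missing γ atoms, ring planes out of order, all-empty PMF grids, and
trajectories shorter than the averaging they are asked for all raise with
informative messages. Determinism is explicit: every stochastic component
(restart offsets, jitter, water placement) takes a seed, and the pipeline
reruns bit-identically for a fixed seed. The validation suite and the
acceptance script use 200-frame, ~5,500-atom synthetic trajectories —
large enough that every analysis path (plateau averaging, flicker
suppression, six-fold consensus) is exercised at full scale, while a
complete run of suite plus script stays within a few minutes on one CPU.
Contact analyses in the validation runs are restricted to the helices that
carry the scripted events (TM3/TM4ext); the machinery itself is
selection-agnostic and the map/oracle equality is also checked on the full
atom set.

## Known limitations

- XTC trajectories are not read; DCD and multi-model PDB are. (No XTC
  codec exists in the R dependency stack this package builds on.)
- The pore axis is straight by convention; strongly curved or tilted pores
  would need re-alignment per segment.
- SASA treats all heavy atoms as occluders with Bondi radii; no
  atom-type-specific radii sets are shipped.
- Ion analyses reuse the water machinery over an ion selection but are not
  validated against reference data here.
- Hydrogen-bond-specific criteria (donor/angle) are not implemented; polar
  contacts are reported through the same heavy-atom contact machinery.
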