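---
title: "Sub-tomogram averaging of membrane-anchored fusogens: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-tomogram averaging of membrane-anchored fusogens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Cell–cell fusogens of the FF family (EFF-1, AFF-1) decorate the surface of
vesicles shed by cells that express them. Cryo-electron tomography of such
vesicles shows a protein layer protruding radially from the membrane, and
sub-tomogram averaging of many single-protein sub-volumes can recover the
ectodomain structure, its orientation relative to the membrane, and its
lateral packing — all without crystallization and in a native membrane
context. `subtomo` re-implements that computational chain as a tested R
package: a ground-truthed synthetic tomogram generator, local-minima particle
picking, constrained iterative alignment with gold-standard even/odd
averaging and Fourier shell correlation (FSC), membrane-geometry statistics,
rigid and hinge-restricted flexible fitting of multi-domain atomic models
into EM density, and emPAI-based relative protein abundance.

Because the raw tomograms behind the original study are not publicly
deposited, the package treats its own generator as the data source: the
generator's defaults *are* the study conditions, and the pipeline is
validated by parameter recovery — simulate with known ground truth, run the
blind pipeline, and compare what comes out with what went in.

## The synthetic scene and what it emulates

`make_protein_template()` builds the ectodomain phantom: a distal
ellipsoidal head of 60 x 40 Å cross-section on a thin proximal tail,
130 Å long in total. The head's axial extent defaults to 0.4 of the
length and the tail radius to 10 Å, chosen so the phantom's solid volume
(about 90,000 ų) matches the displacement volume of an ~87 kDa monomer —
the same volume later used for isosurface thresholding, so the thresholded
average should recover the full phantom, not a core or a halo.

`place_particles()` distributes particles on a spherical vesicle:

* anchors uniform on the sphere, with the anchor sphere offset outward by
  half the membrane thickness (the ectodomain protrudes from the outer
  leaflet, not from the bilayer mid-plane);
* tilt of the long axis to the local membrane normal drawn from a Gaussian
  with mean 33° and SD 17°, truncated to [0°, 90°), about a uniformly
  random tangent direction — "evenly distributed in all radial directions";
* a hard-core centre-to-centre exclusion of 100 Å enforced by rejection
  sampling (capped at 10,000 attempts per particle; an infeasible request
  raises a capacity error that reports the achieved count, never a silent
  shortfall).

The default vesicle radius is 800 Å. A 600 Å sphere cannot hold 500
particles at a 100 Å hard core — the anchor-disk coverage would be ~87% of
the surface, far beyond the ~55% jamming limit of random sequential
adsorption — whereas 800 Å gives ~49% coverage, dense enough to emulate a
"uniformly covered" vesicle while remaining samplable.

`render_tomogram()` sums a dark spherical shell (50 Å, a typical bilayer
with head-group peaks) and the phantom resampled at every particle pose.
`apply_missing_wedge()` zeroes the Fourier double wedge outside a ±60°
tilt range about the y axis — the sole anisotropy modelled; there is no
CTF, no dose weighting and no reconstruction point-spread beyond the
wedge. `add_noise()` adds white Gaussian noise at a target
signal-variance-to-noise-variance ratio; the default SNR of 2 describes
contrast at the rendered 7.6 Å voxel scale (two times the 3.8 Å pixel of
the emulated acquisition), roughly what dose-limited tomograms reach after
comparable binning.

What passing tests on these scenes do **not** show: robustness to CTF
effects, to non-spherical membranes (nanotubes are out of scope), to
reconstruction artefacts other than the wedge, or to proteins whose shape
departs from the head-plus-tail phantom. The generator's phantom is also
featureless along its axis, which makes axial registration *harder* than
for a real protein with internal domain structure.

## Picking

Picking follows the local-minima rule: 2x binning (to 15.2 Å voxels,
matching the emulated 4x-binned pixel), Gaussian smoothing, then strict
26-neighbour minima below `mean - 2 SD` of the whole preprocessed map,
kept only within 150 Å of the membrane (fitted from the map itself by a
robust least-squares sphere — never from ground truth). Choices made where
the method description is silent:

* **Filter width.** The smoothing sigma defaults to 0.5 binned voxels
  (~8 Å). At sigma = 2 the phantom's well depth falls below the
  `mean - 2 SD` threshold (the map SD is dominated by the membrane shell)
  and recall collapses; at sigma = 0.5 the detector keeps >90% of planted
  particles under the default SNR.
* **Threshold statistics** are taken over the whole map: the simplest
  reproducible choice.
* **Pipeline-level cleanups** (the operations themselves stay faithful):
  candidates inside the vesicle lumen or the bilayer band are dropped
  (ectodomains protrude outward, 30–150 Å outside the surface), and
  detections closer than 70 Å collapse to the deepest well — non-maximum
  suppression against overlap minima between adjacent particles. Duplicates
  that survive to alignment converge onto the same molecule and are removed
  by cc-ranked deduplication at 60 Å.

Positions are reported in unbinned Angstrom; initial orientations are the
outward membrane normals with zero in-plane spin.

## Alignment and averaging

The refinement has two stages, mirroring the two-stage protocol of the
original study:

* **Stage A** — five unmasked iterations of every picked sub-volume against
  the global average of all picks, coarse angular sampling (±30°, 15°
  steps), aligning the membrane together with the particle to refine the
  picking. Nearest-neighbour statistics come from this stage's output.
* **Selection** — particles scoring strictly above the mean cc are kept;
  the kept set is re-centred on its average's structural midpoint and split
  by even/odd record index into two halves that never share a reference
  again until the final combined map (the gold-standard discipline).
* **Stage B** — six masked iterations per half with successively finer
  sampling (half-ranges 30, 20, 15, 10, 6, 4°; steps a third of the
  half-range) and a low-pass cutoff rising linearly from 1/4 to 3/4
  Nyquist. The first masked iteration additionally sweeps the full
  in-plane spin, because membrane-normal initialization leaves spin
  unconstrained.

Numerical design decisions that mattered in practice:

* **Mask geometry.** The mask is a soft ball (radius 66 Å, cosine edge)
  about the box centre rather than a cylinder: a centred rod of half-length
  65 Å stays inside the ball at *any* tilt, whereas a cylinder cuts off
  tilted particles and stalls orientation refinement.
* **Membrane suppression.** The membrane band (56 Å around the fitted
  sphere) is replaced by the local mean in both the scored sub-volumes and
  the rebuilt references. The membrane slab is the strongest coherent
  feature in membrane-normal-initialized boxes; left in place it dominates
  the correlation and locks orientations to the normal, erasing exactly the
  tilt signal the analysis is after.
* **Wedge-compensated scoring.** On masked iterations the rotation search
  scores in Fourier space over each particle's *sampled* region only (the
  missing wedge rotated into the particle's frame is excluded from both
  volumes). Scoring wedge-filtered data against an unfiltered reference
  biases orientations toward placing sharp features in the sampled region;
  restricting the correlation to the shared support removes that bias.
  Shifts are then refined in real space at the best rotation.
* **Shift discipline.** Integer-voxel shift searches are capped by a total
  displacement budget per particle (35 Å in stage A, 60 Å in stage B)
  so low-contrast particles cannot random-walk across the map.
* **Determinism.** Pure grid search; candidate lists start with the
  identity, and ties keep the first candidate in scan order.
* **Frame registration.** Reference-free refinement condenses each half's
  common frame to an arbitrary in-plane gauge, so the odd average is
  rigid-registered onto the even average before the FSC, and all
  orientation statistics are measured against the axis *estimated from the
  final average itself* (the leading principal axis of the
  volume-thresholded map), which makes them gauge-independent.

The combined map refines all selected particles together and is low-pass
filtered with a Gaussian whose width is least-squares fitted to the
half-set FSC curve. Resolution is read from the first
downward crossing of the FSC at 0.143 and 0.5, linearly interpolated.

## Geometry statistics

Tilt is the angle between a particle's rotated long axis and the outward
membrane normal at its *anchor* — found by tracing the axis from the
particle centre toward the membrane and intersecting the fitted sphere
(falling back to the radially nearest surface point). Two estimation
details matter:

* **The template-frame axis.** Reference-free refinement leaves the
  common frame's gauge arbitrary, so the long-axis direction in that
  frame must be estimated. Because tilt azimuths are uniform about the
  membrane normal, the pull-backs of the outward normals into each
  particle's template frame scatter symmetrically around the long axis;
  their mean direction (`estimate_reference_axis()`) estimates it with
  error of order `sd(sin(tilt))/sqrt(n)` — well under a degree at the
  study's particle counts, where the principal axis of the thresholded
  average is 5–8° off and would bias every tilt.
* **The physical gate.** Picks that never converge onto a molecule
  (overlap minima, wedge artefacts of the membrane) survive selection
  with middling scores but acquire near-tangent orientations. A
  surface-anchored ectodomain cannot point into the membrane, and the
  generator's truncated tilt prior carries ~0.3% of its mass beyond 80°,
  so particles whose measured tilt exceeds 80° are excluded from the
  reported statistics table (the maps keep the full set).

Azimuths use the local tangent basis and are summarised with a Rayleigh
uniformity test.
Nearest-neighbour distances are Euclidean centre-to-centre minima.
Isosurface levels are chosen by target volume (87,000 ų, the monomer
volume) on the dark convention; extents are measured along the principal
axes of the largest 26-connected component, with cross-section axes
evaluated over the distal half when a membrane reference direction is
supplied, and one voxel added to each max-minus-min centre span to account
for voxel extent.

## Model fitting

Atomic models are synthesized into density as mass-weighted Gaussians
(real-space SD = resolution / (2π√2), negated to match the dark
convention). The rigid fit is an exhaustive grid search maximizing the
about-the-mean correlation over the model's footprint (voxels deeper than
10% of the synthesized minimum — the correlation definition in the source
study is not recorded, so this package states and tests its own). The
hinge-restricted flexible fit alternately rotates domains II and III as
rigid bodies about pivots at the backbone midpoint of their hinge
residues, domain I fixed, hinge residues following their moving domain;
each of four rounds halves the rotation-vector grid, so the identity is
always available and the flexible CCC can never fall below the rigid one.
No stereochemical regularization is applied at the hinge junctions — a
documented limitation relative to molecular-dynamics-based flexible
fitting; validation is by CCC and recovered hinge angles, not geometry
scores. Domain rotations between conformers are measured by Kabsch
superposition on the fixed domain followed by the optimal rotation of the
moving domain, reported as an axis-angle magnitude. Salt-bridge style
residue-pair distances default to Glu side-chain carboxylate oxygens
versus the Lys side-chain nitrogen, configurable because atom sets are a
convention. The deposited reference structures themselves are not shipped;
tests exercise these operations on constructed conformer pairs with known
rotations and distances, including a synthetic stand-in pair built with
the published geometry (hinge rotations near 16° and 19°, donor–acceptor
distance closing from ~12 Å to ~4 Å).

## emPAI relative abundance

`empai()` implements `10^(observed/observable) - 1`;
`relative_abundance()` normalizes each detected protein's emPAI by the
column sum over detected entries. The packaged vesicle-preparation table
ships the published emPAI values and printed percentages: the column-sum
normalization reproduces the printed integers, except two entries of the
EFF-1 column that differ by one point because the published emPAI values
are printed to at most two decimals while the published percentages were
evidently computed from unrounded values ("not detected" entries are
excluded from the denominator, not treated as zero).

## Problem sizes and reproducibility

The acceptance-scale runs use one 800 Å vesicle with 500 particles
(tilt recovery, packing) and 300 particles (metrology) in 256³ boxes at
7.6 Å voxels; unit tests use 25–80-particle scenes on 300–400 Å vesicles
so each file runs in seconds to a couple of minutes. All randomness
derives from one integer seed: the placement stage uses `seed*100+1`, the
noise stage `seed*100+2`, and identical configuration plus seed gives
bit-identical particle tables and maps. `run_end_to_end()` writes every
stage artifact (MRC maps, TSV tables, the FSC table, a machine-readable
run log of per-iteration mean cc, and a JSON manifest recording the
package version, seed and full configuration).

## Known limitations

* The wedge filter is the only anisotropy modelled; real tomograms add
  CTF, dose and alignment errors the generator does not emulate.
* The phantom is axially featureless, so axial registration of the tail is
  weaker than for real proteins; the measured length of the averaged map
  is accordingly a slight underestimate of the planted 130 Å.
* Spherical vesicles only; nanotube geometries are future work.
* Flexible fitting optimizes hinge torsions only and does not regularize
  stereochemistry across the hinge junction.
* PCA classification operates on aligned sub-volumes and cannot rescue
  gross misalignment.
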