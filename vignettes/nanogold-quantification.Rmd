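---
title: "Quantifying nanogold labeling in cryo-electron tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nanogold labeling in cryo-electron tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomogold)
```

## The problem

Gold nanoparticles conjugated to a HaloTag ligand label a Halo-tagged
protein in live cells with single-particle EM contrast: gold (Z = 79) is far
denser than protein, so a 1.4 nm or 5 nm bead is visible in an in-situ
cryo-electron tomogram where the protein itself is at or below the noise
floor.  Turning that contrast into biology requires four computations, each
implemented here as an independently testable stage:

1. **detect** — find gold beads in a whole tomogram;
2. **randomize** — hide gold in subtomograms so alignment is driven by the
   macromolecule;
3. **tether geometry** — relate gold centers (`r̂_G`) to tag sites (`r̂_R`)
   and estimate labeling efficiency;
4. **quantify** — probe-dose and copy-number arithmetic.

A synthetic tomogram generator with exact ground truth closes the loop: it
is the only way to test recovery of known quantities without terabytes of
raw tilt series and an external refinement stack.

## Conventions

All internal geometry is in ångströms; distances cross the API boundary in
nanometres (`min_pairwise_distances()` and everything downstream).  A voxel
with 0-based index `(i, j, k)` has its **center** at
`(i + 0.5, j + 0.5, k + 0.5) · s + origin`.  This voxel-center convention is
used for rasterization, centroids and subtomogram extraction alike; mixing
corner and center conventions is a classic half-voxel bug, so only one is
allowed.

Contrast is an explicit field of every volume.  Conventional cryo-EM
reconstructions are *density-dark* (dense = black).  Every thresholding
operator here requires *density-bright* input and throws on dark input
rather than silently negating — sign errors are the dominant failure mode in
tomogram intensity analysis.  `invert_contrast()` is the single sanctioned
conversion.

Orientations are intrinsic ZYZ Euler angles (rot, tilt, psi, degrees),
`R = Rz(rot)·Ry(tilt)·Rz(psi)`, matching the common subtomogram-averaging
STAR dialect.  The source material for this pipeline never states its
convention; ZYZ intrinsic is a declared choice, recorded in the STAR writer
header, not an inference.

## Whole-tomogram detection

`detect_gold()` composes, in order: block-mean resampling to the 3 Å working
grid (detection was designed for reconstructions at 3 Å/px), slab averaging
along z, normalization to [0, 1], thresholding at `mean + k·SD` (k = 3.3),
26-connected component labeling, removal of single-voxel components
(background), a voxel-count gate, and unweighted centroids.

Decisions where the procedure's description was ambiguous:

* **"Averaged over ten slices"** is implemented as a dimension-preserving
  running mean along z (centered window, edges shrink), so centroid
  z-coordinates stay in the source frame.  The alternative reading —
  decimation into non-overlapping 10-slice bands — is available as
  `decimate_z()` but is not the default, because it divides z-resolution by
  the window width.
* **Threshold statistics** are computed globally over the volume, after slab
  averaging and normalization, in that stated order.  Per-slab statistics
  are a defensible alternative nobody specified; global is the declared
  choice.
* **Connectivity** defaults to 26 ("neighboring voxels", unqualified) and is
  configurable, since the neighborhood was never defined.
* **The voxel-count gate** defaults to [40, 55], bracketing the theoretical
  53-voxel volume of a 7 Å sphere on a 3 Å grid.  53 is the volume ratio
  `round((4/3)πr³/s³)`; a brute-force lattice enumeration shows that
  center-in-sphere counting gives 57 for a sphere on a voxel center (48–60
  over random placements), so the volume-ratio definition is the only one
  consistent with the reference count — the acceptance suite carries this
  oracle.  For other gold/grid combinations `derive_size_gate()` scales the
  reference gate by its ratios to the 53-voxel count
  (`[0.75·V, 1.04·V]`); this mimics the 40/53/55 ratios and is a declared
  heuristic, not a measured calibration.  The 40-voxel lower bound absorbs
  grid-sampling undersampling of a sphere; no closed form for it was ever
  given.

Two properties are tested rather than assumed: detection is invariant to
affine intensity rescaling (normalization absorbs it), and raising `k_sd`
never increases the detection count.

### Detection parameters for synthetic volumes

Synthetic worlds differ from real reconstructions in two ways that matter to
the gate.  Noiseless isotropic volumes need no slab smoothing
(`slab_width = 1`); under noise, a 3-slice slab is used and smoothing
inflates a gold component along z by roughly one slice per side, so the gate
maximum is widened to `3·V` (and the minimum relaxed to `0.5·V`).
Block-mean resampling from finer grids creates partial-volume voxels that
are bright relative to a noiseless threshold, inflating blobs further —
tests on resampled input widen the maximum to `2.5·V`.  These are
imaging-condition-driven parameter choices made from the mechanism above,
not fits to test outcomes.

## Gold-signal randomization

In subtomogram averaging the gold wins the alignment.
`randomize_gold_signal()` replaces every voxel above `μ + 3.3σ` — statistics
of *that* subtomogram, never pooled, matching the per-particle procedure —
with an independent draw *within one standard deviation of the mean*.  The
replacement distribution was never specified beyond that phrase; uniform on
`[μ − σ, μ + σ]` is the least-assuming reading and is the default, with a
truncated-Gaussian alternative behind `method = "gaussian"`.

The operator's contract, enforced by tests: sub-threshold voxels are
bit-identical to the input; with the *original* statistics no output voxel
exceeds `μ + kσ` (for k ≥ 1, since `μ + σ ≤ μ + kσ`); identical (input,
seed) gives bit-identical output, and the caller's RNG state is untouched.
A constant box (all padding) is returned unchanged with a warning, not an
error, so batch runs survive.  One pass suffices: re-estimating statistics
on the output flags only noise-level counts.

## Tether geometry and labeling efficiency

`recenter_to_tag_site()` maps each particle center to
`center + R(euler)·offset` with the default offset `(0, 0, 129)` Å — the
12.9 nm from the ribosome center to the last ordered residue of L29, placed
on the particle z-axis.  Since only the displacement *norm* is
orientation-invariant (129 Å for every record, a tested invariant), the
direction of the offset in the particle frame is a modeling choice that the
simulator and the pipeline share.

`min_pairwise_distances()` is the exhaustive matrix minimum (computed via
the quadratic expansion, verified against a double-loop brute force on
random instances).  Sites within `cutoff` of a gold count as labeled;
`labeling_efficiency()` is `N_l / (N_l + N_u)`.  The default cutoff of
10 nm is the adopted maximum extended tether distance: a worm-like-chain
estimate for the disordered residues
(`wlc_rms_end_to_end(L, l_p) = sqrt(2 l_p L (1 − (l_p/L)(1 − e^{−L/l_p})))`)
plus ~3.6 nm of dextran and a ~2.2 nm ligand.  The WLC functional form is
the standard finite-chain mean-square end-to-end expression; persistence
length defaults to 4 Å (typical for unstructured polypeptide) and 3.8 Å of
contour per residue.  None of these reproduce a measured value — the
chain's residue count was never stated — so the 10 nm cutoff is taken as
primitive and the WLC is exposed for sensitivity analysis.

Assignment is nearest-neighbor *without* exclusivity: one gold may label two
sites, because only the matrix-minimum procedure was ever described.  A
greedy one-to-one assignment (globally closest pairs first) is available via
`exclusive = TRUE`; on dilute data the two agree.

`efficiency_pipeline()` additionally reports the fraction of golds with no
tag site within the cutoff — the unbound-gold fraction (~15 % in the
reference in-situ data).

A note on the reference distance statistics: the raw center-to-gold distance
distribution in the reference data has mean 16.8 nm, from which 12.9 nm of
center-to-tag geometry is subtracted by re-centering, yet the plotted
labeled-subset summary is 5.1 ± 1.9 nm (not 16.8 − 12.9 = 3.9).  How that
subset was selected was never fully specified, so the pipeline reports the
summary of the *bound-classified* distances and keeps all per-particle
distances available rather than guessing the selection.

## The synthetic world

`simulate_truth()` draws geometry; `simulate_tomogram()` rasterizes it.
Defaults are stand-ins tied to reported summary statistics — the reference
experiments have no generative model — chosen once:

| parameter | default | why |
|---|---|---|
| `particle_radius` | 110 Å | 80S ribosome scale |
| `tag_offset` | (0, 0, 129) Å | center-to-tag distance of the L29 tag |
| `tether_mean`, `tether_sd` | 51, 19 Å | the observed 5.1 ± 1.9 nm summary |
| `tether_max` | 100 Å | the adopted maximum extended distance |
| `tether_min` | `gold_radius + coat` | see below |
| `gold_radius` | 7 Å | 1.4-nm gold (use 25 for 5-nm) |
| `gold_coat_thickness` | 18 Å | half the ~3.6 nm 10 kDa dextran diameter |
| `labeled_fraction` | 0.7 | near observed efficiencies (0.695, 0.87) |
| `gold_amplitude : particle_amplitude` | 10 : 1 | gold ≫ protein contrast |
| `noise_sd` | 0.2 | sets protein near the noise floor |

Tether lengths are Gaussian, truncated to `[tether_min, tether_max]`.  The
lower bound exists because the tag-to-gold-*center* distance can never be
smaller than the coated gold radius — a near-zero draw is geometrically
impossible.  Directions are isotropic, rejected against excluded volume:
the coated gold may not penetrate any particle, and beads keep four radii
apart.  Only the direction is redrawn on rejection, so the tether-length
marginal is preserved; in the rare case where a short tether has no clear
direction at all (a tag pointing into a crowded neighborhood), the length is
redrawn too — the realized distribution is the truncated Gaussian
conditioned on local feasibility, and the recorded `tether_lengths` always
equal the realized tag-to-gold distances exactly.
`truncated_tether_mean()` gives the closed-form truncation-corrected mean
used as the reference in distance-recovery tests (cross-checked against an
independent Monte-Carlo oracle).

Spheres are rasterized by voxel-center membership — the simplest
reproducible rule, documented because voxel-count gates depend on it.
Overlaps keep the maximum amplitude, so gold is never shadowed by its
particle.  Noise is white Gaussian.

**What the generator does not emulate**: the missing wedge, CTF, electron
optics, membranes, filaments, crowding beyond hard-sphere exclusion, and
multiple labels per particle (exactly zero or one gold per particle, as in
the reference averages).  A green detection test therefore establishes that
the thresholding/gating machinery is correct on blob-plus-noise worlds, not
that it would survive wedge-artifact streaks; the intensity-and-morphology
operators validated here are exactly the ones whose definitions do not
involve wedge effects.

### Scale of the validation worlds

Rendered test worlds are shrunk (25 Å particles, 30 Å tag offset,
20 ± 5 Å tethers, ≤ 112³ voxels) so the suite runs in seconds.
Efficiency- and distance-recovery checks instead need realistic dilution:
500 ribosome-sized particles at cytoplasmic density occupy a ~0.45 µm box —
about 4 × 10⁹ voxels at 3 Å, unrasterizable in 8 GiB.  These checks run on
`simulate_truth()` geometry with ground-truth gold positions standing in
for detections; the separately verified detection oracle (precision = recall
= 1, centroid error ≤ 1 working voxel on rendered worlds, with and without
noise) is what licenses that substitution.  A rendered end-to-end version
at reduced n runs in the regular suite.

## Quantification arithmetic

Ordinary least squares for the fluorescence calibration (only "linear
regression" was ever specified); `invert_calibration()` clips negative
molecule estimates to zero with a warning, since counts are non-negative.
`extrapolate_copies()` is plain proportionality — note that the reference
inputs (5 × 10⁴ particles, 10.1 µm³, 5282.5 µm³) yield 2.6 × 10⁷ by this
arithmetic while the reference text prints 2.6 × 10⁶; the implementation
performs the stated arithmetic and documents the tenfold inconsistency
rather than resolving it.  Size-distribution separability uses
`|μ₁ − μ₂| > 2(σ₁ + σ₂)`, a conservative declared criterion for "clearly
separated" (the reference 1.52 ± 0.359 nm vs 5.62 ± 0.911 nm populations
pass it with 4.10 > 2.54).

## Numerical and degenerate-input policy

* Constant volumes: normalization and thresholding error ("degenerate
  range"); randomization warns and passes through.
* Empty gold sets: distance operators error rather than returning
  infinities.
* `labeling_efficiency` requires a positive denominator; 9567 of 13748
  gives 0.69588…, whose printed form 0.695 truncates (not rounds) the third
  decimal — tests assert the exact quotient and its truncation.
* Component ordering is deterministic (ascending minimum linear index), so
  detection output is reproducible across platforms.
* MRC I/O is little-endian, modes 0/1/2, isotropic grids only; anisotropic
  headers are rejected with a message since every operator assumes cubic
  voxels.
* Seeds: every stochastic operation takes an explicit seed;
  `randomize_stack` derives child seeds as `master_seed + i − 1` so
  per-item outputs are order-independent.

## Known limitations

No missing-wedge or CTF modeling (see above); no template matching or
particle picking (external tools in the reference workflow); no
multi-volume MRC stacks; the gate-derivation heuristic for non-default gold
sizes is unvalidated against real data; the efficiency estimator inherits
the nearest-neighbor assignment's small positive bias in crowded fields
(one gold can label two sites unless `exclusive = TRUE`).
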