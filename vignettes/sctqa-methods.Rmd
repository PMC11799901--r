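---
title: "Methods: patient-specific QA of synthetic CT with sctqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patient-specific QA of synthetic CT with sctqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

In an MR-only radiotherapy workflow the planning CT is replaced by a
synthetic CT (sCT) generated from MR images, so no CT exists against which
an individual patient's sCT could be checked. One proposed remedy is to
run a second, independent sCT generator and use the agreement between the
two sCT dose calculations as a patient-specific quality-assurance (PSQA)
gate. `sctqa` implements the full analysis chain needed to study that
idea quantitatively:

* dose recalculation on image pairs with the monitor units fixed,
* voxel-wise mean error (ME) and DVH point-metric differences
  (D2%, D95%, D98%, Dmean) normalised to the prescription,
* 3D local gamma analysis (1%/1 mm, 20% low-dose threshold),
* tolerance-based accept/reject verdicts, the TP/FN/FP/TN ledger and
  sensitivity = TP/(TP+FN),
* DRR-based 2D/2D patient-positioning comparison with an orthogonal kV
  pair, including the subtraction of the systematic sCT/CT registration
  offset.

Because clinical CT/sCT pairs cannot be redistributed, every stage is
exercised end-to-end on *synthetic head phantoms* with planted,
ground-truth-known sCT error modes. The phantom cohort defines the study
conditions; all acceptance-style tests run against it.

# The metrics and their conventions

**Mean error.** For a structure with `N` voxels,
`ME = (1/N) * sum(D_eval[i] - D_ref[i])` in Gy, where the evaluated dose
is always the clinical sCT's recalculation and the reference is the CT or
one of the QA generators. The normalised form is `100 * ME / D_pres`.

**DVH deltas.** `Dx` is the dose received by the hottest `x`% of the
structure. The package sorts voxel doses descending and assigns voxel `k`
(1-based) the cumulative volume fraction `k/N`, interpolating linearly
between those points; requests below `100/N` return the hottest voxel.
This convention is continuous, monotone and testable against a
brute-force cumulative-histogram construction; DVH libraries differ in
their choice and no particular convention is canonical.
`ΔDx = 100 * (Dx_eval - Dx_ref) / D_pres`.

**Structures.** The PTV is part of the phantom ground truth. Brain and
skull are generated by thresholding the CT: brain = HU in [-100, 100],
skull = HU >= 100, both intersected with the body (the largest connected
component of HU > -300, which excludes exterior air and internal
cavities). Note the deliberate double membership: a voxel at exactly
100 HU belongs to *both* structures, keeping the threshold windows
literally as stated, closed at both ends.

**Gamma.** Local normalisation: at each reference voxel `r` at or above
20% of the maximum reference dose,

```
gamma(r) = min over e of sqrt(|e - r|^2 / 1mm^2
                              + (D_eval(e) - D_ref(r))^2 / (1% * D_ref(r))^2)
```

where `e` runs over a lattice of evaluated positions with step
`interp_fraction * DTA` (default 1/10, i.e. 0.1 mm) within a radius of
`gamma_cap * DTA` (default cap 2). The evaluated dose is sampled by
trilinear interpolation. Voxels below the threshold are excluded
entirely — the threshold governs both inclusion and the safety of the
local denominator. Capped voxels count as failures. The production
search walks the lattice sorted by spatial distance and stops when the
distance term alone exceeds the running minimum; `gamma_bruteforce()`
evaluates the identical lattice exhaustively and is the oracle the
pruned route is tested against (they share only the trilinear sampler,
so agreement is exact, not circular in the search logic).

**Verdicts and sensitivity.** Point metrics accept when
`|value| <= 1%` (inclusive); gamma accepts when the pass rate is
`>= 90%` (inclusive). The *positive* event is "the sCT is accepted":
TP = QA accepts and the CT-based check accepts; FN = QA rejects a truly
acceptable sCT; FP = QA accepts a truly failing one; TN = both reject.
`sensitivity = TP/(TP+FN)`, reported as missing (never 0) when no
positives exist. Specificity is computed the same way from TN and FP and
reported alongside, with the caveat that true negatives are rare by
design in an all-mostly-faithful cohort.

# The toy dose engine

The engine is a deterministic primary-photon model, not a clinical dose
algorithm: HU map to relative density through a piecewise-linear
calibration clamped at its ends (containing (0 HU, 1.0) so water is unit
density); each divergent beam contributes
`weight * exp(-mu_eff * WEPL) * lateral * invsq`, where WEPL is the
Siddon water-equivalent path length from the source to the voxel,
`lateral` is flat inside the aperture (scaled with divergence) with a
Gaussian penumbra (sigma 3 mm), and `invsq` is the inverse-square factor
normalised at the source-axis distance (1000 mm). The plan defaults to
four coplanar beams at 0/90/180/270 degrees aimed at the PTV centroid
with an aperture of the PTV radius + 5 mm, `mu_eff = 0.005/mm` and a
60 Gy prescription. There is no scatter, no electron transport, no
heterogeneity kernel: the PSQA metrics only require a deterministic,
density-sensitive mapping from image to dose, and a primary-attenuation
model provides exactly that while staying exactly reproducible. The
"monitor units unchanged" contract is the `mu_factor`: computed once on
the CT so the mean raw PTV dose equals the prescription, then reused
verbatim for every sCT recalculation.

The Siddon traversal is exact voxel-boundary integration (midpoint
voxel identification between crossings); it is verified against a
fine-step ray-marching oracle and against closed forms (chord x density
on homogeneous cubes; scaling linearity).

# The synthetic head phantom

The default phantom is a 96^3 grid at 2 mm voxels (matching a 2 mm-slice
planning CT while keeping desk-scale runtimes): an ellipsoidal head
(semiaxes 65 x 75 x 70 mm) with a 6 mm bony shell, homogeneous brain
(30 HU), skull at 800 HU, air at -1000 HU, an air sinus box and a
spherical PTV (radius 15 mm) placed either "deep" or "near_sinus". The
HU values are representative textbook numbers chosen so the [-100, 100]
and >= 100 HU windows recover the planted compartments exactly on the
noise-free CT. The sCT adds Gaussian HU noise (sigma 10 HU) inside the
body; the CT is noise-free ground truth.

A plain ellipsoid-plus-shell is almost rotationally symmetric, which
makes projection-based rotation recovery ill-posed — real skulls are
not. The phantom therefore carries asymmetric bony landmarks: two ear
canals (air tubes through the shell), a frontal midline bone ridge and
one mastoid-like bone knob on the right side. These enter the skull /
brain ground-truth masks consistently.

**Error modes.** `NONE` (faithful up to noise); `SYSTEMATIC_BIAS` (a
constant HU offset in brain tissue); `SINUS_MISPREDICTION` (the air
sinus filled with soft tissue, mimicking generators that struggle in the
heterogeneous sinus region); `METAL_ARTIFACT` (a 3000 HU implant sphere
with alternating +-300 HU radial streaks in its slab — the planted "true
failure"); `BULK_DENSITY` (the HU map collapsed to three classes
{-1000, 0, 700} split at -200 and 150 HU, mimicking bulk-density
assignment). The metal implant defaults to a 10 mm radius at
(0, -35, 5) mm, anterior tissue at the PTV's axial level, so that the
implant and streaks shadow the beam paths through the target: a true
failure should fail the PSQA gates decisively, and with this placement
it breaches all three of |ME_PTV| > 1%, |ΔD2| > 1% and gamma < 90%
rather than sitting on a tolerance boundary. The streak pattern has a
strictly positive amplitude floor so the perturbation support is exactly
the geometric artifact region.

`calibrate_bias()` tunes the bulk-density soft-tissue class value by
bisection (range +-300 HU, tolerance 0.2 percentage points, on the
noise-free pair) until the PTV mean error against CT matches a target,
by default the -1% systematic offset that characterises a bulk-density
generator; denser soft tissue attenuates more, so negative targets map
to positive HU shifts.

Cohorts derive one seed per patient from the master seed with a fixed
integer recurrence (recorded in the truth table), so any patient can be
regenerated bit-identically in isolation; this is also what makes
removing a patient leave all other rows untouched.

# Positioning

Orthogonal kV images are simulated as DRRs of the patient at a planted
couch pose (translations and rotations about the isocenter; rotations
compose intrinsically lateral → longitudinal → vertical). For rigid
motion, projecting the moved patient is mathematically identical to
projecting the unmoved volume along inversely-posed rays; the simulator
renders it that way, exactly, rather than resampling the volume first —
trilinear resampling blurs the images asymmetrically relative to the
registration's own renderings and was observed to wash the (weak)
rotation signal out of the optimum. Multiplicative Gaussian noise
(default 2%) models detector noise.

2D/2D registration maximises the mean normalised cross-correlation
between the kV pair and DRRs of the posed volume. The "automatic mode
based on bony structures" is implemented as correlation of
gradient-magnitude images (after light 3x3 smoothing): bone edges
dominate image gradients, while correlating bone-only DRRs against
full-spectrum kV images would compare two different modalities and
biases the optimum by several tenths of a degree. The search runs
coarse-to-fine: iterated per-axis sweeps on a 1 mm / 1 degree lattice
over +-10 mm / +-5 degrees (a full 6-D lattice at that resolution would
be ~10^7 poses and is computationally pointless when each axis is
well-conditioned), using a half-resolution detector and plain-intensity
correlation (the intensity surface is smooth and single-basin, whereas
edge images develop symmetric secondary optima); then Nelder-Mead
refinement at full resolution under the gradient criterion, with a final
small-simplex polish. Each refinement stage optimises an *offset* around
the previous solution so the simplex has a fixed absolute size — R's
Nelder-Mead otherwise scales its start simplex with the parameter
values and stalls near zero. A multi-optimum flag is raised when a
coarse pose within 1% of the best similarity lies more than
2 mm / 2 degrees away (spherically symmetric content triggers it).

3D rigid registration (used for the sCT/CT offset) maximises intensity
NCC with a translation grid search plus Nelder-Mead on a 4x-downsampled
grid, then full-resolution refinement. Both volumes are pre-smoothed
with a separable box kernel: candidate-pose resampling blurs only the
moving volume, and with sharp inputs that asymmetry shifts the NCC
optimum by up to a degree; after matched smoothing the bias is far below
the 0.2 mm / 0.2 degree recovery target.

The positioning difference per axis is
`(sct_pose - ct_pose) - sct_ct_offset` with small-angle additive
composition — for rotations up to 5 degrees the error of treating
rotations additively is below 0.01 degrees, far under the optimizer
noise.

# Numerical and testing choices

* Problem sizes: unit tests run 48^3 phantoms at 3 mm; the cohort-level
  checks use the default 96^3 at 2 mm with a 20-phantom demo cohort
  (16 faithful, 2 metal, 2 bulk-density); pose recovery uses 10 noise
  seeds; gamma oracle equivalence uses 10 random 16-32^3 pairs. These
  sizes make the whole suite reproducible on a laptop while leaving
  every mechanism fully exercised.
* Determinism: every stochastic step (phantom noise, kV noise, planted
  poses) flows from explicit seeds; the RNG state is saved and restored
  around each draw, so library calls cannot perturb downstream draws.
  Two runs of the same study configuration produce byte-identical
  report files.
* The DVH oracle compares against a 0.001 Gy cumulative-histogram
  inverse on dense DVHs (2 x 10^4 voxels), where the k/N interpolation
  convention and the step-function inverse agree to within one bin.
* DICOM support is a deliberately minimal explicit/implicit-VR
  little-endian subset covering CT series, RTDOSE and RTSTRUCT; it
  round-trips its own files and is cross-checked against an independent
  reader. Synthetic fixtures are written by the package itself
  (`write_dicom_ct_series()`, `write_rtstruct_synthetic()`).

# Limitations

The phantom exercises the *metrics*, not anatomy: passing tests show
the pipeline computes ME/DVH/gamma/sensitivity/positioning correctly
and recovers planted failures under the stated noise model; they do not
show that any particular clinical sCT generator is safe, nor calibrate
tolerances for clinical use. The dose engine ignores scatter and
electron transport, so absolute dose distributions are not clinically
meaningful — only paired differences under controlled perturbations
are. MR simulation, CBCT workflows and treatment-plan optimisation are
out of scope.
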