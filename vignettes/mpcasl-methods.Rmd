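---
title: "Models and methods behind mpcasl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mpcasl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mpcasl)
```

This vignette documents the physical and statistical models implemented in
`mpcasl`, the tunable parameters and their defaults, the design choices made
where the methodology was genuinely open, and what the synthetic-data tests
do and do not establish. It states no empirical result that the package's
tests and acceptance script do not themselves compute.

## 1. Bloch simulation of pCASL labelling

A pseudocontinuous labelling train is modelled as 600 µs Hanning-shaped RF
pulses starting every 1.2 ms, each played under a slice-select gradient
`g_max`, followed by a 600 µs rectangular refocusing lobe chosen so that the
per-interval zeroth gradient moment equals `g_mean_ratio × g_max × interval`
(default ratio 0.05). A single spin travels at constant velocity along the
gradient axis from 5 labelling-plane thicknesses upstream to 5 thicknesses
downstream; flow-driven adiabatic inversion occurs as it crosses the plane.

**Numerics.** The magnetisation is propagated by exact axis–angle rotations
about the instantaneous effective field (never forward Euler), with a fixed
0.5 µs step during pulses and analytic z-precession plus relaxation between
pulses (exact, because a z-only field commutes with itself over the
interval). With relaxation disabled the propagator is norm-conserving to
better than 1e-8 over a full 0.9 s train, which the tests assert.

**Parameters and defaults.**

| parameter | default | unit | note |
|---|---|---|---|
| pulse duration / interval | 600 / 1200 | µs | train definition |
| peak B1 | 5 | µT | *peak* of the Hanning envelope |
| labelling plane thickness | 2 | mm | sets `g_max` via BW = 1.44/duration |
| blood velocity | 124 | mm/s | mean carotid velocity in mouse |
| T1 / T2 of blood | 2.1 / 0.033 | s | arterial blood at 9.4 T |
| label duration | 0.9 | s | sequence operating point |

The thickness↔gradient conversion uses the Hanning FWHM time–bandwidth
product 1.44; γ/2π = 42.577 MHz/T. The nominal flip angle implied by a 5 µT
peak 600 µs Hanning pulse is 23°, not the 40° quoted for such sequences — the
two parameterisations are mutually inconsistent, and the package treats the
B1 amplitude in µT as authoritative (flip angle is derived metadata).

**Efficiency read-out (a deliberate design choice).** Two conventions are
implemented. The default reports α = (1 − M_z)/2 where the spin exits the
simulated trajectory, *including* the T1 recovery experienced after the
plane crossing; `compensate_t1 = TRUE` divides that recovery out, referring
the value to the plane itself. At the operating point the plane-exit value
is 0.8175 and the T1-compensated value 0.8498 (the package's own acceptance
test computes the former and checks it against the 78.5% design value of
this operating point within 5 percentage points). The plane-exit convention
was chosen as the default because it reproduces the published design value
of the sequence; the ambiguity is intrinsic — published simulation
frameworks differ in both the read-out location and in whether "B1" denotes
the pulse peak or a mean amplitude — so both options are exposed.

**Phase-increment symmetry.** Efficiency is an even function of the
multiphase increment θ only up to the off-resonance history of the moving
spin; the exact mirror symmetry would also flip the gradient polarity. At
the operating point the asymmetry is below 2%, and the control condition
(θ = 180°) destroys labelling (≤ 10% of the θ = 0 efficiency), which the
tests assert.

**Accumulated label vs duration.** `saturation_vs_duration()` reports
α(τ) × (1 − e^(−τ/T1b)): the inversion efficiency of the (possibly
truncated) train times the longitudinal build-up factor of continuous
labelling. This metric is zero at zero duration, monotone, and plateaus at
α once τ ≫ T1b — the behaviour asserted by the property tests. It is a
design-space summary, not a tissue signal model (that is the kinetic
model's job).

## 2. Buxton kinetic model

The single-compartment general kinetic model for continuous labelling is
implemented in closed piecewise form (zero before arrival Δt, exponential
approach to a plateau during the τ-long bolus, apparent-T1 decay after it),
with 1/T1′ = 1/T1_tissue + f̃/λ and f̃ = f/6000 converting mL/100 g/min to
s⁻¹·mL/g. An independent quadrature oracle (numerical convolution of the
delivery function with the clearance kernel) agrees to 1e-6 across a 10×10
(f, Δt) grid in the tests. No dispersion, macrovascular component or
two-compartment exchange is modelled.

Defaults, chosen as standard literature values because the quantitation
constants of custom preclinical pipelines are typically unpublished:
λ = 0.9 mL/g, T1_tissue = 1.9 s (9.4 T), T1_blood = 2.1 s, α = 0.785 (the
Bloch module's operating point), τ = 0.9 s, PLD = 0.4 s. All are
config-overridable; they are documented defaults, not assertions about any
particular scanner's calibration.

Single-delay inversion solves the forward model for f by bisection (the
model is monotone in f; T1′ itself depends on f, so the inversion is not
algebraic). Multi-delay fitting minimises least squares over (f, Δt) with
bounds f ∈ [0, 1000], Δt ∈ [0, max PLD], multi-start in Δt at
{0.05, 0.2, 0.5} s with ties broken toward the smaller Δt; the map-level
fitter seeds a per-voxel Nelder–Mead polish from a vectorised coarse grid.

**Arrival-fraction estimation.** Thresholding a noisy per-voxel Δt estimate
at 0.4 s is biased wherever the true arrival-time density is asymmetric
around the threshold, and voxels with no perfusion (ventricle) produce
meaningless fits. `fit_bat_map()` therefore offers a perfusion floor
(`f_floor`, voxels below it get `NA` arrival) and Gaussian spatial
regularisation of the arrival map (`smooth_fwhm`, default off; the
acceptance test uses 2 voxels, matching the pipeline's phase-smoothing
default). This mirrors the spatial regularisation used by the standard ASL
toolchains this package emulates.

## 3. Multiphase analysis chain

The per-voxel signal across the 8 labelling phases is modelled as
S(θ) = C − A·F(wrap(θ − θ₀)) — the labelled condition *reduces* signal — with
the modified Fermi response F(Δθ) = 1/(1 + exp((|Δθ| − α_f)/β_f)), α_f = 70°,
β_f = 19°. The published form of the "modified Fermi" function is cited but
not printed in the multiphase literature; this even, saturating form
honours the printed (α, β) semantics (half-maximum at |Δθ| = α_f) and is
documented here as an assumption.

θ₀ is found by a 5° grid search with closed-form (A, C) per candidate (the
model is linear in A and C given θ₀) followed by bounded 1-D refinement —
deterministic, immune to the local minima an 8-sample objective invites;
grid ties break toward the smallest |θ₀|. Amplitudes are constrained
non-negative. All phase arithmetic is circular with the wrap convention
(−180°, 180°].

The chain then: (1) smooths the raw phase map by Gaussian averaging of the
phase *unit vectors* (circular mean; undefined-phase voxels carry no
weight; kernel truncated at 3σ; default FWHM 2 voxels); (2) clusters the
smoothed map with a SLIC-style k-means in (phase-unit-vector, position)
space — position scaled by the seed-grid spacing and a compactness weight
(default 0.1), deterministic farthest-point seeding from the mask centroid,
and post-hoc connectivity enforcement that reassigns disconnected fragments
to the neighbour with the largest shared boundary; (3) re-fits the Fermi
model to each cluster's mean 8-phase signal (high SNR) and assigns the
cluster phase to its members; (4) re-fits only (A, C) per voxel with θ₀
fixed to the high-precision phase — A is the perfusion-weighted signal;
(5) calibrates M0_blood = reference/λ from the unlabelled scan and inverts
the kinetic model voxelwise.

The supervoxel count defaults to 60 per axial slice (the published analyses
do not state their count; 60/slice gives ~25-voxel clusters on the 64×64
mouse matrix, small enough that the smooth phase field is near-constant
within a cluster). The assumed arrival time for single-delay quantification
(`delta_t`, scalar or map, default 0.2 s) is a config choice; the validation
experiments pass the phantom's true arrival field so that they measure the
fitting chain, not arrival assumptions.

## 4. The digital phantom: what it emulates, and what a green test means

`make_mouse_phantom()` builds a 64×64×8 grid (0.3125 mm in-plane, 1 mm
slices, matching the acquisition FOV/matrix) of nested ellipsoids: cortical
shell, thin corpus-callosum band, striatal interior, small midline
ventricles. Ground-truth CBF defaults are the published healthy-mouse
regional values (cortex 103, striatum 90, corpus callosum 77 mL/100 g/min);
the optional tumour overrides the left striatum with a core (69) and rim
(83) whose voxelwise jitter (SD 14 and 10, the printed group SDs) emulates
the elevated intra-lesion variance that the F-test utilities are meant to
detect. Bolus arrival rises posterior→anterior (0.12–0.44 s plus 15 ms
jitter) so that ~97% of brain voxels arrive within the 0.4 s threshold —
the regime the published arrival mapping reports. The phase-offset field is
a sum of three low-order cosine modes scaled to ±60° by default (±90° in
the robustness property test); the true spatial scale of B0-driven phase
offsets at 9.4 T is not published, so this amplitude is a documented
assumption.

The forward simulators share the package's own response functions (the
Fermi response and `buxton_delta_m()`; an import-level test asserts this),
add seeded Gaussian noise (Rician magnitude optional), and calibrate the
noise to a *perfusion-weighted* SNR: mean control-minus-label difference
signal over the brain divided by the background noise SD. Target 15.1
emulates the respiration-triggered acquisition; in untriggered mode a
respiration-locked multiplicative fluctuation (period 1.07 s against the
4 s repetition spacing, weighted toward the inferior slices, plus an
EPI-ghost-like component across the field of view) is scaled so the
measured SNR degrades to 6.5.

Because the generator and the pipeline share the forward model, a green
recovery test establishes internal consistency of the chain — correct
fitting, clustering, calibration, inversion and their composition under the
stated noise — not agreement with real mouse data. Features of real data
deliberately *not* emulated: anatomy beyond nested ellipsoids, EPI
distortion and susceptibility dropout, motion, laminar/pulsatile flow,
partial-volume mixing, and any dispersion of the labelled bolus.

## 5. Densitometry

Film calibration uses shape-preserving monotone (Fritsch–Carlson)
interpolation of activity against reading — exact at the standards, no
overshoot between them, flagged clamping outside the calibrated range. The
Kety one-compartment operational equation
Ci(T) = K ∫₀ᵀ Ca(t) e^(−K(T−t)) dt is solved for K by a monotone root
search with f = K·λ·6000; λ defaults to 0.8 mL/g for iodoantipyrine. The
arterial input is reconstructed from the single terminal blood sample as a
linear ramp 0 → Ca(T) over the 2-minute circulation — the dominant
uncertainty of the method, so arbitrary input functions are accepted and
integrated numerically. Film-to-MR alignment fits a projective homography
to ≥ 4 control-point pairs (normalised DLT; near-rank-deficient systems are
rejected as degenerate), inverse-warps with bilinear interpolation and
block-averages to the 64×64 MR grid. The positive-pixel vessel-area
fraction replicates the thresholding rule only (moderate intensity in
[185, 202] or strong < 10, disjoint by construction), not the proprietary
implementation around it.

## 6. Input/output and reproducibility

NIfTI-1 reading and writing is implemented in-package (the target R
environment provides no NIfTI library): single-file `.nii`/`.nii.gz`, both
endiannesses, the common scalar datatypes with slope/intercept scaling on
read, float64 on write so round trips are bit-exact, and the sform affine
preserved. Configs are JSON for the same environment reason (no YAML
parser available); every CLI command writes a resolved-config manifest next
to its outputs, and a stored manifest + seed regenerates a dataset
bit-identically (asserted by a test).

## 7. Known limitations

- The Bloch module models one spin at constant velocity; no laminar or
  pulsatile velocity distribution, no B0 map, no vessel geometry.
- The efficiency read-out convention and the B1 parameterisation of the
  78.5% operating point are ambiguous in the source material; both
  conventions are exposed and the default is the one that reproduces the
  design value.
- Single-compartment kinetics without dispersion; arrival-fraction
  estimates from noisy data depend on the documented regularisation.
- The phantom's geometry and phase-offset amplitude are stylised; recovery
  tests validate the pipeline's internal consistency, not in-vivo accuracy.
- The published in-vivo group comparisons (MP pCASL vs autoradiography,
  tumour contrasts) require animals and are represented here only as the
  phantom's default ground-truth values.
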