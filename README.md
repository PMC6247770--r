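# mpcasl

Quantitative cerebral blood flow (CBF) measurement in the mouse brain with
multiphase pseudocontinuous arterial spin labelling (MP pCASL).

pCASL inverts arterial blood water with a long train of short RF pulses and
gradients at a labelling plane in the neck. Off-resonance at the plane rotates
the effective per-pulse RF phase and silently destroys labelling efficiency;
the multiphase variant re-acquires the data at 8 labelling phase offsets
(0°–315° in 45° steps) and fits the phase response per voxel, recovering the
optimal phase and with it a robust perfusion-weighted signal. This package
re-implements the computational chain needed to design, simulate, analyse and
validate such measurements:

- **`bloch_label`** — Bloch-equation simulation of labelling efficiency for a
  spin flowing through the labelling plane (600 µs Hanning pulses every
  1.2 ms, slice-select gradient with `Gmean = 0.05 Gmax`, blood T1/T2 at
  9.4 T). Inversion efficiency is α = (1 − M_z)/2 at plane exit.
- **`kinetic_model`** — the Buxton general kinetic model for continuous
  labelling: ΔM(t) = 2 M₀b f̃ α T₁′ e^(−Δt/T₁b) (1 − e^(−(t−Δt)/T₁′)) during
  the bolus (f̃ = f/6000, 1/T₁′ = 1/T₁t + f̃/λ), its inverse for CBF
  quantification, M0 calibration, and multi-delay bolus-arrival fitting.
- **`multiphase_pipeline`** — the analysis chain: per-voxel fit of
  S(θ) = C − A·F(θ − θ₀) with the modified Fermi response
  F(Δθ) = 1/(1 + exp((|Δθ| − 70°)/19°)), angle-aware smoothing, SLIC-style
  supervoxel clustering, high-SNR cluster re-fit, fixed-phase amplitude
  mapping and CBF inversion.
- **`phantom`** — a digital mouse-brain phantom (cortex / striatum / corpus
  callosum / ventricle, optional tumour core+rim) with ground-truth CBF,
  arrival time and phase-offset fields, and seeded forward simulators for
  multiphase and multi-delay acquisitions.
- **`densitometry`** — quantitative autoradiography utilities: monotone film
  calibration against 0–35 µCi/g standards, Kety one-compartment CBF from
  terminal tracer uptake, projective alignment and down-sampling to the
  64×64 MR grid, CD31 positive-pixel vessel area fraction, ROI statistics
  (paired t, variance-ratio F, Bonferroni).
- **`cli_io`** — NIfTI-1 image I/O, JSON configs, and the `mpcasl`
  command-line entry point (`bloch-sim`, `simulate`, `quantify`,
  `densitometry`, `report`).

## Worked example

```r
library(mpcasl)

# 1. labelling efficiency at the sequence operating point:
#    2 mm plane, 5 uT peak B1, mean carotid velocity 124 mm/s
simulate_passage(pulse_train(peak_b1 = 5, label_duration = 0.9),
                 label_geometry(label_thickness = 2),
                 flowing_spin(velocity = 124))
#> [1] 0.8175153

# 2. simulate a triggered-SNR acquisition of the phantom and quantify it
phan <- make_mouse_phantom(seed = 1, shape = c(32, 32, 4))
sim  <- simulate_multiphase(phan, acquisition_config(target_snr = 15.1,
                                                     seed = 1))
res  <- run_pipeline(sim$series, sim$m0, sim$mask,
                     pipeline_config(delta_t = phan$bat, k_per_slice = 30))
region_means(res$cbf, phan)
#>            region    n        mean       sd
#> 1          cortex 1264 102.8331477 2.395184
#> 2        striatum  480  89.7302284 2.466327
#> 3 corpus_callosum  240  76.8661323 2.281174
#> 4       ventricle   64   0.9240701 1.083624
```

The efficiency (81.8% at plane exit, 78.5% being the nominal design value of
this operating point) feeds the kinetic model as α. The recovered regional
means reproduce the phantom's ground truth (103 / 90 / 77 mL/100 g/min)
within ~0.3% despite a ±60° spatial phase-offset field and SNR-15 noise —
the point of the multiphase fit.

The same pipeline is scriptable from the shell:

```sh
mpcasl simulate --config inst/extdata/phantom_demo.json --seed 17 --out sim/
mpcasl quantify --asl sim/raw.nii.gz --m0 sim/m0.nii.gz \
                --mask sim/mask.nii.gz --out quant/
```

(`inst/cli/mpcasl` is the wrapper script; after installation call it as
`Rscript -e 'mpcasl::mpcasl_main()' --args ...` or put it on your PATH.)

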