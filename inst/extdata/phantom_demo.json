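{
  "phantom": {"shape": [64, 64, 8], "phase_amp": 60, "tumour": false},
  "acquisition": {"pld_s": 0.4, "tau_s": 0.9, "target_snr": 15.1,
                  "triggered": true},
  "kinetic": {"lambda": 0.9, "t1_tissue_s": 1.9, "t1_blood_s": 2.1,
              "alpha": 0.785, "tau_s": 0.9, "pld_s": 0.4},
  "pipeline": {"alpha_f": 70, "beta_f": 19, "smooth_fwhm": 2,
               "k_per_slice": 60, "compactness": 0.1, "delta_t_s": 0.2}
}
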