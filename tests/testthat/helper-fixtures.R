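# shared fixtures: all synthetic, generated in code

# noiseless multiphase signal of one voxel from the generative model
fermi_signal <- function(A, theta0, C, phases = seq(0, 315, by = 45),
                         alpha_f = 70, beta_f = 19) {
  C - A * fermi_response(phases - theta0, alpha_f, beta_f)
}

# small phantom + noiseless acquisition, shared across tests
small_phantom <- function(seed = 1, shape = c(32, 32, 4), phase_amp = 60) {
  make_mouse_phantom(seed = seed, shape = shape, phase_amp = phase_amp)
}

# control-minus-label difference series (what SNR is measured on)
diff_series <- function(sim) {
  d <- array(sim$truth$baseline, dim(sim$series$signal)) - sim$series$signal
  multiphase_series(d, sim$series$phase_angles)
}

# default operating point of the labelling simulator (peak 5 uT, 0.9 s train)
op_train <- function(...) pulse_train(...)
op_geom <- function() label_geometry(label_thickness = 2)
op_spin <- function(velocity = 124) flowing_spin(velocity = velocity)
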