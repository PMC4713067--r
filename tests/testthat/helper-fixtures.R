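# Shared fixtures: small, fast synthetic worlds for unit tests.

# A compact lamellipodium movie: short period, 2 cycles, small field.
small_params <- function(noise_sd = 2, seed = 1L, n_cycles = 2L, ...) {
  motility_params(period_s = 60, persistence_um = 1.2, retro_rate_um_s = 0.08,
                  n_cycles = n_cycles, noise_sd = noise_sd, seed = seed, ...)
}

small_config <- function(...) {
  imaging_config(image_shape = c(40L, 120L), ...)
}

# Height-0-only config for tests that never touch other planes.
flat_config <- function(...) {
  imaging_config(heights_um = c(0, 1), image_shape = c(40L, 120L), ...)
}

# Single-height "stack" built from a list of plane matrices.
raw_stack <- function(planes, frame_interval_s = 5, pixel_um = 0.1) {
  shape <- dim(planes[[1]])
  cfg <- imaging_config(pixel_um = pixel_um,
                        frame_interval_s = frame_interval_s,
                        heights_um = c(0, 1),
                        image_shape = shape)
  blank <- matrix(0, shape[1], shape[2])
  image_stack_sequence(lapply(planes, function(p) list(p, blank)), cfg)
}

# Event schedule realizing each of the four stereotyped behaviours once,
# with returns to baseline between events so detection separates them.
four_behaviour_schedule <- function() {
  list(bead_event(5,  "+z", 25, 5),   # VP: F_z to +10 pN
       bead_event(20, "-z", 25, 5),   # release
       bead_event(40, "-z", 25, 5),   # VR: F_z to -10 pN
       bead_event(55, "+z", 25, 5),   # release
       bead_event(75, "+x", 28, 5),   # LP: F_x to +14 pN
       bead_event(90, "-x", 28, 5),   # release
       bead_event(110, "-x", 28, 5),  # LR: F_x to -14 pN
       bead_event(125, "+x", 28, 5))  # release
}
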