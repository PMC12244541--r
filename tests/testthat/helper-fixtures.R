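# Shared test fixtures. Simulation sizes here are deliberately small; the
# acceptance suite runs the full-size study conditions.

quick_config <- function(n_particles = 100, t_end_s = 0.0015, seed = 1,
                         ...) {
  simulation_config(n_particles = n_particles, t_end_s = t_end_s,
                    seed = seed, ...)
}

# Exact two-level rendering of a domain (cell bright, pore dark).
noiseless_emulation <- function(pore_level = 20, cell_level = 200, seed = 1) {
  grayscale_emulation_spec(cell_brightness_mean = cell_level,
                           cell_brightness_sd = 0,
                           pore_brightness_mean = pore_level,
                           pore_brightness_sd = 0,
                           blur_sigma_px = 0, seed = seed)
}

random_map <- function(nr = 20, nc = 20, seed = 1) {
  set.seed(seed)
  grayscale_map(matrix(sample(0:255, nr * nc, replace = TRUE), nr, nc))
}
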