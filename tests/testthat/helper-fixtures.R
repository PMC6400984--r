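# Shared fixtures, all built in code.

default_library <- function(seed = 1) {
  build_library(generate_endmember_library(seed = seed), band_set())
}

# a reduced scene keeping the 8 x 3 nitrogen design but with small plot
# regions, for fast end-to-end tests
small_scene_config <- function(seed = 1, ...) {
  scene_config(plot_rows = 24, plot_cols = 20, seed = seed, ...)
}

# the fully deterministic limit: no DN noise, no yield noise, constant
# canopy greenness so yield is exactly affine in Abd_L - Abd_P
noiseless_scene_config <- function(seed = 1, ...) {
  small_scene_config(seed = seed, noise_sd_dn = 0, yield_noise_sd = 0,
                     greenness = c(0.85, 0, 0), ...)
}

# pixel index rows covering plots and ridges but not the calibration strip
below_panel_rows <- function(config, image) {
  strip <- 2 * config$ridge + config$panel_size
  (strip + 1):dim(image$values)[1]
}

# brute-force simplex-grid minimum of the unmixing objective (squared
# residual), via the compiled exhaustive enumerator
grid_min_objective <- function(spectrum, library, step = 0.01) {
  paddysma:::fcls_grid_objective_cpp(spectrum, library$matrix,
                                     as.integer(round(1 / step)))
}

random_mixture <- function(library, noise_sd = 0.005) {
  N <- nrow(library$matrix)
  a <- stats::rgamma(N, 1)
  a <- a / sum(a)
  list(abund = a,
       spectrum = as.numeric(t(library$matrix) %*% a) +
         stats::rnorm(ncol(library$matrix), 0, noise_sd))
}
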