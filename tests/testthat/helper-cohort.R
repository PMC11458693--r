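# Shared fixtures: all synthetic, built in code.

# Deterministic noise-free cohort on the default grid.
noise_free_cohort <- function(n = 2L, bands = band_table(),
                              grid = default_grid()) {
  simulate_cohort(
    cohort_design(n_cells = c(ctrl = n), cell_cv = 0, noise_sd = 0,
                  mie_amplitude = 0, drift_sd = 0, seed = 1),
    bands = bands, grid = grid)
}

# Small hand-made spectrum set: k cells of given absorbance columns.
toy_set <- function(cols, grid = seq(2000, 1000, by = -10)) {
  m <- do.call(cbind, cols)
  spectrum_set(grid, m, sprintf("cell%02d", seq_along(cols)))
}

# Gaussian band evaluated on a grid.
gauss_band <- function(grid, center, fwhm, amp = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-(grid - center)^2 / (2 * s^2))
}
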