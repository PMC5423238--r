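# Shared fixtures for the test suite: preset models, small grids, and a
# noise-free simulation shortcut.

preset <- default_analyte_models()

noise_free <- function(model, conc, grid = wl_grid()) {
  simulate_spectrum(model, conc, noise = NULL, grid = grid)
}

# analytic nth derivatives of a Gaussian exp(-(x - mu)^2 / (2 s2)), used as
# independent oracles for the derivative operator
gauss_d3 <- function(x, mu, s2) {
  t <- x - mu
  (3 * t / s2^2 - t^3 / s2^3) * exp(-t^2 / (2 * s2))
}
gauss_d1 <- function(x, mu, s2) {
  t <- x - mu
  (-t / s2) * exp(-t^2 / (2 * s2))
}

# fast noise-free end-to-end study configuration (small but complete)
quiet_config <- function(seed = 99) {
  study_config(noise = noise_model(sd_au = 0, baseline_drift_au = 0),
               excipient_baseline_au = 0, calib_replicates = 2L,
               screen_scans = 1L, seed = seed)
}
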