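# Shared fixtures, built once per test run.

drs_grid <- default_grid()
drs_basis <- load_chromophore_basis(drs_grid)
drs_geom <- probe_geometry()
drs_inst <- default_instrument(drs_grid, drs_basis, drs_geom)

# a flat spectrum on the working grid
flat_spec <- function(value, units = "mm^-1", grid = drs_grid) {
  spectrum(rep(value, length(grid)), grid, units)
}

# an ad-hoc multiplicative perturbation on one channel
flat_perturbation <- function(channel, transmittance, grid = drs_grid) {
  structure(list(index = paste0(channel, "-flat"), channel = channel,
                 transfer = flat_spec(transmittance, "dimensionless",
                                      grid)),
            class = "perturbation_spec")
}

spectral_perturbation <- function(channel, values, grid = drs_grid) {
  structure(list(index = paste0(channel, "-spectral"), channel = channel,
                 transfer = spectrum(values, grid, "dimensionless")),
            class = "perturbation_spec")
}

# an extinction spectrum object built directly from values (for inversion
# edge cases that no measurement produces)
manual_extinction <- function(values, grid = drs_grid,
                              method = "S1S2D1D2") {
  structure(list(mu_eff = spectrum(values, grid, "mm^-1"),
                 method = method,
                 valid_mask = rep(TRUE, length(grid)),
                 source_set = "manual"),
            class = "extinction_spectrum")
}

# a fit_result carrying given parameters (for deviation-report oracles)
manual_fit <- function(params) {
  structure(list(params = params, objective = 0, converged = TRUE,
                 start_index = 1L, n_evaluations = 0L),
            class = "fit_result")
}

# instrument with both detector transients identical
equal_detector_instrument <- function() {
  inst <- drs_inst
  inst$A_D2 <- inst$A_D1
  inst
}
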