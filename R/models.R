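#' Rayleigh-Mie reduced scattering spectrum
#'
#' Two-term power law referenced to 500 nm:
#' `mu_s'(lambda) = a * (f * (lambda/500)^-4 + (1 - f) * (lambda/500)^-b)`.
#' The Rayleigh term (`lambda^-4`) dominates in the blue, the Mie term
#' (`lambda^-b`) in the NIR.
#'
#' @param params a [tissue_params()].
#' @param grid a [spectral_grid()].
#' @return a [spectrum()] in mm^-1.
#' @export
reduced_scattering <- function(params, grid = default_grid()) {
  stopifnot(inherits(params, "tissue_params"))
  if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
  rel <- unclass(grid) / lambda0()
  v <- params[["a"]] * (params[["f"]] * rel^(-4) +
                          (1 - params[["f"]]) * rel^(-params[["b"]]))
  spectrum(v, grid, "mm^-1")
}

#' Tissue absorption spectrum
#'
#' Weighted sum of the chromophore basis:
#' `mu_a = C_water * mua_water + C_mel * mua_mel +
#'  C_blood * (StO2 * mua_oxy + (1 - StO2) * mua_deoxy) + mua_dry`.
#'
#' @param params a [tissue_params()].
#' @param basis a `chromophore_basis` (defines the grid).
#' @return a [spectrum()] in mm^-1, non-negative.
#' @export
absorption <- function(params, basis) {
  stopifnot(inherits(params, "tissue_params"),
            inherits(basis, "chromophore_basis"))
  blood <- params[["StO2"]] * basis$mua_oxy$values +
    (1 - params[["StO2"]]) * basis$mua_deoxy$values
  v <- params[["C_water"]] * basis$mua_water$values +
    params[["C_mel"]] * basis$mua_mel$values +
    params[["C_blood"]] * blood +
    params[["mua_dry"]]
  spectrum(v, grid_of(basis$mua_oxy), "mm^-1")
}

#' Effective extinction coefficient of diffuse light
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`, the decay constant of the
#' diffusion-theory Green's function.  Absorption and reduced scattering
#' enter only through this product, which is the root cause of the
#' continuous-wave identifiability problem the dual-slope method inherits.
#'
#' @param mua,musp [spectrum()] objects on a shared grid, mm^-1,
#'   non-negative.
#' @return a [spectrum()] in mm^-1.
#' @export
effective_extinction <- function(mua, musp) {
  stopifnot(inherits(mua, "spectrum"), inherits(musp, "spectrum"))
  stopifnot_same_grid(mua, musp)
  if (any(mua$values < 0) || any(musp$values < 0))
    stop("effective_extinction requires non-negative inputs")
  spectrum(sqrt(3 * mua$values * (mua$values + musp$values)),
           grid_of(mua), "mm^-1")
}

#' Forward extinction model for fitting
#'
#' Composes [absorption()], [reduced_scattering()] and
#' [effective_extinction()]: the model curve `mu_eff(K; lambda)` whose
#' least-squares distance to a measured extinction spectrum defines the
#' inversion objective.
#'
#' @param params a [tissue_params()].
#' @param basis a `chromophore_basis`.
#' @param grid optional [spectral_grid()]; defaults to the basis grid, and
#'   must be a subset of it otherwise.
#' @return a [spectrum()] in mm^-1.
#' @export
model_extinction <- function(params, basis, grid = NULL) {
  g_basis <- grid_of(basis$mua_oxy)
  mua <- absorption(params, basis)
  musp <- reduced_scattering(params, g_basis)
  out <- effective_extinction(mua, musp)
  if (!is.null(grid)) {
    if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
    idx <- match(unclass(grid), unclass(g_basis))
    if (anyNA(idx))
      stop("requested grid is not a subset of the basis grid")
    out <- spectrum(out$values[idx], grid, out$units)
  }
  out
}
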