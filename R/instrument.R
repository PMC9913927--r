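#' Probe geometry
#'
#' Symmetric in-line four-fiber layout (D1, S1, S2, D2 with equal neighbor
#' spacing): both sources see one detector at the short distance `r_S` and
#' the other at the long distance `r_L` (`r11 = r22 = r_S`,
#' `r12 = r21 = r_L`).  This symmetry is what makes the dual-slope ratio
#' self-calibrating.
#'
#' @param r_S,r_L short and long source-detector distances in mm,
#'   `0 < r_S < r_L`.  Defaults 2 and 4 mm.
#' @param source_core_um,detect_core_um fiber core diameters in micrometers
#'   (defaults 400 and 200), used by the insertion-loss perturbation model.
#' @return an object of class `probe_geometry`.
#' @export
probe_geometry <- function(r_S = 2, r_L = 4,
                           source_core_um = 400, detect_core_um = 200) {
  if (!(r_S > 0 && r_L > r_S)) stop("require 0 < r_S < r_L")
  structure(list(r_S = r_S, r_L = r_L,
                 layout = c("D1", "S1", "S2", "D2"),
                 source_core_um = source_core_um,
                 detect_core_um = detect_core_um),
            class = "probe_geometry")
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("<probe_geometry> r_S = %g mm, r_L = %g mm, layout %s\n",
              x$r_S, x$r_L, paste(x$layout, collapse = "-")))
  invisible(x)
}

# source-detector distance for pair (k, j) under the symmetric layout
pair_distance <- function(geometry, k, j) {
  if (k == j) geometry$r_S else geometry$r_L
}

#' Photon fluence rate of a point source in an infinite medium
#'
#' Diffusion-theory Green's function
#' `phi(r) = 3 (mu_a + mu_s') / (4 pi r) * exp(-mu_eff r)` for a unit-power
#' point source; medium boundaries and fiber radiation patterns are
#' deliberately neglected, as in the forward model the extraction formulas
#' assume.
#'
#' @param r distance from the source in mm, positive.
#' @param mua,musp absorption and reduced scattering [spectrum()]s, mm^-1.
#' @return a [spectrum()] (units `mm^-2`).
#' @export
fluence <- function(r, mua, musp) {
  if (!(is.numeric(r) && length(r) == 1 && r > 0))
    stop("r must be a single positive distance in mm")
  stopifnot_same_grid(mua, musp)
  mueff <- effective_extinction(mua, musp)
  v <- 3 * (mua$values + musp$values) / (4 * pi * r) * exp(-mueff$values * r)
  spectrum(v, grid_of(mua), "mm^-2")
}

#' Instrument model
#'
#' Spectral transfer chain and acquisition settings of the four-channel
#' spectrometer system: source intensity `I0`, per-channel transient
#' characteristics `A_S1`, `A_S2`, `A_D1`, `A_D2`, detector sensitivity
#' `eta`, per-pair exposure times, dark level, readout noise, and the
#' heartbeat period that sets the averaging count
#' `n = max(1, round(heartbeat_period / E_kj))`.
#'
#' Use [default_instrument()] to build a realistic default.
#'
#' @param source_intensity,A_S1,A_S2,A_D1,A_D2,eta non-negative
#'   [spectrum()]s on a shared grid.
#' @param exposures named numeric vector `c(E11=, E12=, E21=, E22=)` in ms,
#'   all positive.
#' @param dark_level mean dark counts per frame.
#' @param readout_sigma readout noise standard deviation, counts.
#' @param heartbeat_period averaging window, ms (default 1000).
#' @return an object of class `instrument_model`.
#' @export
instrument_model <- function(source_intensity, A_S1, A_S2, A_D1, A_D2, eta,
                             exposures = c(E11 = 15, E12 = 80,
                                           E21 = 80, E22 = 15),
                             dark_level = 100, readout_sigma = 10,
                             heartbeat_period = 1000) {
  sp <- list(source_intensity = source_intensity, A_S1 = A_S1, A_S2 = A_S2,
             A_D1 = A_D1, A_D2 = A_D2, eta = eta)
  for (nm in names(sp)) {
    if (!inherits(sp[[nm]], "spectrum")) stop(nm, " must be a spectrum")
    stopifnot_same_grid(sp[[nm]], source_intensity)
    if (any(sp[[nm]]$values < 0)) stop(nm, " must be non-negative")
  }
  if (!all(c("E11", "E12", "E21", "E22") %in% names(exposures)))
    stop("exposures must name E11, E12, E21, E22")
  if (any(exposures <= 0)) stop("exposures must be positive")
  structure(c(sp, list(exposures = exposures, dark_level = dark_level,
                       readout_sigma = readout_sigma,
                       heartbeat_period = heartbeat_period)),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  g <- grid_of(x$source_intensity)
  cat(sprintf(paste0("<instrument_model> %d wavelengths, %g-%g nm; ",
                     "E = %s ms; dark %g, readout %g, heartbeat %g ms\n"),
              length(g), min(g), max(g),
              paste(x$exposures[c("E11", "E12", "E21", "E22")],
                    collapse = "/"),
              x$dark_level, x$readout_sigma, x$heartbeat_period))
  invisible(x)
}

#' Default instrument model
#'
#' Smooth positive default curves: a Xenon-like source with enhanced
#' visible radiance, a CCD-like sensitivity peaking near 700 nm, and gentle
#' channel transients with `A_D2` differing from `A_D1` by a few percent
#' (so the single-slope formulas, which assume equal detector transients,
#' carry a small systematic bias as real systems do).  The source scale is
#' set so the brightest unperturbed channel for `reference_scene` reaches
#' `peak_counts` expected counts per frame; the enhanced visible radiance
#' keeps all four channels within the usable dynamic range across the whole
#' band, mirroring the design goal the two exposure times serve.
#'
#' @param grid working [spectral_grid()].
#' @param basis `chromophore_basis` used to scale counts.
#' @param geometry [probe_geometry()].
#' @param reference_scene [tissue_params()] the count scale refers to
#'   (default [palm_preset()]).
#' @param peak_counts target full-scale expected counts per frame
#'   (default 5e4).
#' @param detector_imbalance peak relative difference between `A_D2` and
#'   `A_D1` (default 0.04).
#' @param ... passed to [instrument_model()] (exposures, dark_level, ...).
#' @return an `instrument_model`.
#' @export
default_instrument <- function(grid = default_grid(),
                               basis = load_chromophore_basis(grid),
                               geometry = probe_geometry(),
                               reference_scene = palm_preset(),
                               peak_counts = 5e4,
                               detector_imbalance = 0.04, ...) {
  if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
  l <- unclass(grid)
  s <- (l - min(l)) / max(1, diff(range(l)))        # 0..1 ramp
  sp <- function(v) spectrum(v, grid, "dimensionless")
  I0 <- spectrum(0.35 + 1.6 * exp(-((l - 480) / 110)^2), grid,
                 "arbitrary")
  eta <- spectrum(exp(-((l - 700) / 280)^2), grid, "counts_per_energy")
  A_S1 <- sp(0.92 + 0.08 * exp(-((l - 600) / 250)^2))
  A_S2 <- sp(0.95 - 0.05 * s)
  A_D1 <- sp(0.90 + 0.06 * exp(-((l - 800) / 300)^2))
  A_D2 <- sp(A_D1$values * (1 - detector_imbalance + 1.25 *
                              detector_imbalance * s))
  inst <- instrument_model(I0, A_S1, A_S2, A_D1, A_D2, eta, ...)
  # scale the source so the brightest channel hits peak_counts per frame
  peak <- max(vapply(expected_counts(reference_scene, basis, inst,
                                     geometry), function(x) max(x$values),
              numeric(1)))
  inst$source_intensity$values <- inst$source_intensity$values *
    (peak_counts / peak)
  inst
}

#' Perturbation transfer functions
#'
#' Builds one of the cataloged instrumental perturbations as a
#' multiplicative spectral transfer on a single source or detection
#' channel:
#' \describe{
#'   \item{D1L / S1L}{insertion of a 105 um core fiber into the detection /
#'     source channel; flat transmittance equal to the core-area ratio,
#'     (105/200)^2 = 0.275625 and (105/400)^2 = 0.06890625 for the default
#'     fiber cores.}
#'   \item{D1C / S1C}{fiber curved into a 50 mm ring; flat transmittance
#'     0.98 (close to 100%).}
#'   \item{D1B/D1G/D1P, S1B/S1G/S1P}{colored sticker at the probe-tissue
#'     interface; smooth band-pass transmission curve (visible band set by
#'     the color, partial NIR recovery).  A qualitative approximation of
#'     measured sticker curves.}
#'   \item{INIT}{no perturbation; transfer identically 1.}
#' }
#'
#' @param index perturbation label (`"D1L"`, `"D1C"`, `"D1B"`, `"D1G"`,
#'   `"D1P"`, `"S1L"`, `"S1C"`, `"S1B"`, `"S1G"`, `"S1P"`, `"INIT"`).
#' @param grid working [spectral_grid()].
#' @param geometry [probe_geometry()] supplying the fiber core diameters
#'   for the insertion-loss transmittance.
#' @param catalog parameter catalog as from [perturbation_catalog()].
#' @return an object of class `perturbation_spec` with fields `index`,
#'   `channel` and `transfer` (a [spectrum()] with values in \[0, 1\]).
#' @export
#' @examples
#' make_perturbation("D1L")$transfer$values[1]
make_perturbation <- function(index, grid = default_grid(),
                              geometry = probe_geometry(),
                              catalog = perturbation_catalog()) {
  if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
  l <- unclass(grid)
  known <- perturbation_labels()
  if (!index %in% c(known, "INIT"))
    stop("unknown perturbation label '", index, "'")
  channel <- if (index == "INIT") "none" else substr(index, 1, 2)
  kind <- if (index == "INIT") "INIT" else substr(index, 3, 3)
  st <- catalog$sticker
  sticker <- function(color) {
    band <- st$colors[[color]]
    pmin(st$floor +
           st$band_amplitude *
             exp(-((l - band$center_nm) / band$width_nm)^2) +
           st$nir_amplitude /
             (1 + exp(-(l - st$nir_center_nm) / st$nir_width_nm)), 1)
  }
  t <- switch(kind,
    INIT = rep(1, length(l)),
    L = {
      core <- if (channel == "D1") geometry$detect_core_um
              else geometry$source_core_um
      rep((catalog$loss$inserted_core_um / core)^2, length(l))
    },
    C = rep(catalog$curve$transmittance, length(l)),
    B = sticker("B"),
    G = sticker("G"),
    P = sticker("P"))
  structure(list(index = index, channel = channel,
                 transfer = spectrum(t, grid, "dimensionless")),
            class = "perturbation_spec")
}

#' Load the perturbation parameter catalog
#'
#' Reads the YAML catalog mapping perturbation kinds to transfer-function
#' parameters (inserted-fiber core diameter for losses, flat transmittance
#' for fiber curving, band-pass parameters per sticker color).
#'
#' @param path YAML path; default the catalog shipped with the package.
#' @return a nested list of parameters.
#' @export
perturbation_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "perturbations.yaml",
                        package = "dualslope", mustWork = TRUE)
  yaml::read_yaml(path)
}

#' The ten cataloged perturbation labels (excluding INIT)
#' @return character vector of labels.
#' @export
perturbation_labels <- function() {
  c("D1L", "D1C", "D1B", "D1G", "D1P",
    "S1L", "S1C", "S1B", "S1G", "S1P")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> %s on channel %s, T in [%.3g, %.3g]\n",
              x$index, x$channel, min(x$transfer$values),
              max(x$transfer$values)))
  invisible(x)
}

# expected per-frame counts for all four pairs (no noise, no dark)
expected_counts <- function(params, basis, instrument, geometry,
                            perturbations = list()) {
  mua <- absorption(params, basis)
  musp <- reduced_scattering(params, grid_of(mua))
  A <- list(S1 = instrument$A_S1$values, S2 = instrument$A_S2$values,
            D1 = instrument$A_D1$values, D2 = instrument$A_D2$values)
  seen <- character(0)
  for (p in perturbations) {
    if (!inherits(p, "perturbation_spec"))
      stop("perturbations must be perturbation_spec objects")
    if (p$channel == "none") next
    if (p$channel %in% seen)
      stop("two perturbations on channel ", p$channel)
    seen <- c(seen, p$channel)
    stopifnot_same_grid(p$transfer, mua)
    A[[p$channel]] <- A[[p$channel]] * p$transfer$values
  }
  base <- instrument$source_intensity$values * instrument$eta$values
  out <- list()
  for (k in 1:2) for (j in 1:2) {
    r <- pair_distance(geometry, k, j)
    phi <- fluence(r, mua, musp)
    E <- instrument$exposures[[paste0("E", k, j)]]
    out[[paste0("I", k, j)]] <- spectrum(
      phi$values * A[[paste0("S", k)]] * A[[paste0("D", j)]] * base * E,
      grid_of(mua), "counts")
  }
  out
}

#' Simulate a four-channel DRS measurement
#'
#' Forward-simulates the detected spectra `I11`, `I12`, `I21`, `I22` for a
#' homogeneous medium under the diffusion Green's function, the per-channel
#' transfer chains, per-pair exposure times and heartbeat-period averaging.
#' With `noise = TRUE`, each of the `n = max(1, round(heartbeat / E_kj))`
#' sub-frames receives shot noise (Gaussian with variance equal to expected
#' counts including dark) plus readout noise; a matched dark frame sequence
#' is simulated identically with the source off and subtracted, as the
#' acquisition procedure does.  Noise-free simulation returns expected
#' dark-subtracted counts exactly.
#'
#' @param params a [tissue_params()] scene.
#' @param basis a `chromophore_basis`.
#' @param instrument an [instrument_model()].
#' @param geometry a [probe_geometry()].
#' @param perturbations list of [make_perturbation()] objects, at most one
#'   per channel.
#' @param noise logical; add shot/readout noise?
#' @param seed integer seed, required when `noise = TRUE`.
#' @return an object of class `measurement_set` with the four count
#'   spectra, exposures, geometry, per-pair averaging counts, seed,
#'   perturbation label(s), and a `negative_values` flag set when noisy
#'   dark subtraction produced non-positive counts.
#' @export
simulate_measurement <- function(params, basis, instrument, geometry,
                                 perturbations = list(), noise = FALSE,
                                 seed = NULL) {
  if (noise && is.null(seed)) stop("a seed is required when noise is on")
  exp_counts <- expected_counts(params, basis, instrument, geometry,
                                perturbations)
  g <- grid_of(exp_counts$I11)
  nl <- length(g)
  n_avg <- vapply(c("E11", "E12", "E21", "E22"), function(e)
    max(1L, as.integer(round(instrument$heartbeat_period /
                               instrument$exposures[[e]]))), integer(1))
  names(n_avg) <- c("I11", "I12", "I21", "I22")
  out <- list()
  if (noise) set.seed(derive_seed(seed, "simulate"))
  for (nm in names(exp_counts)) {
    S <- exp_counts[[nm]]$values
    if (!noise) {
      out[[nm]] <- spectrum(S, g, "counts")
      next
    }
    n <- n_avg[[nm]]
    dk <- instrument$dark_level
    sr <- instrument$readout_sigma
    sig <- matrix(S + dk, nl, n) +
      matrix(stats::rnorm(nl * n, 0, sqrt(S + dk)), nl, n) +
      matrix(stats::rnorm(nl * n, 0, sr), nl, n)
    drk <- matrix(dk, nl, n) +
      matrix(stats::rnorm(nl * n, 0, sqrt(dk)), nl, n) +
      matrix(stats::rnorm(nl * n, 0, sr), nl, n)
    out[[nm]] <- spectrum(rowMeans(sig) - rowMeans(drk), g, "counts")
  }
  labels <- vapply(perturbations, function(p) p$index, character(1))
  structure(list(
    I11 = out$I11, I12 = out$I12, I21 = out$I21, I22 = out$I22,
    exposures = instrument$exposures, geometry = geometry,
    n_averages = n_avg, seed = seed,
    perturbation = if (length(labels)) paste(labels, collapse = "+")
                   else "INIT",
    negative_values = any(vapply(out, function(s) any(s$values <= 0),
                                 logical(1))),
    provenance = "dualslope::simulate_measurement"),
    class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  g <- grid_of(x$I11)
  cat(sprintf(paste0("<measurement_set> %s, %d wavelengths %g-%g nm, ",
                     "E = %s ms, n_avg = %s%s\n"),
              x$perturbation, length(g), min(g), max(g),
              paste(x$exposures[c("E11", "E12", "E21", "E22")],
                    collapse = "/"),
              paste(x$n_averages, collapse = "/"),
              if (isTRUE(x$negative_values)) " [non-positive counts]"
              else ""))
  invisible(x)
}
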