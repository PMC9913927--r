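#' Write / read a measurement set (CSV + JSON sidecar)
#'
#' The on-disk format is a CSV with columns `wavelength_nm`, `I11`, `I12`,
#' `I21`, `I22` plus a JSON sidecar (same path with extension `.json`)
#' recording exposures, geometry, averaging counts, seed and perturbation
#' label.  The round trip is lossless (full double precision).
#'
#' @param ms a `measurement_set`.
#' @param path CSV path; the sidecar is written next to it.
#' @return invisibly, `path`.
#' @export
write_measurement_set <- function(ms, path) {
  stopifnot(inherits(ms, "measurement_set"))
  g <- unclass(grid_of(ms$I11))
  lines <- c("wavelength_nm,I11,I12,I21,I22",
             sprintf("%.17g,%.17g,%.17g,%.17g,%.17g", g,
                     ms$I11$values, ms$I12$values, ms$I21$values,
                     ms$I22$values))
  writeLines(lines, path)
  side <- list(exposures_ms = as.list(ms$exposures),
               r_S_mm = ms$geometry$r_S, r_L_mm = ms$geometry$r_L,
               n_averages = as.list(ms$n_averages),
               seed = ms$seed, perturbation = ms$perturbation,
               negative_values = ms$negative_values,
               provenance = ms$provenance)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[Cc][Ss][Vv]$", ".json", path)

fmt_err <- function(path, msg) stop(path, ": ", msg, call. = FALSE)

#' @rdname write_measurement_set
#' @param path CSV path written by [write_measurement_set()].
#' @return for `read_measurement_set`, the reconstructed
#'   `measurement_set`.
#' @export
read_measurement_set <- function(path) {
  if (!file.exists(path)) fmt_err(path, "no such file")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) fmt_err(sp, "missing JSON sidecar")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (field in c("exposures_ms", "r_S_mm", "r_L_mm", "n_averages"))
    if (is.null(side[[field]]))
      fmt_err(sp, paste0("sidecar missing field '", field, "'"))
  E <- unlist(side$exposures_ms)
  if (!all(c("E11", "E12", "E21", "E22") %in% names(E)))
    fmt_err(sp, "exposures_ms must name E11, E12, E21, E22")
  if (any(E <= 0)) fmt_err(sp, "exposures must be positive")
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "I11", "I12", "I21", "I22")
  if (!all(need %in% names(tab)))
    fmt_err(path, paste("expected columns", paste(need, collapse = ", ")))
  if (any(diff(tab$wavelength_nm) <= 0))
    fmt_err(path, "wavelengths must be strictly increasing")
  g <- spectral_grid(tab$wavelength_nm)
  geometry <- probe_geometry(r_S = side$r_S_mm, r_L = side$r_L_mm)
  n_avg <- unlist(side$n_averages)
  structure(list(
    I11 = spectrum(tab$I11, g, "counts"),
    I12 = spectrum(tab$I12, g, "counts"),
    I21 = spectrum(tab$I21, g, "counts"),
    I22 = spectrum(tab$I22, g, "counts"),
    exposures = E, geometry = geometry, n_averages = n_avg,
    seed = side$seed,
    perturbation = if (is.null(side$perturbation)) "INIT"
                   else side$perturbation,
    negative_values = isTRUE(side$negative_values),
    provenance = if (is.null(side$provenance)) path else side$provenance),
    class = "measurement_set")
}

#' Write / read an extinction spectrum (CSV + JSON sidecar)
#'
#' CSV columns `wavelength_nm`, `mu_eff_mm-1`, `valid`; the sidecar records
#' the extraction method and source measurement identity.
#'
#' @param ext an `extinction_spectrum`.
#' @param path CSV path.
#' @return invisibly, `path` (write); the `extinction_spectrum` (read).
#' @export
write_extinction <- function(ext, path) {
  stopifnot(inherits(ext, "extinction_spectrum"))
  g <- unclass(grid_of(ext$mu_eff))
  v <- ext$mu_eff$values
  lines <- c("wavelength_nm,mu_eff_mm-1,valid",
             sprintf("%.17g,%s,%d", g,
                     ifelse(ext$valid_mask, sprintf("%.17g", v), "NA"),
                     as.integer(ext$valid_mask)))
  writeLines(lines, path)
  jsonlite::write_json(list(method = ext$method,
                            source_set = ext$source_set),
                       sidecar_path(path), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_extinction
#' @export
read_extinction <- function(path) {
  if (!file.exists(path)) fmt_err(path, "no such file")
  sp <- sidecar_path(path)
  if (!file.exists(sp)) fmt_err(sp, "missing JSON sidecar")
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (is.null(side$method)) fmt_err(sp, "sidecar missing field 'method'")
  tab <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavelength_nm", "mu_eff_mm-1", "valid")
  if (!all(need %in% names(tab)))
    fmt_err(path, paste("expected columns", paste(need, collapse = ", ")))
  g <- spectral_grid(tab$wavelength_nm)
  new_extinction_spectrum(tab$`mu_eff_mm-1`, as.logical(tab$valid), g,
                          side$method,
                          if (is.null(side$source_set)) path
                          else side$source_set)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  jsonlite::write_json(
    list(params = as.list(unclass(fit$params)),
         objective = fit$objective, converged = fit$converged,
         start_index = fit$start_index,
         n_evaluations = fit$n_evaluations,
         method = fit$method),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

run_config_schema <- function() {
  list(
    seed = c("integer"),
    output_dir = c("character"),
    log_level = c("character"),
    grid = list(min_nm = "numeric", max_nm = "numeric",
                step_nm = "numeric"),
    geometry = list(r_S_mm = "numeric", r_L_mm = "numeric"),
    instrument = list(peak_counts = "numeric", dark_level = "numeric",
                      readout_sigma = "numeric",
                      heartbeat_ms = "numeric",
                      detector_imbalance = "numeric"),
    scene = list(preset = "character", C_blood = "numeric",
                 StO2 = "numeric", C_water = "numeric",
                 mua_dry = "numeric", a = "numeric", b = "numeric",
                 f = "numeric", C_mel = "numeric"),
    study = list(perturbations = "character", n_perturbed = "numeric",
                 n_unperturbed = "numeric", methods = "character",
                 noise = "logical", jitter = "numeric", fit = "logical"),
    fit = list(n_starts = "numeric", tolerance = "numeric",
               max_eval = "numeric"))
}

#' Read and validate a study run configuration (YAML or JSON)
#'
#' The file is validated against the published key schema; unknown keys are
#' rejected with the offending path named.  All keys are optional; defaults
#' are the package defaults.
#'
#' @param path YAML (or JSON) configuration file.
#' @return a validated nested list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) fmt_err(path, "no such file")
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  check <- function(node, schema, where) {
    if (!is.list(node)) fmt_err(path, paste0(where, " must be a mapping"))
    extra <- setdiff(names(node), names(schema))
    if (length(extra))
      fmt_err(path, paste0("unknown key", if (length(extra) > 1) "s",
                           " at ", where, ": ",
                           paste(extra, collapse = ", ")))
    for (k in names(node)) {
      if (is.list(schema[[k]])) check(node[[k]], schema[[k]],
                                      paste0(where, k, "."))
    }
  }
  check(cfg, run_config_schema(), "")
  structure(cfg, class = "run_config")
}

# materialize package objects from a run_config (missing keys -> defaults)
build_from_config <- function(cfg) {
  gr <- cfg$grid
  grid <- if (is.null(gr)) default_grid()
          else spectral_grid(seq(gr$min_nm %||% 460, gr$max_nm %||% 1030,
                                 by = gr$step_nm %||% 1))
  geometry <- probe_geometry(
    r_S = cfg$geometry$r_S_mm %||% 2, r_L = cfg$geometry$r_L_mm %||% 4)
  basis <- load_chromophore_basis(grid)
  scene <- if (is.null(cfg$scene) || identical(cfg$scene$preset, "palm"))
    palm_preset()
  else if (identical(cfg$scene$preset, "phantom")) phantom_preset()
  else do.call(tissue_params, cfg$scene[setdiff(names(cfg$scene),
                                                "preset")])
  inst_args <- cfg$instrument
  instrument <- default_instrument(
    grid, basis, geometry, reference_scene = scene,
    peak_counts = inst_args$peak_counts %||% 5e4,
    detector_imbalance = inst_args$detector_imbalance %||% 0.04,
    dark_level = inst_args$dark_level %||% 100,
    readout_sigma = inst_args$readout_sigma %||% 10,
    heartbeat_period = inst_args$heartbeat_ms %||% 1000)
  seed <- cfg$seed %||% 7
  st <- cfg$study
  config <- study_config(
    perturbations = st$perturbations %||% perturbation_labels(),
    n_perturbed = st$n_perturbed %||% 3,
    n_unperturbed = st$n_unperturbed %||% 6,
    methods = st$methods %||% c("S1D1D2", "S2D1D2", "S1S2D1D2"),
    seed = seed, noise = st$noise %||% TRUE,
    jitter = st$jitter %||% 0.01, fit = st$fit %||% TRUE)
  fit_cfg <- fit_config(seed = derive_seed(seed, "fit"),
                        n_starts = cfg$fit$n_starts %||% 5,
                        tolerance = cfg$fit$tolerance %||% 1e-10,
                        max_eval = cfg$fit$max_eval %||% 2000)
  list(grid = grid, geometry = geometry, basis = basis, scene = scene,
       instrument = instrument, study = config, fit_cfg = fit_cfg,
       seed = seed, output_dir = cfg$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
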