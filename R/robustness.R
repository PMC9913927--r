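#' Study configuration for the perturbation robustness experiment
#'
#' Mirrors the measurement protocol of the perturbation study: each
#' perturbation measured `n_perturbed` times (default 3), the unperturbed
#' baseline `n_unperturbed` times (default 6, three before and three after
#' in the original protocol), probe repositioning between repeats emulated
#' by a small seeded multiplicative jitter on `C_blood` and `a`.
#'
#' @param perturbations character vector of perturbation labels (default
#'   the ten cataloged ones, [perturbation_labels()]).
#' @param n_perturbed repeats per perturbation (>= 1, default 3).
#' @param n_unperturbed baseline repeats (>= 2, default 6).
#' @param methods extraction methods to evaluate (subset of `"S1D1D2"`,
#'   `"S2D1D2"`, `"S1S2D1D2"`).
#' @param seed global integer seed; every simulation, jitter and fit seed
#'   is derived from it.
#' @param noise simulate shot/readout noise?
#' @param jitter standard deviation of the log-normal repositioning jitter
#'   applied to `C_blood` and `a` between repeats (default 0.01, i.e. 1%;
#'   set 0 for exactness checks).
#' @param fit fit dual-slope spectra and build the parameter-deviation
#'   report? (default `TRUE`; requires `"S1S2D1D2"` in `methods`).
#' @return an object of class `study_config`.
#' @export
study_config <- function(perturbations = perturbation_labels(),
                         n_perturbed = 3, n_unperturbed = 6,
                         methods = c("S1D1D2", "S2D1D2", "S1S2D1D2"),
                         seed = 7, noise = TRUE, jitter = 0.01,
                         fit = TRUE) {
  stopifnot(n_perturbed >= 1, n_unperturbed >= 2)
  if (!all(methods %in% c("S1D1D2", "S2D1D2", "S1S2D1D2")))
    stop("unknown extraction method in 'methods'")
  if (fit && !"S1S2D1D2" %in% methods)
    stop("fitting requires the S1S2D1D2 method")
  structure(list(perturbations = perturbations,
                 n_perturbed = as.integer(n_perturbed),
                 n_unperturbed = as.integer(n_unperturbed),
                 methods = methods, seed = as.integer(seed),
                 noise = isTRUE(noise), jitter = jitter,
                 fit = isTRUE(fit)),
            class = "study_config")
}

#' Baseline extinction spectrum
#'
#' Pointwise mean of repeated unperturbed extinction spectra of one
#' method, over the intersection of their validity masks (wavelengths
#' masked in any replicate are NA in the baseline).
#'
#' @param unperturbed list of `extinction_spectrum` objects with a common
#'   method tag (>= 2).
#' @return a [spectrum()] in mm^-1 with NA outside the joint mask.
#' @export
baseline_spectrum <- function(unperturbed) {
  if (length(unperturbed) < 2)
    stop("need at least 2 unperturbed spectra")
  methods <- vapply(unperturbed, function(e) e$method, character(1))
  if (length(unique(methods)) != 1)
    stop("mixed extraction methods: ", paste(unique(methods),
                                             collapse = ", "))
  g <- grid_of(unperturbed[[1]]$mu_eff)
  for (e in unperturbed) stopifnot_same_grid(e$mu_eff,
                                             unperturbed[[1]]$mu_eff)
  mask <- Reduce(`&`, lapply(unperturbed, function(e) e$valid_mask))
  vals <- rowMeans(vapply(unperturbed, function(e) e$mu_eff$values,
                          numeric(length(g))))
  vals[!mask] <- NA_real_
  spectrum(vals, g, "mm^-1")
}

#' RMSE deviation of a perturbed extinction spectrum from baseline
#'
#' Root mean square of the pointwise difference over the joint valid mask:
#' \deqn{\Delta\mu_{eff} = \sqrt{\sum_i (\mu^{P}(\lambda_i) -
#'   \mu^{INIT}(\lambda_i))^2 / N_\lambda}.}
#' `N_lambda` counts the jointly valid wavelengths; band edges are not
#' specially trimmed.
#'
#' @param perturbed an `extinction_spectrum`.
#' @param baseline a [spectrum()] as from [baseline_spectrum()].
#' @return scalar deviation in mm^-1.
#' @export
rmse_deviation <- function(perturbed, baseline) {
  stopifnot(inherits(perturbed, "extinction_spectrum"),
            inherits(baseline, "spectrum"))
  stopifnot_same_grid(perturbed$mu_eff, baseline)
  mask <- perturbed$valid_mask & is.finite(baseline$values)
  if (!any(mask)) stop("empty joint valid mask")
  d <- perturbed$mu_eff$values[mask] - baseline$values[mask]
  sqrt(mean(d^2))
}

#' Mean of per-measurement deviations
#'
#' @param devs non-empty numeric vector of RMSE deviations.
#' @return their arithmetic mean.
#' @export
mean_deviation <- function(devs) {
  if (length(devs) == 0) stop("no deviations to average")
  mean(devs)
}

jitter_params <- function(params, seed, jitter) {
  if (jitter <= 0) return(params)
  set.seed(seed)
  fac <- exp(stats::rnorm(2, 0, jitter))
  p <- unclass(params)
  p[["C_blood"]] <- min(1, p[["C_blood"]] * fac[1])
  p[["a"]] <- min(param_bounds()["a", "upper"], p[["a"]] * fac[2])
  do.call(tissue_params, as.list(p))
}

#' Relative parameter deviations under perturbation
#'
#' For each reported parameter (`C_blood`, `StO2`, `C_water`, `a`, `f`;
#' the Mie index `b` is excluded because its baseline sits at the boundary
#' near zero and relative deviations would blow up), computes
#' `|x_P,m - x_INIT| / x_INIT` for every perturbed fit and averages over
#' repeats and over the perturbations of each class (source vs detector).
#' Parameters whose baseline magnitude is below 1e-6 are flagged and
#' excluded rather than reported.
#'
#' @param fits_perturbed named list: one entry per perturbation label, each
#'   a list of `fit_result` repeats.
#' @param fits_baseline list of `fit_result` objects from unperturbed
#'   spectra; the reference value per parameter is their mean.
#' @param grouping named character vector mapping perturbation label to
#'   class; by default labels starting with "D" are `"detector"` and with
#'   "S" `"source"`.
#' @param parameters parameters to report.
#' @return an object of class `param_deviation_report`: `cells` (class x
#'   parameter mean relative deviations), `detail` (per perturbation and
#'   repeat), `baseline` (reference parameter means) and `excluded`.
#' @export
relative_param_deviations <- function(fits_perturbed, fits_baseline,
                                      grouping = NULL,
                                      parameters = c("C_blood", "StO2",
                                                     "C_water", "a",
                                                     "f")) {
  if (is.null(grouping)) {
    grouping <- ifelse(startsWith(names(fits_perturbed), "D"),
                       "detector", "source")
    names(grouping) <- names(fits_perturbed)
  }
  base_mat <- vapply(fits_baseline,
                     function(f) unclass(f$params)[parameters],
                     numeric(length(parameters)))
  baseline <- rowMeans(matrix(base_mat, nrow = length(parameters),
                              dimnames = list(parameters, NULL)))
  excluded <- parameters[abs(baseline) < 1e-6]
  kept <- setdiff(parameters, excluded)
  detail <- do.call(rbind, lapply(names(fits_perturbed), function(P) {
    do.call(rbind, lapply(seq_along(fits_perturbed[[P]]), function(m) {
      x <- unclass(fits_perturbed[[P]][[m]]$params)[kept]
      data.frame(perturbation = P, class = grouping[[P]], rep = m,
                 parameter = kept,
                 rel_dev = abs(x - baseline[kept]) / abs(baseline[kept]),
                 row.names = NULL)
    }))
  }))
  cells <- stats::aggregate(rel_dev ~ class + parameter, data = detail,
                            FUN = mean)
  names(cells)[names(cells) == "rel_dev"] <- "mean_rel_dev"
  structure(list(cells = cells, detail = detail, baseline = baseline,
                 excluded = excluded),
            class = "param_deviation_report")
}

#' @export
print.param_deviation_report <- function(x, ...) {
  cat("<param_deviation_report> mean |x - x_INIT| / x_INIT by class:\n")
  print(x$cells, row.names = FALSE)
  if (length(x$excluded))
    cat("excluded (near-zero baseline):",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Run the full perturbation robustness study
#'
#' Simulates `n_unperturbed` baseline measurement sets and `n_perturbed`
#' repeats for each perturbation (fresh derived seed and repositioning
#' jitter per repeat), extracts extinction spectra with every requested
#' method, computes per-perturbation RMSE deviations from the per-method
#' baselines, and -- when `config$fit` -- fits each dual-slope spectrum
#' and assembles the relative parameter deviation report.  Fully
#' reproducible from `(config, seed)`.
#'
#' @param config a [study_config()].
#' @param scene generating [tissue_params()] (default [palm_preset()]).
#' @param instrument an [instrument_model()]; default
#'   [default_instrument()] on the basis grid.
#' @param geometry a [probe_geometry()].
#' @param basis a `chromophore_basis`.
#' @param fit_cfg a [fit_config()]; its seed defaults to one derived from
#'   the study seed.
#' @return an object of class `study_result`: `deviation` (a
#'   `deviation_report` with per-measurement deviations, per-perturbation
#'   means and baselines) and `params` (a `param_deviation_report`, or NULL
#'   when fitting is off).
#' @export
run_study <- function(config = study_config(), scene = palm_preset(),
                      instrument = NULL, geometry = probe_geometry(),
                      basis = load_chromophore_basis(),
                      fit_cfg = fit_config(
                        seed = derive_seed(config$seed, "fit"))) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(instrument))
    instrument <- default_instrument(grid_of(basis$mua_oxy), basis,
                                     geometry)
  simulate_one <- function(label, m, perts) {
    sc <- jitter_params(scene, derive_seed(config$seed, "jitter", label, m),
                        config$jitter)
    simulate_measurement(sc, basis, instrument, geometry,
                         perturbations = perts, noise = config$noise,
                         seed = derive_seed(config$seed, label, m))
  }

  # baselines
  base_ext <- lapply(config$methods, function(mth) vector("list", 0))
  names(base_ext) <- config$methods
  base_sets <- lapply(seq_len(config$n_unperturbed), function(i)
    simulate_one("INIT", i, list()))
  for (mth in config$methods)
    base_ext[[mth]] <- lapply(base_sets, extract_extinction, method = mth)
  baselines <- lapply(base_ext, baseline_spectrum)

  rows <- list()
  pert_ext_dual <- list()
  for (P in config$perturbations) {
    pert <- make_perturbation(P, grid_of(basis$mua_oxy),
                              geometry = geometry)
    pert_ext_dual[[P]] <- vector("list", config$n_perturbed)
    for (m in seq_len(config$n_perturbed)) {
      ms <- simulate_one(P, m, list(pert))
      for (mth in config$methods) {
        ext <- extract_extinction(ms, mth)
        if (mth == "S1S2D1D2") pert_ext_dual[[P]][[m]] <- ext
        rows[[length(rows) + 1]] <- data.frame(
          method = mth, perturbation = P, rep = m,
          delta_mu_eff = rmse_deviation(ext, baselines[[mth]]))
      }
    }
  }
  deviations <- do.call(rbind, rows)
  summary <- stats::aggregate(delta_mu_eff ~ method + perturbation,
                              data = deviations, FUN = mean_deviation)
  names(summary)[names(summary) == "delta_mu_eff"] <- "mean_delta_mu_eff"
  sds <- stats::aggregate(delta_mu_eff ~ method + perturbation,
                          data = deviations, FUN = stats::sd)
  summary$sd_delta_mu_eff <- sds$delta_mu_eff[
    match(paste(summary$method, summary$perturbation),
          paste(sds$method, sds$perturbation))]
  deviation_report <- structure(
    list(deviations = deviations, summary = summary,
         baselines = baselines),
    class = "deviation_report")

  params_report <- NULL
  if (config$fit) {
    fits_base <- lapply(base_ext[["S1S2D1D2"]], fit_extinction,
                        basis = basis, config = fit_cfg)
    fits_pert <- lapply(pert_ext_dual, function(exts)
      lapply(exts, fit_extinction, basis = basis, config = fit_cfg))
    params_report <- relative_param_deviations(fits_pert, fits_base)
  }
  structure(list(deviation = deviation_report, params = params_report,
                 config = config),
            class = "study_result")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("<deviation_report> mean RMSE deviation (mm^-1) by perturbation:\n")
  wide <- stats::reshape(
    x$summary[c("method", "perturbation", "mean_delta_mu_eff")],
    idvar = "perturbation", timevar = "method", direction = "wide")
  names(wide) <- sub("^mean_delta_mu_eff\\.", "", names(wide))
  print(wide, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.study_result <- function(x, ...) {
  print(x$deviation)
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Bar chart of extinction deviations by perturbation and method
#'
#' @param x a `deviation_report` (or `study_result`).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted matrix.
#' @export
plot_deviation_report <- function(x, ...) {
  if (inherits(x, "study_result")) x <- x$deviation
  s <- x$summary
  methods <- sort(unique(s$method))
  perts <- unique(s$perturbation)
  m <- vapply(perts, function(P)
    vapply(methods, function(mt)
      s$mean_delta_mu_eff[s$method == mt & s$perturbation == P][1],
      numeric(1)),
    numeric(length(methods)))
  graphics::barplot(m, beside = TRUE, names.arg = perts,
                    legend.text = methods,
                    ylab = expression(Delta * mu[eff] ~ (mm^-1)), ...)
  invisible(m)
}
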