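#' Fit configuration
#'
#' Settings for the bounded least-squares inversion of an extinction
#' spectrum: box bounds, initial guess, frozen parameters, multi-start
#' count, wavelength window and convergence tolerance.
#'
#' The default initial guess sits at physiological midpoints
#' (`C_blood` 0.01, `StO2` 0.7, `C_water` 0.5, `mua_dry` 0.01 mm^-1,
#' `a` 2 mm^-1, `b` 1, `f` 0.2); additional starts are seeded uniform draws
#' inside the bounds to mitigate local minima of the non-convex objective.
#' `C_mel` is frozen at 0.005 by default: melanin absorption and reduced
#' scattering both decrease monotonically with wavelength, so their joint
#' reconstruction is ill-posed.
#'
#' @param bounds matrix as from [param_bounds()].
#' @param initial_guess a [tissue_params()] within bounds.
#' @param fixed character vector of frozen parameters (default `"C_mel"`;
#'   only `C_mel` freezing is supported).
#' @param n_starts number of optimizer starts (>= 1, default 5).
#' @param seed integer seed for the start draws.
#' @param fit_range wavelength window in nm (default c(460, 1030)).
#' @param tolerance objective convergence tolerance (default 1e-10).
#' @param max_eval maximum residual evaluations per start (default 2000).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(bounds = param_bounds(),
                       initial_guess = tissue_params(
                         C_blood = 0.01, StO2 = 0.7, C_water = 0.5,
                         mua_dry = 0.01, a = 2, b = 1, f = 0.2),
                       fixed = "C_mel", n_starts = 5, seed = 1,
                       fit_range = c(460, 1030), tolerance = 1e-10,
                       max_eval = 2000) {
  stopifnot(inherits(initial_guess, "tissue_params"), n_starts >= 1)
  if (!identical(fixed, "C_mel"))
    stop("only C_mel may be frozen in this release")
  structure(list(bounds = bounds, initial_guess = initial_guess,
                 fixed = fixed, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), fit_range = fit_range,
                 tolerance = tolerance, max_eval = as.integer(max_eval)),
            class = "fit_config")
}

free_param_names <- function() {
  c("C_blood", "StO2", "C_water", "mua_dry", "a", "b", "f")
}

# fast forward model on precomputed basis columns
model_mueff_values <- function(th, W, M, O, D, rel) {
  mua <- th[["C_water"]] * W + th[["C_mel"]] * M +
    th[["C_blood"]] * (th[["StO2"]] * O + (1 - th[["StO2"]]) * D) +
    th[["mua_dry"]]
  musp <- th[["a"]] * (th[["f"]] * rel^(-4) +
                         (1 - th[["f"]]) * rel^(-th[["b"]]))
  sqrt(3 * mua * (mua + musp))
}

#' Invert an extinction spectrum into tissue parameters
#'
#' Minimizes the unweighted sum of squared differences between the forward
#' model [model_extinction()] and the measured extinction spectrum over the
#' valid wavelengths in the fit window, subject to the parameter box, with
#' `C_mel` frozen.  Bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]) is run from `n_starts` seeded starts and the
#' lowest objective wins.  Masked wavelengths are dropped from the sum, not
#' interpolated.  Non-convergence on every start yields a flagged result,
#' not an error.
#'
#' @param ext an `extinction_spectrum` with at least 50 valid wavelengths
#'   in the fit window.
#' @param basis a `chromophore_basis` covering the extinction grid.
#' @param config a [fit_config()].
#' @return an object of class `fit_result`: `params` ([tissue_params()]),
#'   `objective` (sum of squared residuals, mm^-2), `model_spectrum` (on
#'   the fitted wavelengths), `n_evaluations`, `converged`, `start_index`.
#' @export
fit_extinction <- function(ext, basis, config = fit_config()) {
  stopifnot(inherits(ext, "extinction_spectrum"),
            inherits(basis, "chromophore_basis"),
            inherits(config, "fit_config"))
  g <- unclass(grid_of(ext$mu_eff))
  use <- ext$valid_mask & g >= config$fit_range[1] &
    g <= config$fit_range[2]
  if (sum(use) < 50)
    stop("only ", sum(use), " valid wavelengths in the fit window; ",
         "need at least 50")
  gb <- unclass(grid_of(basis$mua_oxy))
  idx <- match(g[use], gb)
  if (anyNA(idx)) stop("basis grid does not cover the extinction grid")
  W <- basis$mua_water$values[idx]; M <- basis$mua_mel$values[idx]
  O <- basis$mua_oxy$values[idx]; D <- basis$mua_deoxy$values[idx]
  rel <- g[use] / lambda0()
  y <- ext$mu_eff$values[use]
  C_mel <- config$initial_guess[["C_mel"]]

  nms <- free_param_names()
  lower <- config$bounds[nms, "lower"]
  upper <- config$bounds[nms, "upper"]
  width <- upper - lower
  # Two-stage optimization in box-normalized coordinates (the raw
  # parameters span three orders of magnitude).  Stage 1 runs LM on a
  # logit reparameterization, which enforces the box smoothly and avoids
  # the stalls that hard clamping produces at active bounds; stage 2
  # polishes with box-clamped LM so parameters can land exactly on a
  # bound.
  to_unit <- function(par) (par - lower) / width
  from_unit <- function(u) lower + u * width
  n_eval <- 0L
  resid_unit <- function(u) {
    n_eval <<- n_eval + 1L
    th <- c(as.list(from_unit(u)), C_mel = C_mel)
    model_mueff_values(th, W, M, O, D, rel) - y
  }
  resid_logit <- function(v) resid_unit(stats::plogis(v))
  objective_at <- function(u) sum(resid_unit(u)^2)
  ctrl <- minpack.lm::nls.lm.control(
    ftol = config$tolerance, ptol = 1e-12,
    maxfev = config$max_eval, maxiter = 500)

  starts <- list(to_unit(unclass(config$initial_guess)[nms]))
  if (config$n_starts > 1) {
    for (i in seq_len(config$n_starts - 1)) {
      set.seed(derive_seed(config$seed, "fit-start", i))
      starts[[i + 1]] <- stats::setNames(stats::runif(length(nms)), nms)
    }
  }

  best <- NULL
  for (i in seq_along(starts)) {
    u <- pmin(pmax(starts[[i]], 1e-9), 1 - 1e-9)
    s1 <- tryCatch(
      minpack.lm::nls.lm(par = stats::qlogis(u), fn = resid_logit,
                         control = ctrl),
      error = function(e) NULL)
    u1 <- if (is.null(s1)) u else stats::plogis(coef(s1))
    s2 <- tryCatch(
      minpack.lm::nls.lm(par = u1, lower = rep(0, length(nms)),
                         upper = rep(1, length(nms)), fn = resid_unit,
                         control = ctrl),
      error = function(e) NULL)
    cand <- list()
    if (!is.null(s1)) cand <- c(cand, list(list(
      u = stats::plogis(coef(s1)), obj = s1$deviance,
      conv = s1$info %in% 1:4)))
    if (!is.null(s2)) cand <- c(cand, list(list(
      u = pmin(pmax(coef(s2), 0), 1), obj = s2$deviance,
      conv = s2$info %in% 1:4)))
    for (cd in cand) {
      if (is.null(best) || cd$obj < best$objective)
        best <- list(par = stats::setNames(from_unit(cd$u), nms),
                     objective = cd$obj, converged = cd$conv,
                     start_index = i)
    }
  }
  if (is.null(best)) {  # every start failed outright: flag, don't throw
    u0 <- starts[[1]]
    best <- list(par = stats::setNames(from_unit(u0), nms),
                 objective = objective_at(u0),
                 converged = FALSE, start_index = 1L)
  }
  params <- do.call(tissue_params, c(as.list(best$par), list(C_mel = C_mel)))
  model_vals <- model_mueff_values(c(as.list(best$par), C_mel = C_mel),
                                   W, M, O, D, rel)
  structure(list(params = params, objective = best$objective,
                 model_spectrum = spectrum(model_vals,
                                           spectral_grid(g[use]), "mm^-1"),
                 n_evaluations = n_eval, converged = best$converged,
                 start_index = best$start_index,
                 method = ext$method),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result> %s: objective %.4g mm^-2, %s, ",
                     "start %d, %d evaluations\n"),
              if (is.null(x$method)) "fit" else x$method, x$objective,
              if (x$converged) "converged" else "NOT converged",
              x$start_index, x$n_evaluations))
  print(x$params)
  invisible(x)
}
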