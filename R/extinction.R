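new_extinction_spectrum <- function(values, valid, grid, method, source_set) {
  values[!valid] <- NA_real_
  structure(list(mu_eff = spectrum(ifelse(valid, values, NA_real_), grid,
                                   "mm^-1"),
                 method = method, valid_mask = valid,
                 source_set = source_set),
            class = "extinction_spectrum")
}

#' @export
print.extinction_spectrum <- function(x, ...) {
  g <- grid_of(x$mu_eff)
  cat(sprintf("<extinction_spectrum> %s, %d/%d valid wavelengths, %g-%g nm\n",
              x$method, sum(x$valid_mask), length(g), min(g), max(g)))
  invisible(x)
}

slope_scale <- function(geometry) 1 / (geometry$r_L - geometry$r_S)

check_symmetric <- function(ms) {
  if (!inherits(ms, "measurement_set")) stop("expected a measurement_set")
  if (!inherits(ms$geometry, "probe_geometry"))
    stop("measurement set lacks a symmetric probe geometry")
  invisible(TRUE)
}

#' Single-slope extinction extraction
#'
#' Estimates the effective extinction spectrum from the ratio of the two
#' spectra sharing one source at the two source-detector distances,
#' corrected for exposure times and geometry:
#' \deqn{\mu_{eff} = \frac{1}{r_L - r_S}
#'   \ln\!\left(\frac{I_{11}}{I_{12}}\frac{E_{12}}{E_{11}}
#'   \frac{r_S}{r_L}\right)}
#' for source 1 (method tag `S1D1D2`), and the analogous `I22/I21` ratio
#' for source 2 (`S2D1D2`).  The ratio cancels the source transfer chain
#' and spectrometer sensitivity but *not* a difference between the two
#' detector transients: the formula silently assumes they are equal, which
#' is exactly the assumption the dual-slope scheme removes.
#'
#' Wavelengths where the log argument is non-positive (possible after noisy
#' dark subtraction) are masked out; with `strict = TRUE` they raise an
#' error instead.
#'
#' @param ms a [simulate_measurement()] result or loaded measurement set.
#' @param source which source fiber, 1 or 2.
#' @param strict error on non-positive ratio arguments instead of masking.
#' @return an `extinction_spectrum` with a per-wavelength validity mask.
#' @export
single_slope <- function(ms, source = 1, strict = FALSE) {
  check_symmetric(ms)
  if (!source %in% c(1, 2)) stop("source must be 1 or 2")
  rS <- ms$geometry$r_S; rL <- ms$geometry$r_L
  E <- ms$exposures
  if (source == 1) {
    arg <- (ms$I11$values / ms$I12$values) * (E[["E12"]] / E[["E11"]]) *
      (rS / rL)
    method <- "S1D1D2"
  } else {
    arg <- (ms$I22$values / ms$I21$values) * (E[["E21"]] / E[["E22"]]) *
      (rS / rL)
    method <- "S2D1D2"
  }
  valid <- is.finite(arg) & arg > 0
  if (strict && !all(valid))
    stop("non-positive intensity ratio at ", sum(!valid), " wavelengths")
  mu <- rep(NA_real_, length(arg))
  mu[valid] <- log(arg[valid]) * slope_scale(ms$geometry)
  new_extinction_spectrum(mu, valid, grid_of(ms$I11), method,
                          ms$perturbation)
}

#' Self-calibrating (dual-slope) extinction extraction
#'
#' Combines all four source-detector measurements into the symmetric ratio
#' \deqn{\mu_{eff} = \frac{1}{2(r_L - r_S)}
#'   \ln\!\left(\frac{I_{11} I_{22}}{I_{12} I_{21}}
#'   \frac{E_{12} E_{21}}{E_{11} E_{22}}
#'   \frac{r_S^2}{r_L^2}\right)}
#' in which every per-channel multiplicative transfer characteristic --
#' source and detector alike -- cancels exactly.  Algebraically this is the
#' mean of the two single-slope estimates (method tag `S1S2D1D2`).
#'
#' @inheritParams single_slope
#' @return an `extinction_spectrum`.
#' @export
dual_slope <- function(ms, strict = FALSE) {
  check_symmetric(ms)
  rS <- ms$geometry$r_S; rL <- ms$geometry$r_L
  E <- ms$exposures
  arg <- (ms$I11$values * ms$I22$values) /
    (ms$I12$values * ms$I21$values) *
    (E[["E12"]] * E[["E21"]]) / (E[["E11"]] * E[["E22"]]) *
    (rS^2 / rL^2)
  valid <- is.finite(arg) & arg > 0
  if (strict && !all(valid))
    stop("non-positive intensity ratio at ", sum(!valid), " wavelengths")
  mu <- rep(NA_real_, length(arg))
  mu[valid] <- log(arg[valid]) * slope_scale(ms$geometry) / 2
  new_extinction_spectrum(mu, valid, grid_of(ms$I11), "S1S2D1D2",
                          ms$perturbation)
}

#' Extract extinction by method tag
#'
#' Dispatch helper mapping the method tags `"S1D1D2"`, `"S2D1D2"`,
#' `"S1S2D1D2"` to [single_slope()] / [dual_slope()].
#'
#' @inheritParams single_slope
#' @param method one of the three method tags.
#' @return an `extinction_spectrum`.
#' @export
extract_extinction <- function(ms, method, strict = FALSE) {
  switch(method,
         S1D1D2 = single_slope(ms, 1, strict),
         S2D1D2 = single_slope(ms, 2, strict),
         S1S2D1D2 = dual_slope(ms, strict),
         stop("unknown extraction method '", method, "'"))
}
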