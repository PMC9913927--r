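#' Wavelength grids
#'
#' A `spectral_grid` is a strictly increasing vector of wavelengths in
#' nanometers, restricted to the 380--1100 nm span over which the embedded
#' chromophore tables and instrument curves are meaningful.  It is the common
#' index of every spectral quantity in the package; arithmetic between
#' [spectrum()] objects is only defined on identical grids.
#'
#' @param wavelengths numeric vector of wavelengths in nm, strictly
#'   increasing, all within \[380, 1100\].
#' @return an object of class `spectral_grid` (a classed numeric vector).
#' @seealso [default_grid()] for the working grid of the instrument.
#' @export
#' @examples
#' g <- spectral_grid(seq(500, 600, by = 1))
#' length(g)
spectral_grid <- function(wavelengths) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1 || anyNA(wavelengths))
    stop("wavelengths must be a non-empty numeric vector without NA")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (min(wavelengths) < 380 || max(wavelengths) > 1100)
    stop("wavelengths must lie within [380, 1100] nm")
  structure(wavelengths, class = "spectral_grid")
}

#' Default working grid: 460--1030 nm at 1 nm steps
#'
#' The working band of the broadband VIS-NIR instrument: the short-wavelength
#' edge is set by tissue attenuation, the long-wavelength edge by detector
#' sensitivity.  1 nm resolves all chromophore peaks used for validation.
#'
#' @return a [spectral_grid()] of 571 wavelengths.
#' @export
default_grid <- function() spectral_grid(seq(460, 1030, by = 1))

#' @export
print.spectral_grid <- function(x, ...) {
  cat(sprintf("<spectral_grid> %d wavelengths, %g-%g nm\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Wavelength-indexed spectra
#'
#' A `spectrum` couples a vector of values to a [spectral_grid()] and a unit
#' tag.  All physical quantities in the package (absorption, reduced
#' scattering, extinction, detected counts, transfer functions) are spectra.
#'
#' @param values numeric vector, one value per grid wavelength.
#' @param grid a [spectral_grid()].
#' @param units non-empty unit tag, e.g. `"mm^-1"`, `"counts"`,
#'   `"dimensionless"`.
#' @return an object of class `spectrum`.
#' @export
#' @examples
#' g <- default_grid()
#' s <- spectrum(rep(1, length(g)), g, "dimensionless")
spectrum <- function(values, grid, units) {
  if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
  values <- as.numeric(values)
  if (length(values) != length(grid))
    stop("values length (", length(values), ") must equal grid length (",
         length(grid), ")")
  if (!is.character(units) || length(units) != 1 || !nzchar(units))
    stop("units must be a non-empty string")
  structure(list(grid = grid, values = values, units = units),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> [%s] %d wavelengths, %g-%g nm, range %.4g..%.4g\n",
              x$units, length(x$grid), min(x$grid), max(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.spectrum <- function(x) length(x$values)

#' Grid of a spectral object
#' @param x a `spectrum` or an object carrying one.
#' @return the [spectral_grid()].
#' @export
grid_of <- function(x) {
  if (inherits(x, "spectrum")) return(x$grid)
  if (inherits(x, "spectral_grid")) return(x)
  stop("no spectral grid in object of class ", paste(class(x), collapse = "/"))
}

same_grid <- function(a, b) {
  ga <- grid_of(a); gb <- grid_of(b)
  length(ga) == length(gb) && all(unclass(ga) == unclass(gb))
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) stop("spectra are defined on different grids")
  invisible(TRUE)
}

#' @export
Ops.spectrum <- function(e1, e2) {
  if (!.Generic %in% c("+", "-", "*", "/"))
    stop("operation '", .Generic, "' not defined for spectra")
  if (inherits(e1, "spectrum") && inherits(e2, "spectrum")) {
    stopifnot_same_grid(e1, e2)
    u <- if (.Generic %in% c("*", "/")) {
      if (e1$units == e2$units && .Generic == "/") "dimensionless"
      else paste0(e1$units, .Generic, e2$units)
    } else {
      if (e1$units != e2$units)
        stop("cannot ", .Generic, " spectra with units '", e1$units,
             "' and '", e2$units, "'")
      e1$units
    }
    spectrum(get(.Generic)(e1$values, e2$values), e1$grid, u)
  } else if (inherits(e1, "spectrum")) {
    spectrum(get(.Generic)(e1$values, as.numeric(e2)), e1$grid, e1$units)
  } else {
    spectrum(get(.Generic)(as.numeric(e1), e2$values), e2$grid, e2$units)
  }
}

#' Restrict a spectrum to a wavelength window
#'
#' @param x a [spectrum()].
#' @param lo,hi window bounds in nm (inclusive).
#' @return a spectrum on the sub-grid.
#' @export
clip_spectrum <- function(x, lo, hi) {
  keep <- unclass(x$grid) >= lo & unclass(x$grid) <= hi
  if (!any(keep)) stop("window [", lo, ", ", hi, "] contains no grid point")
  spectrum(x$values[keep], spectral_grid(unclass(x$grid)[keep]), x$units)
}

#' Linear interpolation of a tabulated spectrum onto a grid
#'
#' Extrapolation is forbidden: the target grid must lie within the span of
#' the table.
#'
#' @param wavelength_nm,values table columns.
#' @param grid target [spectral_grid()].
#' @param units unit tag for the result.
#' @return a [spectrum()] on `grid`.
#' @export
interpolate_to_grid <- function(wavelength_nm, values, grid, units) {
  if (!inherits(grid, "spectral_grid")) grid <- spectral_grid(grid)
  if (min(grid) < min(wavelength_nm) || max(grid) > max(wavelength_nm))
    stop("grid [", min(grid), ", ", max(grid),
         "] nm extends beyond the tabulated span [",
         min(wavelength_nm), ", ", max(wavelength_nm), "] nm")
  v <- stats::approx(wavelength_nm, values, xout = unclass(grid),
                     method = "linear", ties = "ordered")$y
  spectrum(v, grid, units)
}
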