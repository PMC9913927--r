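#' Tissue parameter vector
#'
#' The seven free parameters of the skin absorption/scattering model, plus
#' the fixed melanin fraction.  Absorption is a weighted sum of chromophore
#' spectra (blood split by oxygen saturation, water, melanin, flat "dry
#' matter"); reduced scattering follows the two-term Rayleigh + Mie power
#' law referenced to 500 nm.
#'
#' @param C_blood whole-blood volume fraction, in \[0, 1\].
#' @param StO2 hemoglobin oxygen saturation, in \[0, 1\].
#' @param C_water water volume fraction, in \[0, 1\].
#' @param mua_dry wavelength-independent "dry matter" absorption, mm^-1,
#'   non-negative (capped at 10 mm^-1 for the fitting box).
#' @param a reduced scattering at the 500 nm reference wavelength, mm^-1,
#'   in \[0.5, 10\].
#' @param b Mie power index, in \[0, 3\].
#' @param f Rayleigh fraction, in \[0, 1\].
#' @param C_mel melanosome volume fraction; fixed at 0.005 by convention
#'   (absolute melanin content is not separately identifiable from a
#'   monotone scattering background).
#' @return an object of class `tissue_params` (named numeric vector).
#' @export
#' @examples
#' palm_preset()
tissue_params <- function(C_blood, StO2, C_water, mua_dry, a, b, f,
                          C_mel = 0.005) {
  p <- c(C_blood = C_blood, StO2 = StO2, C_water = C_water,
         mua_dry = mua_dry, a = a, b = b, f = f, C_mel = C_mel)
  if (anyNA(p) || !is.numeric(p)) stop("tissue parameters must be numeric")
  bounds <- param_bounds()
  for (nm in rownames(bounds)) {
    if (p[[nm]] < bounds[nm, "lower"] - 1e-12 ||
        p[[nm]] > bounds[nm, "upper"] + 1e-12)
      stop(nm, " = ", p[[nm]], " outside bounds [", bounds[nm, "lower"],
           ", ", bounds[nm, "upper"], "]")
  }
  if (C_mel < 0 || C_mel > 1) stop("C_mel must be in [0, 1]")
  structure(p, class = "tissue_params")
}

#' Box bounds of the tissue parameters
#'
#' Fractions and saturations live in \[0, 1\]; the reduced-scattering
#' amplitude `a` in \[0.5, 10\] mm^-1 and Mie index `b` in \[0, 3\] per the
#' reported physiological skin ranges; the nominally unbounded dry-matter
#' absorption is capped at 10 mm^-1 (far above any physiological value) so
#' the optimizer has a finite box.
#'
#' @return a matrix with rownames the seven free parameters and columns
#'   `lower`, `upper`.
#' @export
param_bounds <- function() {
  m <- rbind(C_blood = c(0, 1), StO2 = c(0, 1), C_water = c(0, 1),
             mua_dry = c(0, 10), a = c(0.5, 10), b = c(0, 3), f = c(0, 1))
  colnames(m) <- c("lower", "upper")
  m
}

#' @export
print.tissue_params <- function(x, ...) {
  cat("<tissue_params>\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Reference wavelength of the scattering power law (nm)
#' @export
lambda0 <- function() 500

#' Human-palm tissue preset
#'
#' Representative healthy palm skin: oxygen saturation about 0.8, blood and
#' water volume fractions about 0.002 and 0.4.  The scattering parameters
#' and dry-matter absorption (not separately reported) are set to
#' `a` = 2 mm^-1, `b` = 0.5, `f` = 0.15, `mua_dry` = 0.015 mm^-1, which give
#' effective extinction of order 2 mm^-1 at 460 nm falling to about
#' 0.6 mm^-1 in the NIR window, as observed on palm skin.
#'
#' @return a [tissue_params()].
#' @export
palm_preset <- function() {
  tissue_params(C_blood = 0.002, StO2 = 0.8, C_water = 0.4,
                mua_dry = 0.015, a = 2.0, b = 0.5, f = 0.15, C_mel = 0.005)
}

#' Homogeneous phantom preset
#'
#' A blood-free, water-free, melanin-free flat absorber emulating a silicone
#' calibration phantom: `mua_dry` = 0.02 mm^-1 with `a` = 1.5 mm^-1,
#' `b` = 1, `f` = 0 scattering.  A documented stand-in: the phantom's actual
#' optical properties are not published.  `StO2` is physically meaningless
#' when `C_blood` = 0 and is carried as 0 with a `"StO2_irrelevant"`
#' attribute.
#'
#' @return a [tissue_params()] with attribute `StO2_irrelevant = TRUE`.
#' @export
phantom_preset <- function() {
  p <- tissue_params(C_blood = 0, StO2 = 0, C_water = 0,
                     mua_dry = 0.02, a = 1.5, b = 1.0, f = 0, C_mel = 0)
  attr(p, "StO2_irrelevant") <- TRUE
  p
}
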