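#' Acoustic medium properties
#'
#' Container for the scalar properties of a homogeneous fluid medium.
#' Internally the package works in millimetres and megahertz; `medium_props`
#' stores SI values (m/s, kg/m^3) and the helpers [wavelength_mm()] and
#' [wavenumber_mm()] do the unit conversion at the formula boundary.
#'
#' @param c Sound speed (m/s).
#' @param rho Density (kg/m^3).
#' @param alpha Attenuation coefficient (Np m^-1 MHz^-1). Defaults to 0,
#'   appropriate for degassed water over centimetre paths.
#' @return An object of class `medium_props`.
#' @examples
#' m <- water_medium()
#' wavelength_mm(m, 4.5)   # ~0.333 mm at 4.5 MHz
#' @export
medium_props <- function(c, rho, alpha = 0) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c), c > 0)
  stopifnot(is.numeric(rho), length(rho) == 1L, is.finite(rho), rho > 0)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha), alpha >= 0)
  structure(list(c = c, rho = rho, alpha = alpha), class = "medium_props")
}

#' @rdname medium_props
#' @export
water_medium <- function() medium_props(c = 1500, rho = 1000, alpha = 0)

#' @rdname medium_props
#' @param medium A `medium_props` object.
#' @param f Frequency (MHz).
#' @export
wavelength_mm <- function(medium, f) {
  stopifnot(inherits(medium, "medium_props"), is.numeric(f), f > 0)
  medium$c / (f * 1000)
}

#' @rdname medium_props
#' @export
wavenumber_mm <- function(medium, f) 2 * pi / wavelength_mm(medium, f)

#' @export
print.medium_props <- function(x, ...) {
  cat(sprintf("<medium_props> c = %g m/s, rho = %g kg/m^3, alpha = %g Np/m/MHz\n",
              x$c, x$rho, x$alpha))
  invisible(x)
}

#' Attenuation unit conversion
#'
#' Convert attenuation coefficients between dB cm^-1 MHz^-1 (the unit most
#' tissue tables use) and Np m^-1 MHz^-1 (the unit used internally).
#' 1 Np = 20/log(10) dB (~8.6859 dB) and 1 m = 100 cm.
#'
#' @param x Attenuation value(s) to convert.
#' @return Converted value(s).
#' @export
db_cm_to_np_m <- function(x) x / (20 / log(10)) * 100

#' @rdname db_cm_to_np_m
#' @export
np_m_to_db_cm <- function(x) x * (20 / log(10)) / 100
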