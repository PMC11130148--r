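#' Angular spectrum of a pressure plane
#'
#' Decomposes a sampled pressure plane into plane waves: the discrete analogue
#' of P(kx, ky, z) = integral of p(x, y, z) exp(-j(kx x + ky y)) dx dy, with the
#' analysis kernel's sign fixed so that forward propagation multiplies by
#' exp(+j z kz). The returned spectrum is scaled by dx*dy to approximate the
#' continuous transform and is laid out on a centered conjugate grid with
#' spacing dk = 2*pi/(n*d) per axis. Satisfies the Parseval relation
#' sum |p|^2 dx dy = sum |P|^2 dkx dky / (2 pi)^2.
#'
#' @param field A [complex_field()].
#' @return List with `kx`, `ky` (centered, rad/mm) and complex matrix `P`.
#' @seealso [propagate()], [backpropagate()]
#' @export
angular_spectrum <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  g <- field$grid
  # centered coordinates <-> FFT origin: shift before and after the transform
  P <- fftshift2(stats::fft(ifftshift2(field$values))) * (g$dx * g$dy)
  kx <- fftshift_vec(grid_kvec(g$nx, g$dx))
  ky <- fftshift_vec(grid_kvec(g$ny, g$dy))
  list(kx = kx, ky = ky, P = P)
}

#' Inverse of [angular_spectrum()]
#'
#' @param spec List as returned by [angular_spectrum()].
#' @param grid The `grid_2d` of the original plane.
#' @param z,f Plane depth (mm) and frequency (MHz) for the reconstructed field.
#' @return A [complex_field()].
#' @export
inverse_angular_spectrum <- function(spec, grid, z, f) {
  v <- fftshift2(stats::fft(ifftshift2(spec$P), inverse = TRUE)) /
    (grid$nx * grid$ny * grid$dx * grid$dy)
  complex_field(grid, v, z = z, f = f)
}

# fftshift helpers (centered layout <-> FFT layout), matrices and vectors.
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq.int(floor(nr / 2) + 1L, nr), seq_len(floor(nr / 2))),
    c(seq.int(floor(nc / 2) + 1L, nc), seq_len(floor(nc / 2)))]
}
ifftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c(seq.int(ceiling(nr / 2) + 1L, nr), seq_len(ceiling(nr / 2))),
    c(seq.int(ceiling(nc / 2) + 1L, nc), seq_len(ceiling(nc / 2)))]
}
fftshift_vec <- function(v) {
  n <- length(v)
  v[c(seq.int(floor(n / 2) + 1L, n), seq_len(floor(n / 2)))]
}

#' Spatial-frequency cutoff of the band-limited angular spectrum
#'
#' Finite aperture and target extents cut off high spatial frequencies over
#' the propagation distance. The cutoff (applied separably to |kx| and |ky|) is
#' pi (La + Li) / (lambda * sqrt(z^2 + (La + Li)^2 / 4)), strictly decreasing
#' in z and tending to 2*pi/lambda as z -> 0.
#'
#' @param La Side length of the source aperture (mm).
#' @param Li Side length of the target pattern plane (mm).
#' @param lambda Wavelength in the medium (mm).
#' @param z Propagation distance (mm).
#' @return Cutoff spatial frequency (rad/mm).
#' @export
band_limit_cutoff <- function(La, Li, lambda, z) {
  stopifnot(La > 0, Li > 0, lambda > 0, z > 0)
  s <- La + Li
  pi * s / (lambda * sqrt(z^2 + s^2 / 4))
}

# Shared worker for propagate()/backpropagate(); sign = +1 forward, -1 backward.
propagate_impl <- function(field, dz, medium, band_limit, sign) {
  stopifnot(inherits(field, "complex_field"), inherits(medium, "medium_props"))
  stopifnot(is.numeric(dz), length(dz) == 1L, is.finite(dz))
  if (dz < 0)
    stop("negative dz: use backpropagate() to move toward the array")
  lam <- check_sampling(field, medium)
  g <- field$grid
  if (dz == 0) return(field)
  km <- 2 * pi / lam
  kx <- grid_kvec(g$nx, g$dx)
  ky <- grid_kvec(g$ny, g$dy)
  kz2 <- outer(kx^2, ky^2, `+`)
  kz2 <- km^2 - kz2
  # evanescent components are zeroed: all distances of interest are >> lambda
  H <- matrix(0 + 0i, g$nx, g$ny)
  prop <- kz2 > 0
  H[prop] <- exp(1i * sign * dz * sqrt(kz2[prop]))
  if (!is.null(band_limit)) {
    stopifnot(length(band_limit) == 2L, all(band_limit > 0))
    kc <- band_limit_cutoff(band_limit[1], band_limit[2], lam, dz)
    H[abs(kx) > kc, ] <- 0
    H[, abs(ky) > kc] <- 0
  }
  if (medium$alpha > 0)
    H <- H * exp(-medium$alpha * field$f * dz / 1000)
  v <- stats::fft(stats::fft(field$values) * H, inverse = TRUE) / (g$nx * g$ny)
  complex_field(g, v, z = field$z + sign * dz, f = field$f)
}

#' Plane-to-plane propagation by the band-limited angular spectrum method
#'
#' Propagates a pressure plane a distance `dz` away from the array by
#' multiplying its angular spectrum with the propagator
#' exp(+j dz sqrt(km^2 - kx^2 - ky^2)). Evanescent components
#' (kx^2 + ky^2 > km^2) are zeroed. If `band_limit = c(La, Li)` is given, the
#' separable cutoff of [band_limit_cutoff()] is applied to suppress the
#' wrap-around artifacts of finite apertures. If the medium has `alpha > 0`
#' the amplitude factor exp(-alpha f dz) is applied.
#'
#' @param field A [complex_field()]; grid must satisfy dx, dy <= lambda/2.
#' @param dz Propagation distance (mm), >= 0.
#' @param medium A [medium_props()].
#' @param band_limit Optional `c(La, Li)` side lengths (mm) for the cutoff.
#' @return A [complex_field()] at depth `z + dz`.
#' @export
propagate <- function(field, dz, medium, band_limit = NULL) {
  propagate_impl(field, dz, medium, band_limit, sign = +1)
}

#' Backpropagation from an image plane to the hologram plane
#'
#' Exact conjugate of [propagate()]: multiplies the angular spectrum with
#' exp(-j dz sqrt(km^2 - kx^2 - ky^2)), so that
#' `backpropagate(propagate(f, dz), dz)` is the identity on the propagating,
#' band-limited subspace.
#'
#' @inheritParams propagate
#' @return A [complex_field()] at depth `z - dz`.
#' @export
backpropagate <- function(field, dz, medium, band_limit = NULL) {
  propagate_impl(field, dz, medium, band_limit, sign = -1)
}

#' Direct Rayleigh-Sommerfeld integral (brute-force oracle)
#'
#' Evaluates the first Rayleigh-Sommerfeld integral
#' p(r) = (1/2pi) * sum p0 (z/R) (1/R - j km) exp(j km R) dx dy
#' over every source sample, at arbitrary target points. O(N*M), no FFT;
#' serves as the independent cross-check for [propagate()].
#'
#' @param source A [complex_field()] at z = 0, sampled at <= lambda/2.
#' @param targets Numeric matrix with columns x, y, z (mm); all z > 0.
#' @param medium A [medium_props()].
#' @return Complex vector of pressures, one per target row.
#' @export
rs_oracle <- function(source, targets, medium) {
  stopifnot(inherits(source, "complex_field"))
  targets <- matrix(as.numeric(targets), ncol = 3)
  if (any(targets[, 3] <= 0))
    stop("rs_oracle targets must have z > 0 (z = 0 touches the singular kernel)")
  check_sampling(source, medium)
  km <- wavenumber_mm(medium, source$f)
  g <- source$grid
  co <- grid_coords(g)
  nz <- which(source$values != 0)
  sx <- co$x[(nz - 1L) %% g$nx + 1L]
  sy <- co$y[(nz - 1L) %/% g$nx + 1L]
  sv <- source$values[nz]
  dS <- g$dx * g$dy
  vapply(seq_len(nrow(targets)), function(i) {
    R <- sqrt((targets[i, 1] - sx)^2 + (targets[i, 2] - sy)^2 + targets[i, 3]^2)
    k <- (targets[i, 3] / R) * (1 / R - 1i * km) * exp(1i * km * R) / R
    sum(sv * k) * dS / (2 * pi)
  }, complex(1))
}

#' Spherically focused piston source plane
#'
#' Unit-amplitude disk of diameter `D` carrying the spherical focusing phase
#' -km (sqrt(r^2 + F^2) - F), zero outside the disk: the plane-projected model
#' of the single-element focused transducers (3, 5.4, 12 and 20 MHz, all with
#' 10 mm focal length).
#'
#' @param D Aperture diameter (mm).
#' @param F_mm Geometric focal length (mm).
#' @param f Frequency (MHz).
#' @param grid A [grid_2d()] with extent >= 1.5 D and sampling <= lambda/2.
#' @param medium A [medium_props()].
#' @return A [complex_field()] at z = 0.
#' @export
focused_piston_source <- function(D, F_mm, f, grid, medium = water_medium()) {
  stopifnot(D > 0, F_mm > 0)
  lam <- wavelength_mm(medium, f)
  if (grid$dx > lam / 2 || grid$dy > lam / 2)
    stop("grid undersampled: need dx, dy <= lambda/2")
  if (grid$nx * grid$dx < 1.5 * D || grid$ny * grid$dy < 1.5 * D)
    stop("grid extent must be >= 1.5 * aperture diameter")
  km <- 2 * pi / lam
  co <- grid_coords(grid)
  r2 <- outer(co$x^2, co$y^2, `+`)
  v <- ifelse(r2 <= (D / 2)^2, exp(-1i * km * (sqrt(r2 + F_mm^2) - F_mm)), 0 + 0i)
  complex_field(grid, v, z = 0, f = f)
}

#' Padded propagation grid for a given physical extent
#'
#' Builds a [grid_2d()] whose sample count is the next power of two at or
#' above `pad` times the samples needed to cover `extent_mm`, so that FFT
#' wrap-around from finite apertures is pushed outside the region of interest.
#'
#' @param extent_mm Physical extent to cover (mm).
#' @param dx Sample spacing (mm).
#' @param pad Zero-padding factor (default 2).
#' @return A square [grid_2d()].
#' @export
propagation_grid <- function(extent_mm, dx, pad = 2) {
  stopifnot(extent_mm > 0, dx > 0, pad >= 1)
  n <- ceiling(extent_mm / dx)
  N <- 2L^ceiling(log2(pad * n))
  grid_2d(N, N, dx)
}
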