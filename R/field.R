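#' Uniform 2D sampling grid
#'
#' A centered uniform grid on which pressure planes are sampled. Sample
#' coordinates span a symmetric range about 0: `x = (0:(nx-1) - nx %/% 2) * dx`
#' (and likewise for y), so a grid always contains the origin. The conjugate
#' (spatial-frequency) grid has spacing `dk = 2*pi/(n*d)` per axis.
#'
#' @param nx,ny Sample counts (>= 2).
#' @param dx,dy Sample spacings (mm); `dy` defaults to `dx`.
#' @return An object of class `grid_2d`.
#' @examples
#' g <- grid_2d(64, 64, 0.1)
#' range(grid_coords(g)$x)
#' @export
grid_2d <- function(nx, ny = nx, dx, dy = dx) {
  stopifnot(nx >= 2, ny >= 2, dx > 0, dy > 0)
  nx <- as.integer(nx); ny <- as.integer(ny)
  structure(list(nx = nx, ny = ny, dx = dx, dy = dy), class = "grid_2d")
}

#' @rdname grid_2d
#' @param grid A `grid_2d`.
#' @return `grid_coords`: list with numeric vectors `x` (length `nx`) and
#'   `y` (length `ny`) in mm.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_2d"))
  list(x = (seq_len(grid$nx) - 1 - grid$nx %/% 2) * grid$dx,
       y = (seq_len(grid$ny) - 1 - grid$ny %/% 2) * grid$dy)
}

# Wrapped (FFT-order) spatial frequencies, rad/mm, one vector per axis.
grid_kvec <- function(n, d) {
  idx <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  2 * pi * idx / (n * d)
}

#' @export
print.grid_2d <- function(x, ...) {
  cat(sprintf("<grid_2d> %d x %d samples, dx = %g mm, dy = %g mm (extent %g x %g mm)\n",
              x$nx, x$ny, x$dx, x$dy, x$nx * x$dx, x$ny * x$dy))
  invisible(x)
}

#' Complex pressure field on a plane
#'
#' Samples of the complex acoustic pressure p(x, y) on a [grid_2d()] at a
#' stated plane depth `z` (mm from the array surface, increasing away from
#' the array) and frequency `f` (MHz). The matrix is indexed `[ix, iy]`,
#' rows following x.
#'
#' @param grid A `grid_2d`.
#' @param values Complex (or numeric) matrix of dim `c(nx, ny)`, pressure in Pa.
#' @param z Plane depth (mm).
#' @param f Frequency (MHz), > 0.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(grid, values, z, f) {
  stopifnot(inherits(grid, "grid_2d"))
  values <- as.matrix(values)
  if (!is.complex(values)) storage.mode(values) <- "complex"
  if (!all(dim(values) == c(grid$nx, grid$ny)))
    stop("`values` must have dim c(nx, ny) = c(", grid$nx, ", ", grid$ny, ")")
  if (!all(is.finite(Re(values)) & is.finite(Im(values))))
    stop("`values` contains non-finite samples")
  stopifnot(is.numeric(z), length(z) == 1L, is.finite(z))
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f), f > 0)
  structure(list(grid = grid, values = values, z = z, f = f),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d @ z = %g mm, f = %g MHz, max |p| = %.4g Pa\n",
              x$grid$nx, x$grid$ny, x$z, x$f, max(Mod(x$values))))
  invisible(x)
}

# Check the lambda/2 sampling bound shared by the propagation routines.
check_sampling <- function(field, medium, limit = 0.5) {
  lam <- wavelength_mm(medium, field$f)
  if (field$grid$dx > limit * lam || field$grid$dy > limit * lam)
    stop(sprintf("grid undersampled: dx/dy must be <= lambda/2 = %.4g mm", limit * lam))
  invisible(lam)
}
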