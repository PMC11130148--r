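#' Phased-array geometry
#'
#' Geometry of the 2D stimulation array: 16 x 16 elements at 0.75 mm pitch and
#' 4.5 MHz center frequency by default (256 channels). `fill_factor` is the
#' fraction of the pitch occupied by the active element per axis; the kerf is
#' inactive. The aperture side is `La = n * pitch`.
#'
#' @param n_elem_x,n_elem_y Element counts per axis.
#' @param pitch Element pitch (mm).
#' @param f0 Center frequency (MHz).
#' @param fill_factor Active fraction of the pitch per axis, in (0, 1].
#' @return An object of class `array_spec`.
#' @export
array_spec <- function(n_elem_x = 16, n_elem_y = 16, pitch = 0.75, f0 = 4.5,
                       fill_factor = 0.9) {
  stopifnot(n_elem_x >= 1, n_elem_y >= 1, pitch > 0, f0 > 0,
            fill_factor > 0, fill_factor <= 1)
  structure(list(n_elem_x = as.integer(n_elem_x), n_elem_y = as.integer(n_elem_y),
                 pitch = pitch, f0 = f0, fill_factor = fill_factor),
            class = "array_spec")
}

#' @rdname array_spec
#' @param array An `array_spec`.
#' @return `array_aperture`: aperture side lengths `c(La_x, La_y)` in mm.
#' @export
array_aperture <- function(array) {
  c(array$n_elem_x * array$pitch, array$n_elem_y * array$pitch)
}

#' @rdname array_spec
#' @return `element_centers`: list with vectors `x` and `y` of element-center
#'   coordinates (mm), centered on the array axis.
#' @export
element_centers <- function(array) {
  list(x = (seq_len(array$n_elem_x) - (array$n_elem_x + 1) / 2) * array$pitch,
       y = (seq_len(array$n_elem_y) - (array$n_elem_y + 1) / 2) * array$pitch)
}

#' @export
print.array_spec <- function(x, ...) {
  cat(sprintf("<array_spec> %d x %d elements, pitch %g mm, f0 = %g MHz, fill %g\n",
              x$n_elem_x, x$n_elem_y, x$pitch, x$f0, x$fill_factor))
  invisible(x)
}

#' Target stimulation pattern
#'
#' A non-negative 2D intensity image to be projected at depth `z`, with
#' physical side length `Li` (mm, longest axis). The image is normalized to
#' maximum 1 on construction. Intensity targets are converted to pressure
#' amplitude (square root) at decode time.
#'
#' @param image Non-negative numeric matrix, `[ix, iy]` with rows along x.
#' @param Li Physical side length of the pattern plane (mm).
#' @param z Target depth (mm).
#' @return An object of class `target_pattern`.
#' @export
target_pattern <- function(image, Li, z) {
  image <- as.matrix(image)
  stopifnot(is.numeric(image), all(is.finite(image)), all(image >= 0),
            Li > 0, z > 0)
  mx <- max(image)
  if (mx == 0) stop("all-zero target image")
  structure(list(image = image / mx, Li = Li, z = z), class = "target_pattern")
}

#' Eye pose relative to the array
#'
#' @param z Array-to-retina depth (mm), > 0.
#' @param theta_x,theta_y Tilt angles (degrees), |theta| < 45.
#' @return An object of class `eye_pose`.
#' @export
eye_pose <- function(z, theta_x = 0, theta_y = 0) {
  stopifnot(z > 0, abs(theta_x) < 45, abs(theta_y) < 45)
  structure(list(z = z, theta_x = theta_x, theta_y = theta_y), class = "eye_pose")
}

#' Per-element drive solution (the hologram)
#'
#' Amplitude in [0, 1] (global max 1 after normalization) and phase wrapped to
#' [0, 2 pi) for every array element.
#'
#' @param amplitude,phase Numeric matrices of dim `c(n_elem_x, n_elem_y)`.
#' @param array The `array_spec` the drive belongs to.
#' @return An object of class `drive_solution`.
#' @export
drive_solution <- function(amplitude, phase, array) {
  amplitude <- as.matrix(amplitude); phase <- as.matrix(phase)
  dims <- c(array$n_elem_x, array$n_elem_y)
  stopifnot(all(dim(amplitude) == dims), all(dim(phase) == dims),
            all(is.finite(amplitude)), all(amplitude >= 0),
            all(is.finite(phase)))
  mx <- max(amplitude)
  if (mx > 0) amplitude <- amplitude / mx
  structure(list(amplitude = amplitude, phase = phase %% (2 * pi), array = array),
            class = "drive_solution")
}

#' @export
print.drive_solution <- function(x, ...) {
  cat(sprintf("<drive_solution> %d x %d elements, %d active (amplitude > 0.01)\n",
              nrow(x$amplitude), ncol(x$amplitude), sum(x$amplitude > 0.01)))
  invisible(x)
}

# Complex drive values a * exp(i phase).
drive_complex <- function(drive) drive$amplitude * exp(1i * drive$phase)

#' Tilt-compensation phase ramp
#'
#' Linear phase distribution phi(x, y) = km (x tan(theta_x) + y tan(theta_y))
#' evaluated at the element centers and wrapped to [0, 2 pi). Adding it to a
#' drive shifts the synthesized focus laterally by ~ z tan(theta), which
#' compensates an angular misalignment between the array and the eye.
#'
#' @param array An [array_spec()].
#' @param theta_x,theta_y Tilt angles (degrees), |theta| < 45.
#' @param medium A [medium_props()].
#' @param f Frequency (MHz), default the array's `f0`.
#' @return Phase matrix (rad, wrapped) of dim `c(n_elem_x, n_elem_y)`.
#' @export
tilt_phase <- function(array, theta_x, theta_y, medium = water_medium(),
                       f = array$f0) {
  stopifnot(abs(theta_x) < 45, abs(theta_y) < 45)
  km <- wavenumber_mm(medium, f)
  ec <- element_centers(array)
  ph <- km * outer(ec$x * tan(theta_x * pi / 180),
                   ec$y * tan(theta_y * pi / 180), `+`)
  ph %% (2 * pi)
}

#' Geometric focal law for a steered focus
#'
#' Uniform-amplitude drive whose element phases are the conjugate spherical
#' delay law for the target point `(xf, yf, z)`: phase_e = -km * dist(e, target)
#' wrapped to [0, 2 pi), so that all element contributions arrive at the target
#' in phase under the forward propagator.
#'
#' @param xf,yf Lateral target coordinates (mm).
#' @param z Target depth (mm), > 0.
#' @param array An [array_spec()].
#' @param medium A [medium_props()].
#' @return A [drive_solution()].
#' @export
steer_focus <- function(xf, yf, z, array = array_spec(), medium = water_medium()) {
  stopifnot(z > 0)
  ap <- array_aperture(array)
  if (abs(xf) > ap[1] / 2 || abs(yf) > ap[2] / 2)
    warning("target beyond +/- La/2: steering quality degrades")
  km <- wavenumber_mm(medium, array$f0)
  ec <- element_centers(array)
  dist <- sqrt(outer((ec$x - xf)^2, (ec$y - yf)^2, `+`) + z^2)
  drive_solution(matrix(1, array$n_elem_x, array$n_elem_y), (-km * dist) %% (2 * pi),
                 array)
}

#' Decode a target pattern into an array drive (holographic backpropagation)
#'
#' Single-pass band-limited angular-spectrum decode: the target intensity is
#' converted to pressure amplitude (square root), embedded on a padded
#' propagation grid at the target depth, backpropagated to the array plane
#' with the separable band limit c(La, Li), and averaged over each element's
#' active area to give the element's complex drive (the least-squares piston
#' projection). Amplitudes are normalized to max 1; if `pose` carries a tilt,
#' the compensation ramp of [tilt_phase()] is added modulo 2 pi.
#'
#' @param target A [target_pattern()].
#' @param array An [array_spec()].
#' @param medium A [medium_props()].
#' @param pose Optional [eye_pose()]; its depth overrides the target's and its
#'   tilt adds the compensation ramp.
#' @param dx Decode grid sampling (mm); default lambda/4.
#' @param pad Zero-padding factor for the decode grid (default 2).
#' @param refine Number of alternate-projection refinement sweeps (amplitude
#'   constraint at the target plane, piston constraint at the array plane);
#'   default 0 = the single-pass decode.
#' @return A [drive_solution()].
#' @export
decode_pattern <- function(target, array = array_spec(), medium = water_medium(),
                           pose = NULL, dx = NULL, pad = 2, refine = 0) {
  stopifnot(inherits(target, "target_pattern"), inherits(array, "array_spec"))
  z <- if (!is.null(pose)) pose$z else target$z
  f <- array$f0
  lam <- wavelength_mm(medium, f)
  if (is.null(dx)) dx <- lam / 4
  ap <- array_aperture(array)
  grid <- propagation_grid(1.5 * max(ap, target$Li), dx, pad)
  if (target$Li > grid$nx * grid$dx)
    stop("target extent exceeds the decode grid")
  tf <- embed_target(target, grid, z, f)
  bl <- c(max(ap), target$Li)
  src <- backpropagate(tf, z, medium, band_limit = bl)
  drv <- project_to_elements(src, array)
  if (refine > 0) {
    amp_t <- sqrt(resample_image(target$image, grid, target$Li))
    for (i in seq_len(refine)) {
      fld <- synthesize_field(drv, array, z, medium, grid = grid)
      v <- fld$values
      ph <- Arg(v)
      v[amp_t > 0] <- amp_t[amp_t > 0] * exp(1i * ph[amp_t > 0])
      src <- backpropagate(complex_field(grid, v, z, f), z, medium, band_limit = bl)
      drv <- project_to_elements(src, array)
    }
  }
  if (!is.null(pose) && (pose$theta_x != 0 || pose$theta_y != 0))
    drv <- drive_solution(drv$amplitude,
                          drv$phase + tilt_phase(array, pose$theta_x, pose$theta_y,
                                                 medium, f),
                          array)
  drv
}

# Embed a target pattern (as pressure amplitude) centered on `grid` at depth z.
embed_target <- function(target, grid, z, f) {
  amp <- sqrt(resample_image(target$image, grid, target$Li))
  complex_field(grid, amp, z = z, f = f)
}

# Nearest-neighbour resampling of an image with physical side Li (longest
# axis) onto the center of a propagation grid. Returns a grid-sized matrix.
resample_image <- function(image, grid, Li) {
  px <- Li / max(dim(image))
  co <- grid_coords(grid)
  ix <- round(co$x / px + (nrow(image) + 1) / 2)
  iy <- round(co$y / px + (ncol(image) + 1) / 2)
  okx <- ix >= 1 & ix <= nrow(image)
  oky <- iy >= 1 & iy <= ncol(image)
  out <- matrix(0, grid$nx, grid$ny)
  out[okx, oky] <- image[ix[okx], iy[oky]]
  out
}

# Average the complex field over each element's active area -> drive.
project_to_elements <- function(field, array) {
  g <- field$grid
  co <- grid_coords(g)
  ec <- element_centers(array)
  half <- array$fill_factor * array$pitch / 2
  acc <- matrix(0 + 0i, array$n_elem_x, array$n_elem_y)
  for (i in seq_len(array$n_elem_x)) {
    sx <- which(abs(co$x - ec$x[i]) <= half)
    for (j in seq_len(array$n_elem_y)) {
      sy <- which(abs(co$y - ec$y[j]) <= half)
      acc[i, j] <- mean(field$values[sx, sy])
    }
  }
  drive_solution(Mod(acc), Arg(acc), array)
}

#' Forward model: synthesize the field produced by a drive
#'
#' Renders the array source plane as uniform pistons over each element's
#' active area carrying the element's complex drive, then propagates to depth
#' `z` with [propagate()]. Linear in the drive.
#'
#' @param drive A [drive_solution()].
#' @param array An [array_spec()] (defaults to the drive's own).
#' @param z Observation depth (mm).
#' @param medium A [medium_props()].
#' @param grid Optional output [grid_2d()]; default lambda/4 sampling with
#'   2x padding over 1.5x the aperture.
#' @param dx,pad Grid sampling and padding used when `grid` is NULL.
#' @param band_limit Optional `c(La, Li)` for band-limited propagation.
#' @return A [complex_field()] at depth `z`.
#' @export
synthesize_field <- function(drive, array = drive$array, z, medium = water_medium(),
                             grid = NULL, dx = NULL, pad = 2, band_limit = NULL) {
  stopifnot(inherits(drive, "drive_solution"), z > 0)
  f <- array$f0
  lam <- wavelength_mm(medium, f)
  if (is.null(grid)) {
    if (is.null(dx)) dx <- lam / 4
    grid <- propagation_grid(1.5 * max(array_aperture(array)), dx, pad)
  }
  if (grid$nx * grid$dx < max(array_aperture(array)))
    stop("grid smaller than the array aperture")
  src <- render_source(drive, array, grid)
  propagate(complex_field(grid, src, z = 0, f = f), z, medium, band_limit)
}

# Piston rendering of a drive on a sampling grid.
render_source <- function(drive, array, grid) {
  co <- grid_coords(grid)
  ec <- element_centers(array)
  half <- array$fill_factor * array$pitch / 2
  src <- matrix(0 + 0i, grid$nx, grid$ny)
  dc <- drive_complex(drive)
  xidx <- lapply(ec$x, function(xe) which(abs(co$x - xe) <= half))
  yidx <- lapply(ec$y, function(ye) which(abs(co$y - ye) <= half))
  for (i in seq_along(ec$x))
    for (j in seq_along(ec$y))
      if (dc[i, j] != 0) src[xidx[[i]], yidx[[j]]] <- dc[i, j]
  src
}
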