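#' B-mode image container
#'
#' Log-compressed B-mode slice: non-negative intensities in dB above the
#' display floor, rows along the axial (z) direction with row 1 at z = 0 (the
#' array surface) and columns along x. `y` is the slice's lateral elevation
#' position (mm).
#'
#' @param intensity Non-negative matrix (rows axial, cols lateral).
#' @param dz_px Axial pixel size (mm).
#' @param dx_px Lateral pixel size (mm).
#' @param y Slice position along the out-of-plane axis (mm).
#' @param plane Imaging plane: "xz" (lateral axis = x, stacked along y) or
#'   "yz" (lateral axis = y, stacked along x).
#' @return An object of class `bmode_image`.
#' @export
bmode_image <- function(intensity, dz_px, dx_px, y = 0, plane = c("xz", "yz")) {
  intensity <- as.matrix(intensity)
  plane <- match.arg(plane)
  stopifnot(all(is.finite(intensity)), all(intensity >= 0),
            dz_px > 0, dx_px > 0)
  structure(list(intensity = intensity, dz_px = dz_px, dx_px = dx_px, y = y,
                 plane = plane),
            class = "bmode_image")
}

#' @export
print.bmode_image <- function(x, ...) {
  cat(sprintf("<bmode_image> %s plane, %d (axial) x %d (lateral) px, dz = %g mm, dx = %g mm, pos = %g mm\n",
              x$plane, nrow(x$intensity), ncol(x$intensity), x$dz_px, x$dx_px, x$y))
  invisible(x)
}

#' Eye phantom specification
#'
#' Geometry and noise parameters of the synthetic eyeball used to exercise
#' the auto-alignment chain. The globe is a sphere of radius `radius` whose
#' anterior (cornea) apex sits at depth `anterior_depth`; the cornea is a
#' spherical cap of radius `cornea_radius` protruding `cornea_bulge` beyond
#' the globe. Tilting rotates the eye's optical axis about the globe center
#' by (`theta_x`, `theta_y`) degrees (positive theta_x moves the cornea apex
#' toward +x). Speckle is multiplicative exponential-intensity noise at
#' `snr_db` (arc intensity over noise floor); `snr_db = Inf` disables noise.
#' Generation is bit-reproducible under `seed`.
#'
#' Ground truth carried by the object: array-to-retina depth along the array
#' axis is `anterior_depth + cornea_bulge + 2 * radius`.
#'
#' @param radius Globe radius (mm).
#' @param anterior_depth Depth of the cornea apex (mm).
#' @param theta_x,theta_y Tilt angles (degrees).
#' @param snr_db Speckle signal-to-noise ratio (dB).
#' @param seed Integer RNG seed.
#' @param cornea_radius Cornea cap radius (mm).
#' @param cornea_bulge Protrusion of the apex beyond the globe (mm).
#' @return An object of class `eye_phantom_spec`.
#' @export
eye_phantom_spec <- function(radius = 3.2, anterior_depth = 3.0,
                             theta_x = 0, theta_y = 0, snr_db = Inf,
                             seed = 1L, cornea_radius = 2.7,
                             cornea_bulge = 0.25) {
  stopifnot(radius > 0, anterior_depth > 0, abs(theta_x) < 45, abs(theta_y) < 45,
            cornea_radius > 0, cornea_radius <= radius, cornea_bulge >= 0)
  structure(list(radius = radius, anterior_depth = anterior_depth,
                 theta_x = theta_x, theta_y = theta_y, snr_db = snr_db,
                 seed = as.integer(seed), cornea_radius = cornea_radius,
                 cornea_bulge = cornea_bulge),
            class = "eye_phantom_spec")
}

#' @rdname eye_phantom_spec
#' @param spec An `eye_phantom_spec`.
#' @export
phantom_truth <- function(spec) {
  u <- tilt_axis_unit(spec$theta_x, spec$theta_y)
  Cz <- spec$anterior_depth + spec$cornea_bulge + spec$radius
  list(depth = spec$anterior_depth + spec$cornea_bulge + 2 * spec$radius,
       theta_x = spec$theta_x, theta_y = spec$theta_y,
       center = c(0, 0, Cz), axis = u)
}

# Unit vector of the eye's anterior (optical-axis) direction for tilt
# (theta_x, theta_y) in degrees; untilted = (0, 0, -1) (toward the array).
tilt_axis_unit <- function(theta_x, theta_y) {
  tx <- theta_x * pi / 180; ty <- theta_y * pi / 180
  c(sin(tx), cos(tx) * sin(ty), -cos(tx) * cos(ty))
}

#' Synthesize a B-mode eyeball slice stack
#'
#' Renders `n_slices` parallel B-mode slices (planes y = const) of the tilted
#' eye phantom: a bright anterior (cornea cap) arc and a bright posterior
#' (retina cap) arc at analytically known pixel positions, an anechoic
#' interior, multiplicative exponential speckle at the specified SNR, and log
#' compression to dB above a 40 dB display floor. Deterministic under the
#' spec's seed.
#'
#' @param spec An [eye_phantom_spec()].
#' @param n_slices Number of slices (>= 1), spanning `y_span` symmetrically.
#' @param y_span Total out-of-plane extent of the stack (mm).
#' @param dz_px,dx_px Pixel sizes (mm).
#' @param depth_mm,width_mm Image extent (mm).
#' @param plane "xz" (slices stacked along y), "yz" (stacked along x) or
#'   "both" (concatenation of the two sweeps, as acquired in practice).
#' @return List of [bmode_image()] slices.
#' @export
synthesize_bmode <- function(spec, n_slices = 9, y_span = 5,
                             dz_px = 0.05, dx_px = 0.05,
                             depth_mm = 14, width_mm = 10,
                             plane = c("xz", "yz", "both")) {
  plane <- match.arg(plane)
  stopifnot(inherits(spec, "eye_phantom_spec"), n_slices >= 1)
  if (plane == "both")
    return(c(synthesize_bmode(spec, n_slices, y_span, dz_px, dx_px,
                              depth_mm, width_mm, "xz"),
             synthesize_bmode(spec, n_slices, y_span, dz_px, dx_px,
                              depth_mm, width_mm, "yz")))
  tr <- phantom_truth(spec)
  C <- tr$center; u <- tr$axis
  if (C[3] + spec$radius > depth_mm || spec$anterior_depth < 0.5)
    stop("phantom geometry falls outside the image extent")
  Cc <- C + (spec$radius + spec$cornea_bulge - spec$cornea_radius) * u
  if (plane == "yz") {  # swap x and y roles: lateral axis = y
    C <- C[c(2, 1, 3)]; Cc <- Cc[c(2, 1, 3)]; u <- u[c(2, 1, 3)]
  }
  ys <- if (n_slices == 1) 0 else seq(-y_span / 2, y_span / 2, length.out = n_slices)
  nz <- round(depth_mm / dz_px); nxp <- round(width_mm / dx_px)
  xs <- (seq_len(nxp) - (nxp + 1) / 2) * dx_px
  zs <- (seq_len(nz) - 1) * dz_px
  sigma_px <- 1.5
  old <- .Random.seed_save()
  set.seed(spec$seed + (plane == "yz"))
  on.exit(.Random.seed_restore(old))
  lapply(ys, function(y) {
    env <- matrix(0, nz, nxp)
    top <- cornea_arc_z(xs, y, Cc, spec$cornea_radius, u, cap_cos = cos(50 * pi / 180))
    bot <- retina_arc_z(xs, y, C, spec$radius, u, cap_cos = cos(65 * pi / 180))
    for (j in seq_len(nxp)) {
      if (is.finite(top[j]))
        env[, j] <- env[, j] + exp(-0.5 * ((zs - top[j]) / (sigma_px * dz_px))^2)
      if (is.finite(bot[j]))
        env[, j] <- env[, j] + exp(-0.5 * ((zs - bot[j]) / (sigma_px * dz_px))^2)
    }
    if (is.finite(spec$snr_db)) {
      amp <- 10^(spec$snr_db / 20)
      # fully developed speckle: exponential intensity, correlated at the
      # point-spread-function scale (~1 px)
      spk <- gauss_blur(matrix(stats::rexp(nz * nxp), nz, nxp), 1)
      inten <- (amp * env + 1)^2 * spk
    } else {
      inten <- (env + 1e-4)^2
    }
    db <- 10 * log10(inten / max(inten))
    bmode_image(pmax(db + 40, 0), dz_px, dx_px, y = y, plane = plane)
  })
}

# Save/restore .Random.seed so seeded generators do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Axial position (mm) of the anterior cornea-arc centerline per lateral
# sample, NA where the cap is not cut by this slice/column.
cornea_arc_z <- function(xs, y, Cc, Rc, u, cap_cos) {
  dy2 <- (y - Cc[2])^2
  r2 <- Rc^2 - dy2 - (xs - Cc[1])^2
  z <- ifelse(r2 > 0, Cc[3] - sqrt(pmax(r2, 0)), NA_real_)
  keep_cap(xs, y, z, Cc, Rc, u, cap_cos)
}

# Posterior retina-arc centerline (far side of the globe).
retina_arc_z <- function(xs, y, C, R, u, cap_cos) {
  dy2 <- (y - C[2])^2
  r2 <- R^2 - dy2 - (xs - C[1])^2
  z <- ifelse(r2 > 0, C[3] + sqrt(pmax(r2, 0)), NA_real_)
  keep_cap(xs, y, z, C, R, -u, cap_cos)
}

keep_cap <- function(xs, y, z, Ctr, R, axis, cap_cos) {
  ok <- is.finite(z)
  dp <- rep(NA_real_, length(xs))
  dp[ok] <- ((xs[ok] - Ctr[1]) * axis[1] + (y - Ctr[2]) * axis[2] +
               (z[ok] - Ctr[3]) * axis[3]) / R
  ifelse(ok & dp >= cap_cos, z, NA_real_)
}
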