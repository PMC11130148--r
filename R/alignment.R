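#' Canny edge detection on a B-mode image
#'
#' Classic Canny chain: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantized gradient direction, and hysteresis
#' linking. Thresholds default to 40% / 80% of the 99th percentile of the
#' gradient magnitude, chosen for the phantom's contrast.
#'
#' @param image A [bmode_image()] or a numeric matrix.
#' @param sigma Gaussian smoothing scale (pixels).
#' @param low,high Hysteresis thresholds (absolute gradient magnitude); when
#'   NULL they default to `c(0.4, 0.8) * quantile(|grad|, 0.99)`.
#' @return Logical matrix of edge pixels (same dim as the image).
#' @export
detect_edges <- function(image, sigma = 2, low = NULL, high = NULL) {
  m <- if (inherits(image, "bmode_image")) image$intensity else as.matrix(image)
  stopifnot(all(is.finite(m)))
  sm <- gauss_blur(m, sigma)
  nr <- nrow(sm); nc <- ncol(sm)
  pad <- sm[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  ir <- 2:(nr + 1); ic <- 2:(nc + 1)
  # Sobel derivatives: gz along rows (axial), gx along columns (lateral)
  gz <- (pad[ir + 1, ic - 1] + 2 * pad[ir + 1, ic] + pad[ir + 1, ic + 1] -
           pad[ir - 1, ic - 1] - 2 * pad[ir - 1, ic] - pad[ir - 1, ic + 1]) / 8
  gx <- (pad[ir - 1, ic + 1] + 2 * pad[ir, ic + 1] + pad[ir + 1, ic + 1] -
           pad[ir - 1, ic - 1] - 2 * pad[ir, ic - 1] - pad[ir + 1, ic - 1]) / 8
  mag <- sqrt(gz^2 + gx^2)
  if (all(mag == 0)) return(matrix(FALSE, nr, nc))
  if (is.null(high)) high <- 0.8 * stats::quantile(mag, 0.99, names = FALSE)
  if (is.null(low)) low <- 0.5 * high
  stopifnot(low >= 0, low < high)
  # non-maximum suppression, gradient direction quantized to 4 sectors
  ang <- atan2(gz, gx)  # direction of steepest change, (-pi, pi]
  sector <- (round(ang / (pi / 4)) %% 4)  # 0:lateral 1:diag 2:axial 3:anti-diag
  magp <- matrix(0, nr + 2, nc + 2)
  magp[ir, ic] <- mag
  n1 <- matrix(0, nr, nc); n2 <- n1
  s0 <- sector == 0; s1 <- sector == 1; s2 <- sector == 2; s3 <- sector == 3
  n1[s0] <- magp[ir, ic + 1][s0];     n2[s0] <- magp[ir, ic - 1][s0]
  n1[s1] <- magp[ir + 1, ic + 1][s1]; n2[s1] <- magp[ir - 1, ic - 1][s1]
  n1[s2] <- magp[ir + 1, ic][s2];     n2[s2] <- magp[ir - 1, ic][s2]
  n1[s3] <- magp[ir + 1, ic - 1][s3]; n2[s3] <- magp[ir - 1, ic + 1][s3]
  ridge <- mag >= n1 & mag >= n2
  strong <- ridge & mag >= high
  weak <- ridge & mag >= low
  # hysteresis: grow strong edges into connected weak pixels (8-neighbour)
  repeat {
    grown <- weak & dilate8(strong)
    new_strong <- strong | grown
    if (identical(new_strong, strong)) break
    strong <- new_strong
  }
  strong
}

# Separable Gaussian blur with replicated borders.
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2); k <- k / sum(k)
  blur1 <- function(mm) {
    n <- nrow(mm)
    ext <- mm[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(mm))
    for (i in seq_along(k)) out <- out + k[i] * ext[(i - 1) + seq_len(n), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(m))))
}

# Remove connected edge components (8-connectivity) shorter than min_len
# pixels: speckle produces short curls, the anatomical arcs are long curves.
prune_short_edges <- function(edges, min_len = 20L) {
  idx <- which(edges)
  if (!length(idx)) return(edges)
  nr <- nrow(edges)
  nc <- ncol(edges)
  remain <- edges
  out <- edges & FALSE
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  drow <- c(-1L, 1L, 0L, 0L, -1L, 1L, -1L, 1L)
  for (start in idx) {
    if (!remain[start]) next
    comp <- integer(0)
    queue <- start
    remain[start] <- FALSE
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      comp <- c(comp, p)
      r <- (p - 1L) %% nr + 1L
      keep <- r + drow >= 1L & r + drow <= nr
      nb <- p + offs[keep]
      nb <- nb[nb >= 1L & nb <= nr * nc]
      nb <- nb[remain[nb]]
      remain[nb] <- FALSE
      queue <- c(queue, nb)
    }
    if (length(comp) >= min_len) out[comp] <- TRUE
  }
  out
}

# 8-neighbour binary dilation.
dilate8 <- function(b) {
  nr <- nrow(b); nc <- ncol(b)
  p <- matrix(FALSE, nr + 2, nc + 2)
  p[2:(nr + 1), 2:(nc + 1)] <- b
  out <- b
  for (dr in -1:1) for (dc in -1:1)
    out <- out | p[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  out
}

# Per-column centerlines of the top (anterior) and bottom (posterior) arcs
# from a binary edge map. Canny marks both flanks of a bright line (several
# pixels each on slanted segments); the centerline within the edge-bounded
# window is refined by the linear-intensity centroid when the image is
# supplied, else by the mean edge position. Returns axial positions in mm
# (NA where no edge).
arc_centerlines <- function(edges, dz_px, intensity = NULL, max_pair_px = 18L) {
  nc <- ncol(edges)
  nr <- nrow(edges)
  top <- rep(NA_real_, nc); bot <- top
  centroid <- function(win, j, fallback) {
    if (is.null(intensity)) return(fallback)
    win <- win[win >= 1L & win <= nr]
    w <- 10^(intensity[win, j] / 10)  # undo log compression
    sum(win * w) / sum(w)
  }
  for (j in seq_len(nc)) {
    rows <- which(edges[, j])
    if (length(rows) < 1L) next
    r1 <- rows[1]
    cl <- rows[rows <= r1 + max_pair_px]
    top[j] <- centroid((min(cl) - 2L):(max(cl) + 2L), j, mean(cl))
    rn <- rows[length(rows)]
    cl2 <- rows[rows >= rn - max_pair_px]
    bot[j] <- centroid((min(cl2) - 2L):(max(cl2) + 2L), j, mean(cl2))
  }
  list(top_mm = (top - 1) * dz_px, bot_mm = (bot - 1) * dz_px)
}

#' Lift slice edges to a 3D boundary point cloud
#'
#' Detects edges on every slice, prunes short (speckle) components, extracts
#' per-column top (cornea) and bottom (retina) arc centerlines, and lifts
#' them to (x, y, z) mm coordinates in the array frame, honouring each
#' slice's imaging plane ("xz" or "yz").
#'
#' @param slices List of [bmode_image()] (>= 1; >= 2 for a true 3D cloud).
#' @param sigma,low,high Passed to [detect_edges()].
#' @return List of class `eye_surface` with matrices `top` and `bottom`
#'   (columns x, y, z in mm), per-slice records `slices`, and `degenerate_y`
#'   flag (all slices at one out-of-plane position).
#' @export
stack_to_surface <- function(slices, sigma = 2, low = NULL, high = NULL) {
  recs <- process_slices(slices, sigma, low, high)
  lift <- function(rec, which) {
    zmm <- rec[[which]]
    ok <- !is.na(zmm)
    lat <- rec$lateral[ok]
    pos <- rep(rec$pos, sum(ok))
    if (rec$plane == "xz") cbind(x = lat, y = pos, z = zmm[ok])
    else cbind(x = pos, y = lat, z = zmm[ok])
  }
  top <- do.call(rbind, lapply(recs, lift, "top_mm"))
  bottom <- do.call(rbind, lapply(recs, lift, "bot_mm"))
  pos <- vapply(recs, function(r) r$pos, numeric(1))
  structure(list(top = top, bottom = bottom, slices = recs,
                 degenerate_y = length(unique(pos)) < 2L),
            class = "eye_surface")
}

# Detect + classify arcs on every slice; returns per-slice records with the
# slice plane, out-of-plane position, lateral coordinates and arc
# centerlines (mm).
process_slices <- function(slices, sigma = 2, low = NULL, high = NULL) {
  stopifnot(length(slices) >= 1)
  dims <- vapply(slices, function(s) c(dim(s$intensity), s$dz_px, s$dx_px),
                 numeric(4))
  if (any(apply(dims, 1, function(r) length(unique(r)) != 1L)))
    stop("inconsistent pixel geometry across slices")
  lapply(slices, function(s) {
    e <- prune_short_edges(detect_edges(s, sigma, low, high))
    ac <- arc_centerlines(e, s$dz_px, s$intensity)
    # columns where top and bottom nearly coincide see a single arc: in this
    # geometry the cornea cap is laterally narrower than the retina cap, so
    # a lone arc is the retina; merge its two flank estimates
    lone <- !is.na(ac$top_mm) & !is.na(ac$bot_mm) & (ac$bot_mm - ac$top_mm) < 2
    ac$bot_mm[lone] <- (ac$top_mm[lone] + ac$bot_mm[lone]) / 2
    ac$top_mm[lone] <- NA_real_
    nc <- ncol(s$intensity)
    list(plane = if (is.null(s$plane)) "xz" else s$plane, pos = s$y,
         lateral = (seq_len(nc) - (nc + 1) / 2) * s$dx_px,
         top_mm = ac$top_mm, bot_mm = ac$bot_mm)
  })
}

# Robust in-plane circle fit (Kasa linear LS with residual trimming).
# Returns list(center = c(c_lat, c_z), r, lat, z) with inlier points, or NULL.
circle_fit <- function(lat, z) {
  for (it in 1:3) {
    if (length(lat) < 8L) return(NULL)
    beta <- stats::lm.fit(cbind(2 * lat, 2 * z, 1), lat^2 + z^2)$coefficients
    r <- sqrt(pmax(beta[3] + beta[1]^2 + beta[2]^2, 0))
    res <- abs(sqrt((lat - beta[1])^2 + (z - beta[2])^2) - r)
    keep <- res <= max(3 * stats::mad(res), 0.1)
    if (all(keep)) break
    lat <- lat[keep]; z <- z[keep]
  }
  list(center = c(beta[1], beta[2]), r = r, lat = lat, z = z)
}

# In-plane azimuth (rad) of the cornea-cap axis from one slice: bisector of
# the detected arc's angular range about the fitted circle center, taken as
# the uniform-arc-length mean of inlier point azimuths (weights 1/|cos phi|).
# Slices whose fitted radius is anatomically implausible are rejected.
slice_cap_azimuth <- function(lat, z) {
  cf <- circle_fit(lat, z)
  if (is.null(cf) || cf$r < 1 || cf$r > 6) return(NULL)
  phi <- atan2(cf$lat - cf$center[1], -(cf$z - cf$center[2]))
  w <- 1 / pmax(abs(cos(phi)), 0.2)
  az <- sum(phi * w) / sum(w)
  if (abs(az) > 45 * pi / 180) return(NULL)
  list(azimuth = az, n = length(cf$lat))
}

# Weighted median.
wmedian <- function(v, w) {
  o <- order(v)
  v <- v[o]; w <- w[o]
  v[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Estimate eye pose (depth and tilt) from a B-mode stack
#'
#' The retina depth is the axial position of the bottom (retina) arc at the
#' array axis: a robust local quadratic fit of the central slice's bottom
#' centerline, evaluated at lateral 0. Each tilt angle is estimated in the
#' sweep plane that resolves it (theta_x from "xz" slices, theta_y from
#' "yz" slices): per slice, a robust circle fit of the cornea arc gives the
#' in-plane cap-axis azimuth as the arc's angular bisector, and azimuths are
#' pooled across slices weighted by arc length. When only one sweep plane is
#' supplied, the out-of-plane angle falls back to a 3D sphere fit of the
#' cornea cloud with a surface-measure-weighted cap centroid (less robust
#' for strongly tilted eyes; acquiring both planes is recommended, and is
#' what [synthesize_bmode()] with `plane = "both"` provides).
#'
#' @param slices List of [bmode_image()].
#' @param sigma,low,high Passed to [detect_edges()].
#' @return Object of class `alignment_result` with `depth` (mm), `theta_x`,
#'   `theta_y` (deg) and the `surface` point cloud.
#' @export
estimate_pose <- function(slices, sigma = 2, low = NULL, high = NULL) {
  surf <- stack_to_surface(slices, sigma, low, high)
  if (is.null(surf$bottom) || nrow(surf$bottom) < 5L)
    stop("alignment failed: retina (bottom) edge not found")
  if (is.null(surf$top) || nrow(surf$top) < 8L)
    stop("alignment failed: cornea (top) edge not found")
  recs <- surf$slices
  planes <- vapply(recs, function(r) r$plane, character(1))
  pos <- vapply(recs, function(r) r$pos, numeric(1))

  # depth: robust quadratic on the central slice's retina centerline
  depth_for <- function(rec) {
    ok <- !is.na(rec$bot_mm) & abs(rec$lateral) <= 1.2
    if (sum(ok) < 5L) return(NA_real_)
    nd <- data.frame(x = rec$lateral[ok], z = rec$bot_mm[ok])
    for (it in 1:3) {
      qf <- stats::lm(z ~ x + I(x^2), data = nd)
      res <- abs(stats::residuals(qf))
      keep <- res <= max(3 * stats::mad(res), 0.1)
      if (all(keep) || sum(keep) < 5L) break
      nd <- nd[keep, ]
    }
    unname(stats::predict(qf, data.frame(x = 0)))
  }
  depths <- vapply(unique(planes), function(p) {
    sel <- which(planes == p)
    depth_for(recs[[sel[which.min(abs(pos[sel]))]]])
  }, numeric(1))
  depths <- depths[is.finite(depths)]
  if (!length(depths)) stop("alignment failed: retina edge absent near the axis")
  depth <- mean(depths)

  # per-plane in-plane cap azimuth (rad), arc-length-weighted across slices
  plane_azimuth <- function(p) {
    az <- lapply(recs[planes == p], function(rec) {
      ok <- !is.na(rec$top_mm)
      if (sum(ok) < 8L) return(NULL)
      slice_cap_azimuth(rec$lateral[ok], rec$top_mm[ok])
    })
    az <- az[!vapply(az, is.null, logical(1))]
    if (!length(az)) return(NULL)
    w <- vapply(az, function(a) a$n, numeric(1))
    v <- vapply(az, function(a) a$azimuth, numeric(1))
    wmedian(v, w)
  }
  phi_x <- if (any(planes == "xz")) plane_azimuth("xz") else NULL
  phi_y <- if (any(planes == "yz")) plane_azimuth("yz") else NULL
  if (is.null(phi_x) && is.null(phi_y))
    stop("alignment failed: cornea (top) edge not found in any slice")

  # fallback for a missing sweep direction: 3D sphere fit + weighted centroid
  axis3d <- function() {
    P <- surf$top
    for (it in 1:4) {
      beta <- stats::lm.fit(cbind(2 * P, 1), rowSums(P^2))$coefficients
      ctr <- beta[1:3]
      r <- sqrt(rowSums(sweep(P, 2, ctr)^2))
      Rc <- stats::median(r)
      res <- abs(r - Rc)
      keep <- res <= max(3 * stats::mad(res), 0.15)
      if (all(keep) || sum(keep) < 8L) break
      P <- P[keep, , drop = FALSE]
    }
    w <- Rc / pmax(abs(P[, "z"] - ctr[3]), 0.2 * Rc)
    ax <- colSums(P * w) / sum(w) - ctr
    ax / sqrt(sum(ax^2))
  }
  if (is.null(phi_x) || is.null(phi_y)) {
    ax <- axis3d()
    if (is.null(phi_x)) phi_x <- atan2(ax[1], -ax[3])
    if (is.null(phi_y)) phi_y <- atan2(ax[2], -ax[3])
  }
  # cap axis u proportional to (tan phi_x, tan phi_y, -1)
  u <- c(tan(phi_x), tan(phi_y), -1)
  u <- u / sqrt(sum(u^2))
  theta_x <- asin(pmin(pmax(u[1], -1), 1)) * 180 / pi
  theta_y <- atan2(u[2], -u[3]) * 180 / pi
  structure(list(depth = depth, theta_x = unname(theta_x),
                 theta_y = unname(theta_y), surface = surf),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> depth = %.3f mm, theta_x = %.2f deg, theta_y = %.2f deg\n",
              x$depth, x$theta_x, x$theta_y))
  invisible(x)
}
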