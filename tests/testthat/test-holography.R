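arr <- array_spec()

test_that("array geometry derives aperture and element centers correctly", {
  expect_equal(array_aperture(arr), c(12, 12))
  ec <- element_centers(arr)
  expect_equal(length(ec$x), 16)
  expect_equal(ec$x, -rev(ec$x))          # symmetric about the axis
  expect_equal(diff(ec$x), rep(0.75, 15)) # pitch
})

test_that("steer_focus produces a radially symmetric on-axis focal law", {
  d <- steer_focus(0, 0, 10, arr, water)
  expect_true(all(d$amplitude == 1))
  expect_equal(d$phase, d$phase[16:1, ])       # mirror in x
  expect_equal(d$phase, t(d$phase))            # x/y exchange symmetry
  expect_error(steer_focus(0, 0, -1, arr, water))
  expect_warning(steer_focus(9, 0, 10, arr, water), "La/2")
})

test_that("steered focus lands at the commanded position", {
  fld <- synthesize_field(steer_focus(-3, 0, 10, arr, water), arr, 10, water)
  pk <- locate_peak(fld)
  expect_lt(abs(pk["x"] - (-3)), 0.15)
  expect_lt(abs(pk["y"]), 0.15)
  # and at a second commanded point from the published scan set
  fld2 <- synthesize_field(steer_focus(1.5, 0, 10, arr, water), arr, 10, water)
  expect_lt(abs(locate_peak(fld2)["x"] - 1.5), 0.15)
})

test_that("decoding a single focal spot recovers the geometric focal law", {
  # delta-like target at the center, z = 10
  img <- matrix(0, 41, 41); img[21, 21] <- 1
  tp <- target_pattern(img, Li = 41 * 0.1, z = 10)
  drv <- decode_pattern(tp, arr, water)
  # oracle: spherical delay law averaged over each element area by direct
  # quadrature (elements are finite pistons, as in the decode projection)
  km <- wavenumber_mm(water, 4.5)
  ec <- element_centers(arr)
  half <- arr$fill_factor * arr$pitch / 2
  sub <- seq(-half, half, length.out = 11)
  law <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    r <- sqrt(outer((ec$x[i] + sub)^2, (ec$y[j] + sub)^2, `+`) + 100)
    law[i, j] <- Arg(mean(exp(-1i * km * r)))
  }
  dphi <- (drv$phase - law) %% (2 * pi)
  # compare where the hologram has support: weakly driven rim elements see
  # only band-limit ringing and their phase is immaterial
  sel <- drv$amplitude >= 0.3
  expect_gt(sum(drv$amplitude[sel]^2) / sum(drv$amplitude^2), 0.85)
  cbar <- Mod(sum((drv$amplitude * exp(1i * dphi))[sel]) / sum(drv$amplitude[sel]))
  circ_sd <- sqrt(-2 * log(cbar))
  expect_lt(circ_sd, 0.05)
  # and the point-sampled steer_focus law agrees with the averaged law at
  # the well-driven central elements
  ref <- steer_focus(0, 0, 10, arr, water)
  ctr <- 6:11
  dd <- Arg(exp(1i * (ref$phase - law)))[ctr, ctr]
  expect_lt(diff(range(dd)), 0.2)
})

test_that("a zero-tilt pose leaves the decoded drive unchanged", {
  tp <- target_pattern(letter_mask("C", 32), Li = 3, z = 10)
  base <- decode_pattern(tp, arr, water)
  posed <- decode_pattern(tp, arr, water, pose = eye_pose(10, 0, 0))
  expect_equal(posed$phase, base$phase)
  expect_equal(posed$amplitude, base$amplitude)
})

test_that("decode -> synthesize reproduces the target pattern (closure)", {
  tp <- target_pattern(letter_mask("C", 48), Li = 4, z = 10)
  drv <- decode_pattern(tp, arr, water)
  fld <- synthesize_field(drv, arr, 10, water)
  g <- fld$grid
  # reference: target amplitude blurred to the diffraction resolution
  amp <- sonoretina:::resample_image(tp$image, g, 4)
  res_mm <- wavelength_mm(water, arr$f0) * 10 / 12   # lambda z / La
  blur <- sonoretina:::gauss_blur(sqrt(amp), res_mm / g$dx / 2.355)
  co <- grid_coords(g)
  sel <- abs(co$x) <= 3
  mag <- Mod(fld$values)[sel, sel]
  expect_gt(pattern_similarity(mag / max(mag), blur[sel, sel] / max(blur)), 0.6)
})

test_that("tilt phase is the wrapped linear compensation ramp", {
  expect_true(all(tilt_phase(arr, 0, 0, water) == 0))
  ph <- tilt_phase(arr, 5, 0, water)
  km <- wavenumber_mm(water, 4.5)
  ec <- element_centers(arr)
  i <- which.min(abs(ec$x - 1))  # element nearest x = 1 mm... exact center below
  expect_equal(ph[i, 1], (km * ec$x[i] * tan(5 * pi / 180)) %% (2 * pi),
               tolerance = 1e-12)
  # hand evaluation at x = 1.125 mm (a real element center), c = 1500, 4.5 MHz
  expect_equal(ph[ec$x == 1.125, 1],
               (2 * pi * 4.5 * 1000 / 1500 * 1.125 * tan(5 * pi / 180)) %% (2 * pi),
               tolerance = 1e-9)
  expect_error(tilt_phase(arr, 50, 0, water))
})

test_that("adding a tilt ramp shifts the focus by z tan(theta)", {
  base <- steer_focus(0, 0, 10, arr, water)
  for (th in c(5, 10)) {
    tilted <- drive_solution(base$amplitude,
                             base$phase + tilt_phase(arr, th, 0, water), arr)
    pk <- locate_peak(synthesize_field(tilted, arr, 10, water))
    expect_lt(abs(pk["x"] - 10 * tan(th * pi / 180)), 0.2)
    expect_lt(abs(pk["y"]), 0.1)
  }
})

test_that("synthesis is linear in the drive and ignores 2 pi phase wraps", {
  dA <- steer_focus(-1, 0, 10, arr, water)
  dB <- steer_focus(1, 1, 10, arr, water)
  g <- propagation_grid(18, wavelength_mm(water, 4.5) / 2, 2)
  fA <- synthesize_field(dA, arr, 10, water, grid = g)
  fB <- synthesize_field(dB, arr, 10, water, grid = g)
  # complex sum of drives
  comb <- sonoretina:::drive_complex(dA) + sonoretina:::drive_complex(dB)
  dAB <- drive_solution(Mod(comb), Arg(comb), arr)
  fAB <- synthesize_field(dAB, arr, 10, water, grid = g)
  scale <- max(Mod(comb))  # drive_solution renormalizes amplitude to max 1
  expect_lt(max(Mod(fAB$values * scale - (fA$values + fB$values))),
            1e-9 * max(Mod(fA$values)))
  # zero drive -> zero field
  z0 <- drive_solution(matrix(0, 16, 16), matrix(0, 16, 16), arr)
  expect_equal(max(Mod(synthesize_field(z0, arr, 10, water, grid = g)$values)), 0)
  # wrapping is a no-op by construction: phases stored modulo 2 pi
  wrapped <- drive_solution(dA$amplitude, dA$phase + 2 * pi, arr)
  expect_equal(wrapped$phase, dA$phase)
})

test_that("a single driven element matches the RS oracle piston field", {
  amp <- matrix(0, 16, 16); amp[8, 8] <- 1
  drv <- drive_solution(amp, matrix(0, 16, 16), arr)
  lam <- wavelength_mm(water, 4.5)
  # fine sampling: the sharp-edged 2-lambda piston needs lambda/8 to keep
  # its aliased spectral tails out of the propagating band
  g <- propagation_grid(18, lam / 8, 2)
  fld <- synthesize_field(drv, arr, 6, water, grid = g)
  src <- complex_field(g, sonoretina:::render_source(drv, arr, g), 0, 4.5)
  ec <- element_centers(arr)
  pts <- cbind(ec$x[8] + c(0, 0.5, 2), ec$y[8], 6)
  rs <- rs_oracle(src, pts, water)
  co <- grid_coords(g)
  ix <- vapply(pts[, 1], function(x) which.min(abs(co$x - x)), integer(1))
  iy <- which.min(abs(co$y - ec$y[8]))
  expect_lt(max(Mod(fld$values[cbind(ix, iy)] - rs)) / max(Mod(rs)), 0.02)
})

test_that("target patterns validate and normalize their inputs", {
  expect_error(target_pattern(matrix(0, 4, 4), 2, 10), "all-zero")
  tp <- target_pattern(matrix(c(1, 2, 3, 4), 2), 2, 10)
  expect_equal(max(tp$image), 1)
  expect_error(eye_pose(10, 60, 0))
  expect_error(drive_solution(matrix(-1, 16, 16), matrix(0, 16, 16), arr))
})
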