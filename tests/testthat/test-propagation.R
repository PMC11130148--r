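test_that("angular spectrum has the expected structure for DC and impulse inputs", {
  g <- grid_2d(32, 32, 0.1)
  # uniform field -> spectrum concentrated at kx = ky = 0
  u <- complex_field(g, matrix(1 + 0i, 32, 32), 0, 4.5)
  sp <- angular_spectrum(u)
  dc <- which(sp$kx == 0)
  expect_equal(Mod(sp$P[dc, dc]), 32 * 32 * 0.1 * 0.1)
  off <- Mod(sp$P); off[dc, dc] <- 0
  expect_lt(max(off), 1e-9)
  # centered unit impulse -> flat magnitude
  v <- matrix(0 + 0i, 32, 32)
  v[17, 17] <- 1  # grid origin sample (n %/% 2 + 1)
  sp2 <- angular_spectrum(complex_field(g, v, 0, 4.5))
  expect_lt(diff(range(Mod(sp2$P))), 1e-12)
  # invertibility
  back <- inverse_angular_spectrum(sp2, g, 0, 4.5)
  expect_lt(max(Mod(back$values - v)), 1e-12)
})

test_that("angular spectrum satisfies Parseval's relation on random fields", {
  for (seed in 1:3) {
    fld <- random_field(n = 24, dx = 0.08, seed = seed)
    sp <- angular_spectrum(fld)
    lhs <- sum(Mod(fld$values)^2) * 0.08 * 0.08
    dk <- 2 * pi / (24 * 0.08)
    rhs <- sum(Mod(sp$P)^2) * dk * dk / (2 * pi)^2
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("propagation rejects bad inputs and handles trivial distances", {
  fld <- random_field(n = 16)
  expect_error(propagate(fld, -1, water), "backpropagate")
  coarse <- complex_field(grid_2d(16, 16, 1), matrix(1 + 0i, 16, 16), 0, 4.5)
  expect_error(propagate(coarse, 1, water), "undersampled")
  bad <- matrix(1 + 0i, 4, 4); bad[2, 2] <- NaN
  expect_error(complex_field(grid_2d(4, 4, 0.1), bad, 0, 4.5), "non-finite")
  # dz = 0 is the identity
  expect_identical(propagate(fld, 0, water)$values, fld$values)
  expect_identical(backpropagate(fld, 0, water)$values, fld$values)
})

test_that("a uniform plane wave gains exactly the normal-incidence phase", {
  g <- grid_2d(32, 32, 0.1)
  fld <- complex_field(g, matrix(1 + 0i, 32, 32), 0, 4.5)
  km <- wavenumber_mm(water, 4.5)
  fwd <- propagate(fld, 2.5, water)
  expect_lt(max(Mod(fwd$values - exp(1i * km * 2.5))), 1e-10)
  expect_equal(fwd$z, 2.5)
  bck <- backpropagate(fld, 2.5, water)
  expect_lt(max(Mod(bck$values - exp(-1i * km * 2.5))), 1e-10)
  expect_equal(bck$z, -2.5)
})

test_that("propagate then backpropagate is the identity on band-limited fields", {
  fld <- bandlimited_field(n = 64, dx = 0.1, seed = 5)
  rt <- backpropagate(propagate(fld, 7, water), 7, water)
  peak <- max(Mod(fld$values))
  expect_lt(max(Mod(rt$values - fld$values)), 1e-8 * peak)
})

test_that("propagation conserves energy and is linear", {
  f1 <- bandlimited_field(n = 48, seed = 7)
  f2 <- bandlimited_field(n = 48, seed = 8)
  p1 <- propagate(f1, 4, water)
  expect_equal(sum(Mod(p1$values)^2), sum(Mod(f1$values)^2), tolerance = 1e-10)
  mix <- complex_field(f1$grid, 2 * f1$values - (0 + 3i) * f2$values, 0, f1$f)
  pmix <- propagate(mix, 4, water)
  expect_lt(max(Mod(pmix$values - (2 * p1$values - (0 + 3i) * propagate(f2, 4, water)$values))),
            1e-12 * max(Mod(pmix$values)))
})

test_that("band-limit cutoff follows the aperture geometry formula", {
  # independently hand-evaluated: pi*(12+6)/(0.333*sqrt(10^2 + 18^2/4))
  expect_equal(band_limit_cutoff(12, 6, 0.333, 10), 12.62231, tolerance = 1e-6)
  # z -> 0 limit tends to the medium wavenumber 2*pi/lambda
  lam <- 0.333
  expect_equal(band_limit_cutoff(12, 6, lam, 1e-9), 2 * pi / lam, tolerance = 1e-6)
  # strictly decreasing in z
  zs <- seq(0.5, 30, by = 0.5)
  cuts <- band_limit_cutoff(12, 6, lam, zs)
  expect_true(all(diff(cuts) < 0))
  expect_error(band_limit_cutoff(-1, 6, lam, 10))
})

test_that("the band limit zeroes spatial frequencies above the cutoff", {
  fld <- random_field(n = 64, dx = 0.1)
  out <- propagate(fld, 10, water, band_limit = c(3, 1.5))
  sp <- angular_spectrum(out)
  lam <- wavelength_mm(water, fld$f)
  kc <- band_limit_cutoff(3, 1.5, lam, 10)
  beyond <- abs(sp$kx) > kc
  expect_lt(max(Mod(sp$P[beyond, ])), 1e-12)
  expect_lt(max(Mod(sp$P[, beyond])), 1e-12)
})

test_that("Rayleigh-Sommerfeld oracle reproduces point-source spreading", {
  g <- grid_2d(4, 4, 0.05)
  v <- matrix(0 + 0i, 4, 4)
  v[3, 3] <- 1  # the origin sample
  src <- complex_field(g, v, 0, 4.5)
  p <- rs_oracle(src, cbind(0, 0, c(20, 40)), water)
  # far-field spherical spreading: |p| ~ 1/r
  expect_equal(Mod(p[1]) / Mod(p[2]), 2, tolerance = 0.01)
  km <- wavenumber_mm(water, 4.5)
  # phase advance between the radii equals km * dr
  expect_equal(Arg(p[2] / p[1]) %% (2 * pi), (km * 20) %% (2 * pi), tolerance = 0.01)
  expect_error(rs_oracle(src, cbind(0, 0, 0), water), "z > 0")
})

test_that("Rayleigh-Sommerfeld oracle matches the closed-form on-axis piston", {
  f <- 3; lam <- wavelength_mm(water, f)
  g <- grid_2d(112, 112, lam / 10)  # fine sampling resolves the disk rim
  co <- grid_coords(g)
  a <- 2  # piston radius mm
  v <- ifelse(outer(co$x^2, co$y^2, `+`) <= a^2, 1 + 0i, 0 + 0i)
  src <- complex_field(g, v, 0, f)
  km <- 2 * pi / lam
  zs <- c(8, 12, 20)
  p <- rs_oracle(src, cbind(0, 0, zs), water)
  expect_equal(Mod(p), piston_onaxis_mag(zs, a, km), tolerance = 0.01)
})

test_that("angular-spectrum propagation agrees with the RS oracle at the focus", {
  # two of the single-element transducers, lambda/2 sampled; <= 2% at focus
  for (cfg in list(c(f = 3, D = 10), c(f = 12, D = 12))) {
    lam <- wavelength_mm(water, cfg[["f"]])
    grid <- propagation_grid(1.5 * cfg[["D"]], lam / 2, 2)
    src <- focused_piston_source(cfg[["D"]], 10, cfg[["f"]], grid, water)
    fld <- propagate(src, 10, water)
    co <- grid_coords(grid)
    pts <- cbind(c(0, 2, 5) * lam, 0, 10)
    ix <- vapply(pts[, 1], function(x) which.min(abs(co$x - x)), integer(1))
    iy <- which.min(abs(co$y))
    as_vals <- fld$values[cbind(ix, iy)]
    rs_vals <- rs_oracle(src, cbind(co$x[ix], 0, 10), water)
    expect_lt(max(Mod(as_vals - rs_vals)) / max(Mod(rs_vals)), 0.02)
  }
})

test_that("focused piston source has the documented geometry and phase", {
  lam <- wavelength_mm(water, 4.5)
  grid <- propagation_grid(15, lam / 4, 2)
  src <- focused_piston_source(10, 10, 4.5, grid, water)
  co <- grid_coords(grid)
  i0 <- which(co$x == 0)
  expect_equal(Arg(src$values[i0, i0]), 0)
  expect_equal(Mod(src$values[i0, i0]), 1)
  # zero outside the disk
  expect_equal(Mod(src$values[which.min(abs(co$x - 5.2)), i0]), 0)
  # phase decreasing with radius over the first unwrapped stretch
  r_in <- co$x[co$x > 0 & co$x < sqrt(lam * 10)]  # within first Fresnel zone
  ph <- Arg(src$values[co$x %in% r_in, i0])
  expect_true(all(diff(ph) < 0))
  expect_error(focused_piston_source(10, 10, 4.5, grid_2d(32, 32, lam / 4), water),
               "extent")
})

test_that("the axial maximum of a focused piston sits near the geometric focus", {
  f <- 5.4; D <- 8; F_mm <- 10
  lam <- wavelength_mm(water, f)
  grid <- propagation_grid(1.5 * D, lam / 2, 2)
  src <- focused_piston_source(D, F_mm, f, grid, water)
  zs <- seq(6, 14, by = 0.25)
  co <- grid_coords(grid)
  i0 <- which(co$x == 0)
  amp <- vapply(zs, function(z) Mod(propagate(src, z, water)$values[i0, i0]),
                numeric(1))
  expect_lte(abs(zs[which.max(amp)] - F_mm), 0.05 * F_mm)
})

test_that("attenuating media damp the propagated amplitude exponentially", {
  g <- grid_2d(32, 32, 0.1)
  fld <- complex_field(g, matrix(1 + 0i, 32, 32), 0, 4.5)
  lossy <- medium_props(1500, 1000, alpha = 30)
  out <- propagate(fld, 5, lossy)
  expect_equal(max(Mod(out$values)), exp(-30 * 4.5 * 5 / 1000), tolerance = 1e-10)
})
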