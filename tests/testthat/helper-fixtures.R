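# Shared fixtures for the suite: everything is generated in code.

water <- water_medium()

# Small random complex field on an n x n grid (seeded).
random_field <- function(n = 32, dx = 0.1, f = 4.5, z = 0, seed = 1) {
  set.seed(seed)
  g <- grid_2d(n, n, dx)
  v <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  complex_field(g, v, z = z, f = f)
}

# Band-limited random field: random spectrum with evanescent and
# near-cutoff components removed (safe for round-trip identities).
bandlimited_field <- function(n = 64, dx = 0.1, f = 4.5, seed = 2,
                              frac = 0.5) {
  set.seed(seed)
  g <- grid_2d(n, n, dx)
  km <- wavenumber_mm(water, f)
  kx <- sonoretina:::grid_kvec(n, dx)
  keep <- outer(kx^2, kx^2, `+`) < (frac * km)^2
  P <- matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
  P[!keep] <- 0
  v <- stats::fft(P, inverse = TRUE) / (n * n)
  complex_field(g, v, z = 0, f = f)
}

# Analytic on-axis pressure magnitude of a flat (unfocused) circular piston
# of radius a, unit surface pressure: |p(z)| = 2 |sin(k (sqrt(z^2+a^2)-z)/2)|.
piston_onaxis_mag <- function(z, a, km) 2 * abs(sin(km * (sqrt(z^2 + a^2) - z) / 2))
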