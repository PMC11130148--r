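# sonoretina

Computational core of an ultrasound retinal prosthesis: acoustic holography
for a 16×16 phased array with imaging-guided auto-alignment, beam and safety
metrics, and the multi-unit-activity (MUA) response-mapping pipeline — all
exercisable end to end on synthetic inputs.

A retinal prosthesis built on focused ultrasound projects patterned pressure
onto the retina instead of light. The package is written for researchers in
therapeutic ultrasound and neuroengineering who need the numerical chain
behind such a device without the hardware: decode an arbitrary target image
into per-element drives, verify the projected field, check that exposure
stays within standard dosimetry indices, and quantify how faithfully a
downstream electrode array sees the pattern.

## The model

Pressure planes propagate by the band-limited angular spectrum method: the
plane's spectrum `P(kx, ky)` is multiplied by the propagator
`exp(j z sqrt(km² − kx² − ky²))` with `km = 2πf/c`, evanescent components
zeroed, and spatial frequencies above the aperture-geometry cutoff

```
k_xy ≤ π (La + Li) / (λ sqrt(z² + (La + Li)²/4))
```

removed. Holograms come from backpropagating the target amplitude to the
array plane (conjugate propagator) and averaging over each element's active
area; angular misalignment (θx, θy) between array and eye is compensated by
the wrapped phase ramp `km (x tanθx + y tanθy)`. A direct
Rayleigh–Sommerfeld integral serves as the brute-force oracle the FFT path
is tested against. Beam quality is quantified by the focal FWHM (half-max of
the focal intensity profile), steering coverage, and a Snellen conversion
(denominator = 4 × FWHM in µm, rounded to a multiple of 20); exposure by
MI, I_SPPA, I_SPTA, TI and the radiation-force law `F = p²αf/(ρc²)`.
Recordings are reduced to MUA amplitudes (500–7000 Hz band-pass → rectify →
10–200 Hz band-pass → peak), mapped on the 56-channel grid with 4×
modified-Akima interpolation and scored against the stimulus by SSIM.

## Worked example

```r
library(sonoretina)

# decode a letter "C" (4 mm wide) for projection at 10 mm depth
target <- target_pattern(letter_mask("C"), Li = 4, z = 10)
drive  <- decode_pattern(target)          # 16x16, 0.75 mm pitch, 4.5 MHz
drive
#> <drive_solution> 16 x 16 elements, 256 active (amplitude > 0.01)

# verify the projected field and steer a focus across the retina
field <- synthesize_field(drive, z = 10)
locate_peak(synthesize_field(steer_focus(-3, 0, 10), z = 10))
#>             x             y
#> -3.003745e+00  4.318572e-17

# spatial resolution of the 20 MHz single-element transducer
fw <- focal_fwhm(20, D = 10, F_mm = 10)
fw$fwhm_um                 # 84.69171 -> lateral FWHM in micrometres
fwhm_to_acuity(fw$fwhm_um) # 340      -> Snellen 20/340 for the simulated spot
fwhm_to_acuity(81)         # 320      -> the measured 81 um maps to 20/320

# exposure metrics for the standard 10 ms pulse at 2.83 MPa
exposure_metrics(pulse_params(2.83, 4.5))
#> <exposure_metrics> MI = 1.334, ISPPA = 266.96 W/cm^2,
#>   ISPTA = 444.94 mW/cm^2, TI = 0.1071 (power branch), ARF = 8.01e+04 N/m^3

# the whole closed loop on synthetic inputs: phantom -> alignment ->
# pose-corrected decode -> field -> synthetic recording -> SC map -> SSIM
cfg <- default_config(seed = 7); cfg$phantom$theta_x <- 5
run_demo(cfg)
#> <demo_report>
#>   pose: depth 9.65 mm (err +0.004), tilt (5.36, -0.19) deg (err +0.36, -0.19)
#>   pattern 'C': center offset 0.072 mm (compensated)
#>   MUA: 16 active channels, mean 8.9 uV; SSIM vs target = 0.462
```

The demo's center offset is the distance between the projected pattern and
where the tilted eye expects it; running the same config with
`cfg$compensate <- FALSE` leaves an offset of 0.84 mm, which the tilt ramp
removes. A thin command-line wrapper with `decode`, `steer`, `align`,
`dose`, `fit-threshold` and `demo` subcommands ships in `inst/cli/urp`.

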