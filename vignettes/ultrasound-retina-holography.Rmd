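---
title: "Acoustic holography and response mapping for an ultrasound retinal prosthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic holography and response mapping for an ultrasound retinal prosthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonoretina)
```

## The problem

An ultrasound retinal prosthesis replaces lost photoreceptor input by
projecting patterned acoustic pressure onto the retina from a 2D phased array
coupled to the front of the eye. `sonoretina` implements the computational
chain that makes this work: given a target image and the eye's pose relative
to the array, compute per-element amplitudes and phases (the *hologram*),
verify the resulting field, quantify beam metrics and exposure safety, and
process the downstream multichannel neural recordings into activation maps
that can be compared against the stimulus. Everything runs on synthetic
inputs — a B-mode eye phantom and a stimulus-locked electrophysiology
generator — so the full loop is testable on a desktop.

## Wave propagation model

Pressure planes are propagated with the band-limited angular spectrum method.
A sampled complex plane $p(x, y, z)$ is decomposed into plane waves

$$P(k_x, k_y, z) = \iint p(x, y, z)\, e^{-j(k_x x + k_y y)}\, dx\, dy,$$

each component advanced by the propagator
$e^{\,j z \sqrt{k_m^2 - k_x^2 - k_y^2}}$ (with $k_m = 2\pi f / c$), and the
plane reassembled by the inverse transform. Backpropagation conjugates the
propagator, so the two maps are exact inverses on the propagating subspace.
Evanescent components ($k_x^2 + k_y^2 > k_m^2$) are zeroed rather than decayed:
every propagation distance of interest here is tens to hundreds of
wavelengths, where their contribution is numerically zero.

Finite apertures alias under the discrete transform. Two measures control
this:

* the separable spatial-frequency cutoff
  $k_{x,y} \le \pi(L_a + L_i)\,/\,\lambda\sqrt{z^2 + (L_a+L_i)^2/4}$,
  where $L_a$ and $L_i$ are the array and target-plane side lengths — applied
  per axis during holographic decoding;
* grid hygiene — $\lambda/4$ sampling and a zero-padding factor of at least 2
  (grid sizes round up to powers of two). The propagation grid is never
  stated in the source material; these are this package's choices. Sharp-edged
  sources (a single bare element) benefit from $\lambda/8$, which the
  cross-validation tests use.

The independent check on all of this is `rs_oracle()`: a direct $O(NM)$
discretization of the first Rayleigh–Sommerfeld integral. It is deliberately
brute force and FFT-free, validated against the closed-form on-axis piston
solution, and the test suite requires angular-spectrum fields to agree with
it within 2% at the focus for all four single-element transducer geometries
(3, 5.4, 12, 20 MHz; 10/8/12/10 mm apertures; 10 mm focal length).

### Units

Space is in millimetres and frequency in megahertz throughout the wave code;
conversions to SI happen only inside the dosimetry formulas. Attenuation is
stored in Np·m⁻¹·MHz⁻¹ with dB·cm⁻¹·MHz⁻¹ converters (`db_cm_to_np_m()`).

## Holographic decoding

`decode_pattern()` embeds the target (converted from intensity to pressure
amplitude by square root, since neural activation is modeled on pressure
magnitude), backpropagates it from the target depth to the array plane under
the band limit, and averages the complex field over each element's active
area — the least-squares projection onto the piston basis (fill factor 0.9
by default; the kerf is epoxy-filled and inactive). Amplitudes keep their
relative apodization and are normalized to a global maximum of 1, matching a
shared voltage ceiling; phases are wrapped to $[0, 2\pi)$.

Two conventions worth stating explicitly:

* **Phase sign.** A stored phase is the argument of the element's physical
  complex drive under the $e^{+jz k_z}$ forward propagator, so the focal law
  of `steer_focus()` is $-k_m\sqrt{(x_e-x_f)^2+(y_e-y_f)^2+z^2}$ wrapped.
  Delay-law tables with the opposite sign convention describe the same
  hologram.
* **Tilt compensation** is the wrapped linear ramp
  $\phi(x,y) = k_m (x \tan\theta_x + y \tan\theta_y)$ evaluated at element
  centers. Adding it shifts the projected pattern laterally by
  $z\tan\theta$, which is how an angular misalignment between array and eye
  is corrected after imaging feedback.

A single-pass decode is the default, as a point-focus hologram from
backpropagation is already within a few hundredths of a radian of the
geometric law wherever the drive has support. An optional
alternate-projections refinement (`refine > 0`) re-imposes the target
amplitude at the image plane and the piston structure at the array plane;
it is off by default. Decoded amplitudes are kept continuous rather than
binarized.

## The synthetic eye and auto-alignment

`synthesize_bmode()` renders what the array's own imaging mode sees: an
anechoic globe with a bright cornea arc (a spherical cap of 2.7 mm radius
protruding 0.25 mm beyond a 3.2 mm globe — rat-eye scale) and a bright
retina arc, log-compressed to a 40 dB display range. Speckle is
multiplicative exponential-intensity noise correlated at the ~1 px
point-spread scale; `snr_db` sets arc-to-floor contrast, with `Inf` giving
the noise-free geometry. Generation is bit-reproducible under the spec's
seed. Both `"xz"` and `"yz"` sweeps can be rendered (`plane = "both"`), the
acquisition pattern the feedback loop uses in practice.

What the phantom does **not** emulate: beamforming point-spread anisotropy,
refraction and shadowing, reverberation clutter, off-sphere globe shape, and
motion. Passing alignment tests on the phantom therefore demonstrates the
estimator's geometric correctness and its robustness to fully developed
speckle — not performance on clinical-grade images.

`estimate_pose()` runs Canny edge detection (σ = 2 px; hysteresis at 40%/80%
of the 99th gradient percentile — none of these are stated in the source
material, so they are exposed as arguments), prunes connected edge
components shorter than 20 px (speckle curls), and takes per-column
arc centerlines refined by the linear-intensity centroid between the two
Canny flanks. Depth is the retina centerline's robust local quadratic
evaluated at the array axis. Tilt is estimated per sweep plane: a trimmed
circle fit of the cornea arc gives the in-plane cap-axis azimuth as the
arc's angular bisector (computed as the uniform-arc-length mean of point
azimuths), which is analytically independent of the slice's out-of-plane
position; azimuths pool across slices by arc-length-weighted median. With a
single sweep, the out-of-plane angle falls back to a 3D sphere fit with a
surface-measure-weighted cap centroid — serviceable, but the two-sweep path
is what meets the ±1° recovery property, and multi-slice fusion of this
kind is a design choice of this package. Over 20 seeded phantoms with tilts
in ±10°, depths 9–12 mm and 15 dB speckle, the suite requires depth within
±0.2 mm and both angles within ±1° in at least 90% of cases.

## Beam metrics

`measure_fwhm()` upsamples a profile 10× with a cubic spline and takes the
half-maximum crossing distance. For focal-spot *resolution* the profile is
the **intensity** ($|p|^2$) through the peak — equivalently the −3 dB
pressure width. That convention is deliberate: it reproduces the quoted
free-field values for all four transducers (the simulation gives 84.7 µm at
20 MHz against a measured 81 µm, and 564 µm at 3 MHz against 590 µm),
whereas the half-max of $|p|$ would give ~116 µm at 20 MHz, contradicting
both the measurement and the sub-100 µm resolution bound. A raw profile
passed by the user is measured as given.

The Snellen conversion `fwhm_to_acuity()` is `round(4 × FWHM µm / 20) × 20`
(20/20 ↔ 5 µm resolved on the retina). No conversion rule is printed in the
source material; this one is reverse-engineered to match both printed pairs
(81 µm → 20/320, 115 µm → 20/460) and documented as such.

`steering_coverage()` operationalizes "stimulable area": a commanded target
counts as covered when the synthesized peak lands within 0.25 mm and keeps
at least 50% of the on-axis amplitude (both configurable; both are this
package's operationalization), and the covered side length is the largest
centered square of fully covered targets. The default ±3.5 mm grid at
0.5 mm spacing runs 225 steered syntheses at $\lambda/2$ sampling in a few
seconds; the 16×16 array at 10 mm depth covers 7 mm — beyond the 6 mm
claim.

`eye_distortion_assay()` propagates the focused source plane-by-plane
through a planar five-layer ocular stack (water 1500, cornea 1586, aqueous
1497, lens 1641, vitreous 1532 m/s; literature values standing in for a
supplementary table, scaled to tile the 10 mm path) with per-layer
wavenumber, attenuation, and normal-incidence amplitude transmission at
interfaces, and compares the focal-plane FWHM against uniform water. The
planar approximation ignores refraction at curved interfaces — the
distortion reported (3.7% at 4.5 MHz, below the 4% bound) is from sound
speed and impedance contrast only. The FWHM is compared at the fixed
geometric focal plane; comparing best-focus planes instead yields ~0.4%,
so the fixed-plane number is the conservative one.

## Dosimetry

The exposure calculators are direct transcriptions: MI = NPP/√f;
I<sub>SPPA</sub> = NPP²/2ρc (W/cm²); I<sub>SPTA</sub> = I<sub>SPPA</sub> ×
duty (mW/cm²); and ARF body force F = p²αf/ρc² (N/m³). The thermal index
uses the soft-tissue small-aperture form TI = min(W, I<sub>SPTA</sub>·1 cm²)
· f / 210 mW·MHz — the source's printed expression is ambiguous about the
frequency factor, but the units only balance with it, so the standard form
is used and the selected min-branch is reported. TI values depend on a
user-supplied derated power W, whose measurement path is not reproducible at
a desk, so TI is validated by hand-computed examples rather than against an
in vivo bound.

`fit_threshold_curve()` fits the activation-threshold power law
p = a·f^b by least squares with b fixed at −1 ("inversely proportional"),
fixed at −1/2 (the prediction if activation requires constant radiation
force, since F ∝ p²f), or free. Both fixed models are offered without
guessing which the data favour; the Monte-Carlo property requires the free
fit to recover the exponent within ±0.1 over 200 noisy replicates.

## MUA pipeline

The amplitude chain is: zero-phase 4th-order Butterworth 500–7000 Hz
band-pass → full-wave rectification → zero-phase 10–200 Hz band-pass →
maximal peak in the post-stimulus window (200 ms default; the analysis
window length is unstated in the source, so it is configurable), per trial,
averaged across trials *after* extraction. Filter order and zero-phase
handling are unstated in the source; 4th-order forward–backward is the
field's default. One numerical note: at 30 kHz the 10–200 Hz band-pass is
implemented as a high-pass/low-pass cascade because the direct
transfer-function band-pass has poles that round outside the unit circle.

The synthetic generator plants band-limited bursts (Hann envelope,
1–3 kHz carrier) on the channels inside an activation mask over white
noise. The carrier is Gaussian noise by default — the model for aggregate
multi-unit spiking — with a `"tone"` option whose rectified envelope is
deterministic; the tone is what the envelope-calibration test uses, because
the max-peak statistic of a rectified noise carrier exceeds its analytic
envelope by a band-dependent factor and has no clean closed form.

`map_sc_response()` arranges the 56 channels on their 7×8, 0.35 mm grid
(the exact grid shape is not printed; 7×8 is configurable) and applies
modified-Akima cubic interpolation separably at 4× refinement. The
implementation follows the modified weights
$w = |\delta_{i+1}-\delta_i| + |\delta_{i+1}+\delta_i|/2$, is exact at the
nodes, and damps the overshoot of plain splines; it is verified against an
independent reference implementation. Standard 4× grid refinement yields
$4(n-1)+1$ samples per axis with all nodes included, which is what the
exactness property needs. `response_similarity()` min–max normalizes the
map and the resampled target and computes SSIM with K₁ = 0.01, K₂ = 0.03
over a 7×7 uniform window on valid positions, dynamic range = joint
maximum.

## The closed loop

`run_demo()` chains everything: phantom → pose estimate → pose-corrected
decode of a letter target → field synthesis at the recovered depth →
thresholded retinotopic activation (field magnitude sampled at electrode
positions mapped 1:1 onto the pattern plane) → synthetic recording → MUA
amplitudes → interpolated map → SSIM. Angular misalignment is modeled as an
angular offset between array axis and eye axis, so the intended pattern
center sits at lateral $(z\tan\theta_x, z\tan\theta_y)$; the measured
pattern position is the cross-correlation peak of $|p|$ against the target,
which is robust to grating lobes where a plain intensity centroid is not.
A paired run with compensation disabled shows the offset the ramp removes
(0.84 mm at 5° tilt, reduced to 0.07 mm). The report is byte-deterministic
given the config seed (wall-clock timing excluded).

The in vivo response similarity (0.91 ± 0.03 in the source) is **not** a
target for this loop: it depends on retinotopic mapping fidelity, electrode
sampling, and biological gain that the synthetic channel model does not
claim to reproduce. The loop's own check is a permutation test — the
observed SSIM must beat the 95th percentile of 100 channel-shuffled nulls.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on a
single CPU in minutes: the 20 MHz focal simulation uses a λ/4-sampled
2048² grid (the largest object in the package), coverage maps use λ/2
sampling over 512² grids, cross-validation against the Rayleigh–Sommerfeld
integral uses λ/2 sources with a handful of target points, and phantom
stacks are 9 + 9 slices of 280×200 px. Ties in peak localization break
toward the smallest radius, then lexicographically. Degenerate inputs —
all-zero targets, all-zero fields, windows outside the record, layers that
do not tile the path — are rejected with explicit messages rather than
propagated as NaN.

## Known limitations

* Scalar, linear, homogeneous-per-layer acoustics: no nonlinearity, shear
  waves, or heterogeneous full-wave solves; no element crosstalk or
  directivity beyond the rigid piston.
* The planar-layer eye model omits refraction by curved interfaces.
* The phantom and ephys generators are statistical stand-ins; absolute
  pressure calibration and hardware output formats are out of scope.
* Alignment assumes a roughly spherical globe with a distinct cornea cap;
  severely truncated or decentered acquisitions degrade the tilt estimate
  before the depth estimate.
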