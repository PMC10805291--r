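---
title: "From dual-camera recordings to animal quantum catches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From dual-camera recordings to animal quantum catches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantacam)
```

## The model

An animal's photoreceptor response to a surface is summarized by its quantum
catch, the wavelength integral of stimulus reflectance, illuminant photon
flux, and receptor spectral sensitivity. A dual-camera rig (one camera
behind a UV-reflecting beam splitter, one recording visible light) measures
four broadband projections of the same spectrum — its camera catches. The
central empirical fact the pipeline rests on is that natural reflectance
spectra are smooth and low-dimensional: over a library of natural spectra,
animal catches are very nearly a *linear* function of camera catches, so a
single matrix `T` (receptors × camera channels, fitted without intercept)
converts calibrated recordings into receptor space. Everything else in the
package exists to deliver calibrated, registered camera catches to that
matrix and to quantify how well the whole chain works.

### Conventions and units

* **Grid.** All spectra live on a canonical 300–700 nm grid at 1 nm. The
  integration rule is a plain discrete sum (rectangle rule): relativizing a
  sensitivity means dividing by its sum on this grid, after which the catch
  of a flat 100% reflector under ideal isoluminant light is *exactly* 1
  under the same rule. Internal consistency (flat-white ≡ 1) is worth more
  here than quadrature order; at 1 nm the difference between rectangle and
  trapezoid sums is far below every tolerance in the package. The
  integration step and rule are this package's convention; nothing else
  depends on them once catches are relativized.
* **Out-of-support values are zero.** Sensitivities, reflectances and
  narrowband illuminants physically vanish where they were not measured, so
  resampling extrapolates with 0, not edge-hold.
* **Reflectance above 1.1 warns rather than errors**, keeping super-white
  standards representable.
* **Catches are relative.** No absolute radiometric calibration is
  attempted; 1.0 always means "what a perfect white diffuser would give
  under the session's conditions".

### Pigment templates

Synthetic receptors are built from the standard A1/A2 visual-pigment
absorbance templates (alpha band as a sum of exponentials in normalized
frequency, plus a Gaussian beta band, included by default and toggleable),
peak-normalized to 1 before relativization. Two cautions, both visible in
the tests: the curve maximum can sit a few nanometres off the nominal
alpha-band peak once the beta band is added, and the A2 fit drifts by
~10 nm when extrapolated into the UV, where it was never calibrated. A2
half-widths are never narrower than A1 at the same peak.

## Sensor calibration

Sensitivity at each monochromator step is the dark-subtracted pixel value
divided by the photon flux summed in an inclusive ±20 nm window around the
set wavelength, on the irradiance spectrum's own grid. Design choices:

* Negative differences are clipped to 0 and *flagged*, not errors — real
  dark frames fluctuate.
* Sweep points whose half-wavelength (second-order diffraction) falls in a
  channel's sensitive band are flagged as suspects rather than removed; the
  caller decides.
* The estimator measures the sensitivity *convolved with the emission line*
  (7.3 nm FWHM by default) and sampled every 5 nm. For band-like
  sensitivities (≥ ~50 nm FWHM) the recovery error is below 2% of peak;
  for curves with features at the few-nm scale it cannot be, and no window
  setting fixes that. Calibration truths in the tests are defined on a
  wider wavelength support (260–780 nm) so that their tails vanish smoothly
  instead of being cut at the working grid's edge, which would otherwise
  dominate the error budget with an artefact.

## Linearization and normalization

The encoding curve is logarithmic with a linear toe:
`r = c1·c2^x + c3` for `x ≥ c4`, `r = c5·x + c6` below, with an input scale
`s` applied to `x` first (for stills and video alike). Two numerical notes:

* The constants are applied exactly as configured. With the default
  constants the two branches do not meet exactly (a ≈ 0.007 jump in `r` at
  the break), so the decode curve is monotone *within* each branch but not
  across the boundary, and its inverse is taken branch-wise (values in the
  small overlap decode through the log branch). This is documented rather
  than "fixed" because the constants are data, not a curve we own.
* An 8-bit round trip (encode, quantize to 256 codes, decode) has a mean
  absolute error an order of magnitude below the theoretical quantization
  floor of the curve's steepest region — the inversion itself adds nothing.

Normalization regresses ideal catches of the grayscale standards (99% down
to 2% flat reflectance) on decoded pixel values, per channel, each session.
The alternative one-step power law `CC = a1·a2^p + a3` is fitted by
bounded Levenberg–Marquardt from five deterministic starts spanning
near-linear (`a2 → 1`) to strongly curved (`a2 ~ 8000`) regimes, keeping
the best residual; the two routes agree to within 1% of full scale on
synthetic grayscale data. Pixel values are handled in [0, 1] (8-bit codes
divided by 255).

## Card detection and patch statistics

The colour card carries four square binary fiducial markers whose bit
patterns are *data* (a dictionary in the layout file), required to be
rotation-asymmetric and mutually rotation-distinct so one detection fixes
both identity and orientation. Detection thresholds the frame (Otsu), finds
dark square candidate components, estimates each quad's corners from the
component's diagonal extremes, sharpens each edge with sub-pixel intensity
crossings (sampling along the edge normal and interpolating the mid-level
crossing — binary boundaries alone carry a systematic half-pixel bias), and
decodes the bit grid against the dictionary. The card-to-image homography
then comes from all 16 marker corners; corner reprojection stays below half
a pixel in the rendered tests. Bit cells need roughly 3 px on the sensor to
decode — small frames hold an alignable card but not a decodable one.

Patch sampling shrinks each rectangle by 25% per side before collecting
pixels (pastel dust contaminates patch borders on physical cards), reports
mean and 10%-trimmed mean, pixel count and saturated fraction, and flags —
rather than fails on — patches that project outside the frame. Detection
runs on the VIS frame only; the UV frame's patch positions come through the
alignment model, because markers need not be visible in UV.

## Alignment

Registration maximizes the enhanced correlation coefficient (ECC) between
intensity projections (UV frames project to their red channel, which
carries that camera's signal; VIS frames to the channel mean). The
optimizer is deliberately simple and derivative-free: an integer translation
grid search (run at half resolution when frames are large enough), then
Nelder–Mead over the motion parameters (translation, affine, or
homography), with one restart to guard against simplex collapse. Failure
(textureless input, vanishing overlap) is a *result*, not an exception,
because candidate fits on poor frames are expected and survivable —
candidates are scored by mean ECC over an evaluation batch and the best
wins, ties to the first index.

Temporal alignment scores motion as mean absolute inter-frame difference,
picks the most dynamic batch — preferring batches for which every candidate
offset keeps the UV indices in range, so no offset is silently excluded —
and evaluates a cheap translation candidate per offset before refining the
winner with the full motion model. The offset search is integer-only: the
cameras free-run, so up to half a frame of residual misalignment is
irreducible and frame interpolation would manufacture data. One structural
caveat the synthetic videos make explicit: if *all* scene motion is a
global translation, any offset error can be absorbed by the spatial
correction and the offset is unidentifiable; the simulator therefore pairs
a static card with an independently moving occluder, which is also the
realistic case (static background, moving subject).

Warping is bilinear with zero fill, and a validity mask rides along so
border fill never contaminates patch statistics. The ghost composite (VIS
red/blue + aligned UV green) is the human check: misalignment shows as
green/magenta fringing.

## The transformation and its diagnostics

`T` is ordinary least squares through the origin, one receptor at a time,
with no regularization — when animal catches truly are a linear map of
camera catches the fit is exact to machine precision, and rank deficiency
is an error carrying the condition number rather than a silent
pseudo-inverse. By default the fit uses four camera channels: the UV
camera's red channel plus the three VIS channels. The UV camera's three
bands are nearly collinear, and feeding all six channels invites
overfitting; a full-channel mode remains available.

Accuracy is reported per receptor as squared Pearson correlation (the
primary R², which measures linear association only — a fit on the wrong
slope can still score high) *and* as the coefficient of determination about
the 1:1 line, together with MAPE, RMSPE (≥ MAPE always, by the power-mean
inequality) and the inner-75% band of signed errors (12.5th–87.5th
percentiles, linear interpolation). Train/test splits are seeded
permutations, 90/10 by default (2244/250 on a 2494-spectrum library).

RNL distances use the receptor-noise-limited model on log catches: closed
forms for di-, tri- and tetrachromats plus a general-n quadratic form (the
noise-weighted metric projected orthogonally to the achromatic axis) that
coincides with the closed forms and supplies the metric for any receptor
count. Noise parameters are viewer configuration, not package constants —
the featured values in the literature are measurement-derived and
species-specific, so hard-coding them would lend false authority.

## The synthetic simulator: what it does and does not show

The simulator is the package's ground truth: seeded Gaussian-mixture
reflectance libraries, camera and receptor curves, rendered frames and
videos, and monochromator sweeps. All randomness flows through one explicit
seeded generator object; nothing touches or depends on the caller's RNG
state. Conditions worth knowing:

* **Library smoothness.** Spectra are mixtures of 1–3 Gaussians
  (FWHM 90–260 nm) plus occasional sigmoid edges, bounded in [0, 1]. These
  widths match the broad, low-dimensional character of natural floral and
  material spectra; with much narrower components the camera-to-receptor
  map degrades for receptors near the inter-camera gap, which is a genuine
  property of the method, not of the code.
* **Camera.** The UV channels peak near 355 nm (FWHM ~70 nm) under a
  shortpass cut at 390 nm and a silicon deep-UV roll-off near 330 nm; the
  VIS channels cover 425–700 nm with the red band reaching 700 nm. The
  390–425 nm gap between the cameras is the rig's signature and produces
  the characteristic dip in the accuracy-vs-receptor-peak sweep.
* **Example viewers.** The bee-like trichromat uses template receptors at
  344/436/544 nm, with the UV receptor's deep-UV flank rolled off — the
  real honeybee UV receptor is narrower and less far-UV-sensitive than the
  generic template, and modelling it as the raw template would overstate
  the far-UV demand on the camera. The bird-like tetrachromat uses
  370/445/508/565 nm templates.
* **Rendering.** Patches are painted in linear catch units, encoded,
  quantized to 8 bits, warped by the scene misalignment and degraded with
  additive Gaussian read noise in encoded units (shot noise is not
  modelled; additive noise is the simplest model that exercises the
  calibration). Supersampled box filtering provides the antialiased edges
  the sub-pixel detector expects from a real sensor.
* **Not modelled:** shadows, speculars, interreflections, geometry — the
  reasons real natural-object accuracy is lower than colour-standard
  accuracy. Passing closed-loop tests therefore demonstrate the *pipeline*
  is correct and stable under noise, misalignment and quantization; they do
  not promise field accuracy on 3-D scenes.

### Problem sizes in the checks

The shipped benchmarks run 40 seeded alignment trials on 96×128 px,
10-frame videos with offsets up to ±3 frames and affine misalignments up to
±4 px; end-to-end catch recovery uses 144×192 px frames, a 24-patch card
and a 2494-spectrum library; the peak sweep uses a 1200-spectrum library at
a 90/10 split. These sizes make the full suite run in minutes on one core
while keeping every stage (marker decoding included) in its operating
regime; real frames are an order of magnitude larger and only easier to
register and decode.

## Pipeline engine and interfaces

Operations are registered functions; pipelines are JSON-serialized DAGs
(`{version, nodes:[{id, op, params}], edges}`) with a cycle check at load,
strict rejection of unknown parameters (catching typos beats forgiving
them), deterministic topological order with ties broken by node id, and
frame streams processed in batches whose size never affects results. Videos
are handled as in-memory frame lists or image-sequence directories; linear
catch outputs do not survive 8-bit media, so false-colour renders carry a
JSON sidecar recording mapping and gamma, and quantitative work stays in
the catch domain.

## Known limitations

* Marker decoding needs ~3 px per bit cell; the detector reports which ids
  it found when it fails, but does not attempt super-resolution.
* ECC refinement is local; it needs the coarse homography (or the integer
  search radius) to land within a few pixels of truth.
* The A2 template, the RNL colour key, and the tetrachromat UV overlay
  weight are documented conventions where the underlying literature is
  qualitative; tests assert qualitative behaviour (hue families, scale
  invariance), not pixel equality.
* Catches below the camera's spectral reach (receptor peaks under
  ~340 nm) are extrapolations of `T` and degrade smoothly but genuinely —
  the accuracy sweep exists so users can see exactly where their viewer
  falls.
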