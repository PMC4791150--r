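---
title: "Calibrated multispectral imaging: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated multispectral imaging: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multispec)
```

## The problem

Consumer cameras are built to make pictures for human viewing, not
measurements: their output is gamma-encoded, white-balanced and clipped,
so raw pixel values cannot be compared across photographs or mapped onto
an animal's photoreceptor responses. `multispec` implements the standard
calibration chain used in visual ecology: linear 16-bit channel images
are combined into an aligned multispectral stack, normalised to
reflectance against grey standards of known reflectance, optionally
converted to photoreceptor quantum catches ("cone catches") via fitted
polynomial mapping models, and finally measured — mean reflectance and
colour per region, receptor-noise-limited colour distances (JND), and
spatial-frequency (granularity) pattern statistics.

All processing after ingestion happens on floating-point images. Nothing
is ever clipped at the 100% reflectance level: shiny, fluorescent or
emissive surfaces legitimately exceed it, and one design rule throughout
the package is that values above 1 and below 0 survive every stage until
a stage exists that mathematically requires non-negativity (cone-catch
application, which floors negatives at zero and warns).

## Linear ingestion

The package ingests 16-bit linear TIFF (and PNG) images. Linearity is a
*contract of the decoder*, not something re-derived here: camera RAW
files must be converted externally (dcraw or an equivalent, configured
for linear output, no auto-brightening, white balance off, 16-bit) and
the result handed to `load_linear_image()`. Files that are 8-bit are
rejected outright — quantising a linear scene to 256 levels destroys the
dark end of the reflectance distribution. The `linearity_experiment()`
function exists to *certify* this contract: it photographs (synthetically)
a row of eight diffuse standards at 2, 5, 10, 20, 40, 60, 80 and 99%
reflectance across several exposures, multiplies stated reflectances by
the pooled standard response of each photograph to put all exposures on
one expected scale, and regresses observed on expected pixel values per
channel. A linear sensor gives R² ≈ 1; a deliberately gamma-distorted
synthetic camera drops visibly below 0.998, which is the practical
pass/fail line we use in the test-suite.

## Normalisation to reflectance

Reflectance is represented internally on a 0–1 scale; the 16-bit value
65535 is the serialisation level of 100% reflectance and enters only
when exporting previews (`reflectance_to_16bit()`). With a single
standard of stated reflectance $S$% and measured mean pixel value $G$,
normalisation is proportional: a pixel $V$ maps to $(S/100)\,V/G$ — the
classic grey-standard rule, a line through the origin. With two or more
standards an ordinary least-squares line of reflectance on pixel value
is fitted per channel, adding an intercept that estimates the
photograph's black point (veiling glare raises it). With three or more
standards the fit R² is recorded and a warning is emitted below 0.98 —
the conventional screening threshold for a photograph whose response is
not usably linear.

Two further normalisation routes exist:

* **Histogram dark point** (`estimate_dark_point()`): with only one
  standard but suspected glare, the pixels at or below the channel's
  0.5th percentile are averaged and assigned a reflectance of 0.5%, and
  the channel's line runs through this dark anchor and the standard.
  The absolute minimum pixel is deliberately not used — it is the most
  noise-contaminated order statistic. Whether to average the bottom
  tail or take the percentile value itself is ambiguous in the
  literature; we average, which is less noisy, and note that the scene
  must actually contain near-black content for the heuristic's
  assumption to hold.
* **Sequential method** (`sequential_normalize()`): standards measured
  in a *separate* frame shot under identical conditions. Its failure
  mode is multiplicative: a standard frame photographed under a
  2×-brighter illuminant biases every recovered reflectance by 0.5.
  The test-suite demonstrates exactly this, because users of the method
  need to know it fails silently.

Regression direction is reflectance-on-pixel, so prediction is direct.
The 0.5% histogram percentile is computed over all channel pixels,
standards included.

## Quantum catches and von Kries adaptation

A receptor's (or camera channel's) quantum catch for a surface with
reflectance $Q_\lambda$ under illuminant $I_\lambda$ is
$\sum_\lambda l_\lambda Q_\lambda I_\lambda$ over a 1-nm integer
wavelength grid with inclusive bounds (`cone_catch()`). The package
*requires* the 1-nm grid rather than weighting coarser grids; curves on
coarser grids are linearly interpolated on load
(`read_spectra_csv()`, `resample_to_grid()`). Outside a curve's measured
range values are zero-filled, never extrapolated — sensitivities are
physically zero outside their band.

Catches are then scaled by the catch of an ideal flat 100% white under
the same illuminant (`von_kries_normalize()`), the coefficient-law
chromatic adaptation that makes any spectrally flat grey yield equal
values in all channels. Both properties — white maps to exact ones, and
greys are channel-uniform — are asserted in the test-suite to machine
precision, since the entire cone-mapping stage conditions on them.

## Camera-to-receptor polynomial mapping

Camera colour space is device-dependent, so per-receptor polynomials in
the normalised camera quanta are fitted against receptor quanta computed
from a reflectance spectra library under a chosen illuminant
(`build_training_table()`, `fit_cone_map()`). Term sets
(`polynomial_terms()`) are all single channels, pairwise products at
interaction level 2, triple products at level 3, and optional squares —
and **no intercept**: a camera in the dark must predict zero catch. Fit
R² is therefore computed against the uncentred total sum of squares
(the centred version would be inconsistent with a no-intercept model;
the choice is fixed and documented here).

Backward stepwise simplification (optional, AIC or BIC) greedily removes
the single term whose removal most improves the criterion, stopping when
nothing improves; ties break by term label order so the procedure is
deterministic. BIC's heavier penalty removes more terms — asserted
statistically over repeated synthetic fits rather than per-fit, since
individual datasets can tie. We read "stepwise" as single-term greedy
steps; fitting is done internally by QR least squares rather than by
delegating to an external statistics process, which makes model files
(`write_cone_map()`) exactly reproducible from their provenance.

The mapping requires at least as many camera channels as receptors, and
at least twice as many library spectra as terms. The package's
validation experiment — 3000 smooth synthetic spectra, the 5-channel
synthetic camera, a 4-receptor avian-like system, level-2 interactions —
yields per-receptor training R² above 0.999, consistent with the
well-established result that natural (smooth) spectra map almost
perfectly through low-order polynomials. Metamerism cannot be ruled out
by any such fit; R² only bounds the error *on spectra like the library's*.

## Channel alignment

Channels come from separate exposures; filter changes knock the camera
and refocusing between wavebands zooms the image slightly. Alignment
minimises the absolute pixel difference between a fixed and a moving
channel over a 3×3 grid of candidate offsets whose spacing starts at a
power of two (default 128 px) and halves to 1, recentring on the best
candidate at each spacing until the incumbent is the local minimum
before halving (`align_translation()`). A scale factor is searched by
hill climbing: perturb by ±step, fully re-align in translation, keep
improvements, halve the step otherwise, stop below 0.001 — the printed
descriptions of such searches never state a termination tolerance, and
0.001 is our choice, comfortably finer than the 0.005 scale accuracy the
recovery tests demand. Ties prefer the scale nearer 1 and the smaller
offset, deterministically.

Two deliberate deviations from the naive reading of "sum of absolute
differences across the whole image":

* The cost is the **mean**, not the sum, over the overlap region —
  a raw sum rewards large offsets that shrink the overlap.
* Sub-unity scaling uses **bilinear** interpolation about the image
  centre, with out-of-footprint pixels `NA` (excluded from the cost).
  The resampler is written in the package rather than delegated to an
  image library because the search needs exactly centre-anchored,
  NA-padded semantics for its cost to be comparable across scales.

The hierarchical search can stall on textures whose cost basin is
narrower than the coarsest probe spacing (periodic or very rough
content). The full search trace is returned for inspection, and
`align_exhaustive()` provides a guaranteed-optimal enumeration for
small images; the test-suite proves equality of the two on smooth
textured fixtures with displacements within the start offset. Rotation
and shear are out of scope, as is feature-point registration, which is
unreliable between UV and visible channels.

## Granularity pattern analysis

`granularity_spectrum()` decomposes a channel into isotropic
spatial-frequency bands — ideal annuli in Fourier space whose
boundaries are the geometric means of adjacent band sizes (octave
series 2, 4, …, 512 px by default; the outermost edges extend by the
same ratio) — and records each band's *energy*, the standard deviation
of the bandpass-filtered image over the measured region. A sine grating
of amplitude $a$ lands in the band containing its period with energy
$a/\sqrt2$, which the tests verify against a space-domain oracle. For
non-rectangular regions, pixels outside the region are filled with the
region mean before the transform (suppressing edge ringing) and the
standard deviation is taken over in-region pixels only. Bands larger
than the region's extent are flagged unreliable rather than dropped.

Pattern statistics are intentionally simple descriptors: total energy
(contrast), dominant band size (marking size; ties toward the smaller
band), proportion of energy at the dominant band, and a diversity count
(bands holding at least half the dominant energy). The diversity
statistic in particular is *our interpretation* of pattern-diversity
descriptors in the granularity literature, which rarely print a
formula. Pairwise pattern difference is the sum of absolute per-band
energy differences; it requires identical band sets **and** identical
pixels-per-mm, because energies at mismatched scales compare different
physical frequencies — `rescale_to_uniform()` (bilinear, driven by
scale bars recorded with `set_scale_bar()`) exists precisely to put a
batch on one scale first.

## Receptor-noise-limited discrimination

Colour distances use the standard receptor-noise-limited model in its
log-linear, neural-noise-only form: receptor signals are natural logs
of von-Kries-normalised quantum catches, so the contrast between two
stimuli is $\Delta f_i = \ln(q_i^a/q_i^b)$, and channel noise $e_i$ is
independent of light level. Which noise regime (neural vs quantum) a
given field tool uses is often unstated; this package pins the
neural-only variant and says so, because the two diverge at low light.
Di-, tri- and tetrachromatic closed forms are implemented
(`chromatic_jnd()`); more than four receptors is an error rather than a
silently generalised formula. Achromatic contrast is
$|\ln(a/b)|/\omega$ (`achromatic_jnd()`). Weber fractions — given
directly or derived from relative receptor abundances as
$e_i = \omega_{\mathrm{ref}}\sqrt{\eta_{\mathrm{ref}}/\eta_i}$ — are
user-supplied properties of the modelled visual system, not outputs of
this package. Distances are invariant to scaling both stimuli by a
common factor (the log-ratio/von-Kries property), and the dichromat
form is the infinite-noise limit of the trichromat form; both are
asserted in tests.

## The synthetic scene renderer

Every pipeline stage is validated against `render_scene()`, which is a
first-class, tested component, not a fixture dump. A scene is a canvas
of rectangular patches with spectral reflectances (grey standards are
flat spectra at stated levels). Per channel and pixel the linear signal
is quantum catch × exposure × gain, plus a veiling-glare offset, with
Gaussian noise of sd $a + b\,\mathrm{signal}$ applied and the result
quantised to 16 bits with saturation at 65535. Channel gain is
auto-calibrated so flat white hits a target count (60000 by default) at
exposure 1 — the synthetic analogue of exposing so the white standard
sits just below saturation. Defaults ($a = 2$ counts, $b = 0.01$, i.e.
1% signal-proportional noise, no glare, gamma 1) reflect a well-behaved
consumer sensor at moderate ISO; shot noise is modelled only through
the signal-proportional term. The renderer also emits ground truth:
ideal normalised camera reflectance images and, on request, ideal
receptor-catch images, enabling pixelwise R² recovery tests
(render → normalise → cone-map recovers truth with R² > 0.99 at default
noise).

The synthetic reflectance library (`generate_spectra_library()`) draws
logistic transforms of sums of 2–5 broad Gaussian bumps (widths drawn
from [smoothness, 3 × smoothness] nm, default smoothness 40 nm), which
reproduces the one property of natural spectra the mapping stage relies
on — smoothness — while guaranteeing values in [0, 1]. What it does
*not* emulate: sharp absorption edges, fluorescence, specular spikes,
or the empirical abundance distribution of natural colours. Passing
mapping tests on this library therefore demonstrates the fitting
machinery, not field accuracy for any particular taxon; users with a
measured spectra library should load it via `read_spectra_csv()` and
refit. Likewise the bundled `synthetic_camera()` and
`avian_receptors()` sensitivities are smooth unimodal stand-ins, not
measurements of any real device or retina.

## Problem sizes and numerical choices

The test-suite and the acceptance script run entirely on synthetic
data sized for a single CPU: scenes up to 104×104 px, alignment
fixtures 64–96 px with displacements within ±8 px and start offsets of
8–16 px, 3000-spectrum mapping tables, 20-fixture oracle comparisons.
These sizes were chosen so the whole suite completes in well under a
minute while every statistical assertion retains a comfortable margin;
none of the thresholds were derived from the fixtures.

Other fixed numerical choices: wavelength grids are integer nm with
inclusive endpoints; polygon rasterisation is pixel-centre-inside with
the even-odd rule (coordinates 0-based, origin top-left, `(dx, dy)`
applied to the moving channel); pooled regions are unified as a set
union so overlaps count once; region statistics use the sample
standard deviation; project files are documented JSON rather than an
opaque binary sidecar, so a serialised project rebuilds a pixel-identical
stack — asserted in tests.

## Known limitations

* No flat-field/vignetting correction and no exposure-metadata
  radiometric scaling between frames.
* No demosaicing, lens-distortion correction, rotation/shear alignment,
  or orientation-selective pattern filtering.
* The dark-point heuristic assumes the scene contains near-black
  content; on scenes without it the 0.5% anchor is biased bright.
* Cone-mapping quality is conditional on the training library; R² on
  smooth spectra says nothing about spiky or fluorescent stimuli.
* JND computations assume strictly positive quanta; true zeros must be
  handled upstream (the normalisation flooring policy).
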