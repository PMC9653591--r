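---
title: "Statistical pixel-pitch calibration of fundus cameras"
author: "fundusPitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical pixel-pitch calibration of fundus cameras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusPitch)
```

## The problem

Quantitative measurements on retinal photographs — vessel calibres,
optic-disc morphology, lesion areas — are only comparable across
cameras if each image's *pixel pitch* (how many micrometres of retina
one pixel spans) is known.  The ISO 10940:2009 procedure measures it by
photographing a graduated target, but the calibration images of the
camera that took a given clinical photograph are almost never
available.  This package implements a statistical alternative: the
pitch is inferred from the photograph itself, using two structures that
every macula-centred 45° fundus image contains — the circular
illuminated region of interest (ROI) and the optic disc.

## The model

**Reduced eye.** The eye is modelled as a single refracting surface
with first focal length $f_1 \approx 17$ mm.  In an emmetropic eye the
retina lies in the second focal plane and the camera-plus-eye system is
a telescope.  Axial ametropia of $D$ diopters displaces the retina by

$$\Delta d = -\frac{f_1^2 D}{1 + f_1 D} \qquad (f_1 \text{ in m}),$$

so a myopic eye of about $-3.3$ D corresponds to $\Delta d \approx
1$ mm, which changes the image magnification by $\Delta d / f_1
\approx 5.9\%$.  At the population mean refraction of $-0.559$ D the
bias is below 1%, which is why cohort-level averages can ignore it; a
per-image correction $P' = P\,(f_1+\Delta d)/f_1$ is available when the
diopter is known.

**The calibration constant.** The physical ROI diameter on the retina
is the arc $L_{ROI} = \alpha (f_1 + \Delta d)$ spanned by the field of
view $\alpha$, so it is essentially fixed for all 45° cameras, while
the physical optic-disc diameter $L_{disc}$ varies between people but
has a stable population mean (~1.9 mm).  Consequently the
pixel-measured ratio

$$r = l_{ROI} / l_{disc}$$

is approximately constant per camera (and nearly so per field of view),
and inverting it gives the pitch around the disc:

$$P_{disc} = \frac{r\,L_{disc}}{l_{ROI}}, \qquad
U_{P} = P_{disc}\sqrt{\left(\tfrac{U_r}{r}\right)^2 +
\left(\tfrac{U_L}{L_{disc}}\right)^2 +
\left(\tfrac{U_l}{l_{ROI}}\right)^2}.$$

The workflow has two phases.  *Offline*: measure $l_{ROI}$ and
$l_{disc}$ over a large cohort from one camera (or one FOV class) and
store the mean and population standard deviation of the per-image
ratio.  *Online*: measure only $l_{ROI}$ of a new image and apply the
stored ratio and the anatomical prior.

**The anatomical prior.** $L_{disc}$ comes from a DerSimonian–Laird
random-effects pooling of seven published population studies of the
vertical disc diameter (the vertical axis is used because the
farthest-pair diameter of an irregular disc tracks its major axis):

```{r}
pool <- poolRandomEffects(opticDiscStudies())
pool
```

The pooled 1.921 ± 0.026 mm is the package's default prior.  We chose
plain DerSimonian–Laird (no Knapp–Hartung adjustment) because it
reproduces both the pooled value and the per-study relative weights of
the published analysis to within 0.04 percentage points; no
between-study variance reproduces those weights more closely, so the
residual is attributable to rounding in the published table.  Studies
reporting only a disc area can be converted with
`diameterFromArea()` ($d = 2\sqrt{A/\pi}$).

## Image analysis

**ROI detection** (`detectROI()`): the red channel (the brightest in
fundus photographs) is thresholded at one third of its whole-frame
mean; the largest 8-connected component is the ROI candidate; a Canny
edge map of that binary mask (so retinal texture cannot contribute
edges) feeds a gradient-voting circular Hough transform.  Because the
circle is often cropped top and bottom by the sensor, edge pixels
within 2 px of the frame border are excluded — they trace the frame,
not the circle — and the surviving arcs still vote for the true centre.
Defaults the source publication leaves open: Canny hysteresis at
0.1/0.3 of the maximum gradient magnitude, radius search over
[0.25, 0.75] of the larger frame dimension in 1 px steps, ties broken
towards the larger radius and then the centre nearest the frame centre,
and acceptance requiring at least 20% of edge pixels to support the
winning circle.  The accumulator is quantised to whole pixels, so the
winning circle is refined by an iterated least-squares (Kåsa) circle
fit on its supporting arc; this brings full-circle accuracy to ~0.5%
and keeps the estimate scale-equivariant.

**Disc measurement** (`measureDisc()`): a pluggable locator supplies an
approximate disc centre; the default classical strategy takes the
centroid of the brightest connected region of the median-smoothed
red+green mean inside the ROI (excluding a 5% frame margin, with a
small morphological closing so vessels crossing the disc do not split
the region).  Any external detector can be substituted as
`locator = function(image, ...) c(x, y)`.  The image is then resampled
on a polar grid around that centre (360 angles, 1 px radial step, out
to three times the expected disc radius) and Canny edges are detected
in polar coordinates, where the disc boundary is a single-valued curve
$r(\theta)$.

Per angular column one radius is selected.  We deliberately score
candidates by the strongest *outward-darkening radial* gradient rather
than raw gradient magnitude: the disc boundary is a bright-to-dark
transition along the radius, whereas vessel side-edges run radially and
carry mostly angular gradient, so the radial criterion suppresses them.
Radii below 0.45 of the expected disc radius are excluded (near the
polar origin a vessel a few pixels wide subtends an enormous angular
range), and the selected radii pass two consistency gates: deviation
from the global median by more than 35% of the median, and deviation
from a circular running median (window 11) by more than
max(1.5 px, 5%) — isolated spikes where a vessel crosses the boundary
would otherwise dominate the farthest pair.  Smooth elliptical
variation passes both gates; we verified the recovered $r(\theta)$ of a
synthetic ellipse against its closed form to 0.3 px RMS.

**Circumscribed circle** (`fitCircumscribedCircle()`): the disc
diameter is defined as the *largest pairwise distance* among the edge
points, with the centre at that pair's midpoint.  This is intentionally
not the minimum enclosing circle: the farthest pair tracks the major
axis of an irregular disc.  The pair is found exactly (convex-hull
reduction for large point sets, with near-maximal candidates
re-evaluated in exact arithmetic), with ties broken towards the
lexicographically smallest index pair.

## The synthetic cohort generator

No image cohort is distributed with the method, so validation uses the
seeded generator in `renderFundus()`/`sampleCohort()`.  It emulates the
statistical structure the method relies on: a per-camera stable ROI
diameter (four camera profiles with the published frame sizes, ROI
means/spreads, and ISO pitches; the Zeiss- and Newvision-like frames
crop the circle top and bottom), a normal population of physical disc
diameters (1.921 ± 0.19 mm, truncated at ±3 sd), a normal diopter
population (−0.559 ± 3.522 D, truncated at ±10 D) whose defocus
rescales each eye's pitch through the reduced-eye model, a
macula-centred layout with the elliptical disc (vertical major axis,
minor/major 0.9) at 0.55 ROI radii lateral offset, dark vessel strokes
radiating from the disc, radial shading, and additive Gaussian noise.
`cohortRatioExpectation()` integrates the generator's own
distributions numerically, giving an analytic mean and sd of the
per-image ratio to test cohort recovery against.

What it does **not** emulate: retinal texture, illumination gradients
and reflex artefacts, pathology, lens-distortion fields (a radial
term exists but is off by default because no published
parameterisation exists), and realistic vessel trees.  Passing tests
on synthetic cohorts therefore demonstrate the correctness of the
geometry, statistics and detection logic — not clinical-grade
robustness on real photographs.

Cohort problem sizes used by the test suite were fixed once:
statistics-level checks use 2000 measurement pairs; rendered
full-pipeline checks use 100-image cohorts at five seeds on a
geometrically 0.2-scaled Canon-like profile (595 × 397 px frames,
ROI ≈ 361 px, true pitch scaled inversely), where the full chain
recovers the true pitch to within 5% with the method's own ametropia
exclusion (|D| > 6 D) applied.  Per-image disc accuracy is ±2% on
vessel-free circular discs; a vessel crossing the boundary genuinely
displaces the local edge, so with vessels the per-image bound tested
is 5%, matching the pipeline-level claim.

## Numerical and interface conventions

* Lengths in mm, pitch in µm/px, angles in radians internally (the CLI
  accepts degrees); the $f_1 D$ product is evaluated with $f_1$ in
  metres.  Magnification bias is defined as $\Delta d/f_1$.
* Pixel coordinates are 0-based, (x, y) = (column, row), pixel-centre.
* All cohort standard deviations are population (1/n) deviations.
* The offline ratio is the mean of per-image ratios; the ratio of mean
  diameters is reported alongside (`rOfMeans`) for transparency.
* Images failing either detector are excluded offline, as are eyes
  with |D| > 6 D when diopters are supplied (the exclusion threshold
  is configurable; no published value exists).
* Comparisons against published tables round intermediate pitches to
  3 decimals before differencing, mirroring how those tables were
  printed; `pitchBias(digits =)` controls this.
* Canny thresholds are relative to each image's maximum gradient, so a
  featureless raster yields no edges; genuinely weak-contrast images
  are instead rejected by the vote gate ("ROI not found") or the
  column gate ("edge too weak").

## A worked example

```{r, eval = FALSE}
prof <- defaultCameraProfiles(scale = 0.2)$canon
co <- sampleCohort(prof, n = 100, seed = 1, render = TRUE)

offline <- runOffline(co$images, scope = "canon",
                      diopters = co$truths$diopterD)
offline$stats

est <- runOnline(co$images[[1]], offline$stats,
                 discPrior(poolRandomEffects(opticDiscStudies())),
                 scenario = "camera-specified")
est
```

## Known limitations

* The classical disc locator assumes the disc is the brightest
  structure; bright pathology (exudates, atrophy) would defeat it —
  that is what the pluggable locator interface is for.
* The pitch is calibrated *around the disc*; lens distortion makes the
  frame-wide pitch larger towards the edges, and no distortion field
  is estimated.
* The FOV-specified scenario inherits any between-camera distortion
  differences as bias (the published comparison bounds it at ~5%).
* The farthest-pair diameter is an extreme-value statistic; its
  robustness relies entirely on the edge-selection gates described
  above.
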