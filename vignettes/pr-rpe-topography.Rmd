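---
title: "Quantifying PR-RPE complex topography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PR-RPE complex topography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Cone photoreceptors (PR) and the retinal pigment epithelium (RPE) form a
functional unit whose cellular architecture varies systematically across the
macula. Cellular-resolution retinal imaging (adaptive optics OCT and related
modalities) resolves both mosaics and, in depth-resolved volumes, the paired
axial reflections of each cone — the inner/outer segment junction (IS/OS)
and the cone outer segment tip (COST) — from which the outer segment length
(OSL) of individual cones can be measured. `aomosaic` implements the
quantification side of such a study: mosaic metrics, per-cone axial
measurements, magnification scaling, topographic model fits, and
reproducibility statistics, together with a synthetic data generator that
makes every stage testable by parameter recovery.

```{r setup}
library(aomosaic)
```

## The normative topographic models

Three eccentricity relationships, with eccentricity $E$ in degrees temporal:

* **Cone density** follows a power law $D_{PR}(E) = a\,E^{b}$, with defaults
  $a = 53{,}329$ cells/mm$^2$ (the 1° density) and $b = -0.731$, chosen so
  that the curve passes through 8,669 cells/mm$^2$ at 12°. The power law is
  evaluated from 1° outward: at the fovea individual cones are not resolved
  by the imaging this emulates, so the generator and pipeline leave cone
  metrics undefined there.
* **RPE density** declines linearly, $D_{RPE}(E) = 6913 - 123\,E$
  (cells/mm$^2$, intercept at the fovea).
* **OSL** follows a second-order polynomial through 33.3 µm at 1° and
  18.0 µm at 12°. Two points do not fix a parabola; the third constraint is
  monotone decrease over 1–12°, which we realize by placing the vertex at
  12° (zero slope at the far endpoint):
  $\mathrm{OSL}(E) = 36.208 - 3.0347\,E + 0.12645\,E^2$ µm. The mid-course
  of this curve is a modeling choice, not ground truth; all three
  coefficients are exposed in `cohort_spec()` and can be replaced.

```{r models}
models <- default_topography_models()
eval_topography_model("osl", c(1, 6, 12), models)
```

## The synthetic mosaic generator

Cell mosaics are jittered hexagonal lattices: points on a lattice whose
spacing $a = \sqrt{2 / (\sqrt{3} D)}$ matches the requested density, rotated
by a seeded random angle, each point perturbed by isotropic Gaussian jitter
(default SD $0.10\,a$). A hexagonal base is essential — cone and RPE mosaics
are quasi-crystalline, and only a quasi-regular arrangement produces the
annular spectral peak (Yellott's ring) that the power-spectrum density
estimator relies on. A Poisson process would not.

Two realism constraints matter downstream:

* **Hard-core separation.** Jittered points are re-drawn until all pairs are
  at least $0.5\,a$ apart (default). Cells are packed somata, nearly
  space-filling; real mosaics do not contain center pairs at half a spacing.
  Without this constraint a Gaussian jitter occasionally places two cells so
  close that their reflectance spots merge into one blob, which no
  intensity-based detector can split.
* **Multiplicative speckle.** Images and volumes are corrupted by lognormal
  multiplicative noise of configurable coefficient of variation (default
  0.15 in the pipeline). This is the simplest model that produces realistic
  contrast variation; it does not simulate coherent interference.

What the generator does *not* emulate: rod photoreceptors and the rod outer
segment tip band (the study design this mirrors quantified cones only),
eye-motion artifacts, residual illumination gradients, cone-to-cone
reflectance variability, and grader disagreement beyond a simple
multiplicative noise model. Passing recovery tests on these synthetics
therefore demonstrates correctness of the *measurement chain*, not
robustness to every pathology of real imaging.

Vessel shadows — dark bands under retinal vessels where cells cannot be
counted — are drawn as smooth curvilinear bands of configurable width and
excluded identically from Voronoi counting (any cell polygon touching the
mask) and from spectral analysis (masked pixels replaced by the image mean).

## Mosaic metrics

`voronoi_metrics()` tessellates the cell centers inside a rectangular
analysis window (implemented as half-plane clipping with labeled edges, so
each finished polygon knows its neighbors and whether it touches the window
boundary). Cells whose polygon touches the boundary or intersects the vessel
mask are excluded; density is the number of included cells divided by their
summed polygon area. Using the summed *polygon* area rather than the window
area removes the bias of partially observed boundary cells — the standard
convention in the cell-mosaic literature. Cell-to-cell spacing is averaged
over Voronoi-adjacent included pairs, which is the natural definition of
"cell-to-cell" under a tessellation analysis (k-nearest-neighbor spacing
would systematically read low, as discussed for the jitter order statistics
below).

`power_spectrum_density()` provides the independent spectral estimate: mean
subtraction, 2-D Hann window, FFT power, radial averaging, then the highest
radial peak within $[0.3, 2] \times f_{\mathrm{exp}}$, where
$f_{\mathrm{exp}}$ derives from an expected-density hint (the band guards
against DC leakage below and harmonics above; the hint is a required input).
The ring radius $f$ (the hexagonal row frequency) converts to density as
$D = (\sqrt{3}/2) f^2$ — the constant is verified in the test suite against
the analytic lattice oracle, since conventions differ in the literature. The
peak is refined by 3-point parabolic interpolation.

On small windows the spectral estimate reads low relative to the Voronoi
density: the windowing kernel smears the ring, and radial averaging of a
smeared ring (whose power is divided over annuli growing as $f$) skews the
detected peak toward lower frequencies, hence lower densities. At 128 µm
windows and 5–15k cells/mm$^2$ the deficit is about 1.5–2%; at the 256 µm
windows used in the density-comparison experiment it shrinks to ~0.2%,
smaller than the seed-to-seed scatter of the regression slope (~0.3%), so
the fitted slope of spectral on Voronoi density sits at 1.000 within
sampling error there. The pronounced underestimation reported on real
imagery reflects additional image imperfections (background structure,
irregular mosaics) that the generator deliberately does not model.

## Cell detection

`detect_cells()` is a deterministic classical stand-in for learned cone
detectors, adequate for synthetic imagery: a difference-of-Gaussians
band-pass tuned to the expected spacing ($\sigma_1 = 0.125 \times$ spacing
in pixels, surround $2\sigma_1$ — the center is chosen *below* the rendered
spot width so that cells jittered to ~0.6 spacing remain separable), strict
local maxima above a configurable intensity quantile (default 0.80),
non-maximum suppression at $0.6 \times$ spacing, and subpixel refinement.
The minimum-separation contract is re-applied after refinement so it holds
exactly. On rendered mosaics across the study's density range the detector
achieves recall ≥ 0.99 and precision 1.0 up to speckle CV 0.2, and Voronoi
density from its detections lands within 1% of generator truth. There is no
manual-correction stage; raw detector output flows downstream.

## Volumes and per-cone OSL

`render_volume()` builds miniature outer-retina volumes: per cone, two
axial Gaussian reflections (default FWHM 8.4 µm, a typical coherence-gated
axial resolution) at the IS/OS depth and at IS/OS + OSL, with per-cone OSL
optionally drawn $N(\mathrm{mean}, \mathrm{SD})$; a brighter continuous RPE
band deeper; optional per-column tilt; speckle. `flatten_volume()` finds the
brightest axially smoothed band per column, median-filters the depth map,
and shifts columns to a common depth (integer shifts, returned for exact
inversion). `extract_enface()` projects slabs (the RPE slab default spans
2–3 axial pixels; the cone image averages the IS/OS and COST slabs).

`measure_osl()` implements the per-cone measurement: average A-scans over a
3×3 lateral neighborhood (speckle suppression without cross-cone
contamination at ≥ 6 µm spacing), find the two dominant local maxima above
the RPE guard band under a minimum-separation constraint (default 8 µm),
refine each by 3-point parabolic interpolation, and report the separation
times the axial pixel size. OSL is defined peak-to-peak — edge-based
definitions read systematically lower and are not comparable. Records with
fewer than two distinct peaks are flagged invalid rather than dropped.
Exact sampling ties (a peak centered midway between two axial samples)
count as one plateau peak, and the parabolic step lands mid-plateau. At
axial pixel 1 µm and speckle CV 0.15 the measurement is unbiased within
0.1 µm; note that two reflections of FWHM 8.4 µm separated by ≤ ~12 µm
genuinely pull each other's intensity peaks together, so construction
oracles in the tests use narrow peaks where exactness is asserted.
Distribution summaries report mean, SD and a bimodality flag (Sarle's
coefficient > 0.555), since some eyes show bimodal OSL at some locations.

## Magnification scaling

All physical units pass through the small-angle schematic-eye relation
$q = 0.01306\,(AL - 1.82)$ mm/degree, where $AL$ is the axial length in mm
and 1.82 mm the distance from the second nodal point to the anterior
retina. With a 2° field sampled at 512 A-scans this reproduces published
per-eye lateral pixel scales to the printed three decimals for 8 of 11
reference eyes; the remaining rows require refraction data the simple
relation does not use, and no refraction-corrected variant is attempted.
`samples_per_fov` defaults to 512 but remains configurable.

## Topographic fitting

`fit_topography()` fits power, linear, or second-order polynomial models by
least squares (the power fit via `nls`, initialized from log–log
regression). Goodness of fit is reported as squared Pearson and squared
Spearman correlations of observed versus predicted, with Spearman on the
raw $(E, y)$ pairs reported separately and labeled — published reports are
ambiguous about which convention a quoted $R_s^2$ uses, so both are always
available. p-values are two-sided for the Pearson correlation; no
multiple-testing correction is applied. Constant responses yield a flagged
degenerate fit rather than an error.

The cohort table fits the *mean* data per eccentricity (power for cone
density and PR/RPE ratio from 1° outward, linear for RPE density including
the fovea, polynomial for OSL). The PR/RPE curve uses per-subject ratios
averaged per eccentricity (mean of ratios); the ratio of cohort means is
reported alongside, and the two coincide as between-subject variation
vanishes. Note the distinction matters at the printed precision: cohort
mean densities of 8,669 and 5,547 cells/mm$^2$ at 12° give a
ratio-of-means of 1.56, while the mean of per-subject ratios can round to
1.5. Per-subject RPE slopes are also fitted and serialized — for a cohort
with multiplicative subject effects, the spread of per-subject slopes (not
the residual SE of the mean-data fit) is the honest uncertainty of the
cohort slope, and the acceptance checks use it.

## Reproducibility statistics

* `icc_agreement()` — intraclass correlation, absolute agreement, average
  of $k$ sessions (McGraw–Wong A,k), computed from the two-way ANOVA mean
  squares, with the standard F-based confidence interval (single-measure
  bounds stepped up by Spearman–Brown, clamped to $[-1, 1]$). The
  mixed-versus-random distinction does not change this point estimate.
  Labels follow the usual thresholds (< 0.5 poor, 0.5–0.75 moderate,
  0.75–0.9 good, > 0.9 excellent).
* `lin_ccc()` — Lin's concordance correlation coefficient with n-divisor
  moments and a Fisher-z interval using Lin's variance.
* `normalized_sd()` — per-subject SD across sessions divided by the
  per-subject mean, averaged with equal subject weights. For small $k$ the
  sample SD is biased low by the factor $c_4(k)$ (≈ 0.886 at $k = 3$); the
  function reports the plain estimator, and recovery tests use enough
  sessions that the bias is inside tolerance.

`generate_repeat_sessions()` produces subjects × sessions tables with
lognormal between-subject means and Gaussian within-session noise — the
structure the reproducibility arm of such a study assumes.

## The pipeline and its problem sizes

`run_pipeline()` chains simulate → analyze → topography → reliability →
report, each stage reading only the previous stage's serialized files
(CSV/JSON/TIFF), so runs restart at any stage and manifests record the seed
and full parameter set. The default design mirrors the study layout this
emulates: 11 subjects, 13 ROIs from the fovea to 12° temporal at 1°
spacing, cones from 1° outward, RPE everywhere, a 7-subject × 3-session
reproducibility arm at the fovea and 7.5°, and a simulated two-grader RPE
comparison scored with Lin's concordance. Analysis windows are
0.25 × 0.25 mm; per-cone OSL is measured on a central 120 µm subregion
volume (about 120–770 cones per ROI depending on eccentricity), which keeps
a full 11 × 13 run around seven minutes on one core while holding the
cohort-mean OSL sampling error at the endpoints below half a percent.
Figures are artifacts of the report stage only; every number they display
comes from the serialized tables.

## Numerical choices and degenerate inputs

* Voronoi cells are clipped against bisectors in order of increasing
  distance with the standard pruning bound (a site beyond twice the current
  max site-to-vertex distance cannot cut); the gather radius grows
  adaptively until the bound certifies completeness. Collinear point sets
  and duplicate centers are rejected explicitly.
* Degenerate biometry ($AL \le 1.82$ mm), zero analysis areas, zero RPE
  densities, empty eccentricity lists, and incomplete session tables all
  raise errors before any computation.
* All generators are pure functions of (parameters, seed) and restore the
  caller's RNG state; the detector and all measurements are deterministic,
  so fixed-seed runs are reproducible bit for bit.

## Known limitations

Foveal cone metrics are out of scope by design. The detector is tuned for
rendered Gaussian-spot imagery and is not expected to transfer to real
images without retuning. The speckle model is incoherent. OSL validity
flags catch indistinct peak pairs but no attempt is made to resolve the
anatomical origin of the reflections; the package measures peak separation
only.
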