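# aomosaic

Quantification of the photoreceptor–retinal pigment epithelium (PR–RPE)
complex from cellular-resolution retinal imaging, with a synthetic data
generator that makes the entire measurement chain verifiable by parameter
recovery.

The package is aimed at researchers analyzing adaptive-optics OCT (or
similar cellular-resolution) data of the outer retina, and at anyone who
needs a tested reference implementation of the standard quantification
steps:

* **Mosaic metrics** — bounded Voronoi tessellation of cell centers with
  boundary and vessel-shadow exclusion: density (included cells over summed
  polygon area), mean cell area, and cell-to-cell spacing over
  Voronoi-adjacent pairs.
* **Spectral density** — the independent Yellott's-ring estimate: radially
  averaged 2-D FFT power with a Hann window; the ring radius *f* (the
  hexagonal row frequency, cycles/mm) gives density *D* = (√3/2) *f*².
* **Per-cone outer segment length (OSL)** — from each cone's paired axial
  reflections (IS/OS junction and outer segment tip): 3×3 A-scan averaging,
  two dominant peaks under a separation constraint, 3-point parabolic
  subpixel refinement, peak-to-peak distance × axial pixel size.
* **Magnification scaling** — the small-angle schematic-eye relation
  *q* = 0.01306 (AL − 1.82) mm/deg converts visual angle to retinal
  microns per eye.
* **Topography** — power (*y = a E^b*), linear, and second-order polynomial
  fits across eccentricity with Pearson/Spearman goodness of fit; PR/RPE
  ratio as mean-of-ratios and ratio-of-means.
* **Reproducibility** — absolute-agreement average-measures ICC from ANOVA
  mean squares with F-based intervals, Lin's concordance coefficient, and
  the mean-normalized between-session SD.
* **Synthetic data** — jittered hexagonal mosaics (with a hard-core
  separation), vessel masks, en-face renders, miniature outer-retina
  volumes with per-cone ground truth, cohorts with lognormal
  between-subject effects, and repeat-session tables.

The default cohort follows normative macular topography: cone density
53,329·*E*^−0.731 cells/mm² (1–12° temporal), RPE density 6913 − 123·*E*
cells/mm², OSL falling from 33.3 µm at 1° to 18.0 µm at 12° along a
monotone second-order polynomial.

## Worked example

Generate a 0.25 × 0.25 mm cone mosaic at the 1° normative density, render a
speckled en-face image, detect the cells, and quantify the mosaic:

```r
library(aomosaic)

m   <- generate_mosaic(53329, 250, seed = 1)            # cells in um space
img <- render_enface(m, noise_cv = 0.15, seed = 2)      # speckled image
det <- detect_cells(img, expected_spacing_um = hex_spacing_um(53329))
voronoi_metrics(det, window = m$window)
#> Mosaic metrics: 3091 cells over 0.0584 mm^2
#>   density 52929 cells/mm^2, mean area 18.9 um^2, spacing 4.72 um
```

The requested density of 53,329 cells/mm² is recovered within 0.8% through
the full render → detect → tessellate chain; mean cell area (18.9 µm²) and
spacing (4.72 µm) match the hexagonal relations for that density. The
spectral route agrees:

```r
ps <- power_spectrum_density(img, expected_density_hint = 53000)
#> ring at 248.1 cycles/mm -> 53307 cells/mm^2
```

Per-cone OSL from a rendered volume of ~200 cones with true OSL
N(33.3, 2.4) µm:

```r
sub <- generate_mosaic(53329, 62, seed = 1)
vol <- render_volume(sub, osl_um = 33.3, osl_sd_um = 2.4,
                     noise_cv = 0.15, seed = 3)
osl_summary(measure_osl(vol, sub$points))
#> OSL: 33.3 (SD 2.4) um over 200 cones
```

And the per-eye magnification scaling:

```r
eye_biometry(24.13)
#> Eye biometry
#>   axial length : 24.13 mm
#>   field of view: 2 deg, 512 samples
#>   scale        : 291.4 um/deg, 1.138 um/pixel
```

A full synthetic study (11 subjects × 13 ROIs, topography fits,
reliability arm, figures) runs end to end with

```r
cfg <- run_config(out_dir = "run1", seed = 7)
run_pipeline(cfg)
```

writing per-ROI metrics, fit coefficients, reliability JSON, and report
figures under `run1/`. A thin command-line wrapper with subcommands
(`simulate`, `analyze`, `topography`, `reliability`, `report`, `all`)
lives at `inst/cli/aomosaic.R`.

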