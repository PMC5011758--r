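---
title: "Methods: micro-CT morphometry and classification of subchondral bone changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-CT morphometry and classification of subchondral bone changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(subchondral)
```

## The model

After microfracture surgery, an awl hole of diameter Ø is punched through
the subchondral bone plate to a working depth.  On follow-up micro-CT,
the bone around each hole has either healed or remodelled into one of
several pathological shapes.  This package implements a deterministic
decision algorithm over two-dimensional calibrated cross-sections.

All vertical measurements are taken relative to the **projected cement
line**: the straight line marking the original top of the subchondral
bone plate, either annotated by a reader or fitted from the image.  The
measured quantities are:

* **Vd1** — vertical distance from the cement line to the deepest point
  of the defect.
* **Vd2** — vertical distance from the cement line to the apex of a bone
  bridge spanning the defect (when present).
* **Hd1** — horizontal lesion diameter at the level of the cement line.
* **Hd2** — horizontal lesion diameter at half the awl penetration depth
  below the cement line.
* **H0** — height of bone protruding above the cement line (osteophyte).

The decision rules, with awl diameter Ø and a configurable
`threshold_config()`:

1. No deviation from an intact plate in any slice → **complete
   reconstitution**.
2. Bone strictly above the projected cement line → **intra-lesional
   osteophyte** (in addition to any cavity class).
3. Two holes are counted when a bridge subdivides the defect and
   `Vd2 < 0.5 * Vd1` (strict; at equality the milder reading — one
   hole — is kept).
4. Per hole, checked in order of severity:
   `Hd2 > 3 Ø` → **subchondral bone cyst** (irrespective of Hd1);
   else `Hd1 > 2 Ø` → **peri-hole bone resorption**;
   else → **residual microfracture hole**.
5. Across slices, each hole keeps its worst (most severe) class.

```{r rules}
awl <- awl_spec(diameter_mm = 1.2, penetration_depth_mm = 2.0)
classify_lesion(c(2.0, 2.5, 1.0), c(3.0, 3.0, 4.0), awl)
count_holes(vd1_mm = 2.0, vd2_mm = 0.8)
```

## Measurement pipeline

`analyze_defect()` runs, per slice:

1. **Segmentation** — `segment_bone()` thresholds the calibrated gray
   image (closed interval, defaults 89–255).
2. **Cement-line fit** — `fit_cement_line()` extracts the topmost-bone
   depth per column and fits a line.  A deterministic consensus search
   over candidate lines through pairs of evenly spaced surface points
   (scored by 0.05 mm inliers) localizes the plate before a final
   least-absolute-deviations refit on the inliers.  Candidates that
   leave more than 15 % of surface points clearly (\> 0.1 mm) *above*
   the line are rejected: the intact plate is the topmost structure, so
   such candidates can only be cavity floors.  After the defect region
   is found the line is refit on the flanking columns only.
3. **Defect region** — columns whose surface deviates more than 0.1 mm
   from the line; gaps up to 0.4 mm are closed (one third of the default
   awl diameter — wide enough to bridge the foot of an osteophyte cap,
   whose deviation crosses the threshold gradually, and narrower than
   any feature the generator can produce).
4. **Bridge detection** — a saddle in the surface profile inside the
   region; a flat bridge top renders as a staircase under a sloped line,
   so all columns within one pixel of the best saddle score form the
   plateau and its middle column is the apex.
5. **Measurements** — `measure_vertical()`, `measure_horizontal()`,
   `measure_area()` and `measure_osteophyte()` per hole, after an
   optional recursive split at bridge apexes.

### Sub-pixel conventions

Pixel centres sit at `(i - 0.5) * pixel_size`.  A surface that runs
between a void-pixel centre and a bone-pixel centre is best estimated by
their common edge; using the bone-pixel centre would bias every surface
depth half a pixel deep, which matters because a width measured on a
flared wall amplifies any line-depth error by the wall slope
`dw/dd`.  The same half-pixel correction applies to the cavity floor
(Vd1).  Horizontal diameters are not read from a single pixel row:
`measure_horizontal()` tracks each cavity wall over up to 12 consecutive
rows, fits wall position against depth by least squares, and evaluates
at the exact measurement level (the cement line for Hd1, half the
penetration depth for Hd2).  This removes both column quantization and
the up-to-one-pixel level error of a single-row reading.

Connected components use 4-connectivity for cavities (a diagonal
void-to-void contact through an intact bone wall must not merge two
holes); `label_components()` also offers 8-connectivity.

## Synthetic phantoms

`phantom_spec()` builds parametric sections with analytic ground truth
— every truth value is computed from the continuous geometry, never
from the rendered pixels.

```{r phantom}
sp <- phantom_spec(lesion_spec(center_x_mm = 4, hd1_mm = 2.0, hd2_mm = 1.5,
                               depth_mm = 1.6),
                   cement_line_depth_mm = 1.2)
ph <- generate_phantom(sp)
ph$truth$lesions[, c("hd1_mm", "hd2_mm", "vd1_mm", "class")]
rep <- analyze_defect(ph$image, awl = awl_spec())
as.data.frame(rep)[, c("hd1_mm", "hd2_mm", "vd1_mm", "class")]
```

Cavity profiles are piecewise linear in width versus depth: a
**trapezoid** (width interpolates from Hd1 at the line towards the base)
or a **bulb** (width peaks at the Hd2 level — an undermining cyst).
Two-lesion sections carve two adjacent trapezoid openings over a shared
flat bridge floor at exactly `bridge_vd2_mm`; they are restricted to
trapezoid profiles because two adjacent bulbs can merge below the bridge
into geometry whose analytic truth would no longer be well defined.
Optional features: a parabolic osteophyte cap (peripheral or central),
Gaussian gray noise, and elliptical trabecular pores.

`sample_random_spec()` rejects draws whose analytic values lie within
0.09 mm (six pixels at the default 15 µm calibration) of a decision
boundary: at finite resolution no measurement can resolve a class across
a boundary closer than the sampling error, so boundary behaviour is
exercised by exact forced examples on `classify_lesion()` and
`count_holes()` instead of rendered images.

**Limitations.** Phantoms are single-line plates with straight cement
lines (slopes up to ±0.03); real sections curve.  Pores are excluded
from a 0.5 mm band under the plate so they never counterfeit a defect.
The default canvas is 8 × 4.6 mm at 15 µm (533 × 307 px); one phantom
renders and analyzes in well under a second.

## Threshold sensitivity

`threshold_sweep()` reclassifies a fixed measurement set under a grid of
Hd1/Hd2 multipliers.  Raising a multiplier can only shrink its own
pathology count:

```{r sweep}
set.seed(1)
m <- data.frame(hd1_mm = runif(100, 0, 6), hd2_mm = runif(100, 0, 6))
threshold_sweep(m)
```

## Agreement statistics

`percent_agreement()` and `cohen_kappa()` (unweighted) take two rating
vectors; internally a square `rating_table()` is built over the union of
both raters' categories.
When the expected agreement is 1 (both raters constant), kappa is
undefined; the package warns and returns 1 for perfect observed
agreement, `NaN` otherwise.

```{r agree}
a <- c("x", "x", "n", "n"); b <- c("x", "n", "x", "n")
percent_agreement(a, b)
cohen_kappa(a, b)
```

## Command-line interface

The installed script `inst/cli/subchondral` exposes `simulate`,
`measure`, `classify`, `sweep` and `agree` subcommands; each writes its
data to files, logs to stderr, and records a JSON manifest (command,
package version, resolved configuration) next to its output.
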