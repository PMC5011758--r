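# subchondral

Micro-CT morphometry and classification of subchondral bone changes
after marrow stimulation (microfracture).

After microfracture surgery, the subchondral bone around each awl hole
either reconstitutes or remodels pathologically. This package implements
a deterministic decision algorithm over calibrated two-dimensional
micro-CT cross-sections. Relative to the projected cement line (the
original top of the bone plate) it measures vertical defect extents
(Vd1, Vd2), horizontal lesion diameters at the line level (Hd1) and at
half the awl penetration depth (Hd2), defect area, and osteophyte height
(H0), and classifies each hole as:

* **complete reconstitution** — no deviation from an intact plate;
* **intra-lesional osteophyte** — bone strictly above the cement line;
* **residual microfracture hole** — neither rule below fires;
* **peri-hole bone resorption** — Hd1 > 2 × awl diameter;
* **subchondral bone cyst** — Hd2 > 3 × awl diameter (checked first,
  irrespective of Hd1).

Two holes are counted when a bone bridge subdivides the defect with
Vd2 < 0.5 × Vd1. Across a slice stack, each tracked hole keeps its most
severe class. The package also provides a synthetic-phantom generator
with analytic ground truth, threshold sensitivity sweeps, two-point bone
mineral density calibration, inter-rater agreement statistics, and a
command-line interface.

## Worked example

Simulate a section containing two adjacent awl holes separated by a low
bone bridge, then analyze it:

```r
library(subchondral)

sp <- phantom_spec(
  list(lesion_spec(center_x_mm = 3.2, hd1_mm = 1.6, hd2_mm = 1.3, depth_mm = 1.8),
       lesion_spec(center_x_mm = 4.7, hd1_mm = 1.4, hd2_mm = 1.1, depth_mm = 2.0)),
  cement_line_depth_mm = 1.2,
  bridge_vd2_mm = 0.6)          # bridge top 0.6 mm below the cement line
ph <- generate_phantom(sp)
ph$image
#> <calibrated_image> 307 x 533 px, 0.015 mm/px (8 x 4.6 mm)

report <- analyze_defect(ph$image, awl = awl_spec(diameter_mm = 1.2,
                                                  penetration_depth_mm = 2.0))
report
#> <defect_report>
#>   2 tracked hole(s) over 1 slice(s); osteophyte: no
#>   hole 1 @ x = 3.20 mm: residual_hole
#>   hole 2 @ x = 4.70 mm: residual_hole

as.data.frame(report)
#>   slice_id lesion_id center_x_mm vd1_mm vd2_mm   hd1_mm   hd2_mm depth_mm
#> 1        1         1    3.198247  1.800    0.6 1.598505 1.298846    1.800
#> 2        1         2    4.699253  1.995    0.6 1.403505 1.098016    1.995
#>   area_mm2         class h0_mm osteophyte_location
#> 1   2.4147 residual_hole    NA                <NA>
#> 2   2.2203 residual_hole    NA                <NA>
```

Two holes are reported because the bridge apex (Vd2 = 0.6 mm) is below
half the deepest extent (Vd1 = 2.0 mm); every recovered measurement is
within two pixels (0.03 mm) of the specified geometry.

The decision rules can be applied directly to tabulated measurements:

```r
awl <- awl_spec(1.2, 2.0)
classify_lesion(hd1_mm = c(2.0, 2.5, 1.0), hd2_mm = c(3.0, 3.0, 4.0), awl)
#> [1] "residual_hole"        "peri_hole_resorption" "subchondral_cyst"
count_holes(vd1_mm = 2.0, vd2_mm = 0.8)
#> [1] 2
```

Inter-rater agreement on categorical readings:

```r
a <- c("residual_hole", "subchondral_cyst", "residual_hole", "peri_hole_resorption")
b <- c("residual_hole", "subchondral_cyst", "peri_hole_resorption", "peri_hole_resorption")
agreement_stats(a, b)[c("n", "n_agree", "percent_agreement", "kappa")]
#> $n
#> [1] 4
#>
#> $n_agree
#> [1] 3
#>
#> $percent_agreement
#> [1] 75
#>
#> $kappa
#> [1] 0.6363636
```

## Command-line interface

The installed script `exec`s five subcommands; data go to files, logs to
stderr, and every run writes a JSON manifest:

```sh
subchondral simulate --n 20 --seed 1 --out phantoms/
subchondral classify --images phantoms/phantom_0001.png --pixel-size 0.015 \
    --awl-diameter 1.2 --penetration-depth 2.0 --out report.json
subchondral sweep --measurements measurements.csv --out sweep.csv
subchondral agree --ratings ratings.csv --out agreement.json
```

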