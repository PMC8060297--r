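# panoquant

Pixel-based quantification and colocalization of immunofluorescence (IF)
signals on whole-section panoramic images.

## The problem

When a marker is expressed ubiquitously across a tissue — extracellular
matrix components, heparan sulfate proteoglycans, pan-leukocyte antigens —
scoring a handful of high-magnification regions of interest throws away
most of the section and biases the estimate. panoquant instead quantifies
the *entire* panoramic image of a histological section with two primitives
only: pixel counts and pixel grey values (GV, 0–255 on 8-bit images). It is
aimed at labs doing standard single-round IF on serial sections with a
slide scanner or stitching microscope, without multiplexed-staining
hardware.

Three attributes of an IF signal are computed:

* **Expression domain** — % of the section (or of the epithelial/stromal
  compartment) covered by supra-threshold signal, from a 256-bin grey-value
  histogram relative to the section area. With the signal threshold at
  GV *t* the reported histogram has `256 − t` bins (246 at *t* = 10).
* **Spatial gradient** — the top-down plot profile: mean in-section GV of
  every 1 px-wide row, top of the image to bottom, calibrated in µm
  (`(H − 1) × µm/px` total scanning distance).
* **Colocalization** — profiles of up to ~30 markers (one serial section
  each) stacked into a matrix and fed to simple/multiple linear regression
  (α = 1 × 10⁻⁸, 99 % coefficient CIs): `y = β₀ + Σ βⱼ xⱼ + ε`, where `y`
  is the dependent marker's profile (e.g. CD45, the inflammatory
  infiltrate) and `xⱼ` the other markers. A 6th-order polynomial
  calibration refines the fit, and *virtual knockout* zeroes one
  predictor's profile to report
  `fold = mean(ŷ_knockout) / mean(ŷ_baseline)` — fold < 1 flags a "pro"
  (supporting) factor, > 1 an "anti" factor.

Supporting machinery: whole-section mask construction from lighten/darken
pixel blends (threshold at GV 1, morphological closing, largest-component
magic-wand analogue, hole filling), three-stage signal thresholding
(background floor scan → candidate regression scan → threshold
application), DAPI-based cellularity, serial-section compatibility tables
from DAPI profile regressions, and a seeded synthetic-panorama generator
with ground truth so everything is testable offline.

## Worked example

```r
library(panoquant)

s <- generate_section(section_params(), seed = 1)   # 1600 x 1024 px world
g <- s$truth$geometry

measure_areas(g, cellularity_pct = cellularity(s$dapi, g$section_mask))
#>   whole_px whole_mm2  epi_pct stroma_pct cellularity_pct
#> 1   785165 0.2284202 25.01219   74.98781        26.00001

f <- background_floor(s$markers$CD45, s$background_mask)   # -> 10
roi <- select_weak_roi(s$markers$CD45, g$section_mask, f)
threshold_scan(roi$roi, candidates = f + c(0L, 10L, 20L, 30L, 40L))
#> <threshold_scan>
#>   THRLD_10: R2 = 0.9787, p = 3.06e-107  <- selected
#>   THRLD_20: R2 =    NA, p =   NA        (degenerate, excluded)
#>   ...

h <- truncate_histogram(gv_histogram(s$markers$CD45, g$section_mask), f)
expression_domain(h)
#> [1] 20.00  (generator truth: 20 %)

td_profile(s$markers$CD45, g$section_mask)
#> <td_profile> 1600 rows, 0.53937 um/px, total scanning distance 862.5 um
```

The section covers 0.228 mm²; the epithelial rim holds 25.0 % of it; 26.0 %
of the section is covered by DAPI-stained nuclei. The background floor scan
finds the first all-black background at GV 10, the candidate scan confirms
10 as the signal threshold (the higher candidates erase the weak signal the
window was chosen for), and the thresholded CD45 histogram reports a 20.0 %
expression domain — the generator's configured truth.

Colocalization across a six-section serial stack, one marker per section:

```r
st <- generate_serial_stack(6, jitter = 1,
                            params = section_params(height = 800L, width = 512L),
                            seed = 7)
profs <- lapply(seq_along(st), function(k)      # marker k stains section k
  td_profile(st[[k]]$markers[[k]], st[[k]]$truth$geometry$section_mask))
X <- stack_profiles(profs,
                    vapply(seq_along(st),
                           function(k) names(st[[k]]$markers)[k], ""))
fit <- multiple_regression(X, "CD45")
virtual_knockout_all(fit, X)
```

(with each section's own marker picked out) gives

```
<regression_fit> multiple linear regression: CD45 ~ Sdc1 + EXT1 + EXT2 + NDST1 + NDST2
  R = 0.99382, R2 = 0.98768, F = 1.273e+04, p = 0 (alpha = 1e-08) -> significant
  factor baseline knockout      fold direction
2   EXT1 4.092778 2.363415 0.5774597       pro
5  NDST2 4.092778 1.721519 0.4206235       pro
3   EXT2 4.092778 4.446580 1.0864454      anti
```

EXT1 and NDST2 — the two factors the generator makes share CD45's stromal
hotspot — come out "pro-inflammatory" under virtual knockout (predicted
CD45 signal drops ~1.7–2.4-fold when they are zeroed), EXT2 mildly "anti".
DAPI compatibility for the same stack: R² = 0.9646 at the 5th section
(slope 0.9789, p below machine precision), decaying monotonically with
section distance.

## Command line

```sh
inst/bin/panoquant simulate  --seed 7 --out sim/ --sections 6 --jitter 1
inst/bin/panoquant threshold --image sim/section01.CD45.tif \
                             --section-mask sim/section01.section.tif --out thr/
inst/bin/panoquant histogram --image sim/section01.CD45.tif \
                             --mask sim/section01.section.tif --threshold 10 --out h.csv
inst/bin/panoquant profile   --image sim/section01.CD45.tif \
                             --mask sim/section01.section.tif --out p.csv
inst/bin/panoquant coloc     --matrix profiles.csv --dependent CD45 --vko all --out m/
```

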