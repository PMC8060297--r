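---
title: "Whole-section IF quantification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-section IF quantification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panoquant)
```

## The measurement model

panoquant quantifies immunofluorescence (IF) staining on 8-bit greyscale
panoramic images of whole histological sections. Every quantity reduces to
two primitives: counting pixels and comparing pixel grey values (GV,
0–255). No cells are counted and no regions of interest are cherry-picked —
the entire section is the measurement unit. Three attributes of an IF
signal are quantified:

* **Expression domain** — the percentage of the section (or of one tissue
  compartment) covered by supra-threshold signal. Computed from the
  grey-value histogram: 256 absolute pixel counts, converted to
  percentages of a reference mask area so sections of different sizes are
  comparable. Truncating at the signal threshold *t* leaves `256 − t`
  reported values (246 at the usual *t* = 10).
* **Spatial gradient** — the top-down (T-D) plot profile: for each 1
  px-wide row, the mean GV over pixels inside the whole-section mask. Using
  the binary section mask as reference removes all influence of background
  pixels on the row means, which subsumes the alternative of rescaling to
  %-of-maximum (the relative form is still emitted for plotting). Row
  positions are calibrated as `row_index × µm/px`; the total scanning
  distance spans the `H − 1` inter-row steps, which is what makes an
  8800-row scan at 0.53937 µm/px print as 4745.9 µm.
* **Colocalization** — profiles of several markers, stained one per serial
  section and stacked into an N×M matrix, enter linear models. If two
  markers colocalize perfectly in space their profiles are linearly
  related, so R and R² measure spatial overlap. A multiple regression of
  one marker (e.g. the leukocyte marker CD45) on all others supports
  *virtual knockout* (VKO): zero one predictor's profile, recompute the
  predicted dependent profile under the fitted coefficients, and report
  `fold = knockout mean / baseline mean`. For a linear model the closed
  form `knockout mean = baseline − β_j · mean(x_j)` holds exactly and is
  used as a cross-check, never as the implementation.

## Mask construction

The whole-section mask is built from the lighten-merge (per-pixel max) of a
marker channel and its DAPI channel, binarized inclusively at GV 1 so every
stained pixel turns white. Two manual steps of the bench protocol are
replaced by deterministic equivalents:

* brushing shut the gaps at the tissue/background interface → morphological
  closing with a Euclidean disk (default radius 15 px at full panorama
  scale; scale it with the image),
* magic-wand selection of the section before flood-filling → keeping only
  the largest connected white component, then filling enclosed holes.

The second replacement matters because real backgrounds are not perfectly
black: faint speckle at GV 1–9 survives the threshold and would otherwise
be glued into the mask by closing. Compartments then partition exactly:
stroma = section ∧ ¬epithelium, checked to the pixel. Epithelium masks are
supplied (hand-drawn in practice, generated in tests); the package does not
attempt epithelium segmentation.

## Signal thresholding

The signal threshold separates IF signal from autofluorescence in three
stages:

1. **Background floor** — the smallest *t* (1…255) at which at most a
   tolerance fraction (default 0) of extra-section background pixels
   survive binarization; at tolerance 0 this is `max(background GV) + 1`.
2. **Candidate scan** — a weak-signal ROI is binarized at each candidate
   (default 10, 20, 30, 40, 50); the ROI's own T-D profile is regressed on
   each binary image's T-D profile, and the candidate with the highest R²
   wins (ties go to the lowest GV, retaining more signal). The regression
   orientation — original profile as dependent throughout — keeps R²
   comparable across candidates.
3. **Application** — pixels below the selected threshold are zeroed;
   equivalent, pixel for pixel, to darken-blending with the inverted
   sub-threshold mask (both routes are tested against each other).

The ROI is the one genuinely manual input. `select_weak_roi()` automates it
by sliding a window over the section and scoring
`weak fraction − 4 × strong fraction − 2 × |signal coverage − 0.5|`. The
three terms encode what "a region containing weak IF signals" means
operationally: rich in the weak band `[floor, 50]`, poor in strong signal
(one bright structure dominates a window profile's variance and drags the
scan toward high candidates), and roughly half-covered (a window fully
inside the expression domain makes the floor candidate's binary image
near-constant and its regression degenerate). With this score the full
procedure recovers a constructed floor in most seeds at the default canvas;
it remains a stochastic surrogate for a human choice, and the occasional
failure mode is selection of floor + 10, never a wild value.

## Group statistics

Histomorphometric scalars (areas, fractions, cellularity) are compared by a
pooled two-sample Student t-test at α = 0.1. Expression domains are
compared by one-way ANOVA at α = 0.01 with each sample contributing its
truncated relative-histogram vector (246 values at *t* = 10), so both the
domain size and the intensity distribution inform the test; the pooled
t-test convention preserves the two-group identity F = t², which the test
suite checks numerically. Gradient correlations use α = 1e-8 and 99 %
coefficient confidence intervals throughout. The 6th-order polynomial
refinement of a fitted model is a predicted→observed calibration curve:
it keeps the multiple-regression structure, captures a non-linear link,
and — being nested above the linear fit — can only raise R². The
alternative (polynomial terms per predictor) was rejected: it explodes the
design matrix in a way nothing in the protocol motivates.

## The synthetic world

`generate_section()` renders a stated world, not a tuned one:

| parameter | default | why |
|---|---|---|
| canvas | 1600 × 1024 px | desk-scale stand-in for ~12000 × 6000 panoramas |
| resolution | 0.53937 µm/px | the 10× panoramic scan calibration |
| epithelial fraction | 25 % | within the 18–29 % range of real gingiva sections |
| cellularity | 26 % | healthy-gingiva whole-section DAPI domain |
| autofluorescence floor | GV 10 | the worked floor of the thresholding protocol |
| marker domains | 20–40 % | whole-section domains of the HS GAG panel |
| jitter = 1 drift | R² ≈ 0.98 at 30th section | the published serial-compatibility regime |

Mechanically: a blob (ellipse with low-order harmonic boundary
perturbation) on near-black background; the epithelial rim is the
in-section pixels nearest the boundary, cut at the distance quantile that
yields the configured fraction exactly; DAPI is a thresholded
high-frequency field whose selected pixels get brightness as a
deterministic map of the field; markers are smooth low-frequency fields
(compartment-weighted, optionally sharing a stromal "inflammatory
infiltrate" hotspot) plus a fine-grained texture component, rendered so
that exactly the configured fraction of section pixels lies at or above the
floor. The normalized intensity is cubed before mapping to `[floor, 255]`
because IF grey-value histograms decay steeply from the floor — with a
linear map, weak signal carries no profile variance and the threshold-scan
recovery property fails for any ROI. Sub-floor texture is dense (30 %)
inside the section and sparse (5 × 10⁻⁴) outside, with eight "debris"
pixels at floor − 1 pinning the floor exactly on any canvas size.

Serial stacks drift along a *fixed random direction* with linearly
accumulating magnitude — centre shift, axis scaling, boundary deformation
and speckle-field turnover — like structures entering and leaving a
slightly wedge-shaped block as it is cut. A per-section random walk was
implemented first and rejected: realized random-walk displacement is
non-monotone, so compatibility R² wobbles with section distance instead of
decaying, contradicting both the monotone property the generator must
support and the smooth decline of published compatibility tables. With
drift direction fixed and rendering deterministic given the fields, R²
decays monotonically by construction; `jitter = 0` yields bit-identical
sections.

What the generator does **not** emulate: nucleus shapes and instance
boundaries (cellularity is a domain, not a count), stitching artefacts and
shading, photobleaching, chromatic registration error, and real epithelium
geometry (the rim hugs the whole boundary; real gingival epithelium is
one-sided). A green test therefore establishes that the *measurement
pipeline* is correct on images with known truth — not that the biology of
any particular staining will behave.

## Numerical choices

* Binarization is inclusive (`px ≥ t` → white), so *t* = 1 whitens every
  nonzero pixel.
* Desaturation offers `average` and `luminosity` (0.299/0.587/0.114)
  modes; different imaging software legitimately disagrees (the step-tablet
  makes the disagreement visible), so the mode is a logged parameter,
  default luminosity. Rounding is half-away-from-zero, making outputs
  bit-reproducible.
* R² ties in the threshold scan resolve to the lowest candidate; degenerate
  candidates (constant binary profile) are excluded with a warning rather
  than scored 0.
* Collinear predictors are refused when the design-matrix condition number
  exceeds 1e10, naming the worst-correlated pair.
* The polynomial refinement drops to a lower order automatically when the
  predicted profile has too few distinct values, and a round-off guard
  enforces the nesting inequality at the 1e-12 level.
* mm² conversion is `px × (µm/px ÷ 1000)²`; fractions are computed on the
  exact partition before any rounding, so they sum to 100 by construction.

## Known limitations

* Baseline TIFF only (uncompressed 8-bit grey/RGB): the stack this package
  targets exports exactly that, but compressed or 16-bit TIFFs need
  conversion first. PNG is fully supported.
* Profile alignment across serial sections is a precondition, not a
  feature: `stack_profiles()` errors on length mismatch instead of
  resampling.
* The ROI auto-selection is a reproducible surrogate for a manual choice,
  not a guarantee; log and inspect the selected window (`x`, `y`, `w`,
  `h`) in any real analysis.
* `compare_groups()` treats histogram bins as independent observations in
  the ANOVA, following the source protocol; bins of one histogram are in
  truth correlated, so the nominal α is optimistic for small groups.
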