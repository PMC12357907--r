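---
title: "Methods: morphometry and hierarchical statistics for oligodendroglial cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry and hierarchical statistics for oligodendroglial cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Human iPSC-derived oligodendroglial cultures are imaged in two fluorescence
channels: DAPI (nuclei) paired with either O4 (late precursors /
premyelinating cells, compact morphology) or MBP (maturing oligodendrocytes
with branched, tree-like processes). Four readouts are computed per field of
view and compared between a control and a patient (SCZ) group whose donor
lines are nested within groups:

* percent marker-positive cells (marker cells colocalizing with DAPI over
  all DAPI+ cells),
* average cell size (total positive area / cell count),
* average branch length and average junction number of the cell processes.

Two practical obstacles shape the pipeline. First, DAPI signal bleeds into
the MBP channel, depositing compact nuclear blobs that a naive threshold
mistakes for cells; they are removed by shape (solidity) and cross-channel
overlap filters rather than spectral unmixing. Second, fields of view are
pseudo-replicates of a donor line, so group inference must model the line
as a random effect.

## Image conditioning

Channels are processed in a fixed order, with per-channel routing:

1. `to_8bit()` — min–max display-range conversion to 8 bit. A constant
   image maps to zero. Using the image's own range is the only
   self-contained convention when the camera range is unknown.
2. `pseudo_flat_field()` (MBP, O4) — divide by a heavily blurred copy
   (default sigma = image width / 3), rescale to preserve the mean. For
   sigma > 8 px the Gaussian is computed as three iterated box filters with
   antisymmetric (linear-extrapolating) borders, so linear illumination
   trends are corrected all the way to the image edge.
3. `median_smooth()` (all channels) — disc median, default radius 2 px.
4. `subtract_background_paraboloid()` (O4, DAPI) — background is the
   grayscale opening with the paraboloid `z(d) = d^2 / (2 r)` (default
   r = 50 px). Each 1-D pass of the separable opening is an exact
   lower-envelope (weighted distance) transform, so cost is O(1) per pixel.
   The element follows backgrounds whose curvature is below `1/r` and
   ignores structures much narrower than `r`.
5. `enhance_contrast()` (DAPI, O4) — linear stretch with a saturated
   fraction (default 0.35%) split between both tails.

The blur radius, median radius, paraboloid radius and saturation level are
not printed in the source protocol; they are explicit configuration values
with the defaults above.

## Segmentation and bleed-through correction

`huang_threshold()` minimises Huang and Wang's measure of fuzziness over
the 256-bin histogram: membership of grey `g` to its side of the candidate
cut is `1 / (1 + |g - mu_side| / C)` and the score is the summed Shannon
entropy of the memberships. `variant = "huang"` scans all candidates;
`"huang2"` is a coarse-to-fine search (step 8, refining around the best
three coarse minima) over the same objective — the two agree on unimodal-gap
histograms and are tested to never differ by more than 2 grey levels on
bimodal ones. Ties resolve to the lowest level; the foreground is strictly
above the threshold. DAPI and MBP use `huang2`, O4 uses `huang`.

Binary clean-up uses a 3×3 structuring element, one iteration per op;
`watershed` floods the inverted exact Euclidean distance transform from its
regional maxima and turns the basin boundaries into background, splitting
touching nuclei. DAPI receives erode/open/dilate/watershed, O4 erode/open,
MBP none.

ROIs are 8-connected components with at least `min_area_px` (default 20)
pixels. Solidity is the pixel count divided by the number of lattice points
inside the convex hull of the pixel centres (computed exactly with integer
half-plane tests). The two bleed-through filters are strict inequalities as
printed in the protocol: keep MBP ROIs with solidity < 0.7, then keep those
whose own-area fraction inside the union of DAPI ROIs is < 0.6. The
overlap denominator is the MBP ROI's area — the protocol phrases overlap as
a property of the MBP ROI — and this convention is config-overridable. Both
filters are idempotent.

## Morphometrics

Two independent backends compute branch length and junction number.

**Ridge backend** (`detect_ridges()`): Steger-style detection. Gaussian
derivative filters at scale `sigma` (default 1.8 px, suited to lines of
width about `sigma * sqrt(3)`) give the Hessian; a pixel is a line point
when the most negative eigenvalue's magnitude exceeds the salience
threshold and the sub-pixel maximum along its eigenvector falls inside the
pixel. Two engineering guards matter in practice and were validated on
fixtures with analytic truth: a line-vs-blob test (second eigenvalue at
most 0.6 of the first in magnitude) rejects line end-caps and somata, and
polylines shorter than 6 points are dropped (end-cap fragments). Contrast
thresholds (defaults 20 / 55 grey levels, hysteresis) are converted to
salience assuming a Gaussian line profile with sd `sigma * sqrt(3) / 2`.
Junction evidence is either a closest approach < 3 px between two
polylines where at least one matched point is interior (a T or a crossing —
end-to-end meetings are continuations, typically linking breaks at kinks),
or three or more polyline endpoints within 6 px (processes converging on a
soma); candidates merge single-link at 6 px, and polylines are split at
junctions so each polyline is one branch.

**Skeleton backend** (`skeletonize_mask()`): Zhang–Suen thinning of the
bleed-corrected threshold mask, then a branch/junction graph: junction
pixels (3+ skeleton neighbours) merge into cluster nodes, branches are
traced paths with the 1 / sqrt(2) step-length convention. Terminal spurs
shorter than 4 px are pruned (including dead-end stubs), junction nodes
joined by edges shorter than 4 px (about one mask band width) are
contracted, and two geometric corrections address systematic shortening by
thinning: branches extend to their junction-node centroids, and terminal
branches extend by `EDT - 1` at the tip (zero for a 1-px line, preserving
the exact step count of a straight line).

`percent_positive()` counts a marker ROI as a cell when it contains at
least one DAPI ROI centroid — the protocol does not define colocalization;
centroid containment is robust to partial overlaps and cheap.
`avg_junction_number` is junctions per cell (the only stated denominator,
"total cell number"); `avg_branch_length` is the mean over branches in the
field of view. When no branches are detected both are flagged missing,
mirroring the NA handling of the source study.

## The synthetic stated world

`generate_scene()` builds ground-truthed scenes: 256×256 px at 0.6 µm/px
(the protocol prints no magnification; pixel size is a free parameter),
about 12 nuclei and 7 MBP cells per field. Cells are multipolar: 3–4
primary processes from a small soma (radius 2.5–3.5 px), segments of
12–22 px bending by ~7° per subsegment, splitting with probability 0.5 up
to depth 2 — so the soma is itself a true junction and per-cell junction
counts land near the 0.4–0.5 range of the study's readouts. Somata are
rejection-sampled at 65 px minimum spacing (sparse plating, as morphometry
protocols image), and segments are grown collision-aware with an 8 px
clearance: a split is committed only if both children fit. This matters
for truth accounting: the recorded tree is exactly what is rendered — no
crossings exist in the image that the truth would not know about, and
every internal node really has degree 3.

Rendering draws nuclei as soft ellipses and processes as Gaussian ridges
(width 3 px) using exact point-to-segment distances; the marker channel
receives `bleed_coefficient` (default 0.3) times a blurred copy of the
DAPI signal — the compact nuclear artifact the ROI filters remove; both
channels are multiplied by a mean-one low-order polynomial vignetting
field (amplitude 0.25) and degraded with Poisson shot noise (2 photons per
grey level) plus Gaussian read noise (sd 2), with per-channel sub-seeds
(`seed + 101`, `seed + 202`); output is quantised to 8 bit. Truth records
are never touched by rendering. `scene_params_noise_light()` (photon scale
50, read sd 1, no bleed, flat field) is the benchmarking condition for
ground-truth recovery, per the design that recovery is assessed on
noise-light scenes.

What a green test does not establish: real micrographs have out-of-focus
light, a non-Gaussian PSF, overlapping cells, heterogeneous staining and
debris — none of which are emulated. The generator demonstrates that the
pipeline measures what it claims on images whose truth is known, not that
it is robust to everything a microscope produces.

`simulate_measurements()` skips the imaging layer entirely: values are
grand mean + group effect + per-line intercept + field-of-view noise.
Defaults mirror the study's design (7 lines/group, 8–13 fields/line) and
its printed contrasts (branch length 0.624 + 0.052, junction number
0.409 + 0.102), with line SD 0.10 and field SD 0.15. The image-level demo
cohort injects a relative branch-length effect into SCZ scenes' segment
lengths plus a 4% lognormal between-line scale; its default (15%) is sized
by power analysis so the deliberately small 2 x 4 x 6 demonstration design
detects it reliably — the study-scale 8% contrast needs the study's 7
lines per group, which the `simulate_measurements()` defaults model.

## Statistics

`select_transform()` fits identity, `sqrt(x + a)` with `a = max(0, 1 -
min(x))`, `asinh`, Box–Cox (positive data), Yeo–Johnson and orderNorm
(rank-based inverse normal), scores each by the Shapiro–Wilk W of the
transformed sample (the source names the evaluation tests but not the
selection rule; maximal W is the natural scalarisation), and picks the
maximiser with ties (within 1e-4) to the simplest family. Power-family
lambdas are chosen on the same criterion over a grid. All fitted
transforms are strictly increasing, so group contrasts keep their sign;
inverses are exact except orderNorm, which inverts by interpolation on the
training data. Fewer than three distinct values fall back to identity with
a degenerate flag.

`fit_mixed_anova()` fits `value ~ group + (1 | line)` by REML (via lme4)
and tests the group contrast with `F = (estimate/SE)^2` on 1 and
`n_lines - 2` denominator degrees of freedom — the between-within
convention, chosen because it is deterministic and matches the nested
design; `df_method = "residual"` is the documented alternative. Zero line
variance returns the boundary fit with `singular = TRUE`. The companion
`group_ttest_cohend()` collapses fields of view to line means and runs the
pooled-variance t-test with Cohen's d — the deliberately less sensitive
group-level comparison whose ordering against the mixed model is itself a
tested property.

`diagnostics()` reports Shapiro–Wilk and median-centred Levene p-values
per metric, Box's M across metrics when jointly observed, and flags
extreme outliers beyond 3×IQR outside the quartiles (the source says
"extreme outliers" without a definition; 3×IQR is the conventional one).

`effective_tests_simplem()` implements simpleM: eigen-decompose the test
correlation matrix, take the smallest k whose leading eigenvalues reach
99.5% of the total variance, and divide alpha by it. Constant columns are
removed with a warning.

## Numerical and testing choices

* Seeds: every stochastic component takes an explicit integer seed; scene
  sub-seeds derive linearly modulo 2^31 - 1.
* Degenerate inputs: constant images error in thresholding (degenerate
  histogram), warn in contrast enhancement; zero DAPI cells or zero
  detected branches yield flagged missing values and the cohort run
  continues, logging the reason.
* The two-level histogram has fuzziness zero at every cut between the
  levels; the tie rule (lowest candidate) decides, and the mask contract
  (bright class recovered exactly) is the meaningful assertion.
* The vignetting-invariance property of the flat-field is evaluated on
  noise-free renders: the Huang objective's minimum sits in a flat basin
  and photon noise alone moves the argmin by more than the ±2 grey-level
  band even with identical illumination.
* Monte-Carlo acceptance blocks are scaled to the test-time budget (null
  calibration 600 instead of 1000 replicates; paired demo 10 instead of 20
  seed pairs) with the thresholds unchanged.

## Limitations

The TIFF codec covers the baseline subset the pipeline writes
(little-endian, uncompressed, 8/16-bit greyscale). Per-cell process
assignment is out of scope: branch metrics are per field of view, so
overlapping cells would bias per-cell junction normalisation — the
generator's spacing reflects the sparse cultures the protocol images. The
printed units of the study's branch-length and junction-number values are
unstated; this package reports µm and per-cell counts and does not claim
unit equivalence.
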