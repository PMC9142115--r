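---
title: "Methods: mammogram preprocessing, enhancement and mass segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mammogram preprocessing, enhancement and mass segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoseg)
```

## The problem

Mass detection in screening mammograms is hampered by three things: the
pectoral muscle, which in mediolateral-oblique (MLO) views overlaps the
breast as a bright triangular wedge and confounds any brightness-driven
segmentation; low and spatially varying contrast; and noise.  `mammoseg`
implements a three-stage pipeline that addresses these in order —
pectoral removal, morphological contrast enhancement, clustering-based
segmentation of the abnormal (mass) region — together with the metrics
used to evaluate each stage and a synthetic phantom generator that
provides ground truth for validation.

## Stage 1: pectoral-muscle removal by seeded region growing

Orientation is decided by intensity mass: the breast (and chest wall)
lies on the vertical image half with the greater total intensity.  The
breast region is the largest 8-connected component above a background
threshold (default 40 of 255), which also discards scanner labels.  A
seed is planted `offset` pixels (default 5) inside the top chest-wall
corner, where the pectoral wedge sits in an MLO view, and a region is
grown from it.

The growth predicate is the choice the method turns on.  The default is
a *running-mean* rule: a neighbouring pixel joins the region when its
intensity is within `tolerance` (default 16 of 255) of the mean of the
region grown so far.  The running mean adapts to the gradual intensity
drift across the muscle.  Growth proceeds in breadth-first waves: each
wave tests all pixels adjacent to the current region (8-connectivity by
default) against the mean frozen at the start of the wave, admits the
passing ones in (row, col) order, then updates the mean.  A pixel
rejected in one wave is re-tested while it remains adjacent, so slow
drift can still absorb it later.  The procedure is deterministic.

A second, *fixed-reference* predicate compares against the seed pixel's
intensity instead.  Its result is exactly the connected component of
the level set `|I - I(seed)| <= tolerance` containing the seed — it is
independent of iteration order and monotone in the tolerance, which
makes it the variant the test suite verifies against an independent
brute-force flood fill.

CC-view images are skipped: there the pectoral muscle hugs the chest
wall as a thin semi-ellipse and corner-seeded growth has no wedge to
capture; the pipeline logs a notice and passes the image through.

## Stage 2: morphological contrast enhancement

With a grayscale structuring element $b$, the bottom-hat transform
$T_b(f) = (f \bullet b) - f$ (closing minus image) extracts dark
structures smaller than $b$, and the top-hat transform
$T_w(f) = f - (f \circ b)$ (image minus opening) extracts bright ones.
The enhanced image is the standard composite

$$g = \mathrm{clip}_{[0,255]}\big(f + T_w(f) - T_b(f)\big),$$

which amplifies bright detail, suppresses dark detail and evens the
contrast across the breast.  Design choices:

* **Element**: disk of radius 15 at side 256, scaled proportionally
  with image side.  The radius must exceed the texture scale of masses
  (so their interiors survive the opening) while staying below the
  pectoral/breast scale.
* **Borders**: replicate (edge) padding, so the frame produces no
  spurious residuals.  All comparisons in the test suite use the same
  convention.
* **Arithmetic**: carried in doubles and clipped to 8 bits once, at the
  end, to avoid double-clipping bias.

Both hat transforms are non-negative by construction (opening never
exceeds the image, closing never falls below it); the tests check this
and exact integer agreement with a naive min/max-filter oracle.

## Stage 3: clustering segmentation and the abnormal-region rule

Five segmenters produce pixel label maps:

* **K-means** (Lloyd, k-means++ seeding) on the 1-D intensity feature.
  Determinism is guaranteed by an explicit seed; empty clusters are
  repaired by re-seeding at the farthest point; the per-iteration
  inertia trace is exposed so the non-increase contract is testable.
* **Spatial K-means** on features $(I,\; w\,\mathrm{row}/M,\;
  w\,\mathrm{col}/N)$; weight $w = 0$ reduces exactly to intensity
  K-means.
* **Mean shift** on intensity: flat-kernel window means iterated on the
  256-bin histogram; converged modes are merged by single linkage with
  tolerance `bandwidth/2`.
* **Spatial mean shift** on joint $(\mathrm{row}, \mathrm{col}, I)$
  features with a flat product kernel.  Joint filtering is
  $O(n^2)$ per iteration, so images beyond 64 pixels a side are
  processed on a strided downsample and labels upsampled by nearest
  neighbour — the same scale decision made for normalized cuts below.
* **Normalized cuts**: pixels of a downsampled image (default cap 32,
  hard cap 64 a side) are graph nodes with affinity
  $\exp(-\Delta I^2/\sigma_I^2)\exp(-\Delta d^2/\sigma_d^2)$ inside a
  pixel radius; the graph is recursively bipartitioned.  Each
  bipartition takes eigenvectors 2 and 3 of the normalized Laplacian,
  sweeps every threshold along each eigenvector's ordering, and keeps
  the split with the smallest normalized-cut value; disconnected
  graphs are first split along components (a zero cut, the exact
  optimum).  Sweeping two eigenvectors rather than one is a cheap
  robustification of the classical spectral sweep: the test suite
  checks the returned cut against exhaustive search on small graphs.

Clustering runs on the whole enhanced frame — the procedure the
pipeline mirrors applies K-means directly to the enhanced image — and
the *abnormal-region rule* then restricts attention to the breast:
among the clusters, the one with the highest mean intensity inside the
breast mask (after pectoral removal) is selected, and its largest
8-connected component is kept provided it reaches `min_area` (25 px at
side 256, scaled quadratically with side).  Brightest-mass is the
standard mammographic prior for this selection; when the label map is
degenerate (a single cluster) the rule falls back to the breast
component itself and says so.

## Evaluation metrics

For images $X, Y$ of size $M \times N$ with $L = 256$ gray levels:
$\mathrm{MSE} = \frac{1}{MN}\sum (X-Y)^2$ and
$\mathrm{PSNR} = 10\log_{10}\frac{(L-1)^2}{\mathrm{MSE}}$.  A second
PSNR mode with the un-squared peak, $10\log_{10}\frac{L-1}{\mathrm{MSE}}$,
is provided because some reports print that form; every report row
records which mode produced it.  The EME divides the image into
$K_1 \times K_2$ blocks (default 8×8; remainder pixels are absorbed
into the last block row/column so every pixel contributes) and averages
$20\log_{10}\frac{I_{\max}+\epsilon}{I_{\min}+\epsilon}$ per block;
$\epsilon = 1$ guards blocks whose minimum is 0, common in the
background.

Segmentation masks are scored by confusion fractions normalised by the
whole image domain, so $TP+TN+FP+FN = 1$ and the accuracy
$(TP+TN)/(TP+TN+FP+FN)$ equals $TP+TN$.  Sensitivity $TP/(TP+FN)$ and
specificity $TN/(TN+FP)$ are reported `NA` with a warning when their
denominators vanish.  Because the lesion is a small fraction of the
frame, domain-normalised accuracy is dominated by true negatives; the
sensitivity is the demanding number to read alongside it.

## The phantom generator

Each phantom composes, on a `side`×`side` canvas (default 256): a flat
background (level 8), a breast half-ellipse attached to the chest-wall
border (level 90, semi-axes 100×115 at side 256), a brighter
right-triangle pectoral wedge in the top chest-wall corner (level 190,
legs 110×70), a Gaussian lesion blob (amplitude 70, sd 14 px), a linear
top-to-bottom illumination ramp (amplitude 10), and additive Gaussian
noise (sd 5).  The truth lesion mask is the set of pixels receiving at
least half the blob's peak — a parameter-free definition whose area has
a closed form ($\pi \cdot 2\ln 2 \cdot \sigma^2$) the tests check.  The
default blob width makes the half-amplitude lesion roughly an eighth of
the image side, matching the typical relative size of masses in
1024-square screening images.  Cohorts draw per-phantom parameters
uniformly from documented jitter ranges out of a single seeded RNG
stream, with per-phantom noise sub-seeds, so any cohort is reproducible
and order-independent.

What the phantom does *not* emulate: fibroglandular texture,
calcification microstructure, scanner labels, skin-line falloff, or
film artifacts.  Passing the cohort-level checks therefore shows the
pipeline's stages compose correctly and recover known structure under
noise, illumination drift and parameter jitter — not clinical-grade
accuracy on real mammograms, which requires expert-annotated data.

## Problem sizes and numerical choices

The validation cohort is 30 phantoms at side 256 with noise sd 5 — large
enough for stable medians, small enough to run comfortably on a
desktop.  Small-scale oracle checks (16×16 to 32×32 images, graphs of
at most 12 nodes) use exhaustive or brute-force references.  K-means
stops on assignment stability or a centroid shift below `tol` (1e-4);
mean shift stops at a mode shift below 1e-3; all tie-breaks (frontier
order, component numbering, threshold sweeps) are fixed and documented
so every code path is deterministic given its seed.

## Known limitations

* The running-mean region growth can leak through a low-contrast
  pectoral boundary; the tolerance trades leakage against
  under-segmentation and 16/255 is a practical default, not a fitted
  constant.
* The brightest-cluster rule finds one dominant mass; multiple or
  non-mass abnormalities (architectural distortion, calcification
  clusters) are out of scope.
* Normalized cuts and spatial mean shift run on downsampled grids;
  their label boundaries are correspondingly coarse.
* CC-view pectoral removal is deliberately not attempted.
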