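# mammoseg

Computerized analysis of screening mammograms for mass detection: an R
package implementing a three-stage pipeline —

1. **Pectoral-muscle removal** — in mediolateral-oblique (MLO) views the
   pectoral muscle overlaps the breast as a bright triangular wedge;
   `mammoseg` detects orientation, isolates the breast, and removes the
   wedge by seeded region growing from the chest-wall corner
   (running-mean membership, tolerance 16/255, 8-connectivity).
2. **Contrast enhancement** — the morphological composite
   `g = clip(f + T_w(f) − T_b(f))`, where `T_w(f) = f − f∘b` (top-hat)
   and `T_b(f) = f•b − f` (bottom-hat) over a disk structuring element,
   amplifies bright detail and evens illumination.
3. **Abnormal-region segmentation** — K-means, spatial K-means, mean
   shift, spatial mean shift, or normalized cuts produce a label map;
   the brightest cluster inside the breast, reduced to its largest
   connected component, is the candidate mass `A_S`.

Evaluation follows the standard suite: MSE, PSNR
(`10·log10((L−1)²/MSE)`, plus the un-squared variant some reports
print), block-based EME local contrast, and domain-normalised confusion
fractions with accuracy `AC = TP + TN`, sensitivity, specificity and
Dice.  A synthetic phantom generator (breast half-ellipse, pectoral
wedge, Gaussian lesion, illumination ramp, noise — with exact ground
truth masks) makes every stage testable without clinical data.

Intended users: medical-image-analysis researchers prototyping
mammogram preprocessing chains, and anyone needing a reproducible,
oracle-tested reference implementation of these classic building
blocks.

## Worked example

```r
library(mammoseg)

ph  <- generate_phantom(phantom_spec(noise_sigma = 5))   # image + truth masks
pre <- remove_pectoral(ph$image)                          # stage 1
enh <- enhance_contrast(pre$cleaned, default_se(ph$image))# stage 2
seg <- kmeans_segment(enh, k = 4, seed = 2)               # stage 3
roi <- pre$breast_mask & !pre$pectoral_mask
A_S <- extract_abnormal_region(seg$labels, enh, roi)

dice(pre$pectoral_mask, ph$truth$pectoral_mask)
#> [1] 0.9992392
eme(pre$cleaned); eme(enh)
#> [1] 26.91878
#> [1] 33.91315
accuracy(A_S, ph$truth$lesion_mask)
#> [1] 0.985199
sensitivity_specificity(A_S, ph$truth$lesion_mask)
#> $sensitivity
#> [1] 0.9847597
#> $specificity
#> [1] 0.9852048
```

The pectoral wedge is recovered almost exactly (Dice 0.999), the
enhancement raises block contrast (EME 26.9 → 33.9 dB), and the
segmented mass overlaps the true lesion with 98.5% domain accuracy and
98.5% sensitivity.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","mammoseg.R",package="mammoseg"))')
Rscript $CLI phantom  --n 5 --seed 1 --out-dir data/
Rscript $CLI pipeline --in data/ --out run/ --method kmeans --k 4 --seed 1
```

`run/results.csv` holds one row per image (MSE, PSNR, EME before/after,
confusion fractions, accuracy, sensitivity, specificity, Dice) plus
per-BI-RADS-category means, alongside a `config.json` audit sidecar;
identical config and seed reproduce the CSV bit-for-bit.

## Package layout

- `R/image_io.R` — PGM (P2/P5) and 8-bit grayscale PNG readers/writers,
  square padding, metadata CSV validation
- `R/phantom.R` — phantom specification, rendering, cohorts
- `R/preprocess.R` — orientation, breast mask, seeded region growing,
  pectoral removal
- `R/enhance.R` — grayscale morphology, hat transforms, enhancement,
  histogram
- `R/segment.R` — the five segmenters and the abnormal-region rule
- `R/metrics.R` — MSE/PSNR/EME/confusion/accuracy/Dice and report rows
- `R/pipeline.R` — batch pipeline with config sidecar
- `inst/cli/mammoseg.R` — `phantom | preprocess | enhance | segment |
  evaluate | pipeline` subcommands
- `vignettes/mammoseg-methods.Rmd` — models, parameters, design
  decisions and limitations
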