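# delamina

Quantitative analysis of aortic dissection in rodent models: how strongly
does the aortic media resist radial separation, and how does its
microstructure change as dissection develops?

The package implements the three measurement layers of such a study and the
statistics that join them:

* **Delamination strength** from T-peel force–time traces. The recorded
  force is normalized by sample width to peel tension `T_p = T / w` and
  fitted with the sigmoid `T_p(t) = S_d / (1 + a·exp(−b(t − c)))`; the
  plateau `S_d` (N/m) is the delamination strength. Traces are truncated at
  the terminal failure drop before fitting.
* **Medial composition** from stained sections. Each ROI pixel is assigned
  to elastin / collagen / smooth muscle / background by the nearest RGB
  centroid (centroids are means of 30 annotated points per component);
  area fractions λ_ela (Elastica–Masson) and λ_col (Azan) are pixel counts
  over the ROI size.
* **Interlaminar elastin fibers** from EM images: elastin by green-channel
  thresholding, elastic laminas by binary opening (erode ×5, dilate ×5,
  3×3 square element) plus particle filtering (area ≥ 0.1 µm², circularity
  4πA/P² in [0, 0.3]), fibers by mask subtraction, and λ_fibers as the
  fiber area over the media area.
* **Group statistics**: two-way (group × direction) ANOVA, Tukey–Kramer
  all-pairs comparisons with studentized-range p-values, Pearson
  correlation with Student's t-test, and mean ± SD summaries.

A synthetic-data generator produces sigmoid-plateau peel traces and layered
histology-like images with exact ground-truth masks, emulating a three-group
design (Control / Pre-dissection / Dissection) so that every stage is
testable end to end without animal data.

## Worked example

The `analysis/` drivers run the whole study as a numbered workflow:

```sh
Rscript analysis/01_simulate.R     # synthetic study -> results/study/
Rscript analysis/02_measure.R      # fits + segmentations -> measurements.csv
Rscript analysis/03_statistics.R   # ANOVA, Tukey, correlations -> results/
Rscript analysis/04_replication.R  # significance across replicate studies
```

With the default seed (42), stage 2 prints the per-group delamination
strength and fiber fraction recovered by the full pipeline:

```
Delamination strength (N/m) by group x direction:
  group          direction     n     N  mean    sd
1 Control        theta        20    10 19.3   4.96
2 Control        z            20    10 19.1   6.07
3 Dissection     theta        14     7  9.48  3.69
4 Dissection     z            14     7  9.55  2.35
5 Pre-dissection theta        10     5 16.8   1.92
6 Pre-dissection z            10     5 16.0   2.87

Interlaminar-fiber fraction by group:
  group              n     N   mean     sd
1 Control            9     3 0.102  0.0119
2 Dissection         9     3 0.0542 0.0144
3 Pre-dissection     9     3 0.0897 0.0146
```

Strength falls Control → Pre-dissection → Dissection (generator truth
20 / 16 / 11 N/m) and the fiber fraction falls with it (truth 10.4 / 8.6 /
5.2%). Stage 3 then reports five of the six pairwise Tukey–Kramer
comparisons significant at α = 0.05 — the Control vs Pre-dissection fiber
comparison (1.8 percentage points against SD 1.6 at n = 9) is intrinsically
marginal — and a significant strength–fiber correlation in the θ direction
(R = 0.744, p = 0.0015).

Single-sample use mirrors the pipeline:

```r
library(delamina)
tr  <- gen_peel_trace(peel_trace_params(S_d_true = 20, noise_sd = 0.003))
fit <- delamination_strength(tr$record)   # fit$S_d ~ 20 N/m

img <- gen_histology_image(histo_image_params(fiber_fraction = 0.10,
                                              color_noise_sd = 8))
ext <- extract_interlaminar(img$image, img$roi, img$px_size)
ext$lambda_fibers                         # ~ 0.10
```

## Package layout

```
R/                  generators, peel mechanics, segmentation, morphology,
                    statistics, pipeline (the API everything else calls)
analysis/           numbered workflow drivers
scripts/acceptance.R  headline-quantity recomputation
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette: models, parameters, design choices
```
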