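# posquant

Automated quantification of photoreceptor outer segments (POS) on retinal
microscopy images, at two scales:

* **TEM arm** — on transmission electron micrographs, measures how well the
  stacked POS disc membranes are mutually aligned. Membrane orientation is
  estimated perpendicular to the image intensity gradient (optimized 5x5
  derivative operator with sub-microdegree orientation bias), treated as a
  nematic director θ ∈ [0°, 180°) with weight m = |∇I|, and summarized per
  region of interest by the scalar nematic order parameter ("coherency") of
  the Q-tensor
  Q = Σ m(x) [[cos²θ − ½, cosθ sinθ], [cosθ sinθ, sin²θ − ½]]:
  coherency = 2√(Q²ₓₓ + Q²ₓᵧ)/Σm = |Σ m e^{2iθ}|/Σm ∈ [0, 1].
  Local coherency (25×25 px box) vs global coherency (whole ROI) and their
  ratio index POS maturation; per-replicate alignment aggregates the ROI
  directors once more with a Q-tensor.
* **LM arm** — on 3D fluorescence stacks of S-opsin labelled cone POS,
  segments signal from background with a 100-tree, depth-2 random-forest
  pixel classifier over a convolutional feature bank, validates against
  reference annotations (accuracy/precision/recall/F1/Jaccard), and
  quantifies each segmented POS (volume, bounding-box height, Feret
  diameter, sphericity, intensity) after isotropic rescaling to 0.323 um
  voxels, with a pooled 5–95 % volume filter and replicate-averaged group
  statistics (ANOVA + Tukey, Welch's t, Pearson matrix).

Both arms ship synthetic generators with exact ground truth
(`make_membrane_image()`, `make_pos_phantom()`), plus plain-format I/O for
grayscale TIFF and ImageJ ROI files. See the methods vignette
(`vignettes/posquant-methods.Rmd`) for the models, parameter choices and
limitations.

## Worked example

```r
library(posquant)

## TEM: a coherent ("stacked") vs a patchwork ("partly stacked") texture
mature   <- make_membrane_image(membrane_spec(size = 128, angle_deg = 30,
                                              jitter_sd_deg = 5, seed = 1))
immature <- make_membrane_image(membrane_spec(size = 128,
                                              patches = c(0, 45, 90, 135),
                                              seed = 1))
roi <- matrix(TRUE, 128, 128)
for (mb in list(mature, immature)) {
  f  <- gradient_to_orientation(compute_gradient(mb$image))
  g  <- global_coherency(f, roi)
  cm <- local_coherency_map(f, roi)
  print(summarize_roi(cm, g))
}
```

```
  roi_id mean_local_coherency global_coherency global_angle_deg ratio_global_to_local
1 mature                0.994            0.986               30                 0.992
1 immature              0.824            0.012               79                 0.0145
```

The coherent texture scores high everywhere with ratio ≈ 1; the patchwork is
locally well aligned (0.82) but globally cancelled (0.01), the signature of
immature, partly stacked POS.

```r
## LM: segment and quantify a 20-object phantom
ph  <- make_pos_phantom(phantom_spec(seed = 1))
st  <- preprocess_stack(ph$stack)          # 3D top-hat + max-normalize to 4096
mod <- train_pos_classifier(list(img1 = st),
                            sample_annotations(ph, 100, "img1", seed = 2),
                            seed = 3)
pred <- predict_pos(mod, st)
round(segmentation_scores(confusion_matrix(pred, ph$mask)), 3)
#> accuracy precision    recall        f1   jaccard
#>    1.000     0.999     0.996     0.997     0.994
quantify_mask(pred, st, image_id = "phantom1")$summary
#>      image n_pos summed_volume_um3 mean_volume_um3 mean_bbox_height_um mean_sphericity
#> 1 phantom1    18              75.6            3.66                3.59           0.866
```

All 20 planted objects are recovered as labels (Jaccard 0.994 against the
ground-truth mask); the pooled 5–95 % volume filter then excludes the two
extreme volumes within this single image (`n_pos = 18`), while the summed
volume stays unfiltered by design.

## Command line

`inst/cli/posquant.R` exposes the pipelines as subcommands
(`tem-analyze`, `lm-preprocess`, `lm-train`, `lm-predict`, `lm-validate`,
`lm-quantify`, `synth-membrane`, `synth-phantom`), e.g.

```sh
Rscript inst/cli/posquant.R tem-analyze \
  --image img.tif --rois img_rois.zip --box-radius 12 --out results/
```

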