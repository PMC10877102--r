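# radfoci

Automated quantification of DNA damage foci in confocal microscopy of
irradiated tumor tissue, for ex vivo radiosensitivity assessment.

Tissue slices irradiated outside the patient and stained for DAPI
(nuclei) and 53BP1 (double-strand-break repair foci) carry a candidate
predictive biomarker: the number of unrepaired damage foci per nucleus a
fixed time after exposure. Counting them by hand does not scale — each
183.65 × 183.65 µm² field (1024 × 1024 px, 1 µm z-steps) holds hundreds of
clustered, variably stained nuclei. `radfoci` implements the full
analysis chain in R:

* **Z-stack preparation** — select the DAPI plane with the highest mean
  intensity; build the 3-slice maximum projection of the foci channel
  around it.
* **Semantic segmentation** — a compact U-net per channel (per-image
  normalization, batch norm after every convolution, soft Jaccard loss,
  Adam at 1e-3, dihedral + contrast augmentation,
  lowest-validation-loss checkpointing), trained at 512 × 512 for nuclei
  and native resolution for foci. The network engine (im2col convolutions
  over BLAS, backprop verified against finite differences) is
  self-contained in the package.
* **Nucleus post-processing** — hole filling, watershed separation of
  touching nuclei (tolerance 4 on the distance transform), border
  exclusion and a 10 µm² minimum area.
* **Quantification** — overlay foci on nuclei (foci outside nuclei are
  background and are discarded) and measure per nucleus the foci count
  and the density `foci / (area_µm² × projection_height_µm)`.
* **Evaluation** — pixel Dice/IoU, object-level Dice with one-to-one
  centroid matching within 3 px (strict), agreement regression, paired
  t-tests.
* **Statistics** — per-patient Kruskal–Wallis across conditions
  (control / photon / proton), Dunn's post hoc (Bonferroni) when three or
  more groups and the omnibus test is significant, and intra-tumor
  intra-condition variation as relative standard deviation.
* **Synthetic scenes** — a calibrated generator of DAPI/53BP1 stacks with
  exact ground truth (clustered nuclei, center dimming, dose-dependent
  Poisson foci, out-of-focus contributions, extranuclear speckles), so
  training, quantification and statistics are testable without patient
  data.

## Worked example

```r
library(radfoci)

# a 3-patient synthetic cohort: control (0 Gy) vs photon (5 Gy), 5 images
# each, 256x256 px at the acquisition calibration
scenes <- generate_cohort(
  n_patients = 3, images_per_condition = 5,
  conditions = data.frame(condition = c("control", "photon"), dose_Gy = c(0, 5)),
  base_spec = scene_spec(n_nuclei = 15), seed = 2024)

manifest <- do.call(rbind, lapply(scenes, write_scene, dir = "cohort/img"))
res <- run_pipeline(pipeline_config(manifest, "cohort/out", use_gt = TRUE))

cmp <- compare_conditions(res$nuclei, "foci_per_um3")
for (x in cmp)
  cat(sprintf("%s  KW H = %.1f  p = %.3g  significant: %s\n",
              x$patient_id, x$kw_h, x$kw_p, x$significant))
```

```
P01  KW H = 111.0  p = 5.83e-26  significant: TRUE
P02  KW H = 111.3  p = 4.96e-26  significant: TRUE
P03  KW H = 111.9  p = 3.66e-26  significant: TRUE
```

Every patient shows the dose effect: at 2 foci/Gy/nucleus the 5 Gy
photon condition has a far higher foci-per-volume distribution than its
control (per-nucleus values pooled over the five images per condition).
The per-image spread of the same quantity, as relative SD:

```r
head(variation_report(res$nuclei, "foci_per_um3"), 4)
```

```
  patient_id condition n_images relative_sd_percent
1        P01   control        5            39.20206
2        P02   control        5            27.77802
3        P03   control        5            47.50835
4        P01    photon        5            14.32072
```

Control images have few foci, so their image-to-image variation is
proportionally large; treated images are tighter — the same qualitative
pattern the assay shows on real tissue.

To train the segmenters instead of using the ground-truth bypass, see
`?unet_config`, `?train_unet` and `?predict_mask`; `inst/cli/radfoci.R`
exposes `simulate`, `prep`, `train`, `predict`, `postprocess`,
`quantify`, `evaluate`, `stats` and `run` verbs for shell use.

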