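test_that("overlay keeps foci inside nuclei and assigns the majority label", {
  lab <- matrix(0L, 32, 32)
  lab[5:15, 5:15] <- 3L
  lab[5:15, 17:27] <- 1L
  nuclei <- label_map(lab, PX)

  # fully inside nucleus 3
  fm <- matrix(0L, 32, 32); fm[8:9, 8:9] <- 1L
  rec <- overlay_foci(semantic_mask(fm, PX), nuclei)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$parent_nucleus_id, 3L)
  expect_identical(rec$area_px, 4L)

  # fully in background: discarded
  fm2 <- matrix(0L, 32, 32); fm2[25:26, 2:3] <- 1L
  expect_identical(nrow(overlay_foci(semantic_mask(fm2, PX), nuclei)), 0L)

  # straddling the nucleus edge: clipped to the intersection
  fm3 <- matrix(0L, 32, 32); fm3[10, 13:19] <- 1L  # 3 px in nucleus 3, 3 px in nucleus 1, 1 px between
  rec3 <- overlay_foci(semantic_mask(fm3, PX), nuclei)
  # the gap column 16 splits the intersection into two components
  expect_identical(sort(rec3$parent_nucleus_id), c(1L, 3L))
  expect_identical(sum(rec3$area_px), 6L)
  expect_equal(rec3$area_um2, rec3$area_px * PX^2)

  expect_error(overlay_foci(semantic_mask(matrix(0L, 8, 8), PX), nuclei),
               "shape")
})

test_that("per-nucleus density follows count / (area x height)", {
  # one 100 um^2 nucleus with 6 foci at 3 um projection height -> 0.02
  side <- round(sqrt(100) / PX)  # ~55.8 -> 56 px
  lab <- matrix(0L, 80, 80)
  lab[10:(9 + side), 10:(9 + side)] <- 1L
  area_um2 <- side^2 * PX^2
  foci <- data.frame(focus_id = 1:6, parent_nucleus_id = 1L)
  nr <- measure_nuclei(label_map(lab, PX), foci, 3)
  expect_identical(nr$foci_count, 6L)
  expect_equal(nr$foci_per_um3, 6 / (area_um2 * 3))
  expect_equal(nr$foci_per_um3, 0.02, tolerance = 0.01)

  # zero foci -> density 0; partition across nuclei
  lab[40:60, 40:60] <- 2L
  nr2 <- measure_nuclei(label_map(lab, PX),
                        data.frame(focus_id = 1:2, parent_nucleus_id = c(1L, 1L)),
                        3)
  expect_identical(nr2$foci_count, c(2L, 0L))
  expect_identical(nr2$foci_per_um3[2], 0)

  expect_error(measure_nuclei(label_map(lab, PX),
                              data.frame(focus_id = 1, parent_nucleus_id = 9L), 3),
               "non-existent")
  expect_error(measure_nuclei(label_map(lab, PX), foci, 0), "projection_height")
})

test_that("image summaries equal brute-force recomputation", {
  set.seed(31)
  meta <- image_meta("P02", "photon", 5, 2L)
  nr <- data.frame(foci_per_um3 = runif(7, 0, 0.05))
  fr <- data.frame(area_um2 = runif(12, 0.05, 0.6))
  s <- summarize_image(nr, fr, meta, 3)
  expect_equal(s$mean_foci_per_um3, sum(nr$foci_per_um3) / 7)
  expect_equal(s$median_foci_per_um3, sort(nr$foci_per_um3)[4])
  expect_equal(s$mean_focus_area_um2, sum(fr$area_um2) / 12)
  expect_identical(s$n_nuclei, 7L)

  # density examples: mean = median for a symmetric triple, single nucleus
  s2 <- summarize_image(data.frame(foci_per_um3 = c(0.01, 0.02, 0.03)),
                        fr[0, , drop = FALSE], meta, 3)
  expect_equal(s2$mean_foci_per_um3, 0.02)
  expect_equal(s2$median_foci_per_um3, 0.02)
  s3 <- summarize_image(data.frame(foci_per_um3 = 0.013), fr[0, , drop = FALSE],
                        meta, 3)
  expect_equal(s3$mean_foci_per_um3, s3$median_foci_per_um3)

  # empty image: counts 0, statistics missing
  s4 <- summarize_image(nr[0, , drop = FALSE], fr[0, , drop = FALSE], meta, 3)
  expect_identical(s4$n_nuclei, 0L)
  expect_true(is.na(s4$mean_foci_per_um3))
})

test_that("foci counts are conserved between overlay and nucleus records", {
  sc <- generate_scene(scene_spec(seed = 55, dose_Gy = 3),
                       image_meta("P1", "photon", 3))
  fr <- overlay_foci(sc$gt_foci, sc$gt_nuclei, sc$meta)
  nr <- measure_nuclei(sc$gt_nuclei, fr, 3, sc$meta)
  expect_identical(sum(nr$foci_count), nrow(fr))
  # on ground truth the recovered counts equal the generator's
  expect_identical(nr$foci_count,
                   tabulate(sc$gt_foci_centers$nucleus_id,
                            nbins = max(sc$gt_nuclei$raster)))
})

test_that("recovered densities track ground truth across doses", {
  scenes <- list()
  for (d in c(0, 2, 5)) for (s in 1:3)
    scenes[[length(scenes) + 1]] <- generate_scene(
      scene_spec(seed = 700 + 10 * d + s, dose_Gy = d, n_nuclei = 15L),
      image_meta("P1", if (d == 0) "control" else "photon", d, s))
  rec_mean <- c(); gt_mean <- c(); dose <- c()
  for (sc in scenes) {
    fr <- overlay_foci(sc$gt_foci, sc$gt_nuclei, sc$meta)
    nr <- measure_nuclei(sc$gt_nuclei, fr, 3, sc$meta)
    gt <- gt_measurements(sc)$nuclei
    rec_mean <- c(rec_mean, mean(nr$foci_per_um3))
    gt_mean <- c(gt_mean, mean(gt$foci_per_um3))
    dose <- c(dose, sc$meta$dose_Gy)
  }
  fit_dose <- agreement_regression(rec_mean, dose)
  expect_gt(fit_dose$slope, 0)
  fit <- agreement_regression(rec_mean, gt_mean)
  expect_gte(fit$r_squared, 0.9)
})
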