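test_that("soft Jaccard loss matches its closed form", {
  t <- matrix(0, 20, 20); t[1:10, ] <- 1
  expect_lte(soft_jaccard_loss(t, t), 1e-5)
  expect_gte(soft_jaccard_loss(1 - t, t), 1 - 1e-3)

  # uniform 0.5 prediction vs 25% foreground: 1 - 0.125/(0.5+0.25-0.125)
  t2 <- matrix(0, 16, 16); t2[1:8, 1:8] <- 1
  p2 <- matrix(0.5, 16, 16)
  expect_equal(soft_jaccard_loss(p2, t2), 0.8, tolerance = 1e-5)

  expect_error(soft_jaccard_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shape")
  expect_error(soft_jaccard_loss(matrix(2, 2, 2), matrix(0, 2, 2)), "0, 1")
})

test_that("the loss gradient matches finite differences", {
  set.seed(5)
  p <- matrix(runif(64, 0.05, 0.95), 8)
  t <- matrix(rbinom(64, 1, 0.4), 8)
  g <- radfoci:::soft_jaccard_grad(p, t)
  eps <- 1e-7
  for (i in sample(64, 6)) {
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    num <- (soft_jaccard_loss(pp, t) - soft_jaccard_loss(pm, t)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("dihedral transforms are invertible and area-preserving", {
  set.seed(2)
  m <- matrix(runif(48), 6, 8)
  for (k in 1:8) {
    tr <- dihedral_transform(m, k)
    expect_equal(dihedral_transform(tr, k, inverse = TRUE), m)
    expect_equal(sum(tr), sum(m))
  }
})

test_that("augmentation keeps pairs aligned and applies exact contrast", {
  img <- matrix(100, 10, 10)
  msk <- matrix(rbinom(100, 1, 0.3), 10)
  # identity: no dihedral, and contrast 1 only
  out <- augment_pair(img, msk, list(dihedral = FALSE, contrast_factors = numeric(0)))
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)

  # contrast 0.8 on a flat raster: clipping to [100, 100] leaves 100; on a
  # two-level raster the bright level scales
  img2 <- matrix(c(50, 100), 10, 10)
  out2 <- augment_pair(img2, msk, list(dihedral = FALSE, contrast_factors = c(0.8)))
  repeat {
    if (any(out2$image != img2)) break
    out2 <- augment_pair(img2, msk, list(dihedral = FALSE, contrast_factors = c(0.8)))
  }
  expect_true(all(out2$image %in% c(50, 80)))

  # any dihedral draw preserves mask foreground area
  set.seed(8)
  for (i in 1:8) {
    o <- augment_pair(img2, msk, list(dihedral = TRUE, contrast_factors = c(0.8, 1.2)))
    expect_equal(sum(o$mask), sum(msk))
  }
})

test_that("built networks have the contracted output shape and range", {
  cfg <- unet_config("foci", depth = 2L, base_filters = 4L, seed = 1)
  mdl <- build_unet(cfg)
  rf <- asNamespace("radfoci")
  out <- rf$unet_forward(mdl$params, mdl$state,
                         matrix(0, 64 * 64, 1), 1L, 64L, 64L, 2L,
                         training = FALSE)
  expect_identical(dim(out$prob), c(64L * 64L, 1L))
  expect_true(all(out$prob > 0 & out$prob < 1))

  # same config and seed give identical parameter counts and values
  mdl2 <- build_unet(cfg)
  expect_identical(n_parameters(mdl), n_parameters(mdl2))
  expect_identical(get("enc1_1_W", mdl$params), get("enc1_1_W", mdl2$params))

  expect_error(unet_config("foci", input_size = c(100L, 100L), depth = 4L),
               "divisible")
})

test_that("backpropagation matches finite differences end to end", {
  rf <- asNamespace("radfoci")
  set.seed(1)
  mdl <- build_unet(unet_config("foci", depth = 1L, base_filters = 2L, seed = 3))
  P <- mdl$params; S <- mdl$state
  X <- matrix(runif(64), ncol = 1)
  Tg <- matrix(rbinom(64, 1, 0.3), ncol = 1)
  fwd <- function() {
    out <- rf$unet_forward(P, S, X, 1L, 8L, 8L, 1L, training = TRUE)
    soft_jaccard_loss(out$prob, Tg)
  }
  out <- rf$unet_forward(P, S, X, 1L, 8L, 8L, 1L, training = TRUE)
  grads <- new.env(); grads$P_env <- P; grads$skip_stack <- list()
  rf$unet_backward(out$tape, rf$soft_jaccard_grad(out$prob, Tg), grads)
  S0 <- rf$env_snapshot(S)
  reset <- function() for (nm in ls(S0)) assign(nm, get(nm, S0), envir = S)
  eps <- 1e-3
  for (nm in c("enc1_2_W", "dec1_up_W", "dec1_1_g", "out_W")) {
    p0 <- get(nm, envir = P)
    for (i in sample(length(p0), min(3, length(p0)))) {
      p <- p0; p[i] <- p[i] + eps; assign(nm, p, envir = P); reset()
      lp <- fwd()
      p <- p0; p[i] <- p[i] - eps; assign(nm, p, envir = P); reset()
      lm <- fwd()
      assign(nm, p0, envir = P)
      num <- (lp - lm) / (2 * eps)
      # single-precision convolutions: a few percent relative agreement
      expect_lt(abs(num - grads[[nm]][i]) / max(1e-6, abs(num) + abs(grads[[nm]][i])),
                0.05)
    }
  }
})

test_that("short training improves on the untrained model and checkpoints the best epoch", {
  model <- small_nuclei_model()
  expect_identical(nrow(model$history), 8L)
  expect_identical(model$best_epoch, which.min(model$history$val_loss))

  untrained <- build_unet(model$config)
  val <- lapply(11:13, nuclei_pair)
  expect_lt(unet_validation_loss(model, val),
            unet_validation_loss(untrained, val))
})

test_that("a trained model serializes and reloads with identical predictions", {
  model <- small_nuclei_model()
  dir <- withr::local_tempdir()
  save_unet(model, dir)
  back <- load_unet(dir)
  pr <- nuclei_pair(17)
  m1 <- predict_mask(model, pr$image, pixel_size_um = PX)
  m2 <- predict_mask(back, pr$image, pixel_size_um = PX)
  expect_identical(m1$raster, m2$raster)
})

test_that("nuclei-mode prediction resamples and restores the input geometry", {
  model <- small_nuclei_model()  # input_size 64x64
  pr <- nuclei_pair(18, size = 128L, n_nuclei = 10L)
  m <- predict_mask(model, pr$image, pixel_size_um = PX)
  expect_identical(dim(m$raster), c(128L, 128L))
  expect_equal(m$pixel_size_um, PX)
  expect_error(predict_mask(build_unet(model$config), pr$image,
                            pixel_size_um = PX), "untrained")
})

test_that("predictions are approximately rotation-equivariant on scenes", {
  model <- small_nuclei_model()
  pr <- nuclei_pair(19)
  direct <- predict_mask(model, pr$image, pixel_size_um = PX)$raster
  rot <- predict_mask(model, dihedral_transform(pr$image, 2),
                      pixel_size_um = PX)$raster
  back <- dihedral_transform(rot, 2, inverse = TRUE)
  expect_gte(mean(back == direct), 0.9)
})
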