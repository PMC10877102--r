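msk <- function(m) semantic_mask(m, PX)

test_that("pixel DSC and IoU follow their defining equations", {
  a <- matrix(0L, 10, 10); a[2:5, 2:5] <- 1L
  expect_equal(pixel_metrics(msk(a), msk(a))[c("dsc_pixel", "iou_pixel")],
               list(dsc_pixel = 1, iou_pixel = 1))

  b <- matrix(0L, 10, 10); b[7:9, 7:9] <- 1L
  r <- pixel_metrics(msk(a), msk(b))
  expect_equal(r$dsc_pixel, 0)
  expect_equal(r$iou_pixel, 0)

  # constructed TP=3, FP=3, FN=1 on a 10x10 grid
  truth <- matrix(0L, 10, 10); truth[1, 1:4] <- 1L
  pred <- matrix(0L, 10, 10); pred[1, 1:3] <- 1L; pred[2, 1:3] <- 1L
  r2 <- pixel_metrics(msk(pred), msk(truth))
  expect_identical(c(r2$tp_px, r2$fp_px, r2$fn_px), c(3L, 3L, 1L))
  expect_equal(r2$dsc_pixel, 6 / 10)
  expect_equal(r2$iou_pixel, 3 / 7)

  # both empty: 1 by convention
  z <- matrix(0L, 4, 4)
  expect_equal(pixel_metrics(msk(z), msk(z))$dsc_pixel, 1)
  expect_error(pixel_metrics(msk(a), msk(matrix(0L, 4, 4))), "shape")
})

test_that("DSC >= IoU with the 2 IoU / (1 + IoU) identity on random masks", {
  set.seed(77)
  for (i in 1:40) {
    p <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20)
    t <- matrix(rbinom(400, 1, runif(1, 0.1, 0.6)), 20)
    r <- pixel_metrics(msk(p), msk(t))
    expect_gte(r$dsc_pixel, r$iou_pixel)
    expect_equal(r$dsc_pixel, 2 * r$iou_pixel / (1 + r$iou_pixel),
                 tolerance = 1e-12)
    if (r$dsc_pixel > r$iou_pixel)
      expect_true(r$dsc_pixel > 0 && r$dsc_pixel < 1)
  }
})

test_that("object matching is one-to-one, optimal, and strict at the radius", {
  # close pair: distance sqrt(2) < 3
  r1 <- object_dsc(msk(point_mask(16, 16, list(c(5, 5)))),
                   msk(point_mask(16, 16, list(c(6, 6)))))
  expect_identical(r1$tp_obj, 1L)
  expect_equal(r1$dsc_object, 1)

  # far pair: no match
  r2 <- object_dsc(msk(point_mask(16, 16, list(c(0, 0)))),
                   msk(point_mask(16, 16, list(c(10, 10)))))
  expect_equal(r2$dsc_object, 0)

  # two predictions, one truth: one TP + one FP -> 2/3
  r3 <- object_dsc(msk(point_mask(16, 16, list(c(5, 5), c(7, 5)))),
                   msk(point_mask(16, 16, list(c(5, 6)))))
  expect_identical(c(r3$tp_obj, r3$fp_obj, r3$fn_obj), c(1L, 1L, 0L))
  expect_equal(r3$dsc_object, 2 / 3)
  # the optimal assignment picks the closer prediction (distance 1)
  expect_equal(r3$matches$distance, 1)

  # centers exactly 3.0 px apart are NOT matched (strict <)
  r4 <- object_dsc(msk(point_mask(16, 16, list(c(2, 2)))),
                   msk(point_mask(16, 16, list(c(2, 5)))))
  expect_identical(r4$tp_obj, 0L)

  # both empty -> 1 by convention
  expect_equal(object_dsc(msk(matrix(0L, 8, 8)), msk(matrix(0L, 8, 8)))$dsc_object, 1)
})

test_that("object matching agrees with brute-force enumeration and is symmetric", {
  set.seed(91)
  for (i in 1:25) {
    # even coordinates keep single-pixel objects from 8-connecting
    np <- sample(0:5, 1); nt <- sample(0:5, 1)
    cp <- unique(data.frame(row = sample(seq(0, 14, 2), np, TRUE),
                            col = sample(seq(0, 14, 2), np, TRUE)))
    ct <- unique(data.frame(row = sample(seq(0, 14, 2), nt, TRUE),
                            col = sample(seq(0, 14, 2), nt, TRUE)))
    mp <- msk(point_mask(16, 16, split(as.matrix(cp), seq_len(nrow(cp)))))
    mt <- msk(point_mask(16, 16, split(as.matrix(ct), seq_len(nrow(ct)))))
    r <- object_dsc(mp, mt)
    bf <- brute_force_match(cp[order(cp$row, cp$col), , drop = FALSE],
                            ct[order(ct$row, ct$col), , drop = FALSE], 3)
    expect_identical(r$tp_obj, bf$tp)
    if (r$tp_obj > 0)
      expect_equal(sum(r$matches$distance), bf$total, tolerance = 1e-9)
    # swapping prediction and truth swaps FP and FN, keeps DSC
    rs <- object_dsc(mt, mp)
    expect_identical(rs$tp_obj, r$tp_obj)
    expect_identical(rs$fp_obj, r$fn_obj)
    expect_identical(rs$fn_obj, r$fp_obj)
    expect_equal(rs$dsc_object, r$dsc_object)
  }
})

test_that("agreement regression reproduces affine relations and the Pearson oracle", {
  x <- c(1, 2, 3, 4, 5)
  r <- agreement_regression(x, x)
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)

  r2 <- agreement_regression(2 * x + 1, x)
  expect_equal(r2$r_squared, 1)
  expect_equal(r2$slope, 2)
  expect_equal(r2$intercept, 1)

  set.seed(13)
  truth <- runif(30, 0, 10)
  pred <- 1.4 * truth + rnorm(30, 0, 0.8)
  r3 <- agreement_regression(pred, truth)
  # independent closed-form Pearson correlation
  pearson <- sum((truth - mean(truth)) * (pred - mean(pred))) /
    sqrt(sum((truth - mean(truth))^2) * sum((pred - mean(pred))^2))
  expect_equal(r3$r_squared, pearson^2, tolerance = 1e-9)
  # reference fit from the stats library
  fit <- summary(stats::lm(pred ~ truth))
  expect_equal(r3$slope, fit$coefficients["truth", 1], tolerance = 1e-10)
  expect_equal(r3$slope_se, fit$coefficients["truth", 2], tolerance = 1e-10)
  expect_equal(r3$intercept_se, fit$coefficients["(Intercept)", 2],
               tolerance = 1e-10)

  expect_error(agreement_regression(1:2, 1:2), "length")
  expect_error(agreement_regression(1:4, rep(1, 4)), "variance")
})

test_that("the paired comparison behaves like a two-sided paired t-test", {
  a <- c(0.9, 0.85, 0.92, 0.88)
  r <- paired_dsc_comparison(a, a)
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(17)
  b <- a + 0.1 + rnorm(4, 0, 0.002)
  r2 <- paired_dsc_comparison(b, a)
  expect_lt(r2$p_value, 0.01)
  ref <- stats::t.test(b, a, paired = TRUE)
  expect_equal(r2$t_statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r2$p_value, ref$p.value, tolerance = 1e-10)

  # minimal n = 2 computes with one degree of freedom
  r3 <- paired_dsc_comparison(c(0.8, 0.9), c(0.7, 0.75))
  expect_equal(r3$df, 1)
  expect_true(is.finite(r3$t_statistic))
})
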