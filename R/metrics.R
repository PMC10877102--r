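#' Pixelwise segmentation metrics
#'
#' True/false positives and negatives are counted pixelwise against the
#' ground truth; the Dice similarity coefficient is `2TP/(2TP+FP+FN)` and
#' the intersection-over-union (Jaccard index) is `TP/(TP+FP+FN)`. When
#' both masks are empty, both metrics are 1 by convention.
#'
#' @param pred,truth [semantic_mask] objects of the same shape.
#' @return A list with `dsc_pixel`, `iou_pixel`, `tp_px`, `fp_px`, `fn_px`.
#' @export
pixel_metrics <- function(pred, truth) {
  stopifnot(inherits(pred, "semantic_mask"), inherits(truth, "semantic_mask"))
  if (!all(dim(pred$raster) == dim(truth$raster)))
    stopf("prediction and ground truth must share the same shape")
  p <- pred$raster > 0L; t <- truth$raster > 0L
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
  if (tp + fp + fn == 0L)
    return(list(dsc_pixel = 1, iou_pixel = 1, tp_px = 0L, fp_px = 0L, fn_px = 0L))
  list(dsc_pixel = 2 * tp / (2 * tp + fp + fn),
       iou_pixel = tp / (tp + fp + fn),
       tp_px = tp, fp_px = fp, fn_px = fn)
}

#' Object-level Dice with centroid matching
#'
#' Objects are the 8-connected components of each mask; their centroids are
#' unweighted means of member pixel coordinates. Predicted and true objects
#' are matched one-to-one so that the number of matched pairs is maximal
#' and, among such matchings, the total center distance is minimal (optimal
#' assignment); a pair is matchable only if its center distance is strictly
#' below `max_center_distance_px`. `TP` = matched pairs, `FP` = unmatched
#' predictions, `FN` = unmatched truths, `DSC_object = 2TP/(2TP+FP+FN)`.
#' The default radius of 3 px is the average focus size rounded up.
#'
#' @param pred_mask,truth_mask [semantic_mask] objects of the same shape.
#' @param max_center_distance_px matching radius in pixels (strict `<`).
#' @return A list with `dsc_object`, `tp_obj`, `fp_obj`, `fn_obj` and the
#'   matched pair table.
#' @export
object_dsc <- function(pred_mask, truth_mask, max_center_distance_px = 3) {
  stopifnot(inherits(pred_mask, "semantic_mask"),
            inherits(truth_mask, "semantic_mask"))
  if (!all(dim(pred_mask$raster) == dim(truth_mask$raster)))
    stopf("prediction and ground truth must share the same shape")
  if (max_center_distance_px <= 0) stopf("matching radius must be > 0")
  cp <- label_centroids(components8(pred_mask$raster))
  ct <- label_centroids(components8(truth_mask$raster))
  np <- nrow(cp); nt <- nrow(ct)
  matches <- data.frame(pred = integer(0), truth = integer(0),
                        distance = numeric(0))
  tp <- 0L
  if (np > 0L && nt > 0L) {
    d <- sqrt(outer(cp$row, ct$row, "-")^2 + outer(cp$col, ct$col, "-")^2)
    feasible <- d < max_center_distance_px
    if (any(feasible)) {
      BIG <- 1e6
      n <- max(np, nt)
      cost <- matrix(BIG, n, n)
      sub <- cost[seq_len(np), seq_len(nt), drop = FALSE]
      sub[feasible] <- d[feasible]
      cost[seq_len(np), seq_len(nt)] <- sub
      assign <- .hungarian(cost)
      for (i in seq_len(np)) {
        j <- assign[i]
        if (j <= nt && feasible[i, j]) {
          tp <- tp + 1L
          matches <- rbind(matches, data.frame(pred = i, truth = j,
                                               distance = d[i, j]))
        }
      }
    }
  }
  fp <- np - tp; fn <- nt - tp
  dsc <- if (tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  list(dsc_object = dsc, tp_obj = tp, fp_obj = fp, fn_obj = fn,
       matches = matches)
}

#' Agreement between predicted and ground-truth per-image values
#'
#' Ordinary least squares of the predictions on the ground truths, with
#' R^2 equal to the squared Pearson correlation, plus standard errors of
#' slope and intercept — the model-vs-truth agreement analysis for
#' cohort-level quantities such as foci per nuclear volume.
#'
#' @param per_image_pred,per_image_truth equal-length numeric vectors
#'   (length >= 3).
#' @return A list with `r_squared`, `slope`, `intercept`, `slope_se`,
#'   `intercept_se`, `pearson_r`.
#' @export
agreement_regression <- function(per_image_pred, per_image_truth) {
  x <- as.numeric(per_image_truth); y <- as.numeric(per_image_pred)
  n <- length(x)
  if (length(y) != n || n < 3) stopf("need equal-length vectors of length >= 3")
  if (stats::var(x) == 0) stopf("ground-truth values have zero variance")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2); sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  res <- y - intercept - slope * x
  s2 <- sum(res^2) / (n - 2)
  r <- sxy / sqrt(sxx * sum((y - yb)^2))
  list(r_squared = r^2, slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + xb^2 / sxx)),
       pearson_r = r)
}

#' Paired comparison of per-image DSC values between two conditions
#'
#' Two-sided paired t-test on the differences (e.g. DSC of treated vs
#' untreated samples of the same patients).
#'
#' @param dsc_condition_a,dsc_condition_b equal-length paired vectors
#'   (length >= 2).
#' @return A list with `t_statistic`, `p_value`, `df`, `mean_difference`.
#' @export
paired_dsc_comparison <- function(dsc_condition_a, dsc_condition_b) {
  a <- as.numeric(dsc_condition_a); b <- as.numeric(dsc_condition_b)
  n <- length(a)
  if (length(b) != n || n < 2) stopf("need equal-length paired vectors, n >= 2")
  d <- a - b
  sd_d <- sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(list(t_statistic = 0, p_value = 1, df = n - 1,
                                  mean_difference = 0))
    stopf("zero-variance nonzero differences: t statistic undefined")
  }
  t_stat <- mean(d) / (sd_d / sqrt(n))
  list(t_statistic = t_stat,
       p_value = 2 * pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_difference = mean(d))
}
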