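test_that("Kruskal-Wallis matches the hand-ranked formula and the reference", {
  # {1,2,3} vs {10,11,12}: ranks 1..6, rank sums 6 and 15, no ties
  g <- list(c(1, 2, 3), c(10, 11, 12))
  r <- kruskal_wallis(g)
  H_hand <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(r$h, H_hand, tolerance = 1e-12)
  expect_lt(r$p, 0.05)
  ref <- stats::kruskal.test(c(g[[1]], g[[2]]), factor(rep(1:2, each = 3)))
  expect_equal(r$h, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  # identical groups: undefined statistic collapses to H = 0, p = 1
  r0 <- kruskal_wallis(list(c(2, 2), c(2, 2)))
  expect_equal(c(r0$h, r0$p), c(0, 1))
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis with ties matches the reference on seeded fixtures", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(0:6, sample(5:12, 1), replace = TRUE))  # heavy ties
    r <- kruskal_wallis(groups)
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(seq_len(k), lengths(groups))))
    expect_equal(r$h, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(r$p, ref$p.value, tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(29)
  groups <- lapply(1:3, function(i) runif(8, 0, 5))
  h0 <- kruskal_wallis(groups)$h
  expect_equal(kruskal_wallis(lapply(groups, exp))$h, h0)
  expect_equal(kruskal_wallis(lapply(groups, function(x) x^3 + 2))$h, h0)
})

test_that("Dunn's test reproduces hand-computed z statistics", {
  # no ties: A={1,2}, B={3,4}, C={5,6}; mean ranks 1.5, 3.5, 5.5;
  # v0 = N(N+1)/12 = 3.5, SE = sqrt(3.5 * (1/2 + 1/2))
  d <- dunn_posthoc(list(A = c(1, 2), B = c(3, 4), C = c(5, 6)))
  se <- sqrt(3.5)
  expect_equal(d$z[d$group_i == "A" & d$group_j == "B"], -2 / se)
  expect_equal(d$z[d$group_i == "A" & d$group_j == "C"], -4 / se)
  expect_equal(d$p_unadjusted, 2 * pnorm(-abs(d$z)))
  expect_equal(d$p_adjusted, pmin(1, d$p_unadjusted * 3))

  # with ties: A={1,1,2}, B={2,3,3}, C={4,4,5}; midranks give mean ranks
  # 13/6, 29/6, 8; tie term sum(t^3-t) = 24
  dt <- dunn_posthoc(list(A = c(1, 1, 2), B = c(2, 3, 3), C = c(4, 4, 5)))
  v0 <- 9 * 10 / 12 - 24 / (12 * 8)
  se3 <- sqrt(v0 * (2 / 3))
  expect_equal(dt$z[1], (13 / 6 - 29 / 6) / se3, tolerance = 1e-12)
  expect_equal(dt$z[2], (13 / 6 - 8) / se3, tolerance = 1e-12)

  # three identical groups: all adjusted p = 1
  d1 <- dunn_posthoc(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(d1$p_adjusted == 1))
  # Bonferroni never lowers a p-value
  expect_true(all(dt$p_adjusted >= dt$p_unadjusted))
  expect_error(dunn_posthoc(list(1:3, 4:6)), ">= 3 groups")
})

test_that("Dunn flags exactly the shifted group and is order-symmetric", {
  set.seed(41)
  a <- rnorm(20, 0); b <- rnorm(20, 0); c <- rnorm(20, 4)
  d <- dunn_posthoc(list(a = a, b = b, c = c))
  expect_lt(d$p_adjusted[d$group_i == "a" & d$group_j == "c"], 0.05)
  expect_lt(d$p_adjusted[d$group_i == "b" & d$group_j == "c"], 0.05)
  expect_gt(d$p_adjusted[d$group_i == "a" & d$group_j == "b"], 0.5)

  d2 <- dunn_posthoc(list(c = c, b = b, a = a))
  pick <- function(x, i, j) {
    sel <- (x$group_i == i & x$group_j == j) | (x$group_i == j & x$group_j == i)
    x$p_adjusted[sel]
  }
  for (pr in list(c("a", "b"), c("a", "c"), c("b", "c")))
    expect_equal(pick(d, pr[1], pr[2]), pick(d2, pr[1], pr[2]))
})

test_that("relative SD matches the definition and is scale invariant", {
  expect_equal(relative_sd(c(8, 10, 12)), 20)
  expect_equal(relative_sd(c(5, 5, 5, 5)), 0)
  x <- c(3, 7, 9, 14)
  expect_equal(relative_sd(x * 37.5), relative_sd(x))
  expect_error(relative_sd(7), "at least 2")
  expect_error(relative_sd(c(-1, 1)), "mean")
})

test_that("condition comparison pools per-nucleus values and gates Dunn", {
  conds <- data.frame(condition = c("control", "photon"), dose_Gy = c(0, 5))
  scenes <- generate_cohort(2, 3, conds,
                            scene_spec(height_px = 128L, width_px = 128L,
                                       n_nuclei = 10L),
                            seed = 6, render = FALSE)
  tab <- gt_measurements(scenes)$nuclei
  cmp <- compare_conditions(tab, "foci_per_um3")
  expect_length(cmp, 2L)
  for (x in cmp) {
    expect_true(x$significant)   # 2 foci/Gy/nucleus at 5 Gy vs control
    expect_null(x$dunn)          # two conditions: no post hoc
  }

  # three conditions with an effect: Dunn present and ordered conditions
  conds3 <- data.frame(condition = c("control", "photon", "proton"),
                       dose_Gy = c(0, 5, 8))
  sc3 <- generate_cohort(1, 3, conds3,
                         scene_spec(height_px = 128L, width_px = 128L,
                                    n_nuclei = 10L),
                         seed = 8, render = FALSE)
  cmp3 <- compare_conditions(gt_measurements(sc3)$nuclei, "foci_per_um3")
  expect_false(is.null(cmp3[[1]]$dunn))
  expect_lt(cmp3[[1]]$dunn$p_adjusted[
    cmp3[[1]]$dunn$group_i == "control" & cmp3[[1]]$dunn$group_j == "photon"],
    0.05)
})

test_that("variation reports summarize per-image means per patient and condition", {
  tab <- expand.grid(patient_id = "P01", condition = "control",
                     image_index = 1:3, nucleus_id = 1:4,
                     stringsAsFactors = FALSE)
  tab$foci_per_um3 <- rep(c(8, 10, 12), 4) * 1e-3  # per-image means 8, 10, 12
  vr <- variation_report(tab, "foci_per_um3")
  expect_equal(vr$relative_sd_percent, 20)
  expect_identical(vr$n_images, 3L)
})
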