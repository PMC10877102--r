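#' Kruskal-Wallis rank test (with tie correction)
#'
#' Implemented from the rank formula: with pooled ranks (midranks for
#' ties), `H = (12 / (N(N+1))) * sum n_i (Rbar_i - (N+1)/2)^2`, divided by
#' the tie correction `1 - sum(t^3 - t) / (N^3 - N)`; the p-value comes
#' from a chi-squared distribution with `k - 1` degrees of freedom. When
#' every pooled value is identical the statistic is undefined and
#' `H = 0, p = 1` is returned.
#'
#' @param groups list of numeric vectors, each non-empty, at least 2 groups.
#' @return A list with `h`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1)) == 0L))
    stopf("need >= 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  N <- length(x)
  if (length(unique(x)) == 1L)
    return(list(h = 0, p = 1, df = length(groups) - 1L))
  r <- rank(x)
  n_i <- tabulate(g)
  rbar <- rowsum(r, g)[, 1] / n_i
  H <- 12 / (N * (N + 1)) * sum(n_i * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(h = H, p = pchisq(H, df = length(groups) - 1L, lower.tail = FALSE),
       df = length(groups) - 1L)
}

#' Dunn's post hoc test on pooled ranks
#'
#' Pairwise z statistics on the pooled midranks with tie correction:
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) *
#' (1/n_i + 1/n_j))`; two-sided p-values are Bonferroni-adjusted over the
#' `k(k-1)/2` pairs and capped at 1.
#'
#' @param groups list of >= 3 non-empty numeric vectors; names are used in
#'   the pair labels.
#' @param adjustment only `"bonferroni"`.
#' @return Data frame with columns `group_i`, `group_j`, `z`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunn_posthoc <- function(groups, adjustment = c("bonferroni")) {
  adjustment <- match.arg(adjustment)
  if (!is.list(groups) || length(groups) < 3L)
    stopf("Dunn's post hoc needs >= 3 groups")
  if (any(vapply(groups, length, integer(1)) == 0L))
    stopf("all groups must be non-empty")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), vapply(groups, length, integer(1)))
  N <- length(x)
  r <- rank(x)
  n_i <- tabulate(g)
  rbar <- rowsum(r, g)[, 1] / n_i
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  m <- k * (k - 1) / 2
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(v0 * (1 / n_i[i] + 1 / n_i[j]))
    z <- if (se == 0) 0 else (rbar[i] - rbar[j]) / se
    p <- 2 * pnorm(-abs(z))
    out[[length(out) + 1L]] <- data.frame(
      group_i = nm[i], group_j = nm[j], z = z,
      p_unadjusted = p, p_adjusted = min(1, p * m),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Relative standard deviation across images of one sample and condition
#'
#' `100 * sample SD / mean` of the per-image summary values: the
#' intra-tumor intra-condition variation measure.
#'
#' @param per_image_values numeric vector of at least 2 per-image values.
#' @return Relative SD in percent.
#' @export
relative_sd <- function(per_image_values) {
  x <- as.numeric(per_image_values)
  if (length(x) < 2) stopf("need at least 2 per-image values")
  m <- mean(x)
  if (m == 0) stopf("mean of per-image values is zero; relative SD undefined")
  100 * sd(x) / m
}

#' Compare conditions per patient
#'
#' For each patient, pools the per-nucleus foci densities (or per-focus
#' areas) across that patient's images within each condition and runs a
#' Kruskal-Wallis test across the conditions; with three or more
#' conditions and a significant omnibus test, Dunn's post hoc (Bonferroni)
#' follows. This is the cohort analysis of dose response: control vs
#' photon (vs proton).
#'
#' @param measurements a nucleus measurement table (for
#'   `variable = "foci_per_um3"`) or focus table (for
#'   `variable = "focus_area_um2"`), as produced by [measure_nuclei()] /
#'   [overlay_foci()] or [gt_measurements()].
#' @param variable which variable to compare.
#' @param alpha significance level (default 0.05).
#' @return A list of per-patient comparisons, each with `patient_id`,
#'   `variable`, `groups`, `kw_h`, `kw_p`, `significant`, and `dunn`
#'   (present only when >= 3 groups and the omnibus test is significant).
#' @export
compare_conditions <- function(measurements,
                               variable = c("foci_per_um3", "focus_area_um2"),
                               alpha = 0.05) {
  variable <- match.arg(variable)
  col <- if (variable == "foci_per_um3") "foci_per_um3" else "area_um2"
  if (!col %in% names(measurements))
    stopf("measurement table lacks column '%s' for variable %s", col, variable)
  out <- list()
  for (pid in unique(measurements$patient_id)) {
    sub <- measurements[measurements$patient_id == pid, ]
    groups <- split(sub[[col]], sub$condition)
    groups <- groups[order(names(groups))]
    if (length(groups) < 2L)
      stopf("patient %s has fewer than 2 conditions", pid)
    if (any(vapply(groups, length, integer(1)) == 0L))
      stopf("patient %s has a condition with zero objects", pid)
    kw <- kruskal_wallis(groups)
    cmp <- list(patient_id = pid, variable = variable, groups = groups,
                kw_h = kw$h, kw_p = kw$p, significant = kw$p < alpha)
    if (length(groups) >= 3L && kw$p < alpha)
      cmp$dunn <- dunn_posthoc(groups)
    out[[pid]] <- cmp
  }
  out
}

#' Intra-tumor intra-condition variation report
#'
#' Summarizes each image by the mean (or median) of the chosen variable,
#' then expresses the spread between the images of one patient and
#' condition as the relative standard deviation.
#'
#' @inheritParams compare_conditions
#' @param summary per-image summary statistic.
#' @return Data frame with `patient_id`, `condition`, `n_images`,
#'   `relative_sd_percent`.
#' @export
variation_report <- function(measurements,
                             variable = c("foci_per_um3", "focus_area_um2"),
                             summary = c("mean", "median")) {
  variable <- match.arg(variable)
  summary <- match.arg(summary)
  col <- if (variable == "foci_per_um3") "foci_per_um3" else "area_um2"
  fun <- if (summary == "mean") mean else median
  per_image <- stats::aggregate(
    measurements[[col]],
    by = list(patient_id = measurements$patient_id,
              condition = measurements$condition,
              image_index = measurements$image_index),
    FUN = fun)
  out <- list()
  for (key in unique(paste(per_image$patient_id, per_image$condition, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    v <- per_image$x[per_image$patient_id == parts[1] &
                       per_image$condition == parts[2]]
    out[[length(out) + 1L]] <- data.frame(
      patient_id = parts[1], condition = parts[2], n_images = length(v),
      relative_sd_percent = if (length(v) >= 2) relative_sd(v) else NA_real_,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
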