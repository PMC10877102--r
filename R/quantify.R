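#' Overlay the foci segmentation on the nucleus label map
#'
#' Computes the pixelwise intersection of the focus mask with the nucleus
#' foreground; each 8-connected component of the intersection becomes one
#' retained focus, assigned to the nucleus covering the majority of its
#' pixels (ties to the lower label id). Foci entirely outside nuclei are
#' discarded, which is what removes extranuclear background speckles.
#' Foci straddling a nucleus boundary are clipped to the intersection.
#'
#' @param foci_mask a [semantic_mask] (foci channel segmentation).
#' @param nuclei a [label_map] of individual nuclei.
#' @param meta an [image_meta()] attached to each record.
#' @return Data frame of focus records: `focus_id`, `parent_nucleus_id`,
#'   `area_px`, `area_um2`, `centroid_row`, `centroid_col` (0-based).
#' @export
overlay_foci <- function(foci_mask, nuclei, meta = image_meta("NA")) {
  stopifnot(inherits(foci_mask, "semantic_mask"), inherits(nuclei, "label_map"))
  if (!all(dim(foci_mask$raster) == dim(nuclei$raster)))
    stopf("foci mask and nucleus labels must share the same shape")
  if (abs(foci_mask$pixel_size_um - nuclei$pixel_size_um) > 1e-9)
    stopf("foci mask and nucleus labels must share the same pixel size")
  inter <- (foci_mask$raster > 0L) & (nuclei$raster > 0L)
  comp <- components8(inter * 1L)
  n <- max(comp)
  empty <- data.frame(patient_id = character(0), condition = character(0),
                      dose_Gy = numeric(0), image_index = integer(0),
                      focus_id = integer(0), parent_nucleus_id = integer(0),
                      area_px = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  idx <- which(comp > 0L)
  cid <- comp[idx]
  nid <- nuclei$raster[idx]
  # majority nucleus label per focus component, ties to the lower label id
  tab <- stats::aggregate(list(count = nid), list(cid = cid, nid = nid), length)
  tab <- tab[order(tab$cid, -tab$count, tab$nid), ]
  parent <- tab$nid[!duplicated(tab$cid)]
  areas <- tabulate(cid, nbins = n)
  cent <- label_centroids(comp)
  px <- foci_mask$pixel_size_um
  data.frame(patient_id = meta$patient_id, condition = meta$condition,
             dose_Gy = meta$dose_Gy, image_index = meta$image_index,
             focus_id = seq_len(n), parent_nucleus_id = parent,
             area_px = areas, area_um2 = areas * px^2,
             centroid_row = cent$row, centroid_col = cent$col,
             stringsAsFactors = FALSE)
}

#' Per-nucleus measurements including foci per nuclear volume
#'
#' The density is `foci_count / (area_um2 * projection_height_um)`: the
#' number of foci in the nucleus divided by its cross-sectional area in
#' the selected Z-plane times the height of the maximum projection.
#' Nuclei with zero foci are included with density 0.
#'
#' @param nuclei a [label_map] of individual nuclei.
#' @param foci focus records from [overlay_foci()].
#' @param projection_height_um height of the foci maximum projection in um
#'   (3-slice projection at 1 um steps gives 3).
#' @param meta an [image_meta()].
#' @return Data frame of nucleus records.
#' @export
measure_nuclei <- function(nuclei, foci, projection_height_um,
                           meta = image_meta("NA")) {
  stopifnot(inherits(nuclei, "label_map"))
  if (projection_height_um <= 0) stopf("projection_height_um must be > 0")
  K <- max(nuclei$raster)
  empty <- data.frame(patient_id = character(0), condition = character(0),
                      dose_Gy = numeric(0), image_index = integer(0),
                      nucleus_id = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0),
                      foci_count = integer(0), foci_per_um3 = numeric(0),
                      stringsAsFactors = FALSE)
  if (K == 0L) return(empty)
  if (nrow(foci) > 0 && any(!(foci$parent_nucleus_id %in% seq_len(K))))
    stopf("focus references a non-existent nucleus id")
  areas_px <- tabulate(nuclei$raster[nuclei$raster > 0L], nbins = K)
  cent <- label_centroids(nuclei$raster)
  counts <- if (nrow(foci) > 0)
    tabulate(foci$parent_nucleus_id, nbins = K) else integer(K)
  area_um2 <- areas_px * nuclei$pixel_size_um^2
  data.frame(patient_id = meta$patient_id, condition = meta$condition,
             dose_Gy = meta$dose_Gy, image_index = meta$image_index,
             nucleus_id = seq_len(K), area_um2 = area_um2,
             centroid_row = cent$row, centroid_col = cent$col,
             foci_count = counts,
             foci_per_um3 = counts / (area_um2 * projection_height_um),
             stringsAsFactors = FALSE)
}

#' Per-image summary of nucleus and focus measurements
#'
#' Mean and median foci density over nuclei, mean and median focus area
#' over foci, and the nucleus count — the per-image dots of cohort plots.
#'
#' @param nuclei_records from [measure_nuclei()].
#' @param focus_records from [overlay_foci()].
#' @param meta an [image_meta()].
#' @param projection_height_um projection height in um.
#' @return One-row data frame; statistics are `NA` when no objects exist.
#' @export
summarize_image <- function(nuclei_records, focus_records,
                            meta = image_meta("NA"),
                            projection_height_um = NA_real_) {
  dens <- nuclei_records$foci_per_um3
  fa <- focus_records$area_um2
  data.frame(patient_id = meta$patient_id, condition = meta$condition,
             dose_Gy = meta$dose_Gy, image_index = meta$image_index,
             n_nuclei = nrow(nuclei_records),
             n_foci = nrow(focus_records),
             mean_foci_per_um3 = if (length(dens)) mean(dens) else NA_real_,
             median_foci_per_um3 = if (length(dens)) median(dens) else NA_real_,
             mean_focus_area_um2 = if (length(fa)) mean(fa) else NA_real_,
             median_focus_area_um2 = if (length(fa)) median(fa) else NA_real_,
             projection_height_um = projection_height_um,
             stringsAsFactors = FALSE)
}
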