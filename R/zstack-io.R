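#' Calibrated image containers
#'
#' Lightweight S3 containers used throughout the pipeline. All rasters are
#' numeric matrices indexed `[row, col]`; reported coordinates (centroids,
#' focus centers) use the 0-based `(row, col)` convention. A `zstack` holds
#' the ordered planes of one acquisition channel together with its lateral
#' (`pixel_size_um`) and axial (`z_step_um`) calibration.
#'
#' @param planes list of 2D numeric matrices, all the same size, ordered by
#'   acquisition depth.
#' @param pixel_size_um edge length of one pixel in micrometers (> 0).
#' @param z_step_um distance between consecutive planes in micrometers (> 0).
#' @param channel `"DAPI"` (nuclei stain) or `"FOCI"` (53BP1 damage foci).
#' @return An object of class `zstack`.
#' @export
zstack <- function(planes, pixel_size_um, z_step_um,
                   channel = c("DAPI", "FOCI")) {
  channel <- match.arg(channel)
  if (!is.list(planes) || length(planes) < 1L)
    stopf("a zstack needs at least one plane")
  dims <- vapply(planes, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("all planes must share the same height and width")
  check_calibration(pixel_size_um, z_step_um)
  for (p in planes)
    if (anyNA(p) || any(!is.finite(p)) || any(p < 0))
      stopf("plane intensities must be finite and >= 0")
  structure(list(planes = planes, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel = channel),
            class = "zstack")
}

check_calibration <- function(pixel_size_um, z_step_um = 1) {
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      is.na(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number (calibration is never defaulted)")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1L ||
      is.na(z_step_um) || z_step_um <= 0)
    stopf("z_step_um must be a single positive number")
  invisible(TRUE)
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<zstack %s: %d plane(s) of %dx%d px, %.5f um/px, %g um z-step>\n",
              x$channel, length(x$planes), d[1], d[2],
              x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' @rdname zstack
#' @param raster a 2D numeric matrix.
#' @export
plane_image <- function(raster, pixel_size_um) {
  check_calibration(pixel_size_um)
  if (!is.matrix(raster) || anyNA(raster) || any(!is.finite(raster)) ||
      any(raster < 0))
    stopf("plane intensities must be a finite matrix with values >= 0")
  structure(list(raster = raster, pixel_size_um = pixel_size_um),
            class = "plane_image")
}

#' @rdname zstack
#' @export
semantic_mask <- function(raster, pixel_size_um) {
  check_calibration(pixel_size_um)
  if (!is.matrix(raster) || !is_binary(raster))
    stopf("a semantic mask must be a matrix of 0/1 values")
  storage.mode(raster) <- "integer"
  structure(list(raster = raster, pixel_size_um = pixel_size_um),
            class = "semantic_mask")
}

#' @rdname zstack
#' @export
label_map <- function(raster, pixel_size_um) {
  check_calibration(pixel_size_um)
  if (!is.matrix(raster) || anyNA(raster) || any(raster < 0) ||
      any(raster != round(raster)))
    stopf("a label map must be a matrix of non-negative integers")
  storage.mode(raster) <- "integer"
  structure(list(raster = raster, pixel_size_um = pixel_size_um),
            class = "label_map")
}

#' @rdname zstack
#' @param patient_id patient identifier.
#' @param condition `"control"`, `"photon"` or `"proton"`.
#' @param dose_Gy delivered dose in Gray; must be 0 for controls.
#' @param image_index acquisition index within the condition.
#' @export
image_meta <- function(patient_id, condition = c("control", "photon", "proton"),
                       dose_Gy = 0, image_index = 1L) {
  condition <- match.arg(condition)
  if (dose_Gy < 0) stopf("dose_Gy must be >= 0")
  if (condition == "control" && dose_Gy != 0)
    stopf("control condition implies dose_Gy = 0")
  list(patient_id = as.character(patient_id), condition = condition,
       dose_Gy = dose_Gy, image_index = as.integer(image_index))
}

#' Read a single- or multi-page grayscale TIFF as a calibrated Z-stack
#'
#' Pages are taken in file order as consecutive Z-planes. Calibration is
#' never inferred from the file: `pixel_size_um` and `z_step_um` must be
#' supplied. Multi-channel (RGB) pages are rejected.
#'
#' @inheritParams zstack
#' @param path path to the TIFF file.
#' @return A [zstack].
#' @export
read_zstack <- function(path, pixel_size_um, z_step_um,
                        channel = c("DAPI", "FOCI")) {
  if (missing(pixel_size_um) || missing(z_step_um))
    stopf("calibration (pixel_size_um, z_step_um) is required when reading a stack")
  check_calibration(pixel_size_um, z_step_um)
  if (!file.exists(path)) stopf("cannot read TIFF: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  planes <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (dim(p)[3] == 1L) p <- p[, , 1]
      else stopf("multi-channel TIFF pages are not supported: %s", path)
    }
    matrix(as.numeric(p), nrow = nrow(p))
  })
  zstack(planes, pixel_size_um, z_step_um, match.arg(channel))
}

#' Write a Z-stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities must be integers in `[0, 65535]`; the round trip through
#' [read_zstack()] is then exact.
#'
#' @param stack a [zstack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  stopifnot(inherits(stack, "zstack"))
  for (p in stack$planes)
    if (any(p != round(p)) || any(p > 65535))
      stopf("write_zstack stores 16-bit integers; intensities must be whole numbers in [0, 65535]")
  pages <- lapply(stack$planes, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask or label map as a TIFF
#'
#' Semantic masks are stored as 8-bit `{0, 255}`; label maps as 16-bit
#' label ids (at most 65535 labels). Read-back with [read_mask()] /
#' [read_labels()] reproduces the raster exactly, including sparse ids.
#'
#' @param mask a [semantic_mask] or [label_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "semantic_mask")) {
    tiff::writeTIFF(mask$raster + 0, path, bits.per.sample = 8L)
  } else if (inherits(mask, "label_map")) {
    if (max(mask$raster) > 65535L) stopf("label maps with > 65535 labels cannot be stored")
    tiff::writeTIFF(mask$raster / 65535, path, bits.per.sample = 16L)
  } else stopf("write_mask expects a semantic_mask or label_map")
  invisible(path)
}

#' @rdname write_mask
#' @inheritParams read_zstack
#' @export
read_mask <- function(path, pixel_size_um) {
  check_calibration(pixel_size_um)
  r <- tiff::readTIFF(path, as.is = TRUE)
  semantic_mask((matrix(as.numeric(r), nrow = nrow(r)) > 0) * 1L, pixel_size_um)
}

#' @rdname write_mask
#' @export
read_labels <- function(path, pixel_size_um) {
  check_calibration(pixel_size_um)
  r <- tiff::readTIFF(path, as.is = TRUE)
  label_map(matrix(as.integer(r), nrow = nrow(r)), pixel_size_um)
}

measurement_key_cols <- c("patient_id", "condition", "image_index")

#' Write / read object measurement tables
#'
#' Measurement tables are plain data frames keyed by
#' `(patient_id, condition, image_index, object id)`; the object id column
#' is `nucleus_id` for nucleus tables and `focus_id` for focus tables.
#' Numeric columns survive the CSV round trip to better than 1e-9 relative
#' error.
#'
#' @param table a data frame of per-object measurements.
#' @param path output CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_measurements <- function(table, path) {
  stopifnot(is.data.frame(table))
  idcol <- intersect(c("nucleus_id", "focus_id"), names(table))
  keys <- intersect(c(measurement_key_cols, idcol[1]), names(table))
  if (length(keys) > 0 && nrow(table) > 0) {
    key <- do.call(paste, c(table[keys], sep = "\r"))
    if (anyDuplicated(key)) stopf("duplicate measurement keys")
  }
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
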