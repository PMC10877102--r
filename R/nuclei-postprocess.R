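#' Post-processing configuration for nucleus segmentations
#'
#' Defaults follow standard FIJI practice for this assay: watershed
#' tolerance 4 (in distance-map units, i.e. pixels), exclusion of objects
#' touching the image boundary, and a 10 um^2 minimum area.
#'
#' @param watershed_tolerance h-maxima depth on the Euclidean distance
#'   transform below which adjacent peaks are merged (pixels).
#' @param min_area_um2 minimum retained object area in um^2.
#' @param exclude_border drop objects with a pixel on the image boundary.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(watershed_tolerance = 4,
                               min_area_um2 = 10,
                               exclude_border = TRUE) {
  if (watershed_tolerance < 0 || min_area_um2 < 0)
    stopf("watershed_tolerance and min_area_um2 must be >= 0")
  structure(list(watershed_tolerance = watershed_tolerance,
                 min_area_um2 = min_area_um2,
                 exclude_border = isTRUE(exclude_border)),
            class = "postprocess_config")
}

#' Fill holes in a binary mask
#'
#' Every background region that is not connected to the image border
#' (4-connectivity of the background, matching 8-connected foreground)
#' becomes foreground. Idempotent.
#'
#' @param mask a [semantic_mask].
#' @return A [semantic_mask].
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "semantic_mask"))
  bg <- 1L - mask$raster
  # 4-connected background components via EBImage (its labeling is 4-connected)
  lab <- EBImage::imageData(EBImage::bwlabel(bg))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  hole <- lab > 0 & !(lab %in% border_labels)
  out <- mask$raster
  out[hole] <- 1L
  semantic_mask(out, mask$pixel_size_um)
}

#' Separate touching nuclei by a tolerance watershed
#'
#' Computes the Euclidean distance transform of the mask and floods its
#' inverse restricted to the foreground; adjacent catchment basins whose
#' peak rises less than `tolerance` above the contact saddle are merged
#' (h-maxima behavior, the FIJI adjustable-watershed convention).
#' Boundaries between distinct labels are etched as single-pixel background
#' lines, so labels never touch.
#'
#' @param mask a [semantic_mask].
#' @param tolerance merge depth in distance-map units (pixels).
#' @return A [label_map]; the union of all labels is a subset of the input
#'   foreground.
#' @export
separate_touching <- function(mask, tolerance = 4) {
  stopifnot(inherits(mask, "semantic_mask"))
  if (sum(mask$raster) == 0L)
    return(label_map(matrix(0L, nrow(mask$raster), ncol(mask$raster)),
                     mask$pixel_size_um))
  d <- EBImage::distmap(mask$raster)
  ws <- EBImage::imageData(EBImage::watershed(d, tolerance = tolerance, ext = 1))
  storage.mode(ws) <- "integer"
  ws <- etch_label_boundaries(ws)
  # renumber 1..K in first-occurrence order
  ids <- sort(unique(ws[ws > 0L]))
  if (length(ids) > 0L && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    ws[ws > 0L] <- remap[ws[ws > 0L]]
  }
  label_map(ws, mask$pixel_size_um)
}

# set a pixel to background where a right/down/diagonal neighbor carries a
# different nonzero label: a single-pixel separation line
etch_label_boundaries <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  kill <- matrix(FALSE, H, W)
  mark <- function(a_rows, a_cols, b_rows, b_cols) {
    a <- lab[a_rows, a_cols]; b <- lab[b_rows, b_cols]
    diff <- a > 0L & b > 0L & a != b
    kill[a_rows, a_cols][diff] <<- TRUE
  }
  mark(1:(H - 1), 1:W, 2:H, 1:W)             # down
  mark(1:H, 1:(W - 1), 1:H, 2:W)             # right
  mark(1:(H - 1), 1:(W - 1), 2:H, 2:W)       # down-right
  mark(2:H, 1:(W - 1), 1:(H - 1), 2:W)       # up-right
  lab[kill] <- 0L
  lab
}

#' Filter labeled objects by border contact and minimum area
#'
#' Removes every label with a pixel on the outermost row/column (when
#' `exclude_border`) and every label whose physical area
#' `pixels * pixel_size_um^2` is below `min_area_um2`. Survivors are
#' renumbered `1..K` preserving their original order.
#'
#' @param labels a [label_map].
#' @param config a [postprocess_config()].
#' @return A [label_map].
#' @export
filter_regions <- function(labels, config = postprocess_config()) {
  stopifnot(inherits(labels, "label_map"))
  lab <- labels$raster
  if (max(lab) == 0L) return(labels)
  drop <- logical(max(lab))
  if (config$exclude_border) {
    edge <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
    drop[unique(edge[edge > 0L])] <- TRUE
  }
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  drop[areas * labels$pixel_size_um^2 < config$min_area_um2] <- TRUE
  drop[areas == 0L] <- TRUE
  keep <- which(!drop)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- lab
  out[out > 0L] <- remap[out[out > 0L]]
  label_map(out, labels$pixel_size_um)
}

#' Full nucleus post-processing chain
#'
#' `fill_holes` then `separate_touching` then `filter_regions`, returning
#' the final label map; the nucleus count is its maximum label.
#'
#' @param mask a [semantic_mask] (semantic nucleus segmentation).
#' @param config a [postprocess_config()].
#' @return A [label_map] with attribute `n_nuclei`.
#' @export
postprocess_nuclei <- function(mask, config = postprocess_config()) {
  out <- filter_regions(
    separate_touching(fill_holes(mask), config$watershed_tolerance),
    config)
  attr(out, "n_nuclei") <- max(out$raster)
  out
}
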