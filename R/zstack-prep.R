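#' Select the analysis plane of a DAPI stack
#'
#' Returns the plane with the highest mean pixel intensity (arithmetic mean
#' over all pixels, background included); ties are broken by the lowest
#' index. This is the plane in which the largest number of nuclei is in
#' focus for a tissue slice imaged as a Z-stack.
#'
#' @param stack a [zstack].
#' @return A list with `index` (0-based plane index) and `plane`
#'   (a [plane_image]).
#' @export
select_focus_plane <- function(stack) {
  stopifnot(inherits(stack, "zstack"))
  means <- vapply(stack$planes, mean, numeric(1))
  idx <- which.max(means)  # which.max returns the first maximum: lowest index
  list(index = idx - 1L,
       plane = plane_image(stack$planes[[idx]], stack$pixel_size_um))
}

#' Maximum projection of a slice window around a center plane
#'
#' Pixelwise maximum over the planes
#' `[center_index - half_width, center_index + half_width]`, clamped to the
#' stack; with the default `half_width = 1` this is the 3-slice projection
#' used for the foci channel. The number of planes actually used times the
#' z-step is recorded as the projection height, which later becomes the
#' denominator of the foci-per-volume density.
#'
#' @param stack a [zstack].
#' @param center_index 0-based index of the central plane.
#' @param half_width number of planes on each side (default 1).
#' @return A [plane_image] with attribute `projection_height_um` and
#'   `planes_used`.
#' @export
max_project_around <- function(stack, center_index, half_width = 1L) {
  stopifnot(inherits(stack, "zstack"))
  n <- length(stack$planes)
  if (center_index < 0 || center_index >= n)
    stopf("center_index %d outside [0, %d)", center_index, n)
  lo <- max(0L, center_index - half_width)
  hi <- min(n - 1L, center_index + half_width)
  proj <- stack$planes[[lo + 1L]]
  if (hi > lo) for (z in (lo + 1L):hi) proj <- pmax(proj, stack$planes[[z + 1L]])
  out <- plane_image(proj, stack$pixel_size_um)
  attr(out, "planes_used") <- hi - lo + 1L
  attr(out, "projection_height_um") <- (hi - lo + 1L) * stack$z_step_um
  out
}
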