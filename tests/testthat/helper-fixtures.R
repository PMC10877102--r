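# Shared fixtures, built in code at test time.

PX <- 183.65 / 1024  # acquisition calibration, um per pixel

disk_mask <- function(h, w, cy, cx, r) {
  m <- matrix(0L, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
  m
}

annulus_mask <- function(h, w, cy, cx, r_out, r_in) {
  disk_mask(h, w, cy, cx, r_out) - disk_mask(h, w, cy, cx, r_in)
}

# two overlapping radius-15 disks, centers 24 px apart (dumbbell):
# distance-map peaks ~15, saddle ~10 on the pixel grid, merge depth ~5
dumbbell_mask <- function() {
  (disk_mask(64, 80, 32, 28, 15) | disk_mask(64, 80, 32, 52, 15)) * 1L
}

# mask with single-pixel objects at the given 0-based (row, col) centers
point_mask <- function(h, w, centers) {
  m <- matrix(0L, h, w)
  if (length(centers)) for (p in centers) m[p[1] + 1L, p[2] + 1L] <- 1L
  m
}

# brute-force one-to-one matching: maximize matches, then minimize total
# distance, over all injective assignments (small object counts only)
brute_force_match <- function(cp, ct, radius) {
  np <- nrow(cp); nt <- nrow(ct)
  if (np == 0L || nt == 0L) return(list(tp = 0L, total = 0))
  best <- list(tp = -1L, total = Inf)
  d <- sqrt(outer(cp$row, ct$row, "-")^2 + outer(cp$col, ct$col, "-")^2)
  recurse <- function(i, used, tp, total) {
    if (i > np) {
      if (tp > best$tp || (tp == best$tp && total < best$total))
        best <<- list(tp = tp, total = total)
      return(invisible(NULL))
    }
    recurse(i + 1L, used, tp, total)              # leave prediction i unmatched
    for (j in seq_len(nt)) {
      if (!used[j] && d[i, j] < radius) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L, total + d[i, j])
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nt), 0L, 0)
  best
}

# small nuclei training pair; nucleus radius scales with the field so the
# desk-scale scenes stay placeable
nuclei_pair <- function(seed, size = 64L, n_nuclei = 6L,
                        radius_um = if (size <= 64L) 1.6 else 2.5) {
  sc <- generate_scene(scene_spec(height_px = size, width_px = size,
                                  n_nuclei = n_nuclei,
                                  nucleus_radius_um_mean = radius_um,
                                  nucleus_radius_um_sd = radius_um / 5,
                                  seed = seed))
  fp <- select_focus_plane(sc$dapi)
  list(image = fp$plane$raster, mask = (sc$gt_nuclei$raster > 0) * 1,
       scene = sc)
}

foci_pair <- function(seed, dose, size = 96L, n_nuclei = 8L,
                      radius_um = 2.2) {
  sc <- generate_scene(
    scene_spec(height_px = size, width_px = size, n_nuclei = n_nuclei,
               nucleus_radius_um_mean = radius_um,
               nucleus_radius_um_sd = radius_um / 5,
               dose_Gy = dose, seed = seed),
    image_meta("P1", if (dose == 0) "control" else "photon", dose))
  fp <- select_focus_plane(sc$dapi)
  pr <- max_project_around(sc$foci, fp$index)
  list(image = pr$raster, mask = sc$gt_foci$raster, scene = sc)
}

# a small desk-scale spec for count-level cohort simulations
tiny_spec <- function(...) {
  scene_spec(height_px = 96L, width_px = 96L, n_nuclei = 6L,
             nucleus_radius_um_mean = 2, nucleus_radius_um_sd = 0.4, ...)
}
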