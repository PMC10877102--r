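#' Specify a synthetic tissue scene
#'
#' Parameters of one synthetic DAPI / 53BP1 acquisition. Defaults emulate
#' the imaging regime the pipeline targets: 63x confocal fields at
#' 183.65/1024 = 0.17935 um/px and 1 um z-steps, densely packed and partly
#' overlapping tumor nuclei with variable staining and a dimmer nucleus
#' center, and dose-dependent punctate 53BP1 foci inside nuclei plus
#' spurious extranuclear speckles. The default geometry is a 256x256 px
#' desk-scale field; set `height_px = width_px = 1024` for full-scale
#' scenes at the same calibration.
#'
#' Per-nucleus focus counts are Poisson with mean
#' `baseline_foci_per_nucleus + dose_Gy * foci_per_Gy_per_nucleus`.
#'
#' @param height_px,width_px scene size in pixels.
#' @param pixel_size_um lateral calibration (um per pixel).
#' @param n_planes,z_step_um,focal_plane_index axial geometry; the focal
#'   plane index is 0-based.
#' @param n_nuclei number of nuclei to place.
#' @param nucleus_radius_um_mean,nucleus_radius_um_sd nucleus radius
#'   distribution (um).
#' @param overlap_fraction fraction of nuclei placed touching/overlapping
#'   a neighbor (the clustering challenge for the watershed stage).
#' @param center_dimming relative DAPI intensity drop at the nucleus center.
#' @param stain_intensity_scale global multiplier on stain amplitudes.
#' @param background_level,noise_sd constant background offset and additive
#'   Gaussian noise, in 16-bit counts.
#' @param dose_Gy,foci_per_Gy_per_nucleus,baseline_foci_per_nucleus focus
#'   count model.
#' @param focus_radius_um_mean,focus_radius_um_sd focus radius distribution.
#' @param extranuclear_speckle_rate expected spurious bright puncta outside
#'   nuclei per image (foci channel only; never in the ground truth).
#' @param seed integer seed; identical seeds give identical scenes.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(height_px = 256L, width_px = 256L,
                       pixel_size_um = 183.65 / 1024,
                       n_planes = 7L, z_step_um = 1,
                       focal_plane_index = 3L,
                       n_nuclei = 16L,
                       nucleus_radius_um_mean = 4.0,
                       nucleus_radius_um_sd = 0.8,
                       overlap_fraction = 0.25,
                       center_dimming = 0.35,
                       stain_intensity_scale = 1,
                       background_level = 800,
                       noise_sd = 250,
                       dose_Gy = 0,
                       foci_per_Gy_per_nucleus = 2,
                       baseline_foci_per_nucleus = 0.5,
                       focus_radius_um_mean = 0.25,
                       focus_radius_um_sd = 0.05,
                       extranuclear_speckle_rate = 8,
                       seed = 1L) {
  spec <- as.list(environment())
  if (spec$focal_plane_index < 0 || spec$focal_plane_index >= spec$n_planes)
    stopf("focal_plane_index must lie in [0, n_planes)")
  rates <- c(spec$dose_Gy, spec$foci_per_Gy_per_nucleus,
             spec$baseline_foci_per_nucleus, spec$extranuclear_speckle_rate,
             spec$background_level, spec$noise_sd)
  if (any(rates < 0)) stopf("rates, dose and noise parameters must be >= 0")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 1)
    stopf("overlap_fraction must lie in [0, 1]")
  if (spec$stain_intensity_scale <= 0) stopf("stain_intensity_scale must be > 0")
  check_calibration(spec$pixel_size_um, spec$z_step_um)
  class(spec) <- "scene_spec"
  spec
}

# ellipse membership helper: squared normalized radius over a pixel grid
ellipse_rho2 <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2
}

place_nuclei <- function(spec) {
  px <- spec$pixel_size_um
  H <- spec$height_px; W <- spec$width_px
  n <- spec$n_nuclei
  r_mean <- spec$nucleus_radius_um_mean / px
  r_sd <- spec$nucleus_radius_um_sd / px
  n_free <- round(n * (1 - spec$overlap_fraction))
  out <- vector("list", n)
  accepted <- 0L
  draw_shape <- function() {
    r <- min(max(rnorm(1, r_mean, r_sd), 0.4 * r_mean), 1.8 * r_mean)
    ecc <- runif(1, 0.85, 1.2)
    a <- r * ecc; b <- r / ecc
    list(a = a, b = b, theta = runif(1, 0, pi), Rmax = max(a, b))
  }
  for (k in seq_len(n)) {
    sh <- draw_shape()
    m <- ceiling(sh$Rmax) + 2
    if (2 * m + 4 >= min(H, W))
      stopf("nuclei too large for the image: cannot place within bounds")
    ok <- FALSE
    cluster_k <- accepted > 0L && k > n_free
    for (try in seq_len(1200L)) {
      if (try %% 150L == 0L) {  # crowded field: re-draw the shape
        sh <- draw_shape()
        m <- ceiling(sh$Rmax) + 2
      }
      if (try > 900L && accepted > 0L) cluster_k <- TRUE  # fall back to adjacent placement
      if (!cluster_k) {
        cy <- runif(1, m + 1, H - m); cx <- runif(1, m + 1, W - m)
        clash <- FALSE
        for (j in seq_len(accepted)) {
          o <- out[[j]]
          if (sqrt((cy - o$cy)^2 + (cx - o$cx)^2) <= (sh$Rmax + o$Rmax)) {
            clash <- TRUE; break
          }
        }
        if (!clash) { ok <- TRUE; break }
      } else {
        anchor <- out[[sample.int(accepted, 1)]]
        ang <- runif(1, 0, 2 * pi)
        d <- runif(1, 0.55, 0.9) * (sh$Rmax + anchor$Rmax)
        cy <- anchor$cy + d * sin(ang); cx <- anchor$cx + d * cos(ang)
        if (cy > m && cy < H - m + 1 && cx > m && cx < W - m + 1) {
          ok <- TRUE; break
        }
      }
    }
    a <- sh$a; b <- sh$b; theta <- sh$theta; Rmax <- sh$Rmax
    if (!ok) stopf("could not place nucleus %d within image bounds after bounded retries", k)
    accepted <- accepted + 1L
    out[[k]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta,
                     Rmax = Rmax,
                     amp = 10000 * spec$stain_intensity_scale * rlnorm(1, 0, 0.25))
  }
  out
}

#' Generate one synthetic scene with exact ground truth
#'
#' Renders a DAPI and a 53BP1 (foci) Z-stack plus the ground truth:
#' a nucleus label map at the focal plane (overlapping nuclei keep distinct
#' ids even where the rendered intensities merge), a focus mask for the
#' 3-slice focal projection, and the list of focus centers with their
#' parent nucleus. Foci are placed uniformly inside the parent nucleus,
#' rejection-sampled so each focus footprint lies fully on its parent's
#' label and foci never touch each other; a focus whose placement cannot
#' be realized after bounded retries is dropped. Foci are rendered with
#' full amplitude at the focal plane and reduced amplitude in the adjacent
#' planes, so the 3-slice maximum projection is exercised.
#'
#' @param spec a [scene_spec()].
#' @param meta an [image_meta()] for the scene (defaults to a control image
#'   when `dose_Gy = 0`, photon otherwise).
#' @param render if `FALSE`, skip intensity rendering and return the ground
#'   truth only (fast path for count-level simulations).
#' @return A `scene` list with elements `dapi`, `foci` (zstacks or `NULL`),
#'   `gt_nuclei`, `gt_foci`, `gt_foci_centers`, `meta`, `spec`.
#' @export
generate_scene <- function(spec, meta = NULL, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  if (is.null(meta))
    meta <- image_meta("P1", if (spec$dose_Gy == 0) "control" else "photon",
                       spec$dose_Gy, 1L)
  local_seed(spec$seed, {
    H <- spec$height_px; W <- spec$width_px
    px <- spec$pixel_size_um
    nuclei <- place_nuclei(spec)
    n <- length(nuclei)

    gt <- matrix(0L, H, W)
    dapi_base <- matrix(0, H, W)
    for (k in seq_len(n)) {
      o <- nuclei[[k]]
      m <- ceiling(o$Rmax) + 1
      rows <- max(1, floor(o$cy - m)):min(H, ceiling(o$cy + m))
      cols <- max(1, floor(o$cx - m)):min(W, ceiling(o$cx + m))
      rho2 <- ellipse_rho2(rows, cols, o$cy, o$cx, o$a, o$b, o$theta)
      inside <- rho2 <= 1
      gt[rows, cols][inside] <- k
      if (render) {
        edge <- pmin(1, pmax(0, (1 - rho2) / 0.15))
        dim_f <- 1 - spec$center_dimming * pmax(0, 1 - rho2)
        patch <- o$amp * edge * dim_f
        cur <- dapi_base[rows, cols]
        dapi_base[rows, cols] <- pmax(cur, patch)
      }
    }

    # focus placement: uniform within the parent's gt label, full footprint
    # on the parent, and global center separation so gt components never merge
    sigma_px_mean <- spec$focus_radius_um_mean / px
    lam <- spec$baseline_foci_per_nucleus +
      spec$dose_Gy * spec$foci_per_Gy_per_nucleus
    centers <- list()
    Hn <- nrow(gt)
    pix_by_label <- split(which(gt > 0L), gt[gt > 0L])
    for (k in seq_len(n)) {
      n_foci <- rpois(1, lam)
      if (n_foci == 0L) next
      pk <- pix_by_label[[as.character(k)]]
      if (is.null(pk) || length(pk) == 0L) next
      for (f in seq_len(n_foci)) {
        sig <- max(0.6, rnorm(1, sigma_px_mean, spec$focus_radius_um_sd / px))
        r_gt <- max(1L, as.integer(round(sig)))
        placed <- FALSE
        for (try in seq_len(200L)) {
          p <- pk[sample.int(length(pk), 1)]
          fr <- (p - 1L) %% Hn + 1L
          fc <- (p - 1L) %/% Hn + 1L
          if (fr - r_gt < 1 || fr + r_gt > H || fc - r_gt < 1 || fc + r_gt > W) next
          # footprint entirely on the parent label
          sub <- gt[(fr - r_gt):(fr + r_gt), (fc - r_gt):(fc + r_gt)]
          dd <- outer((-r_gt):r_gt, (-r_gt):r_gt,
                      function(a, b) a^2 + b^2) <= r_gt^2
          if (any(sub[dd] != k)) next
          # separation from every accepted focus (no touching gt disks)
          sep_ok <- TRUE
          if (length(centers) > 0L) for (cc in centers) {
            if (sqrt((fr - cc$r)^2 + (fc - cc$c)^2) <= (r_gt + cc$r_gt + 1.9)) {
              sep_ok <- FALSE; break
            }
          }
          if (!sep_ok) next
          centers[[length(centers) + 1L]] <-
            list(r = fr, c = fc, r_gt = r_gt, sig = sig, parent = k,
                 amp = 18000 * spec$stain_intensity_scale * rlnorm(1, 0, 0.2))
          placed <- TRUE
          break
        }
        if (!placed) next  # dropped focus (crowded nucleus)
      }
    }

    gt_foci <- matrix(0L, H, W)
    for (cc in centers) {
      rr <- (cc$r - cc$r_gt):(cc$r + cc$r_gt)
      ccl <- (cc$c - cc$r_gt):(cc$c + cc$r_gt)
      dd <- outer(rr - cc$r, ccl - cc$c, function(a, b) a^2 + b^2) <= cc$r_gt^2
      gt_foci[rr, ccl][dd] <- 1L
    }

    # extranuclear speckles: rendered only, never in gt
    speckles <- list()
    n_spk <- rpois(1, spec$extranuclear_speckle_rate)
    bg_pix <- which(gt == 0L)
    if (n_spk > 0L && length(bg_pix) > 0L && render) {
      for (s in seq_len(n_spk)) {
        for (try in seq_len(100L)) {
          p <- bg_pix[sample.int(length(bg_pix), 1)]
          fr <- (p - 1L) %% Hn + 1L
          fc <- (p - 1L) %/% Hn + 1L
          r_ck <- 3L
          if (fr - r_ck < 1 || fr + r_ck > H || fc - r_ck < 1 || fc + r_ck > W) next
          if (any(gt[(fr - r_ck):(fr + r_ck), (fc - r_ck):(fc + r_ck)] != 0L)) next
          speckles[[length(speckles) + 1L]] <-
            list(r = fr, c = fc, sig = max(0.6, rnorm(1, sigma_px_mean, 0.05 / px)),
                 amp = 15000 * spec$stain_intensity_scale * rlnorm(1, 0, 0.3))
          break
        }
      }
    }

    dapi_stack <- NULL; foci_stack <- NULL
    if (render) {
      zf <- spec$focal_plane_index  # 0-based
      # focal-plane foci accumulator (puncta + diffuse nuclear 53BP1)
      puncta <- matrix(0, H, W)
      add_punctum <- function(img, cc) {
        ext <- ceiling(3 * cc$sig)
        rr <- max(1, cc$r - ext):min(H, cc$r + ext)
        ccl <- max(1, cc$c - ext):min(W, cc$c + ext)
        g <- cc$amp * exp(-outer((rr - cc$r)^2, (ccl - cc$c)^2, "+") /
                            (2 * cc$sig^2))
        img[rr, ccl] <- img[rr, ccl] + g
        img
      }
      for (cc in centers) puncta <- add_punctum(puncta, cc)
      for (cc in speckles) puncta <- add_punctum(puncta, cc)
      diffuse <- 0.08 * dapi_base

      dapi_planes <- vector("list", spec$n_planes)
      foci_planes <- vector("list", spec$n_planes)
      for (z in seq_len(spec$n_planes) - 1L) {
        zfac <- exp(-(z - zf)^2 / (2 * 1.8^2))
        foc_fac <- if (z == zf) 1 else if (abs(z - zf) == 1) 0.55 else
          if (abs(z - zf) == 2) 0.12 else 0
        d <- dapi_base * zfac + spec$background_level +
          rnorm(H * W, 0, spec$noise_sd)
        f <- puncta * foc_fac + diffuse * zfac + spec$background_level +
          rnorm(H * W, 0, spec$noise_sd)
        dapi_planes[[z + 1L]] <- matrix(pmin(pmax(round(d), 0), 65535), H, W)
        foci_planes[[z + 1L]] <- matrix(pmin(pmax(round(f), 0), 65535), H, W)
      }
      dapi_stack <- zstack(dapi_planes, px, spec$z_step_um, "DAPI")
      foci_stack <- zstack(foci_planes, px, spec$z_step_um, "FOCI")
    }

    gt_centers <- if (length(centers) == 0L)
      data.frame(row = numeric(0), col = numeric(0), nucleus_id = integer(0))
    else data.frame(
      row = vapply(centers, function(cc) cc$r - 1, numeric(1)),   # 0-based
      col = vapply(centers, function(cc) cc$c - 1, numeric(1)),
      nucleus_id = vapply(centers, function(cc) cc$parent, numeric(1))
    )

    structure(list(
      dapi = dapi_stack, foci = foci_stack,
      gt_nuclei = label_map(gt, px),
      gt_foci = semantic_mask(gt_foci, px),
      gt_foci_centers = gt_centers,
      meta = meta, spec = spec
    ), class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene %s/%s %g Gy #%d: %dx%d px, %d nuclei, %d gt foci%s>\n",
              x$meta$patient_id, x$meta$condition, x$meta$dose_Gy,
              x$meta$image_index, x$spec$height_px, x$spec$width_px,
              max(x$gt_nuclei$raster), nrow(x$gt_foci_centers),
              if (is.null(x$dapi)) ", gt only" else ""))
  invisible(x)
}

#' Generate a multi-patient synthetic cohort
#'
#' Mirrors the acquisition design of the targeted assay: several images per
#' condition per patient, with a per-patient lognormal radiosensitivity
#' multiplier applied to `foci_per_Gy_per_nucleus`.
#'
#' @param n_patients number of patients.
#' @param images_per_condition images acquired per patient and condition.
#' @param conditions data frame with columns `condition` and `dose_Gy`.
#' @param base_spec the [scene_spec()] shared by all scenes.
#' @param patient_sensitivity_sd sd (log scale) of the per-patient
#'   sensitivity multiplier; 0 gives identical expected foci rates.
#' @param seed cohort-level seed; per-scene seeds are derived from it.
#' @param render passed to [generate_scene()].
#' @return A list of `scene` objects with coherent metadata.
#' @export
generate_cohort <- function(n_patients, images_per_condition,
                            conditions = data.frame(
                              condition = c("control", "photon"),
                              dose_Gy = c(0, 5)),
                            base_spec = scene_spec(),
                            patient_sensitivity_sd = 0.3,
                            seed = 1L, render = TRUE) {
  stopifnot(n_patients >= 1, images_per_condition >= 1)
  mult <- local_seed(seed, rlnorm(n_patients, 0, patient_sensitivity_sd))
  scenes <- list()
  counter <- 0L
  for (p in seq_len(n_patients)) {
    for (ci in seq_len(nrow(conditions))) {
      for (im in seq_len(images_per_condition)) {
        counter <- counter + 1L
        sp <- base_spec
        sp$dose_Gy <- conditions$dose_Gy[ci]
        sp$foci_per_Gy_per_nucleus <-
          base_spec$foci_per_Gy_per_nucleus * mult[p]
        sp$seed <- (seed + counter * 7919L) %% .Machine$integer.max
        meta <- image_meta(sprintf("P%02d", p),
                           as.character(conditions$condition[ci]),
                           conditions$dose_Gy[ci], im)
        scenes[[counter]] <- generate_scene(sp, meta, render = render)
      }
    }
  }
  scenes
}

#' Ground-truth measurement tables for synthetic scenes
#'
#' Builds the nucleus/focus measurement tables directly from a scene's
#' ground truth (areas from the gt label map, counts from the gt focus
#' centers), bypassing segmentation entirely. The foci-per-volume
#' denominator uses a 3-slice projection height (`3 * z_step_um`).
#'
#' @param scenes a `scene` or list of scenes.
#' @return A list with data frames `nuclei` and `foci`.
#' @export
gt_measurements <- function(scenes) {
  if (inherits(scenes, "scene")) scenes <- list(scenes)
  nuc <- list(); foc <- list()
  for (s in scenes) {
    px <- s$gt_nuclei$pixel_size_um
    height_um <- 3 * s$spec$z_step_um
    areas <- label_areas_px(s$gt_nuclei$raster)
    ids <- as.integer(names(areas))
    counts <- tabulate(s$gt_foci_centers$nucleus_id,
                       nbins = max(ids, 0L))[ids]
    cent <- label_centroids(s$gt_nuclei$raster)
    area_um2 <- as.numeric(areas) * px^2
    nuc[[length(nuc) + 1L]] <- data.frame(
      patient_id = s$meta$patient_id, condition = s$meta$condition,
      dose_Gy = s$meta$dose_Gy, image_index = s$meta$image_index,
      nucleus_id = ids, area_um2 = area_um2,
      centroid_row = cent$row, centroid_col = cent$col,
      foci_count = counts,
      foci_per_um3 = counts / (area_um2 * height_um),
      stringsAsFactors = FALSE)
    if (nrow(s$gt_foci_centers) > 0) {
      foc[[length(foc) + 1L]] <- data.frame(
        patient_id = s$meta$patient_id, condition = s$meta$condition,
        dose_Gy = s$meta$dose_Gy, image_index = s$meta$image_index,
        focus_id = seq_len(nrow(s$gt_foci_centers)),
        parent_nucleus_id = s$gt_foci_centers$nucleus_id,
        centroid_row = s$gt_foci_centers$row,
        centroid_col = s$gt_foci_centers$col,
        stringsAsFactors = FALSE)
    }
  }
  list(nuclei = do.call(rbind, nuc),
       foci = if (length(foc)) do.call(rbind, foc) else NULL)
}

#' Write a scene to disk as TIFFs plus a manifest row
#'
#' @param scene a `scene`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return A one-row data frame suitable for a pipeline manifest.
#' @export
write_scene <- function(scene, dir, prefix = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prefix))
    prefix <- sprintf("%s_%s_%02d", scene$meta$patient_id,
                      scene$meta$condition, scene$meta$image_index)
  paths <- list(
    dapi = file.path(dir, paste0(prefix, "_dapi.tif")),
    foci = file.path(dir, paste0(prefix, "_foci.tif")),
    gt_nuclei = file.path(dir, paste0(prefix, "_gt_nuclei.tif")),
    gt_foci = file.path(dir, paste0(prefix, "_gt_foci.tif"))
  )
  if (is.null(scene$dapi))
    stopf("cannot write a gt-only scene; generate with render = TRUE")
  write_zstack(scene$dapi, paths$dapi)
  write_zstack(scene$foci, paths$foci)
  write_mask(scene$gt_nuclei, paths$gt_nuclei)
  write_mask(scene$gt_foci, paths$gt_foci)
  data.frame(patient_id = scene$meta$patient_id,
             condition = scene$meta$condition,
             dose_Gy = scene$meta$dose_Gy,
             image_index = scene$meta$image_index,
             dapi = paths$dapi, foci = paths$foci,
             gt_nuclei = paths$gt_nuclei, gt_foci = paths$gt_foci,
             stringsAsFactors = FALSE)
}
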