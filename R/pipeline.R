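#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end run: the image manifest, the
#' calibration, the projection half-width, the segmentation threshold, the
#' post-processing settings and the statistics level. `manifest` is a data
#' frame (or CSV path) with columns `patient_id`, `condition`, `dose_Gy`,
#' `image_index`, `dapi`, `foci` and — for ground-truth bypass runs —
#' `gt_nuclei`, `gt_foci`.
#'
#' @param manifest data frame or CSV path.
#' @param out_dir output directory.
#' @param pixel_size_um,z_step_um calibration applied to all stacks.
#' @param projection_half_width planes on each side of the selected DAPI
#'   plane in the foci maximum projection (default 1: three slices).
#' @param threshold probability threshold for the U-net masks.
#' @param postprocess a [postprocess_config()].
#' @param match_radius_px object-matching radius for evaluation.
#' @param alpha significance level for the statistics.
#' @param use_gt bypass the segmentation models with the manifest's
#'   ground-truth masks.
#' @param nuclei_model,foci_model trained `unet_model`s or model
#'   directories (needed unless `use_gt`).
#' @param seed run seed (the pipeline itself is deterministic; the seed is
#'   recorded and passed to any stochastic component).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir,
                            pixel_size_um = 183.65 / 1024, z_step_um = 1,
                            projection_half_width = 1L,
                            threshold = 0.5,
                            postprocess = postprocess_config(),
                            match_radius_px = 3,
                            alpha = 0.05,
                            use_gt = FALSE,
                            nuclei_model = NULL, foci_model = NULL,
                            seed = 1L) {
  if (is.character(manifest)) manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  problems <- character(0)
  need <- c("patient_id", "condition", "dose_Gy", "image_index", "dapi", "foci")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    problems <- c(problems, sprintf("manifest lacks column(s): %s",
                                    paste(miss, collapse = ", ")))
  if (pixel_size_um <= 0) problems <- c(problems, "pixel_size_um must be > 0")
  if (z_step_um <= 0) problems <- c(problems, "z_step_um must be > 0")
  if (projection_half_width < 0)
    problems <- c(problems, "projection_half_width must be >= 0")
  if (threshold < 0 || threshold > 1)
    problems <- c(problems, "threshold must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) problems <- c(problems, "alpha must lie in (0, 1)")
  if (match_radius_px <= 0) problems <- c(problems, "match_radius_px must be > 0")
  if (!use_gt && (is.null(nuclei_model) || is.null(foci_model)))
    problems <- c(problems, "models are required unless use_gt = TRUE")
  if (use_gt && length(miss) == 0 &&
      !all(c("gt_nuclei", "gt_foci") %in% names(manifest)))
    problems <- c(problems, "use_gt needs manifest columns gt_nuclei and gt_foci")
  if (length(problems))
    stopf("invalid pipeline configuration:\n- %s",
          paste(problems, collapse = "\n- "))
  structure(list(manifest = manifest, out_dir = out_dir,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 projection_half_width = as.integer(projection_half_width),
                 threshold = threshold, postprocess = postprocess,
                 match_radius_px = match_radius_px, alpha = alpha,
                 use_gt = isTRUE(use_gt),
                 nuclei_model = nuclei_model, foci_model = foci_model,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and validate a YAML run configuration
#'
#' Parses the file, range-checks every field, applies the documented
#' defaults (watershed tolerance 4, minimum area 10 um^2, matching radius
#' 3 px, threshold 0.5) and reports all violations at once; unknown keys
#' produce a warning, not an error.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
validate_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("manifest", "out_dir", "pixel_size_um", "z_step_um",
             "projection_half_width", "threshold", "postprocess",
             "match_radius_px", "alpha", "use_gt", "nuclei_model",
             "foci_model", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  pp <- y$postprocess
  post <- postprocess_config(
    watershed_tolerance = if (is.null(pp$watershed_tolerance)) 4 else pp$watershed_tolerance,
    min_area_um2 = if (is.null(pp$min_area_um2)) 10 else pp$min_area_um2,
    exclude_border = if (is.null(pp$exclude_border)) TRUE else pp$exclude_border)
  args <- y[intersect(names(y), setdiff(known, "postprocess"))]
  args$postprocess <- post
  nm <- args$nuclei_model; fm <- args$foci_model
  if (is.character(nm)) args$nuclei_model <- load_unet(nm)
  if (is.character(fm)) args$foci_model <- load_unet(fm)
  do.call(pipeline_config, args)
}

resolve_model <- function(m) {
  if (is.null(m) || inherits(m, "unet_model")) m else load_unet(m)
}

#' Run the full segmentation and quantification pipeline
#'
#' For every manifest image: select the DAPI plane with the highest mean
#' intensity, build the foci maximum projection around it, produce the
#' semantic nuclei mask (U-net, or ground truth with `use_gt`),
#' post-process it into individual nuclei (hole filling, tolerance
#' watershed, border/area filtering), produce the foci mask, overlay, and
#' measure. Per-image masks and label maps are written as TIFFs, the
#' pooled nucleus/focus tables and per-image summaries as CSVs, and a run
#' manifest (provenance, selected planes, projection heights, timings,
#' errors) as JSON. A failing image is recorded and skipped; the run
#' continues. Identical config and inputs give byte-identical CSVs.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `nuclei`, `foci`, `summaries` (data
#'   frames) and `manifest` (per-image provenance records).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  nuclei_model <- if (!config$use_gt) resolve_model(config$nuclei_model)
  foci_model <- if (!config$use_gt) resolve_model(config$foci_model)
  mf <- config$manifest
  records <- list(); nuc_tabs <- list(); foc_tabs <- list(); summ <- list()
  for (i in seq_len(nrow(mf))) {
    row <- mf[i, ]
    key <- sprintf("%s_%s_%02d", row$patient_id, row$condition, row$image_index)
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      meta <- image_meta(row$patient_id, row$condition, row$dose_Gy,
                         row$image_index)
      dapi <- read_zstack(row$dapi, config$pixel_size_um, config$z_step_um,
                          "DAPI")
      foci <- read_zstack(row$foci, config$pixel_size_um, config$z_step_um,
                          "FOCI")
      if (!all(dim(dapi$planes[[1]]) == dim(foci$planes[[1]])))
        stopf("DAPI and foci stacks disagree in shape for %s", key)
      sel <- select_focus_plane(dapi)
      proj <- max_project_around(foci, sel$index, config$projection_half_width)
      height_um <- attr(proj, "projection_height_um")
      if (config$use_gt) {
        nuclei_labels <- filter_regions(
          read_labels(row$gt_nuclei, config$pixel_size_um),
          config$postprocess)
        foci_mask <- read_mask(row$gt_foci, config$pixel_size_um)
      } else {
        nuclei_mask <- predict_mask(nuclei_model, sel$plane,
                                    threshold = config$threshold)
        nuclei_labels <- postprocess_nuclei(nuclei_mask, config$postprocess)
        foci_mask <- predict_mask(foci_model, proj,
                                  threshold = config$threshold)
      }
      frecs <- overlay_foci(foci_mask, nuclei_labels, meta)
      nrecs <- measure_nuclei(nuclei_labels, frecs, height_um, meta)
      nuc_tabs[[key]] <- nrecs
      foc_tabs[[key]] <- frecs
      summ[[key]] <- summarize_image(nrecs, frecs, meta, height_um)
      lab_path <- file.path(config$out_dir, paste0(key, "_nuclei_labels.tif"))
      msk_path <- file.path(config$out_dir, paste0(key, "_foci_mask.tif"))
      write_mask(nuclei_labels, lab_path)
      write_mask(foci_mask, msk_path)
      list(image = key, status = "ok",
           inputs = list(dapi = row$dapi, foci = row$foci),
           selected_z_index = sel$index,
           projection_height_um = height_um,
           n_nuclei = nrow(nrecs), n_foci = nrow(frecs),
           outputs = list(nuclei_labels = lab_path, foci_mask = msk_path),
           seconds = round(proc.time()[["elapsed"]] - t0, 3))
    }, error = function(e) {
      list(image = key, status = "error", message = conditionMessage(e),
           seconds = round(proc.time()[["elapsed"]] - t0, 3))
    })
    records[[key]] <- rec
  }
  nuclei <- if (length(nuc_tabs)) do.call(rbind, unname(nuc_tabs)) else NULL
  foci <- if (length(foc_tabs)) do.call(rbind, unname(foc_tabs)) else NULL
  summaries <- if (length(summ)) do.call(rbind, unname(summ)) else NULL
  if (!is.null(nuclei))
    write_measurements(nuclei, file.path(config$out_dir, "nuclei_measurements.csv"))
  if (!is.null(foci) && nrow(foci) > 0)
    write_measurements(foci, file.path(config$out_dir, "foci_measurements.csv"))
  if (!is.null(summaries))
    write.csv(summaries, file.path(config$out_dir, "image_summaries.csv"),
              row.names = FALSE)
  run_manifest <- list(
    config = list(pixel_size_um = config$pixel_size_um,
                  z_step_um = config$z_step_um,
                  projection_half_width = config$projection_half_width,
                  threshold = config$threshold,
                  watershed_tolerance = config$postprocess$watershed_tolerance,
                  min_area_um2 = config$postprocess$min_area_um2,
                  exclude_border = config$postprocess$exclude_border,
                  use_gt = config$use_gt, seed = config$seed),
    images = unname(records))
  jsonlite::write_json(run_manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(nuclei = nuclei, foci = foci, summaries = summaries,
                 manifest = records))
}
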