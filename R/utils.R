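# Internal helpers shared across modules.

# Run code with a private RNG stream; the caller's RNG state is untouched.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_binary <- function(x) all(x %in% c(0, 1))

# 8-connected component labeling (see src/ops.cpp).
components8 <- function(mask_raster) {
  storage.mode(mask_raster) <- "integer"
  .label8(mask_raster)
}

# Per-label pixel areas (px) of an integer label raster; named by label id.
label_areas_px <- function(labels) {
  v <- labels[labels > 0L]
  if (length(v) == 0L) return(integer(0))
  table_v <- tabulate(v)
  keep <- which(table_v > 0L)
  stats::setNames(table_v[keep], keep)
}

# Centroids of labeled objects in the package-wide 0-based (row, col)
# convention: arithmetic mean of member pixel coordinates.
label_centroids <- function(labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  H <- nrow(labels)
  lab <- labels[idx]
  r0 <- (idx - 1L) %% H          # 0-based row
  c0 <- (idx - 1L) %/% H         # 0-based col
  n <- tabulate(lab)
  keep <- which(n > 0L)
  data.frame(
    label = keep,
    row = rowsum(as.numeric(r0), lab)[, 1] / n[keep],
    col = rowsum(as.numeric(c0), lab)[, 1] / n[keep]
  )
}
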