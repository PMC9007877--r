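## Coordinate conventions used package-wide: pixels are (row, col), 0-based;
## bounding boxes are half-open (row_min, col_min, row_max, col_max).

#' Extract per-nucleus records from a label mask
#'
#' One record per mask label with at least `min_nucleus_area` pixels;
#' smaller components are dropped and counted in the attached report.
#' Nuclei touching the patch border are flagged: their centroids remain
#' valid graph nodes but their truncated contours bias shape features, so
#' downstream shape/texture blocks exclude them by default.
#'
#' @param label_mask Integer matrix, 0 = background, k > 0 = nucleus k.
#' @param image Optional intensity matrix of the same shape; per-nucleus
#'   intensities are attached when given.
#' @param min_nucleus_area Minimum pixel count (default 10).
#' @return List of `nm_nucleus` records (fields: `label`, `pixels` (n x 2,
#'   0-based row/col), `centroid`, `bbox`, `border`, `contour` (ordered,
#'   closed), `intensity`), with attributes `n_dropped`, `dropped_area`.
#' @export
extract_nuclei <- function(label_mask, image = NULL, min_nucleus_area = 10) {
  stopif(!is.matrix(label_mask), "label_mask must be a matrix")
  stopif(any(label_mask %% 1 != 0) || any(label_mask < 0),
         "label_mask must contain non-negative integers")
  if (!is.null(image))
    stopif(!identical(dim(image), dim(label_mask)),
           "image and label_mask shapes differ")
  nr <- nrow(label_mask); nc <- ncol(label_mask)
  lin <- which(label_mask > 0)
  groups <- split(lin, label_mask[lin])

  recs <- list(); n_drop <- 0L; area_drop <- 0L
  for (lab in names(groups)) {
    g <- groups[[lab]]
    if (length(g) < min_nucleus_area) {
      n_drop <- n_drop + 1L
      area_drop <- area_drop + length(g)
      next
    }
    r <- (g - 1L) %% nr          # 0-based
    cc <- (g - 1L) %/% nr
    border <- any(r == 0L | r == nr - 1L | cc == 0L | cc == nc - 1L)
    contour <- trace_contour(r, cc)
    recs[[length(recs) + 1L]] <- structure(list(
      label = as.integer(lab),
      pixels = cbind(row = r, col = cc),
      centroid = c(row = mean(r), col = mean(cc)),
      bbox = c(row_min = min(r), col_min = min(cc),
               row_max = max(r) + 1L, col_max = max(cc) + 1L),
      border = border,
      contour = contour,
      intensity = if (is.null(image)) NULL else as.numeric(image[g])),
      class = "nm_nucleus")
  }
  attr(recs, "n_dropped") <- n_drop
  attr(recs, "dropped_area") <- area_drop
  recs
}

## Moore-neighbor boundary tracing with Jacob's stopping criterion.
## r, cc: 0-based member pixel coordinates of one connected nucleus.
## Returns ordered closed contour as an n x 2 matrix (row, col), 0-based.
trace_contour <- function(r, cc) {
  if (length(r) == 1L) return(cbind(row = r, col = cc))
  r0 <- min(r); c0 <- min(cc)
  h <- max(r) - r0 + 3L; w <- max(cc) - c0 + 3L  # 1-px pad
  B <- matrix(FALSE, h, w)
  B[cbind(r - r0 + 2L, cc - c0 + 2L)] <- TRUE
  ## clockwise Moore neighborhood starting due west (dr, dc)
  off <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
               c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  ## start: uppermost, then leftmost foreground pixel; its west neighbor is
  ## guaranteed background, giving the initial backtrack
  idx <- which(B, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  start <- as.integer(idx[1, ])
  b0 <- start + off[1L, ]            # west of start
  p <- start; b <- b0
  path <- list(p)
  max_steps <- 8L * length(r) + 8L
  for (step in seq_len(max_steps)) {
    db <- which(off[, 1] == b[1] - p[1] & off[, 2] == b[2] - p[2])
    moved <- FALSE
    for (k in 1:8) {
      d <- (db + k - 1L) %% 8L + 1L   # clockwise scan starting after b
      q <- p + off[d, ]
      if (B[q[1], q[2]]) {
        dprev <- (db + k - 2L) %% 8L + 1L
        b <- p + off[dprev, ]         # last background examined
        p <- q
        moved <- TRUE
        break
      }
    }
    if (!moved) break
    ## Jacob's criterion: initial (position, backtrack) state repeats
    if (all(p == start) && all(b == b0)) break
    path[[length(path) + 1L]] <- p
  }
  m <- do.call(rbind, path)
  cbind(row = m[, 1] + r0 - 2L, col = m[, 2] + c0 - 2L)
}

#' Tile an image (and mask) into patches
#'
#' Row-major tiling; partial edge tiles are discarded; each tile records
#' its 0-based origin in the parent image.
#'
#' @param image Matrix.
#' @param mask Optional matrix of the same shape.
#' @param patch_size Tile side (<= both image dims).
#' @param stride Step between tile origins (default `patch_size`).
#' @return List of `list(image, mask, origin = c(row, col))`.
#' @export
tile_image <- function(image, mask = NULL, patch_size, stride = patch_size) {
  stopif(patch_size > nrow(image) || patch_size > ncol(image),
         "patch_size exceeds image dimensions")
  if (!is.null(mask))
    stopif(!identical(dim(mask), dim(image)), "image/mask shape mismatch")
  r_origins <- seq(0L, nrow(image) - patch_size, by = stride)
  c_origins <- seq(0L, ncol(image) - patch_size, by = stride)
  out <- list()
  for (r0 in r_origins) for (c0 in c_origins) {
    rows <- (r0 + 1):(r0 + patch_size)
    cols <- (c0 + 1):(c0 + patch_size)
    out[[length(out) + 1L]] <- list(
      image = image[rows, cols],
      mask = if (is.null(mask)) NULL else mask[rows, cols],
      origin = c(row = r0, col = c0))
  }
  out
}

#' Classical watershed nucleus segmentation
#'
#' A deterministic threshold + distance-transform + watershed segmenter
#' for dark nuclei on a bright background, serving as the package's
#' built-in alternative to learned segmentation.
#'
#' @param image Single-channel intensity matrix (0..255 scale).
#' @param min_nucleus_area Components smaller than this are removed.
#' @param tolerance Watershed merge tolerance (EBImage convention).
#' @return Integer label mask (consecutive labels 1..n).
#' @export
watershed_segment <- function(image, min_nucleus_area = 10, tolerance = 1) {
  stopif(length(dim(image)) != 2, "single-channel image required")
  if (diff(range(image)) == 0) {
    warning("constant image; returning all-background mask")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  x <- 1 - image / 255                  # nuclei dark -> foreground bright
  thr <- EBImage::otsu(EBImage::Image(x))
  binary <- x > thr
  if (!any(binary)) {
    warning("no foreground after thresholding")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  d <- EBImage::distmap(EBImage::Image(binary))
  ws <- EBImage::watershed(d, tolerance = tolerance, ext = 1)
  m <- matrix(as.integer(EBImage::imageData(ws)), nrow(image), ncol(image))
  ## drop tiny components, relabel consecutively
  tab <- tabulate(m[m > 0])
  keep <- which(tab >= min_nucleus_area)
  relab <- integer(length(tab))
  relab[keep] <- seq_along(keep)
  m[m > 0] <- relab[m[m > 0]]
  m
}

#' Read / write a cohort patch manifest
#'
#' CSV with one row per patch: `patient_id`, `class_label`, `image_path`,
#' `mask_path`, `origin_row`, `origin_col`, and optional `time`, `event`.
#' Reading validates that referenced files exist.
#'
#' @param path CSV path.
#' @param check_files Verify referenced files exist (default `TRUE`).
#' @return Data frame of manifest entries.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  stopif(!file.exists(path), paste("manifest not found:", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "image_path", "mask_path")
  stopif(!all(need %in% names(df)),
         paste("manifest must contain:", paste(need, collapse = ", ")))
  if (check_files && nrow(df)) {
    base <- dirname(path)
    for (i in seq_len(nrow(df))) {
      for (col in c("image_path", "mask_path")) {
        p <- df[[col]][i]
        if (!file.exists(p) && !file.exists(file.path(base, p)))
          stop(sprintf("row %d (patient %s): missing file %s",
                       i, df$patient_id[i], p), call. = FALSE)
      }
    }
  }
  df
}

#' @rdname read_manifest
#' @param entries Data frame of manifest entries.
#' @export
write_manifest <- function(entries, path) {
  write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

#' Read / write images and label masks
#'
#' Intensity images are 8-bit grayscale PNG (RGB inputs are collapsed by
#' Rec. 601 luminance weights); label masks are 16-bit grayscale TIFF
#' (8-bit PNG also accepted on read for masks with <= 255 labels).
#'
#' @param path File path (`.png` or `.tif`/`.tiff`).
#' @return Integer matrix.
#' @export
read_image <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 3L)
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  x <- read_raster(path)
  stopif(length(dim(x)) == 3L, "mask must be single-channel")
  scale <- if (grepl("\\.png$", path, ignore.case = TRUE)) 255 else 65535
  matrix(as.integer(round(x * scale)), nrow(x), ncol(x))
}

read_raster <- function(path) {
  stopif(!file.exists(path), paste("file not found:", path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
  else tiff::readTIFF(path)
}

#' @rdname read_image
#' @param image Integer matrix in 0..255.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_image
#' @param mask Integer label matrix (labels < 65536).
#' @export
write_mask <- function(mask, path) {
  stopif(max(mask) > 65535, "more than 65535 labels")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Materialize a synthetic cohort to disk
#'
#' Writes every patch image (PNG) and label mask (16-bit TIFF), a CSV
#' manifest with survival columns, and a YAML echo of the generator
#' configuration.
#'
#' @param cohort An `nm_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(cohort$patches)
  entries <- data.frame(
    patient_id = cohort$patches$patient_id,
    class_label = cohort$patches$class,
    image_path = file.path(dir, paste0(cohort$patches$patch_id, ".png")),
    mask_path = file.path(dir, paste0(cohort$patches$patch_id, "_mask.tif")),
    origin_row = 0L, origin_col = 0L, stringsAsFactors = FALSE)
  surv <- cohort$patients[match(cohort$patches$patient_id,
                                cohort$patients$patient_id), ]
  entries$time <- surv$time
  entries$event <- surv$event
  for (i in seq_len(n)) {
    p <- cohort_patch(cohort, i)
    write_image(p$image, entries$image_path[i])
    write_mask(p$label_mask, entries$mask_path[i])
  }
  cfg <- list(seed = cohort$seed, patch_size = cohort$patch_size,
              archetypes = lapply(cohort$archetypes, unclass),
              survival_params = cohort$survival_params)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- file.path(dir, "manifest.csv")
  write_manifest(entries, manifest)
  invisible(manifest)
}
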