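#' Feature-extraction configuration
#'
#' One configuration object shared by every feature family. Defaults:
#' minimum nucleus size 10 px; patches with fewer than 5 usable nuclei are
#' skipped; 8 gray levels and 4 symmetric offsets for the GLCM; 10 Fourier
#' descriptor magnitudes; 18 orientation-histogram bins (10 degrees each);
#' CCG decay exponent 1 with link threshold 0.1 on distances expressed as
#' percent of the patch diagonal; 4 equal-frequency bins for run-length
#' and diversity attributes, run lengths capped at 10.
#'
#' @param min_nucleus_area Minimum nucleus pixel count.
#' @param min_nuclei Minimum usable nuclei per patch.
#' @param glcm_levels GLCM gray levels G.
#' @param offsets GLCM offsets, list of `(dr, dc)`.
#' @param n_fourier Fourier descriptor count K.
#' @param orientation_bins Orientation-entropy histogram bins.
#' @param ccg_alpha,ccg_r CCG decay exponent and link threshold.
#' @param rle_bins,rle_lmax Run-length attribute bins and length cap.
#' @param ccm_bins Morphology bins M for the diversity matrix.
#' @return Named list of class `nm_config`.
#' @export
nm_config <- function(min_nucleus_area = 10, min_nuclei = 5,
                      glcm_levels = 8, offsets = default_offsets(),
                      n_fourier = 10, orientation_bins = 18,
                      ccg_alpha = 1, ccg_r = 0.1,
                      rle_bins = 4, rle_lmax = 10, ccm_bins = 4) {
  structure(list(min_nucleus_area = min_nucleus_area,
                 min_nuclei = min_nuclei, glcm_levels = glcm_levels,
                 offsets = offsets, n_fourier = n_fourier,
                 orientation_bins = orientation_bins,
                 ccg_alpha = ccg_alpha, ccg_r = ccg_r,
                 rle_bins = rle_bins, rle_lmax = rle_lmax,
                 ccm_bins = ccm_bins),
            class = "nm_config")
}

#' Full feature vector of one patch
#'
#' Runs nucleus extraction and all feature families (shape, texture,
#' Delaunay, CCG shape, orientation tensor, run-length, diversity) on one
#' image + label-mask pair.
#'
#' @param image Intensity matrix (0..255).
#' @param label_mask Integer label mask of the same shape.
#' @param config [nm_config()].
#' @return Named numeric vector, or `NULL` when the patch has fewer than
#'   `config$min_nuclei` usable nuclei (skipped).
#' @export
patch_features <- function(image, label_mask, config = nm_config()) {
  nuclei <- extract_nuclei(label_mask, image, config$min_nucleus_area)
  if (length(nuclei) < config$min_nuclei) return(NULL)
  border <- vapply(nuclei, function(x) x$border, logical(1))
  if (sum(!border) < config$min_nuclei) return(NULL)
  ## shared per-nucleus computations (all nuclei; shape/texture blocks use
  ## interior rows only, graph families use all nodes)
  desc_all <- descriptor_matrix(nuclei, config, interior_only = FALSE)
  har_all <- haralick_matrix(nuclei, config)
  colnames(har_all) <- haralick_names
  shape <- aggregate_block(desc_all[!border, , drop = FALSE], "shape")
  texture <- aggregate_block(har_all[!border, , drop = FALSE], "texture")
  graph <- graph_block_impl(nuclei, desc_all, har_all[, "contrast"],
                            nrow(label_mask), config)
  c(shape, texture, graph)
}

#' Feature table for a whole synthetic cohort
#'
#' Materializes every patch of an [generate_cohort()] cohort from its
#' stored seed, extracts the full feature vector, and stacks them into a
#' patches x features matrix. Patches with too few nuclei are skipped and
#' reported.
#'
#' @param cohort `nm_cohort`.
#' @param config [nm_config()].
#' @param progress Print a dot every 25 patches.
#' @return List of class `nm_features`: `features` (matrix), `meta`
#'   (data.frame aligned with rows: patient_id, class, patch_id),
#'   `n_skipped`.
#' @export
cohort_features <- function(cohort, config = nm_config(), progress = FALSE) {
  n <- nrow(cohort$patches)
  rows <- vector("list", n)
  kept <- logical(n)
  for (i in seq_len(n)) {
    p <- cohort_patch(cohort, i)
    fv <- patch_features(p$image, p$label_mask, config)
    if (!is.null(fv)) {
      rows[[i]] <- fv
      kept[i] <- TRUE
    }
    if (progress && i %% 25 == 0) cat(".")
  }
  if (progress) cat("\n")
  stopif(!any(kept), "no patch yielded features")
  features <- do.call(rbind, rows[kept])
  rownames(features) <- cohort$patches$patch_id[kept]
  structure(list(features = features,
                 meta = cohort$patches[kept,
                   c("patient_id", "class", "patch_id")],
                 n_skipped = sum(!kept)),
            class = "nm_features")
}

#' @export
print.nm_features <- function(x, ...) {
  cat(sprintf("<nm_features> %d patches x %d features (%d skipped)\n",
              nrow(x$features), ncol(x$features), x$n_skipped))
  invisible(x)
}

#' Feature table from a patch manifest
#'
#' Computes the same feature matrix as [cohort_features()] for
#' user-supplied images and masks listed in a manifest CSV (see
#' [read_manifest()]).
#'
#' @param manifest_path Manifest CSV path.
#' @param config [nm_config()].
#' @return `nm_features`.
#' @export
features_from_manifest <- function(manifest_path, config = nm_config()) {
  man <- read_manifest(manifest_path)
  rows <- vector("list", nrow(man))
  kept <- logical(nrow(man))
  for (i in seq_len(nrow(man))) {
    img <- read_image(man$image_path[i])
    msk <- read_mask(man$mask_path[i])
    fv <- patch_features(img, msk, config)
    if (!is.null(fv)) {
      rows[[i]] <- fv
      kept[i] <- TRUE
    }
  }
  stopif(!any(kept), "no patch yielded features")
  features <- do.call(rbind, rows[kept])
  meta <- data.frame(patient_id = man$patient_id[kept],
                     class = (man$class_label %||% rep(NA, nrow(man)))[kept],
                     patch_id = seq_len(nrow(man))[kept],
                     stringsAsFactors = FALSE)
  structure(list(features = features, meta = meta,
                 n_skipped = sum(!kept)),
            class = "nm_features")
}

#' Patient-level feature profiles
#'
#' Mean of patch feature vectors per patient — the representation used for
#' clustering and embedding.
#'
#' @param feats `nm_features`.
#' @param columns Optional subset of feature names.
#' @return List: `profile` (patients x features matrix), `patients`
#'   (data.frame patient_id, class).
#' @export
patient_profiles <- function(feats, columns = NULL) {
  X <- feats$features
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  ids <- unique(feats$meta$patient_id)
  prof <- t(vapply(ids, function(pid)
    colMeans(X[feats$meta$patient_id == pid, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(X))))
  rownames(prof) <- ids
  cls <- feats$meta$class[match(ids, feats$meta$patient_id)]
  list(profile = prof, patients = data.frame(patient_id = ids, class = cls,
                                             stringsAsFactors = FALSE))
}
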