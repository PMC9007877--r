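## Programmatic fixtures; nothing is stored on disk.

## Archetype for small fast test patches: ~30 nuclei on a 512 x 512 patch.
small_archetype <- function(name = "test", area_log_mean = log(300),
                            area_log_sd = 0.3, aspect_mean = 1.8,
                            orientation_kappa = 4, contrast_sd = 8,
                            density_mean = 115) {
  archetype_params(name, area_log_mean, area_log_sd, aspect_mean,
                   orientation_kappa, contrast_sd, density_mean)
}

## label mask with a filled axis-aligned rectangle
rect_mask <- function(nr, nc, r0, c0, h, w, label = 1L) {
  m <- matrix(0L, nr, nc)
  m[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)] <- label   # r0, c0 are 0-based
  m
}

## label mask with a filled disk
disk_mask <- function(nr, nc, cr, cc, radius, label = 1L) {
  m <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r - 1 - cr)^2 + (c - 1 - cc)^2 <= radius^2) m[r, c] <- label
  }
  m
}

## one extracted nm_nucleus from a mask + intensity image
one_nucleus <- function(mask, image = NULL, min_area = 1) {
  recs <- extract_nuclei(mask, image, min_nucleus_area = min_area)
  stopifnot(length(recs) == 1L)
  recs[[1]]
}

## nucleus record with prescribed intensities on a h x w rectangle
textured_nucleus <- function(intensities, h, w, pad = 3) {
  stopifnot(length(intensities) == h * w)
  mask <- rect_mask(h + 2 * pad, w + 2 * pad, pad, pad, h, w)
  img <- matrix(0, h + 2 * pad, w + 2 * pad)
  img[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- matrix(intensities, h, w)
  one_nucleus(mask, img)
}

## tiny three-class cohort feature set for classifier tests (cached)
tiny_cohort_features <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(
        c(stage2 = 8, stage4_hematogenous = 8), patches_per_patient = 2,
        seed = 301, patch_size = 512,
        archetypes = list(
          stage2 = small_archetype("stage2", orientation_kappa = 8,
                                   area_log_mean = log(250),
                                   contrast_sd = 3),
          stage4_hematogenous = small_archetype("stage4_hematogenous",
                                                orientation_kappa = 1.5,
                                                area_log_mean = log(450),
                                                contrast_sd = 18)))
      cache <<- suppressWarnings(cohort_features(co))
    }
    cache
  }
})
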