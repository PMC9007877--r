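#' Generate one synthetic nuclei patch
#'
#' Renders a patch of non-overlapping elliptical nuclei on a bright
#' background together with its integer label mask and a ground-truth table
#' of the generative parameters. Nucleus count is Poisson with mean
#' `density_mean * (patch_size/1000)^2`; areas are lognormal; orientations
#' are von Mises around a per-patch random direction, folded to [0, 180);
#' each nucleus's interior intensity is a dark base, plus a fixed-amplitude
#' smooth gradient along the major axis (a chromatin-like structure), plus
#' zero-mean granular noise whose amplitude is that nucleus's contrast
#' draw — so the contrast draw controls how rough the nuclear texture is
#' relative to its smooth structure.
#'
#' All geometry (count, sizes, angles, placement, contrast draws) is sampled
#' before any pixel noise, so the label mask and truth table are identical
#' whether or not the intensity image is rendered.
#'
#' @param params An [archetype_params()] object.
#' @param patch_size Patch side in pixels (>= 64).
#' @param seed Integer seed; the patch is deterministic given
#'   `(params, patch_size, seed)`.
#' @param render_image If `FALSE`, skip intensity rendering (mask and truth
#'   only); useful when only geometry is needed.
#' @return An object of class `nm_patch`: list with `image` (integer matrix
#'   in 0..255, or `NULL`), `label_mask` (integer matrix, 0 = background,
#'   labels consecutive 1..n), `truth` (data.frame: label, center_row,
#'   center_col, semi_major, semi_minor, theta_deg, target_area, area_px,
#'   contrast), `params`, `patch_size`, `seed`.
#' @export
generate_patch <- function(params, patch_size = 1000, seed,
                           render_image = TRUE) {
  stopifnot(inherits(params, "nm_archetype"))
  stopif(patch_size < 64, "patch_size must be >= 64")
  stopif(missing(seed), "seed is required")

  with_seed(seed, {
    n <- rpois(1L, params$density_mean * (patch_size / 1000)^2)
    mu_deg <- runif(1, 0, 180)
    area <- rlnorm(n, params$area_log_mean, params$area_log_sd)
    aspect <- pmax(1.05, rnorm(n, params$aspect_mean, 0.25))
    theta <- (mu_deg + rvonmises(n, 0, params$orientation_kappa) * 180 / pi) %% 180
    contrast <- abs(rnorm(n, 10, params$contrast_sd))
    b <- sqrt(area / (pi * aspect))
    a <- aspect * b

    ## Rejection-sampled placement: bounding circles (radius = semi-major)
    ## must not intersect; capped at 100 attempts per nucleus.
    cr <- numeric(0); cc <- numeric(0); keep <- integer(0)
    for (i in seq_len(n)) {
      margin <- a[i] + 2
      if (2 * margin >= patch_size) next
      placed <- FALSE
      for (att in seq_len(100L)) {
        r0 <- runif(1, margin, patch_size - margin)
        c0 <- runif(1, margin, patch_size - margin)
        if (!length(cr) ||
            all((cr - r0)^2 + (cc - c0)^2 > (a[keep] + a[i] + 1)^2)) {
          placed <- TRUE
          break
        }
      }
      if (placed) {
        cr <- c(cr, r0); cc <- c(cc, c0); keep <- c(keep, i)
      }
    }
    if (length(keep) < n)
      warning(sprintf("placement failed for %d of %d nuclei; patch has %d",
                      n - length(keep), n, length(keep)))

    m <- length(keep)
    mask <- matrix(0L, patch_size, patch_size)
    pix_list <- vector("list", m)
    for (k in seq_len(m)) {
      i <- keep[k]
      th <- theta[i] * pi / 180
      r0 <- cr[k]; c0 <- cc[k]
      rr <- max(1L, floor(r0 - a[i])):min(patch_size, ceiling(r0 + a[i]))
      cols <- max(1L, floor(c0 - a[i])):min(patch_size, ceiling(c0 + a[i]))
      dr <- (rr - 1) - r0          # 0-based pixel coords
      dc <- (cols - 1) - c0
      ## major axis unit vector in (col, row) space at angle theta from +col
      s <- outer(dr, dc, function(y, x) (x * cos(th) + y * sin(th)) / a[i])
      t <- outer(dr, dc, function(y, x) (-x * sin(th) + y * cos(th)) / b[i])
      inside <- s^2 + t^2 <= 1
      idx <- which(inside, arr.ind = TRUE)
      if (!nrow(idx)) next
      lin <- (cols[idx[, 2]] - 1L) * patch_size + rr[idx[, 1]]
      lin <- lin[mask[lin] == 0L]
      mask[lin] <- k
      pix_list[[k]] <- lin
    }

    truth <- data.frame(
      label = seq_len(m),
      center_row = cr, center_col = cc,
      semi_major = a[keep], semi_minor = b[keep],
      theta_deg = theta[keep],
      target_area = area[keep],
      area_px = vapply(pix_list, length, integer(1)),
      contrast = contrast[keep])

    img <- NULL
    if (render_image) {
      v <- integer(patch_size * patch_size)
      for (k in seq_len(m)) {
        lin <- pix_list[[k]]
        if (!length(lin)) next
        ## chromatin-like smooth gradient of fixed amplitude along the
        ## major axis; the contrast draw sets the granular noise on top,
        ## so it controls the rough-to-smooth ratio that normalized
        ## co-occurrence contrast measures
        i <- keep[k]
        th <- theta[i] * pi / 180
        pr <- (((lin - 1L) %/% patch_size) - cc[k]) * cos(th) +
              (((lin - 1L) %% patch_size) - cr[k]) * sin(th)
        ramp <- 15 * pr / a[i]
        v[lin] <- 100L + as.integer(round(ramp +
          rnorm(length(lin), 0, truth$contrast[k])))
      }
      bg <- which(mask == 0L)
      v[bg] <- 200L + as.integer(round(rnorm(length(bg), 0, 3)))
      v[v < 0L] <- 0L
      v[v > 255L] <- 255L
      img <- matrix(v, patch_size, patch_size)
    }

    structure(list(image = img, label_mask = mask, truth = truth,
                   params = params, patch_size = patch_size, seed = seed),
              class = "nm_patch")
  })
}

#' @export
print.nm_patch <- function(x, ...) {
  cat(sprintf("<nm_patch> %dx%d, %d nuclei (%s), seed %d\n",
              x$patch_size, x$patch_size, nrow(x$truth),
              x$params$name, x$seed))
  invisible(x)
}

#' Generate a synthetic patient cohort
#'
#' Builds a cohort skeleton: patients with class labels, per-patch
#' generation seeds, and exponential survival times with class-specific
#' hazards and independent exponential censoring. Patch pixel data are not
#' materialized here; each patch is reproducible from its stored seed via
#' [generate_patch()] (see [cohort_features()] and [write_cohort()]).
#'
#' @param n_per_class Named integer vector/list, class name -> patient
#'   count. Class names must match `names(archetypes)`.
#' @param patches_per_patient Patches per patient (>= 1).
#' @param survival_params Named list per class:
#'   `list(hazard = , censor_rate = )`, rates per month. Default gives
#'   stage II a median overall survival of 60 months, both stage IV classes
#'   a hazard ratio of 2 relative to stage II, and light censoring.
#' @param seed Master seed; everything is reproducible from it.
#' @param patch_size Patch side in pixels.
#' @param archetypes Named list of [archetype_params()]; defaults to
#'   [archetype_presets()].
#' @return Object of class `nm_cohort`: `patients` (patient_id, class,
#'   time, event), `patches` (patient_id, class, patch_id, patch_seed),
#'   `archetypes`, `patch_size`, `seed`.
#' @export
generate_cohort <- function(n_per_class, patches_per_patient = 5,
                            survival_params = NULL, seed,
                            patch_size = 1000,
                            archetypes = archetype_presets()) {
  stopif(missing(seed), "seed is required")
  n_per_class <- unlist(n_per_class)
  stopif(is.null(names(n_per_class)) || any(names(n_per_class) == ""),
         "n_per_class must be named by class")
  stopif(any(n_per_class < 0), "counts must be >= 0")
  stopif(sum(n_per_class) == 0, "cohort must contain at least one patient")
  stopif(patches_per_patient < 1, "patches_per_patient must be >= 1")
  bad <- setdiff(names(n_per_class), names(archetypes))
  stopif(length(bad) > 0, paste("unknown class:", paste(bad, collapse = ", ")))

  if (is.null(survival_params)) {
    base <- log(2) / 60    # stage II median 60 months
    survival_params <- lapply(names(n_per_class), function(cl) {
      hr <- if (cl == "stage2") 1 else 2
      list(hazard = base * hr, censor_rate = base / 3)
    })
    names(survival_params) <- names(n_per_class)
  }
  for (cl in names(n_per_class))
    stopif(survival_params[[cl]]$hazard <= 0, "hazard must be > 0")

  cls <- rep(names(n_per_class), times = n_per_class)
  n_pat <- length(cls)
  patients <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n_pat)),
    class = cls, stringsAsFactors = FALSE)

  with_seed(seed, {
    haz <- vapply(cls, function(cl) survival_params[[cl]]$hazard, numeric(1))
    cens <- vapply(cls, function(cl)
      survival_params[[cl]]$censor_rate %||% 0, numeric(1))
    t_event <- rexp(n_pat, haz)
    t_cens <- ifelse(cens > 0, rexp(n_pat, pmax(cens, 1e-12)), Inf)
    patients$time <- pmin(t_event, t_cens)
    patients$event <- as.integer(t_event <= t_cens)
  })

  n_patch <- n_pat * patches_per_patient
  patches <- data.frame(
    patient_id = rep(patients$patient_id, each = patches_per_patient),
    class = rep(cls, each = patches_per_patient),
    patch_id = sprintf("%s_patch%02d",
                       rep(patients$patient_id, each = patches_per_patient),
                       rep(seq_len(patches_per_patient), n_pat)),
    patch_seed = derive_seeds(seed + 1L, n_patch),
    stringsAsFactors = FALSE)

  structure(list(patients = patients, patches = patches,
                 archetypes = archetypes[names(n_per_class)],
                 survival_params = survival_params,
                 patch_size = patch_size, seed = seed),
            class = "nm_cohort")
}

#' @export
print.nm_cohort <- function(x, ...) {
  cat("<nm_cohort>", nrow(x$patients), "patients,",
      nrow(x$patches), "patches, seed", x$seed, "\n")
  print(table(x$patients$class))
  invisible(x)
}

#' Materialize a patch from a cohort row
#'
#' @param cohort An `nm_cohort`.
#' @param i Row index into `cohort$patches`.
#' @param render_image Passed to [generate_patch()].
#' @return `nm_patch`.
#' @export
cohort_patch <- function(cohort, i, render_image = TRUE) {
  row <- cohort$patches[i, ]
  generate_patch(cohort$archetypes[[row$class]], cohort$patch_size,
                 seed = row$patch_seed, render_image = render_image)
}
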