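haralick_names <- c("asm", "contrast", "correlation", "sum_squares_variance",
                    "inv_diff_moment", "sum_average", "sum_variance",
                    "sum_entropy", "entropy", "diff_variance",
                    "diff_entropy", "imc1", "imc2")

default_offsets <- function() list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

## Per-nucleus min-max quantization to G levels. For integer-valued
## intensities levels are floor((I - min) * G / (range + 1)), which reverses
## exactly under intensity inversion whenever (range + 1) is a multiple of G.
quantize_levels <- function(intensity, G) {
  rng <- max(intensity) - min(intensity)
  if (rng == 0) return(rep(0L, length(intensity)))
  if (all(intensity %% 1 == 0)) {
    pmin(G - 1L, as.integer(floor((intensity - min(intensity)) * G / (rng + 1))))
  } else {
    pmin(G - 1L, as.integer(floor((intensity - min(intensity)) / rng * G)))
  }
}

#' Gray-level co-occurrence matrix of one nucleus
#'
#' Intensities are quantized to `G` levels by per-nucleus min-max scaling
#' (so texture is measured relative to the nucleus's own intensity range);
#' pairs are counted only when both pixels belong to the nucleus,
#' accumulated over all offsets, symmetrized, and normalized to sum 1.
#'
#' @param nucleus `nm_nucleus` record carrying `intensity` (see
#'   [extract_nuclei()] with `image`).
#' @param G Number of gray levels (default 8).
#' @param offsets List of `(dr, dc)` displacements.
#' @return Object of class `nm_glcm`: `matrix` (G x G, sums to 1), `levels`,
#'   `offsets`, `symmetric = TRUE`.
#' @export
glcm <- function(nucleus, G = 8, offsets = default_offsets()) {
  stopif(is.null(nucleus$intensity), "nucleus has no intensity data")
  px <- nucleus$pixels
  stopif(nrow(px) < 2, "need >= 2 pixels")
  q <- quantize_levels(nucleus$intensity, G)

  ## crop with quantized levels; -1 outside the nucleus
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  h <- max(px[, 1]) - r0 + 1L; w <- max(px[, 2]) - c0 + 1L
  crop <- matrix(-1L, h, w)
  crop[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- q

  counts <- matrix(0, G, G)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rs <- max(1L, 1L - dr):min(h, h - dr)
    cs <- max(1L, 1L - dc):min(w, w - dc)
    if (!length(rs) || !length(cs)) next
    a <- crop[rs, cs, drop = FALSE]
    b <- crop[rs + dr, cs + dc, drop = FALSE]
    ok <- a >= 0L & b >= 0L
    if (!any(ok)) next
    tab <- tabulate(a[ok] * G + b[ok] + 1L, nbins = G * G)
    counts <- counts + matrix(tab, G, G, byrow = TRUE)
  }
  counts <- counts + t(counts)                 # symmetrize
  tot <- sum(counts)
  if (tot > 0) counts <- counts / tot
  structure(list(matrix = counts, levels = G, offsets = offsets,
                 symmetric = TRUE),
            class = "nm_glcm")
}

#' The 13 Haralick measurements of a co-occurrence matrix
#'
#' Angular second moment (energy), contrast, correlation, sum-of-squares
#' variance, inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy, and the two
#' information measures of correlation. Logarithms are base 2 (bits) with
#' 0 log 0 := 0. A degenerate single-entry matrix yields zero entropies and
#' correlation reported as 0 (flagged).
#'
#' @param cm `nm_glcm` or a normalized square matrix.
#' @return Named numeric vector of the 13 measurements.
#' @export
haralick13 <- function(cm) {
  p <- if (inherits(cm, "nm_glcm")) cm$matrix else cm
  G <- nrow(p)
  stopif(abs(sum(p) - 1) > 1e-8, "co-occurrence matrix must be normalized")
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  pxm <- rowSums(p); pym <- colSums(p)
  mux <- sum(seq_len(G) * pxm); muy <- sum(seq_len(G) * pym)
  sdx <- sqrt(sum((seq_len(G) - mux)^2 * pxm))
  sdy <- sqrt(sum((seq_len(G) - muy)^2 * pym))

  asm <- sum(p^2)
  contrast <- sum(p * (i - j)^2)
  flagged <- sdx < 1e-12 || sdy < 1e-12
  correlation <- if (flagged) 0 else
    (sum(i * j * p) - mux * muy) / (sdx * sdy)
  ssq_var <- sum(p * (i - mux)^2)
  idm <- sum(p / (1 + (i - j)^2))

  ## p_{x+y}(k), k = 2..2G and p_{x-y}(k), k = 0..G-1
  pxy_sum <- vapply(2:(2 * G), function(k) sum(p[i + j == k]), numeric(1))
  pxy_diff <- vapply(0:(G - 1), function(k) sum(p[abs(i - j) == k]),
                     numeric(1))
  ks <- 2:(2 * G); kd <- 0:(G - 1)
  sum_avg <- sum(ks * pxy_sum)
  sum_var <- sum((ks - sum_avg)^2 * pxy_sum)
  sum_ent <- entropy_bits(pxy_sum)
  ent <- entropy_bits(as.numeric(p))
  mu_d <- sum(kd * pxy_diff)
  diff_var <- sum((kd - mu_d)^2 * pxy_diff)
  diff_ent <- entropy_bits(pxy_diff)

  hx <- entropy_bits(pxm); hy <- entropy_bits(pym)
  pp <- outer(pxm, pym)
  nz <- p > 0 & pp > 0
  hxy1 <- -sum(p[nz] * log2(pp[nz]))
  nz2 <- pp > 0
  hxy2 <- -sum(pp[nz2] * log2(pp[nz2]))
  imc1 <- if (max(hx, hy) < 1e-12) 0 else (ent - hxy1) / max(hx, hy)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))

  out <- c(asm, contrast, correlation, ssq_var, idm, sum_avg, sum_var,
           sum_ent, ent, diff_var, diff_ent, imc1, imc2)
  names(out) <- haralick_names
  attr(out, "degenerate") <- flagged
  out
}

## per-nucleus Haralick matrix over a patch's nuclei
haralick_matrix <- function(nuclei, config) {
  t(vapply(nuclei, function(nuc)
    as.numeric(haralick13(glcm(nuc, config$glcm_levels, config$offsets))),
    numeric(13)))
}

#' Variance of nuclear contrast across a patch
#'
#' Per-nucleus contrast is the Haralick contrast of that nucleus's GLCM;
#' the feature is the population variance of these values over the patch's
#' interior nuclei (`texture.contrast.variance`).
#'
#' @param nuclei List of `nm_nucleus` records with intensities.
#' @param config [nm_config()].
#' @return Scalar, or `NA` if the patch has too few nuclei.
#' @export
contrast_variance <- function(nuclei, config = nm_config()) {
  keep <- Filter(function(x) !x$border, nuclei)
  if (length(keep) < config$min_nuclei) return(NA_real_)
  vals <- vapply(keep, function(nuc)
    haralick13(glcm(nuc, config$glcm_levels, config$offsets))[["contrast"]],
    numeric(1))
  pop_var(vals)
}

#' Patch-level texture feature block
#'
#' [aggregate_first_order()] over each of the 13 per-nucleus Haralick
#' measurements of the patch's interior nuclei; names
#' `texture.<measurement>.<stat>`.
#'
#' @inheritParams contrast_variance
#' @return Named feature vector or `NULL` when the patch is skipped.
#' @export
patch_texture_block <- function(nuclei, config = nm_config()) {
  keep <- Filter(function(x) !x$border, nuclei)
  if (length(keep) < config$min_nuclei) return(NULL)
  hm <- haralick_matrix(keep, config)
  colnames(hm) <- haralick_names
  aggregate_block(hm, "texture")
}
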