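#' Per-nucleus shape descriptors
#'
#' Size, shape and orientation descriptors of one segmented nucleus.
#' Axis lengths and orientation come from the eigen-decomposition of the
#' pixel-coordinate covariance (ellipse-of-inertia convention: axis length
#' = 4 sqrt(eigenvalue)); the perimeter is weighted boundary-step counting
#' along the traced contour (1 per lateral step, sqrt(2) per diagonal);
#' Hu's 7 invariant moments are translation/rotation/scale invariant; the
#' Fourier descriptors are the magnitudes of harmonics 2..K+1 of the
#' complex contour sequence, normalized by the first harmonic magnitude
#' (translation/rotation/scale/start-point invariant).
#'
#' Orientation is the major-axis angle in degrees in [0, 180), measured
#' from the +col axis toward the +row axis.
#'
#' @param nucleus An `nm_nucleus` record from [extract_nuclei()].
#' @param n_fourier Number of Fourier descriptor magnitudes K (default 10).
#' @return Named numeric vector: `area`, `perimeter`, `major_axis_len`,
#'   `minor_axis_len`, `eccentricity`, `length_width_ratio`,
#'   `orientation_theta`, `circularity`, `hu1`..`hu7`, `fd1`..`fdK`.
#' @export
shape_features <- function(nucleus, n_fourier = 10) {
  px <- nucleus$pixels
  n <- nrow(px)
  r <- px[, 1]; cc <- px[, 2]

  ## ellipse of inertia from population covariance of pixel coordinates
  mr <- mean(r); mc <- mean(cc)
  crr <- mean((r - mr)^2); ccc <- mean((cc - mc)^2)
  crc <- mean((r - mr) * (cc - mc))
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc; l2 <- max(0, tr / 2 - disc)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  flagged <- FALSE
  if (minor < 1) { minor <- 1; flagged <- TRUE }   # 1-px-wide degenerate
  if (major < minor) major <- minor
  ## eigenvector for l1 in (col, row) space; angle from +col axis
  theta <- if (abs(l1 - ccc) < 1e-12 && abs(crc) < 1e-12) 0
           else atan2(l1 - ccc, crc)
  theta_deg <- (theta * 180 / pi) %% 180

  per <- contour_perimeter(nucleus$contour)
  circ <- 4 * pi * n / per^2

  hu <- hu_moments(r, cc)
  fd <- fourier_descriptors(nucleus$contour, n_fourier)

  out <- c(area = as.numeric(n), perimeter = per,
           major_axis_len = major, minor_axis_len = minor,
           eccentricity = sqrt(max(0, 1 - (minor / major)^2)),
           length_width_ratio = major / minor,
           orientation_theta = theta_deg, circularity = circ,
           hu, fd)
  attr(out, "degenerate") <- flagged
  out
}

## weighted steps around the closed contour
contour_perimeter <- function(contour) {
  m <- nrow(contour)
  if (m == 1L) return(1)
  d <- contour - contour[c(2:m, 1L), , drop = FALSE]
  steps <- pmax(abs(d[, 1]), abs(d[, 2]))
  diag <- abs(d[, 1]) == 1 & abs(d[, 2]) == 1
  sum(ifelse(diag, sqrt(2), steps))
}

## Hu's seven invariant moments from 0-based pixel coordinates.
hu_moments <- function(r, cc) {
  x <- cc - mean(cc); y <- r - mean(r)
  n <- length(x)
  mu <- function(p, q) sum(x^p * y^q)
  eta <- function(p, q) mu(p, q) / n^(1 + (p + q) / 2)
  e20 <- eta(2, 0); e02 <- eta(0, 2); e11 <- eta(1, 1)
  e30 <- eta(3, 0); e03 <- eta(0, 3); e21 <- eta(2, 1); e12 <- eta(1, 2)
  h1 <- e20 + e02
  h2 <- (e20 - e02)^2 + 4 * e11^2
  h3 <- (e30 - 3 * e12)^2 + (3 * e21 - e03)^2
  h4 <- (e30 + e12)^2 + (e21 + e03)^2
  h5 <- (e30 - 3 * e12) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) +
        (3 * e21 - e03) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  h6 <- (e20 - e02) * ((e30 + e12)^2 - (e21 + e03)^2) +
        4 * e11 * (e30 + e12) * (e21 + e03)
  h7 <- (3 * e21 - e03) * (e30 + e12) *
          ((e30 + e12)^2 - 3 * (e21 + e03)^2) -
        (e30 - 3 * e12) * (e21 + e03) *
          (3 * (e30 + e12)^2 - (e21 + e03)^2)
  c(hu1 = h1, hu2 = h2, hu3 = h3, hu4 = h4, hu5 = h5, hu6 = h6, hu7 = h7)
}

## Magnitudes of contour Fourier harmonics 2..K+1 over harmonic 1.
fourier_descriptors <- function(contour, K) {
  nm <- paste0("fd", seq_len(K))
  m <- nrow(contour)
  if (m < 3L) {
    out <- rep(0, K); names(out) <- nm
    return(out)
  }
  z <- complex(real = contour[, 2], imaginary = contour[, 1])
  f <- fft(z) / m
  mags <- Mod(f[-1])                   # drop DC (translation)
  if (mags[1] < 1e-12) {
    out <- rep(0, K); names(out) <- nm
    return(out)
  }
  idx <- seq(2L, length.out = K)
  vals <- ifelse(idx <= length(mags), mags[pmin(idx, length(mags))], 0)
  out <- vals / mags[1]
  names(out) <- nm
  out
}

#' Patch-level shape feature block
#'
#' Applies [aggregate_first_order()] to every shape descriptor across the
#' patch's interior (non-border) nuclei; names are
#' `shape.<descriptor>.<stat>`.
#'
#' @param nuclei List of `nm_nucleus` records.
#' @param config An [nm_config()] list.
#' @return Named numeric feature vector, or `NULL` when fewer than
#'   `config$min_nuclei` interior nuclei are present (patch skipped).
#' @export
patch_shape_block <- function(nuclei, config = nm_config()) {
  desc <- descriptor_matrix(nuclei, config, interior_only = TRUE)
  if (is.null(desc)) return(NULL)
  aggregate_block(desc, "shape")
}

## Shape descriptor matrix (rows = nuclei). interior_only drops
## border-touching nuclei, whose truncated contours bias shape features.
descriptor_matrix <- function(nuclei, config, interior_only = TRUE) {
  keep <- if (interior_only)
    Filter(function(x) !x$border, nuclei) else nuclei
  if (length(keep) < config$min_nuclei) return(NULL)
  t(vapply(keep, shape_features, n_fourier = config$n_fourier,
           FUN.VALUE = numeric(8 + 7 + config$n_fourier)))
}
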