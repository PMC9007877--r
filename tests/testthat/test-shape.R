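test_that("a rasterized disk is round: low eccentricity, high circularity", {
  r <- one_nucleus(disk_mask(40, 40, 19, 19, 10))
  f <- shape_features(r)
  expect_lt(f[["eccentricity"]], 0.05)
  expect_gt(f[["circularity"]], 0.9)
  expect_lte(f[["circularity"]], 1.1)
  expect_equal(f[["area"]], sum(disk_mask(40, 40, 19, 19, 10) > 0))
})

test_that("rectangle axes match the coordinate-covariance oracle", {
  ## 20 columns x 10 rows, so the major axis lies along +col (theta ~ 0)
  m <- rect_mask(40, 60, 10, 15, 10, 20)
  nuc <- one_nucleus(m)
  f <- shape_features(nuc)
  expect_lt(min(f[["orientation_theta"]], 180 - f[["orientation_theta"]]),
            1e-6)
  ## oracle: eigen-decomposition of the raw pixel covariance
  C <- cov(nuc$pixels) * (nrow(nuc$pixels) - 1) / nrow(nuc$pixels)
  ev <- eigen(C, symmetric = TRUE)$values
  expect_equal(f[["major_axis_len"]], 4 * sqrt(max(ev)), tolerance = 1e-10)
  expect_equal(f[["minor_axis_len"]], 4 * sqrt(min(ev)), tolerance = 1e-10)
  expect_equal(f[["length_width_ratio"]],
               f[["major_axis_len"]] / f[["minor_axis_len"]])
})

test_that("axis lengths agree with the eigen oracle on generated nuclei", {
  p <- generate_patch(small_archetype(density_mean = 60), 512, seed = 31)
  recs <- Filter(function(x) !x$border, extract_nuclei(p$label_mask))
  for (nuc in recs[1:min(10, length(recs))]) {
    f <- shape_features(nuc)
    C <- cov(nuc$pixels) * (nrow(nuc$pixels) - 1) / nrow(nuc$pixels)
    ev <- eigen(C, symmetric = TRUE)$values
    expect_equal(f[["major_axis_len"]], 4 * sqrt(max(ev)), tolerance = 1e-8)
  }
})

test_that("Hu moments and Fourier magnitudes are translation invariant", {
  m1 <- disk_mask(60, 60, 20, 20, 8)
  m1[12:14, 25:30] <- 1L                        # asymmetric appendage
  base <- shape_features(one_nucleus(m1))
  m2 <- matrix(0L, 60, 60)
  m2[18:60, 6:60] <- m1[1:43, 1:55]             # translate by (+17, +5)
  shifted <- shape_features(one_nucleus(m2))
  idx <- c(paste0("hu", 1:7), paste0("fd", 1:10))
  expect_equal(base[idx], shifted[idx], tolerance = 1e-9)
})

test_that("90-degree rotation: area exact, invariants stable, theta shifts", {
  p <- generate_patch(small_archetype(), 512, seed = 17)
  m <- p$label_mask
  mr <- t(m)[ncol(m):1, ]                       # rotate 90 degrees
  r1 <- Filter(function(x) !x$border, extract_nuclei(m))
  r2 <- Filter(function(x) !x$border, extract_nuclei(mr))
  expect_gte(length(r1), 3)
  f1 <- lapply(r1, shape_features)
  f2 <- lapply(r2, shape_features)
  key <- function(f) round(f[["area"]])
  o1 <- order(vapply(f1, key, numeric(1)), vapply(f1, function(f) f[["hu1"]], numeric(1)))
  o2 <- order(vapply(f2, key, numeric(1)), vapply(f2, function(f) f[["hu1"]], numeric(1)))
  expect_equal(length(r1), length(r2))
  for (i in seq_along(o1)) {
    a <- f1[[o1[i]]]; b <- f2[[o2[i]]]
    expect_equal(a[["area"]], b[["area"]])
    expect_equal(a[paste0("hu", 1:7)], b[paste0("hu", 1:7)],
                 tolerance = 1e-6)
    expect_equal(a[paste0("fd", 1:10)], b[paste0("fd", 1:10)],
                 tolerance = 1e-6)
    dtheta <- abs((a[["orientation_theta"]] + 90) %% 180 -
                  b[["orientation_theta"]])
    expect_lt(min(dtheta, 180 - dtheta), 1.0)
  }
})

test_that("isoperimetric bound holds for the weighted perimeter", {
  areas_ok <- TRUE
  count <- 0
  for (seed in 41:50) {
    p <- generate_patch(small_archetype(density_mean = 120), 512,
                        seed = seed)
    recs <- Filter(function(x) !x$border, extract_nuclei(p$label_mask))
    for (nuc in recs) {
      f <- shape_features(nuc)
      count <- count + 1
      if (4 * pi * f[["area"]] > f[["perimeter"]]^2 * 1.1)
        areas_ok <- FALSE
    }
  }
  expect_gt(count, 200)
  expect_true(areas_ok)
})

test_that("first-order statistics match hand-computed values", {
  s <- aggregate_first_order(c(1, 2, 3, 4))
  expect_equal(s[["mean"]], 2.5)
  expect_equal(s[["median"]], 2.5)
  expect_equal(s[["range"]], 3)
  expect_equal(s[["variance"]], mean((c(1, 2, 3, 4) - 2.5)^2))
  expect_equal(s[["sd"]]^2, s[["variance"]])

  s0 <- aggregate_first_order(c(7, 7, 7))
  expect_equal(s0[["variance"]], 0)
  expect_equal(s0[["skewness"]], 0)
  expect_equal(s0[["kurtosis"]], 0)

  ## skewness oracle: standardized third moment computed directly
  x <- c(1, 2, 3, 4, 10)
  m <- mean(x)
  sk <- mean((x - m)^3) / mean((x - m)^2)^1.5
  expect_gt(sk, 0)
  expect_equal(aggregate_first_order(x)[["skewness"]], sk)

  for (i in 1:10) {
    x <- rnorm(20)
    s <- aggregate_first_order(x)
    expect_equal(s[["sd"]]^2, s[["variance"]], tolerance = 1e-12)
    expect_true(s[["min"]] <= s[["median"]] && s[["median"]] <= s[["max"]])
    expect_equal(s[["range"]], s[["max"]] - s[["min"]])
  }
})

test_that("patch shape block has the configured width and fixed names", {
  p <- generate_patch(small_archetype(), 512, seed = 55)
  recs <- extract_nuclei(p$label_mask)
  blk <- patch_shape_block(recs)
  cfg <- nm_config()
  n_desc <- 8 + 7 + cfg$n_fourier
  expect_length(blk, n_desc * 10)
  expect_true(all(grepl("^shape\\.", names(blk))))
  expect_contains(names(blk),
                  c("shape.area.mean", "shape.perimeter.mean",
                    "shape.major_axis_len.mean", "shape.hu7.kurtosis",
                    "shape.fd10.variance"))
})

test_that("identical nuclei give zero shape variance across the patch", {
  m <- matrix(0L, 60, 120)
  for (k in 0:4) {
    sub <- disk_mask(60, 20, 29, 9, 6, label = k + 1L)
    m[, (k * 20 + 1):(k * 20 + 20)][sub > 0] <- k + 1L
  }
  m2 <- cbind(m, m[, 1:60] * 0L)    # padding so none touch the border
  recs <- extract_nuclei(m2)
  blk <- patch_shape_block(recs)
  expect_equal(blk[["shape.area.variance"]], 0)
  expect_equal(blk[["shape.perimeter.variance"]], 0)
})

test_that("doubling linear scale quadruples mean nuclear area", {
  a1 <- small_archetype(density_mean = 40, area_log_mean = log(200))
  a2 <- small_archetype(density_mean = 40,
                        area_log_mean = log(200) + log(4))
  m1 <- mean(unlist(lapply(1:20, function(s)
    generate_patch(a1, 512, seed = 700 + s,
                   render_image = FALSE)$truth$area_px)))
  m2 <- mean(unlist(lapply(1:20, function(s)
    generate_patch(a2, 512, seed = 700 + s,
                   render_image = FALSE)$truth$area_px)))
  expect_gt(m2 / m1, 3.6)
  expect_lt(m2 / m1, 4.4)
})
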