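test_that("small components are dropped and counted", {
  m <- rect_mask(40, 40, 2, 2, 5, 5, label = 1L)      # 25 px
  m[rect_mask(40, 40, 20, 20, 3, 3, label = 1L) == 1L] <- 2L  # 9 px
  recs <- extract_nuclei(m, min_nucleus_area = 10)
  expect_length(recs, 1L)
  expect_equal(nrow(recs[[1]]$pixels), 25L)
  expect_equal(attr(recs, "n_dropped"), 1L)
  expect_equal(attr(recs, "dropped_area"), 9L)
  expect_length(extract_nuclei(matrix(0L, 10, 10)), 0L)
})

test_that("centroid of a filled square is its exact center", {
  m <- rect_mask(30, 30, 7, 11, 5, 5)
  r <- one_nucleus(m)
  expect_equal(unname(r$centroid), c(7 + 2, 11 + 2))   # mean of 0-based coords
  expect_equal(unname(r$bbox), c(7, 11, 12, 16))
  expect_false(r$border)
})

test_that("border-touching nuclei are flagged", {
  m <- rect_mask(20, 20, 0, 5, 4, 4)
  expect_true(one_nucleus(m)$border)
  m2 <- rect_mask(20, 20, 5, 16, 4, 4)                 # touches last col
  expect_true(one_nucleus(m2)$border)
})

test_that("pixel accounting: areas + dropped + background = total", {
  p <- generate_patch(small_archetype(), 512, seed = 21)
  recs <- extract_nuclei(p$label_mask, min_nucleus_area = 50)
  areas <- sum(vapply(recs, function(x) nrow(x$pixels), integer(1)))
  total <- areas + attr(recs, "dropped_area") + sum(p$label_mask == 0L)
  expect_equal(total, length(p$label_mask))
})

test_that("extraction is invariant to label permutation", {
  p <- generate_patch(small_archetype(), 512, seed = 3)
  m <- p$label_mask
  n <- max(m)
  expect_gte(n, 2)
  perm <- sample(n)
  m2 <- m
  m2[m > 0] <- perm[m[m > 0]]
  r1 <- extract_nuclei(m)
  r2 <- extract_nuclei(m2)
  key <- function(recs) sort(vapply(recs, function(x)
    paste(x$pixels[order(x$pixels[, 1], x$pixels[, 2]), ], collapse = ","),
    character(1)))
  expect_identical(key(r1), key(r2))
})

test_that("contours are closed 8-connected boundaries within the nucleus", {
  p <- generate_patch(small_archetype(), 512, seed = 8)
  recs <- extract_nuclei(p$label_mask)
  for (r in recs[1:min(5, length(recs))]) {
    cont <- r$contour
    pixset <- paste(r$pixels[, 1], r$pixels[, 2])
    expect_true(all(paste(cont[, 1], cont[, 2]) %in% pixset))
    d <- cont - cont[c(2:nrow(cont), 1), ]
    expect_true(all(pmax(abs(d[, 1]), abs(d[, 2])) <= 1))
  }
})

test_that("tiling counts and origins follow the stride arithmetic", {
  img <- matrix(seq_len(200 * 200), 200, 200)
  expect_length(tile_image(img, patch_size = 100), 4L)
  expect_length(tile_image(matrix(0, 150, 100), patch_size = 100), 1L)
  expect_length(tile_image(img, patch_size = 100, stride = 50), 9L)
  expect_error(tile_image(matrix(0, 50, 50), patch_size = 100), "exceeds")

  ## origins reconstruct the parent exactly when stride = patch_size
  tiles <- tile_image(img, patch_size = 100)
  rec <- matrix(0, 200, 200)
  for (t in tiles)
    rec[t$origin[1] + 1:100, t$origin[2] + 1:100] <- t$image
  expect_equal(rec, img)
})

test_that("watershed recovers well-separated synthetic nuclei", {
  a <- small_archetype(density_mean = 40, contrast_sd = 3)
  p <- generate_patch(a, 512, seed = 12)
  skip_if(nrow(p$truth) < 5)
  seg <- watershed_segment(p$image)
  n_true <- nrow(p$truth)
  n_seg <- max(seg)
  expect_gte(n_seg, round(0.8 * n_true))
  expect_lte(n_seg, round(1.2 * n_true))
  ## per-label areas match truth within 15% for matched nuclei
  recs <- extract_nuclei(seg)
  cents <- t(vapply(recs, function(x) x$centroid, numeric(2)))
  ok <- 0
  for (i in seq_len(n_true)) {
    d2 <- (cents[, 1] - p$truth$center_row[i])^2 +
          (cents[, 2] - p$truth$center_col[i])^2
    j <- which.min(d2)
    if (abs(nrow(recs[[j]]$pixels) - p$truth$area_px[i]) <
        0.15 * p$truth$area_px[i]) ok <- ok + 1
  }
  expect_gte(ok / n_true, 0.8)
})

test_that("watershed handles blank and two-blob images", {
  expect_warning(seg <- watershed_segment(matrix(100, 64, 64)), "constant")
  expect_equal(max(seg), 0L)
  img <- matrix(200L, 64, 64)
  img[10:20, 10:20] <- 80L
  img[40:50, 40:50] <- 80L
  expect_equal(max(watershed_segment(img)), 2L)
})

test_that("manifest round-trips and validates file existence", {
  d <- withr::local_tempdir()
  img <- matrix(150L, 32, 32)
  msk <- rect_mask(32, 32, 5, 5, 6, 6)
  ip <- file.path(d, "p1.png"); mp <- file.path(d, "p1_mask.tif")
  write_image(img, ip)
  write_mask(msk, mp)
  entries <- data.frame(patient_id = c("A", "B", "C"),
                        class_label = "stage2",
                        image_path = ip, mask_path = mp,
                        origin_row = 0L, origin_col = 0L,
                        stringsAsFactors = FALSE)
  path <- file.path(d, "manifest.csv")
  write_manifest(entries, path)
  back <- read_manifest(path)
  expect_equal(back, entries)

  entries$mask_path[2] <- file.path(d, "absent.tif")
  write_manifest(entries, path)
  expect_error(read_manifest(path), "patient B")

  write_manifest(entries[0, ], path)
  expect_equal(nrow(read_manifest(path)), 0L)
})

test_that("image and 16-bit mask files round-trip losslessly", {
  d <- withr::local_tempdir()
  img <- matrix(as.integer(sample(0:255, 32 * 32, TRUE)), 32, 32)
  msk <- matrix(as.integer(sample(0:300, 32 * 32, TRUE)), 32, 32)
  write_image(img, file.path(d, "i.png"))
  write_mask(msk, file.path(d, "m.tif"))
  expect_equal(read_image(file.path(d, "i.png")), img)
  expect_equal(read_mask(file.path(d, "m.tif")), msk)
})

test_that("extraction rejects malformed inputs", {
  expect_error(extract_nuclei(matrix(0.5, 4, 4)), "integer")
  expect_error(extract_nuclei(matrix(0L, 4, 4), image = matrix(0, 5, 5)),
               "shape")
})
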