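test_that("triangulation matches brute-force circumcircle enumeration", {
  ## the documented 4-point case: 2 triangles, 5 edges
  xy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 0.9))
  tris <- nucmorph:::delaunay_triangulate(xy)
  expect_equal(nrow(tris), 2L)
  expect_equal(nrow(nucmorph:::triangle_edges(tris)), 5L)
  expect_identical(tri_key(tris), tri_key(brute_delaunay(xy)))

  set.seed(81)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    xy <- matrix(runif(2 * n, 0, 100), n, 2)
    tris <- nucmorph:::delaunay_triangulate(xy)
    expect_identical(tri_key(tris), tri_key(brute_delaunay(xy)))
    ## Euler: triangles = 2n - 2 - hull points (general position)
    h <- length(chull(xy))
    expect_equal(nrow(tris), 2 * n - 2 - h)
  }
})

test_that("delaunay features: equilateral triangle and outlier behavior", {
  ## equilateral needs a 4th point for features; use the documented stats
  ## on edge lengths directly from a unit square
  sq <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  f <- delaunay_features(sq)
  expect_equal(f[["graph.delaunay.edge_len.min"]], 1)
  expect_equal(f[["graph.delaunay.tri_area.mean"]], 0.5)

  set.seed(82)
  base <- matrix(runif(20, 0, 10), 10, 2)
  f1 <- delaunay_features(base)
  f2 <- delaunay_features(rbind(base, c(100, 100)))
  expect_gt(f2[["graph.delaunay.edge_len.variance"]],
            f1[["graph.delaunay.edge_len.variance"]])

  expect_true(all(is.na(delaunay_features(rbind(c(0, 0), c(1, 1),
                                                c(2, 2), c(3, 3))))))
  expect_true(all(is.na(delaunay_features(rbind(c(0, 0), c(1, 1))))))
})

test_that("graph features are invariant to node input order", {
  set.seed(83)
  pts <- matrix(runif(24, 0, 500), 12, 2)
  perm <- sample(12)
  expect_equal(delaunay_features(pts), delaunay_features(pts[perm, ]))
  g1 <- build_ccg(pts, 1000)
  g2 <- build_ccg(pts[perm, ], 1000)
  expect_equal(sort(table(g1$clusters)), sort(table(g2$clusters)),
               ignore_attr = TRUE)
  expect_equal(nrow(g1$edges), nrow(g2$edges))
})

test_that("CCG clustering: near triplets link, far triplets separate", {
  tight <- rbind(c(0, 0), c(0, 30), c(30, 0))
  g <- build_ccg(tight, 1000)
  expect_equal(max(g$clusters), 1L)

  two <- rbind(tight, tight + 700)
  g2 <- build_ccg(two, 1000)
  expect_equal(max(g2$clusters), 2L)
  expect_equal(sort(as.integer(table(g2$clusters))), c(3L, 3L))
})

test_that("CCG determinism, alpha monotonicity, and degenerate alpha = 0", {
  set.seed(84)
  pts <- matrix(runif(40, 0, 1000), 20, 2)
  g1 <- build_ccg(pts, 1000, alpha = 1, r = 0.1)
  g2 <- build_ccg(pts, 1000, alpha = 1, r = 0.1)
  expect_identical(g1$edges, g2$edges)

  ## normalized spacings exceed 1, so edge count never increases in alpha
  counts <- vapply(c(0.5, 1, 1.5, 2, 3), function(al)
    nrow(build_ccg(pts, 1000, alpha = al, r = 0.1)$edges), numeric(1))
  expect_true(all(diff(counts) <= 0))

  gc <- build_ccg(pts, 1000, alpha = 0, r = 0.5)
  expect_equal(nrow(gc$edges), choose(20, 2))

  gp1 <- build_ccg(pts, 1000, mode = "probabilistic", seed = 4)
  gp2 <- build_ccg(pts, 1000, mode = "probabilistic", seed = 4)
  expect_identical(gp1$edges, gp2$edges)
})

test_that("CCG neighborhood shape statistics follow the cluster oracle", {
  ## two tight pairs far apart; areas {10,10} and {30,30}
  pts <- rbind(c(0, 0), c(0, 20), c(800, 800), c(800, 820))
  g <- build_ccg(pts, 1000)
  expect_equal(max(g$clusters), 2L)
  desc <- cbind(area = c(10, 10, 30, 30), perimeter = c(5, 5, 9, 9),
                major_axis_len = c(4, 4, 8, 8))
  f <- ccg_neighborhood_shape(g, desc)
  ## population variance of the cluster means {10, 30} is 100
  expect_equal(f[["graph.ccg.shape.area_cluster_mean.variance"]], 100)
  expect_equal(f[["graph.ccg.shape.area_cluster_var.mean"]], 0)

  desc_same <- cbind(area = rep(7, 4), perimeter = rep(5, 4),
                     major_axis_len = rep(4, 4))
  f2 <- ccg_neighborhood_shape(g, desc_same)
  expect_equal(f2[["graph.ccg.shape.area_cluster_mean.variance"]], 0)
  expect_equal(f2[["graph.ccg.shape.area_cluster_var.max"]], 0)
})

test_that("orientation entropy: zero, maximum, and shift invariance", {
  pts <- matrix(runif(36, 0, 200), 18, 2)
  g <- build_ccg(pts, 1000, alpha = 0, r = 0.5)   # one cluster

  f_const <- cgt_orientation(g, rep(45, 18), pts)
  expect_equal(f_const[["graph.cgt.orientation_entropy"]], 0)
  expect_equal(f_const[["graph.cgt.disorder.mean"]], 0)   # coherence 1

  th <- seq(5, 175, by = 10)                      # one per 10-degree bin
  f_unif <- cgt_orientation(g, th, pts, n_bins = 18)
  expect_equal(f_unif[["graph.cgt.orientation_entropy"]], log2(18))

  f_shift <- cgt_orientation(g, (th + 90) %% 180, pts, n_bins = 18)
  expect_equal(f_shift[["graph.cgt.orientation_entropy"]],
               f_unif[["graph.cgt.orientation_entropy"]])
  ## coherence (disorder) invariant under any global rotation
  f_rot <- cgt_orientation(g, (th + 37.3) %% 180, pts, n_bins = 18)
  expect_equal(f_rot[["graph.cgt.disorder.mean"]],
               f_unif[["graph.cgt.disorder.mean"]], tolerance = 1e-9)
})

test_that("orientation concentration sweep raises entropy monotonically", {
  kappas <- c(12, 3, 0.5)
  ents <- vapply(seq_along(kappas), function(k) {
    a <- small_archetype(orientation_kappa = kappas[k])
    mean(vapply(1:25, function(s) {
      tr <- generate_patch(a, 512, seed = 1500 + 100 * k + s,
                           render_image = FALSE)$truth
      h <- tabulate(pmin(18, floor(tr$theta_deg / 10) + 1L), 18)
      -sum((h[h > 0] / sum(h)) * log2(h[h > 0] / sum(h)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ents) > 0))
})

test_that("run-length features follow the enumerated chain cases", {
  ## chain of 5 nodes along a line; Delaunay degenerate, so feed edges
  chain <- cbind(1:4, 2:5)
  lens <- rep(1, 4)
  f_same <- run_length_features(chain, lens, rep(1L, 5), 5, B = 2,
                                Lmax = 10)
  rlm <- attr(f_same, "rlm")
  expect_equal(sum(rlm), 1)                      # single run
  expect_equal(rlm[1, 5], 1)                     # of length 5
  expect_equal(f_same[["graph.rle.run_percentage"]], 1 / 5)
  expect_equal(f_same[["graph.rle.long_run_emphasis"]], 25)

  f_alt <- run_length_features(chain, lens, c(1L, 2L, 1L, 2L, 1L), 5,
                               B = 2, Lmax = 10)
  rlm2 <- attr(f_alt, "rlm")
  expect_equal(sum(rlm2), 5)                     # five singleton runs
  expect_equal(sum(rlm2[, 1]), 5)
  expect_equal(f_alt[["graph.rle.run_percentage"]], 1)

  ## conservation on random graphs: counts sum = number of runs <= nodes
  set.seed(85)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    pts <- matrix(runif(2 * n, 0, 100), n, 2)
    tris <- nucmorph:::delaunay_triangulate(pts)
    edges <- nucmorph:::triangle_edges(tris)
    lens <- sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                          pts[edges[, 2], , drop = FALSE])^2))
    bins <- sample(1:3, n, TRUE)
    f <- run_length_features(edges, lens, bins, n, B = 3)
    rlm <- attr(f, "rlm")
    expect_equal(sum(rlm), f[["graph.rle.run_percentage"]] * n)
    expect_lte(sum(rlm), n)
  }
})

test_that("cCCM pair enumeration matches the hand-computed case", {
  ## one cluster of 3 nuclei with bins {1, 1, 2}
  pts <- rbind(c(0, 0), c(0, 10), c(10, 0))
  g <- build_ccg(pts, 1000)
  expect_equal(max(g$clusters), 1L)
  f <- ccm_diversity(g, c(1L, 1L, 2L), M = 2, prefix = "d")
  cm <- attr(f, "ccm")
  expect_equal(cm[1, 1], 1 / 3)
  expect_equal(cm[1, 2], 1 / 3)
  expect_equal(cm[2, 1], 1 / 3)
  expect_equal(sum(cm), 1)
  expect_equal(cm, t(cm))

  f_one <- ccm_diversity(g, c(1L, 1L, 1L), M = 2, prefix = "d")
  expect_equal(f_one[["d.entropy"]], 0)
  expect_equal(attr(f_one, "ccm")[1, 1], 1)

  ## all singleton clusters -> missing-flagged
  far <- rbind(c(0, 0), c(500, 500), c(900, 100))
  gf <- build_ccg(far, 1000)
  expect_equal(max(gf$clusters), 3L)
  expect_true(all(is.na(ccm_diversity(gf, c(1L, 2L, 1L), M = 2,
                                      prefix = "d"))))
})

test_that("full graph block emits all families on a generated patch", {
  p <- generate_patch(small_archetype(), 512, seed = 86)
  recs <- extract_nuclei(p$label_mask, p$image)
  blk <- patch_graph_block(recs, 512)
  expect_true(all(c("graph.delaunay.edge_len.mean",
                    "graph.ccg.shape.area_cluster_mean.mean",
                    "graph.cgt.orientation_entropy",
                    "graph.rle.short_run_emphasis",
                    "diversity.area.entropy",
                    "diversity.contrast.variance") %in% names(blk)))
})
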