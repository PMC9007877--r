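## ---- Delaunay triangulation (Bowyer-Watson) --------------------------------

## pts: n x 2 (x, y). Returns matrix of triangle index triples (0 rows when
## degenerate). Duplicate points must be removed by the caller.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(matrix(integer(0), 0, 3))
  ## Super-triangle enclosing all points. It sits 1e4 spans away so that
  ## even near-collinear hull slivers (circumradius up to ~1e4 spans) are
  ## retained; triples flatter than that are numerically collinear at
  ## patch scale and are dropped by the degeneracy guard instead.
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1) * 1e4
  sup <- rbind(c(cx - span, cy - span / 2),
               c(cx + span, cy - span / 2),
               c(cx, cy + span))
  P <- rbind(pts, sup)
  s1 <- n + 1L; s2 <- n + 2L; s3 <- n + 3L
  tris <- list(c(s1, s2, s3))
  circ <- list(circumcircle(P[s1, ], P[s2, ], P[s3, ]))

  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- which(vapply(circ, function(cc)
      !is.null(cc) && (p[1] - cc[1])^2 + (p[2] - cc[2])^2 <= cc[3] * (1 + 1e-12),
      logical(1)))
    if (!length(bad)) next   # numerically degenerate; point skipped
    ## boundary polygon: edges of bad triangles appearing exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tt)
      rbind(sort(c(tt[1], tt[2])), sort(c(tt[2], tt[3])),
            sort(c(tt[1], tt[3])))))
    key <- paste(edges[, 1], edges[, 2])
    keep <- !(key %in% key[duplicated(key)])
    boundary <- edges[keep, , drop = FALSE]
    tris <- tris[-bad]; circ <- circ[-bad]
    for (e in seq_len(nrow(boundary))) {
      tt <- c(boundary[e, ], ip)
      cc <- circumcircle(P[tt[1], ], P[tt[2], ], P[tt[3], ])
      if (is.null(cc)) next
      tris[[length(tris) + 1L]] <- tt
      circ[[length(circ) + 1L]] <- cc
    }
  }
  out <- do.call(rbind, tris)
  if (is.null(out)) return(matrix(integer(0), 0, 3))
  out <- out[apply(out, 1, function(tt) all(tt <= n)), , drop = FALSE]
  out
}

## circumcenter (x, y) and squared radius; NULL for (near-)collinear input
circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(NULL)
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

triangle_edges <- function(tris) {
  if (!nrow(tris)) return(matrix(integer(0), 0, 2))
  e <- rbind(tris[, c(1, 2), drop = FALSE], tris[, c(2, 3), drop = FALSE],
             tris[, c(1, 3), drop = FALSE])
  e <- t(apply(e, 1, sort))
  unique(e)
}

#' Delaunay architecture features
#'
#' Triangulates the nucleus centroids and aggregates first-order statistics
#' of edge lengths, triangle areas, and node degrees
#' (`graph.delaunay.<quantity>.<stat>`). Exact duplicate centroids are
#' merged; with fewer than 4 distinct points, or a collinear set, the
#' features are flagged missing (NA).
#'
#' @param centroids n x 2 matrix (row, col) of nucleus centroids.
#' @return Named numeric vector (30 values).
#' @export
delaunay_features <- function(centroids) {
  nm <- paste("graph.delaunay",
              rep(c("edge_len", "tri_area", "degree"), each = 10),
              first_order_names, sep = ".")
  missing_out <- structure(rep(NA_real_, 30), names = nm)
  pts <- unique(round(centroids, 9))
  if (nrow(pts) < 4L) return(missing_out)
  xy <- cbind(pts[, 2], pts[, 1])            # (x = col, y = row)
  tris <- delaunay_triangulate(xy)
  if (!nrow(tris)) return(missing_out)
  edges <- triangle_edges(tris)
  el <- sqrt(rowSums((xy[edges[, 1], , drop = FALSE] -
                      xy[edges[, 2], , drop = FALSE])^2))
  ta <- apply(tris, 1, function(tt) {
    a <- xy[tt[1], ]; b <- xy[tt[2], ]; cc <- xy[tt[3], ]
    abs((b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])) / 2
  })
  deg <- tabulate(as.integer(edges), nbins = nrow(xy))
  out <- c(aggregate_first_order(el), aggregate_first_order(ta),
           aggregate_first_order(deg))
  names(out) <- nm
  out
}

## ---- Cell cluster graph ----------------------------------------------------

#' Build a cell cluster graph (CCG)
#'
#' Inter-nucleus pixel distances are scaled by the patch diagonal and
#' expressed as a percent of it, so typical neighbor spacings exceed 1 and
#' the decaying link weight `d^(-alpha)` falls in (0, 1). In deterministic
#' mode an edge exists iff `d^(-alpha) >= r` (equivalently
#' `d <= r^(-1/alpha)`); in probabilistic mode an edge is drawn with
#' probability `min(1, d^(-alpha))` under `seed`. Clusters are the
#' connected components.
#'
#' With `alpha = 0` every pair satisfies the deterministic rule: the graph
#' is complete (documented degenerate case).
#'
#' @param centroids n x 2 (row, col) matrix.
#' @param patch_size Patch side in pixels (sets the diagonal scale).
#' @param alpha Decay exponent (>= 0), default 1.
#' @param r Link threshold in (0, 1), default 0.1.
#' @param mode `"deterministic"` (default) or `"probabilistic"`.
#' @param seed Seed for probabilistic mode.
#' @return Object of class `nm_ccg`: `edges` (m x 2), `lengths` (percent
#'   of diagonal), `clusters` (component id per node), `n`, parameters.
#' @export
build_ccg <- function(centroids, patch_size, alpha = 1, r = 0.1,
                      mode = c("deterministic", "probabilistic"),
                      seed = NULL) {
  mode <- match.arg(mode)
  stopif(alpha < 0, "alpha must be >= 0")
  stopif(r <= 0 || r >= 1, "r must be in (0, 1)")
  n <- nrow(centroids)
  stopif(n < 1, "need at least one point")
  diag_len <- patch_size * sqrt(2)
  if (n == 1L) {
    return(structure(list(edges = matrix(integer(0), 0, 2),
                          lengths = numeric(0), clusters = 1L, n = 1L,
                          alpha = alpha, r = r, mode = mode),
                     class = "nm_ccg"))
  }
  D <- as.matrix(dist(centroids)) / diag_len * 100
  W <- D^(-alpha)
  W[!is.finite(W)] <- Inf                      # coincident centroids link
  if (mode == "deterministic") {
    adj <- W >= r
  } else {
    stopif(is.null(seed), "probabilistic mode requires a seed")
    adj <- with_seed(seed, {
      U <- matrix(runif(n * n), n, n)
      U <- pmin(U, t(U))                       # symmetric draw
      U < pmin(1, W)
    })
  }
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- cbind(idx[, 1], idx[, 2])
  clusters <- connected_components(n, edges)
  structure(list(edges = edges, lengths = D[idx], clusters = clusters,
                 n = n, alpha = alpha, r = r, mode = mode),
            class = "nm_ccg")
}

connected_components <- function(n, edges) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (comp[v] == 0L) {
        comp[v] <- cid
        queue <- c(queue, v)
      }
    }
  }
  comp
}

#' @export
print.nm_ccg <- function(x, ...) {
  cat(sprintf("<nm_ccg> %d nodes, %d edges, %d clusters (alpha %.2f, r %.2f, %s)\n",
              x$n, nrow(x$edges), max(x$clusters), x$alpha, x$r, x$mode))
  invisible(x)
}

#' CCG local neighborhood shape features
#'
#' Per-cluster mean and population variance of member nuclei's area,
#' perimeter and major-axis length; the patch feature is first-order
#' statistics over clusters (`graph.ccg.shape.*`). Singleton clusters
#' contribute means only; their variances are excluded.
#'
#' @param ccg `nm_ccg`.
#' @param desc Descriptor matrix from the same patch's nuclei (rows must
#'   align with the CCG nodes).
#' @return Named feature vector (60 values).
#' @export
ccg_neighborhood_shape <- function(ccg, desc) {
  stopif(nrow(desc) != ccg$n, "descriptor rows must match CCG nodes")
  fields <- c("area", "perimeter", "major_axis_len")
  out <- numeric(0)
  for (f in fields) {
    v <- desc[, f]
    cl_mean <- tapply(v, ccg$clusters, mean)
    sizes <- tapply(v, ccg$clusters, length)
    cl_var <- tapply(v, ccg$clusters, pop_var)[sizes > 1]
    s1 <- aggregate_first_order(as.numeric(cl_mean))
    names(s1) <- paste("graph.ccg.shape", paste0(f, "_cluster_mean"),
                       first_order_names, sep = ".")
    s2 <- aggregate_first_order(as.numeric(cl_var))
    names(s2) <- paste("graph.ccg.shape", paste0(f, "_cluster_var"),
                       first_order_names, sep = ".")
    out <- c(out, s1, s2)
  }
  out
}

## ---- Cell graph tensor orientation features --------------------------------

#' Orientation-disorder (cell graph tensor) features
#'
#' For each node the local neighborhood is its CCG cluster (falling back to
#' the `k_fallback` nearest neighbors when the cluster has fewer than 3
#' members). The neighborhood structure tensor of doubled-angle unit
#' vectors (cos 2t, sin 2t) gives coherence (l1 - l2)/(l1 + l2) in [0, 1]
#' and disorder = 1 - coherence. The patch orientation entropy is the
#' Shannon entropy (bits) of the orientation histogram over `n_bins` equal
#' bins on [0, 180).
#'
#' @param ccg `nm_ccg`.
#' @param theta_deg Per-node orientation in degrees [0, 180).
#' @param centroids n x 2 (row, col), used for the nearest-neighbor
#'   fallback.
#' @param n_bins Histogram bins for the entropy (default 18, i.e. 10
#'   degrees).
#' @param k_fallback Neighborhood size when a cluster is too small.
#' @return Named vector: `graph.cgt.orientation_entropy` plus first-order
#'   statistics of per-node disorder (`graph.cgt.disorder.<stat>`).
#' @export
cgt_orientation <- function(ccg, theta_deg, centroids, n_bins = 18,
                            k_fallback = 5) {
  n <- ccg$n
  stopif(length(theta_deg) != n, "theta length must match nodes")
  D <- if (n > 1) as.matrix(dist(centroids)) else matrix(0, 1, 1)
  disorder <- numeric(n)
  for (u in seq_len(n)) {
    nb <- which(ccg$clusters == ccg$clusters[u])
    if (length(nb) < 3L && n >= 2L) {
      k <- min(k_fallback, n - 1L)
      nb <- c(u, setdiff(order(D[u, ]), u)[seq_len(k)])
    }
    th <- theta_deg[nb] * pi / 180
    v1 <- mean(cos(2 * th)); v2 <- mean(sin(2 * th))
    c11 <- mean(cos(2 * th)^2); c12 <- mean(cos(2 * th) * sin(2 * th))
    c22 <- mean(sin(2 * th)^2)
    ## trace = 1, so l1 - l2 = sqrt((c11 - c22)^2 + 4 c12^2)
    disorder[u] <- 1 - sqrt((c11 - c22)^2 + 4 * c12^2)
  }
  h <- tabulate(pmin(n_bins, floor(theta_deg / 180 * n_bins) + 1L),
                nbins = n_bins)
  ent <- entropy_bits(h / sum(h))
  stats <- aggregate_first_order(disorder)
  names(stats) <- paste("graph.cgt.disorder", first_order_names, sep = ".")
  c(graph.cgt.orientation_entropy = ent, stats)
}

## ---- Cell run-length features ----------------------------------------------

#' Cell run-length graph features
#'
#' Nodes carry a discretized attribute (by default equal-frequency area
#' bins). Runs are maximal paths of consecutive same-bin nodes traversed
#' greedily from each unvisited node along shortest available graph edges,
#' marking nodes visited. Classical run-length statistics of the resulting
#' bin x length matrix are returned: short-run emphasis, long-run emphasis,
#' bin nonuniformity, run-length nonuniformity, and run percentage
#' (`graph.rle.*`).
#'
#' @param edges m x 2 edge matrix (e.g. Delaunay edges).
#' @param lengths Edge lengths (for the greedy nearest-neighbor choice).
#' @param bins Integer attribute bin per node (1..B).
#' @param n_nodes Number of nodes.
#' @param B Number of attribute bins.
#' @param Lmax Runs longer than this are counted at `Lmax`.
#' @return Named numeric vector (5 values), NA-flagged when the graph is
#'   empty.
#' @export
run_length_features <- function(edges, lengths, bins, n_nodes, B = 4,
                                Lmax = 10) {
  nm <- paste0("graph.rle.",
               c("short_run_emphasis", "long_run_emphasis",
                 "bin_nonuniformity", "run_length_nonuniformity",
                 "run_percentage"))
  if (n_nodes < 1L) return(structure(rep(NA_real_, 5), names = nm))
  adj <- vector("list", n_nodes)
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1]; b <- edges[e, 2]
      adj[[a]] <- rbind(adj[[a]], c(b, lengths[e]))
      adj[[b]] <- rbind(adj[[b]], c(a, lengths[e]))
    }
  }
  visited <- logical(n_nodes)
  rlm <- matrix(0, B, Lmax)
  n_runs <- 0L
  for (s in seq_len(n_nodes)) {
    if (visited[s]) next
    b <- bins[s]
    len <- 1L
    visited[s] <- TRUE
    u <- s
    repeat {
      nbr <- adj[[u]]
      if (is.null(nbr)) break
      cand <- nbr[!visited[nbr[, 1]] & bins[nbr[, 1]] == b, , drop = FALSE]
      if (!nrow(cand)) break
      u <- cand[which.min(cand[, 2]), 1]
      visited[u] <- TRUE
      len <- len + 1L
    }
    rlm[b, min(len, Lmax)] <- rlm[b, min(len, Lmax)] + 1
    n_runs <- n_runs + 1L
  }
  N <- sum(rlm)
  lv <- matrix(seq_len(Lmax), B, Lmax, byrow = TRUE)
  out <- c(sum(rlm / lv^2) / N,
           sum(rlm * lv^2) / N,
           sum(rowSums(rlm)^2) / N,
           sum(colSums(rlm)^2) / N,
           n_runs / n_nodes)
  names(out) <- nm
  attr(out, "rlm") <- rlm
  out
}

## equal-frequency binning of a per-nucleus descriptor into 1..M
quantile_bins <- function(v, M) {
  br <- unique(quantile(v, probs = seq(0, 1, length.out = M + 1),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(v)))
  as.integer(cut(v, breaks = br, include.lowest = TRUE))
}

## ---- Cellular diversity (cCCM) ---------------------------------------------

#' Cell-cluster co-occurrence morphology matrix (cCCM) features
#'
#' For every unordered pair of nuclei co-resident in a CCG cluster the
#' co-occurrence of their morphology bins is counted (off-diagonal counts
#' split symmetrically), then normalized to sum 1. Texture-style
#' measurements of the matrix summarize local cellular diversity: energy,
#' entropy (bits), contrast, and variance.
#'
#' @param ccg `nm_ccg`.
#' @param bins Integer morphology bin per node (1..M).
#' @param M Number of bins.
#' @param prefix Feature-name prefix, e.g. `"diversity.area"`.
#' @return Named vector of 4 measurements (NA-flagged when every cluster
#'   is a singleton), with the normalized matrix attached as attribute
#'   `ccm`.
#' @export
ccm_diversity <- function(ccg, bins, M = 4, prefix = "diversity.area") {
  nm <- paste0(prefix, ".", c("energy", "entropy", "contrast", "variance"))
  cm <- matrix(0, M, M)
  n_pairs <- 0L
  for (cl in unique(ccg$clusters)) {
    members <- which(ccg$clusters == cl)
    if (length(members) < 2L) next
    for (a in seq_len(length(members) - 1L)) {
      for (b in (a + 1L):length(members)) {
        bu <- bins[members[a]]; bv <- bins[members[b]]
        if (bu == bv) {
          cm[bu, bv] <- cm[bu, bv] + 1
        } else {
          cm[bu, bv] <- cm[bu, bv] + 0.5
          cm[bv, bu] <- cm[bv, bu] + 0.5
        }
        n_pairs <- n_pairs + 1L
      }
    }
  }
  if (n_pairs == 0L) return(structure(rep(NA_real_, 4), names = nm))
  cm <- cm / n_pairs
  i <- matrix(seq_len(M), M, M); j <- t(i)
  mu <- sum(seq_len(M) * rowSums(cm))
  out <- c(sum(cm^2), entropy_bits(as.numeric(cm)),
           sum(cm * (i - j)^2), sum(cm * (i - mu)^2))
  names(out) <- nm
  attr(out, "ccm") <- cm
  out
}

#' Patch-level spatial graph feature block
#'
#' Assembles the Delaunay, CCG neighborhood-shape, orientation-tensor,
#' run-length and cellular-diversity families for one patch. Graph nodes
#' are all nuclei (border-touching nuclei have valid centroids and are
#' retained).
#'
#' @param nuclei List of `nm_nucleus` records with intensities.
#' @param patch_size Patch side in pixels (sets the CCG distance scale).
#' @param config [nm_config()].
#' @return Named feature vector, or `NULL` when the patch has too few
#'   nuclei.
#' @export
patch_graph_block <- function(nuclei, patch_size, config = nm_config()) {
  if (length(nuclei) < config$min_nuclei) return(NULL)
  desc <- descriptor_matrix(nuclei, config, interior_only = FALSE)
  if (is.null(desc)) return(NULL)
  contr <- vapply(nuclei, function(nuc)
    haralick13(glcm(nuc, config$glcm_levels, config$offsets))[["contrast"]],
    numeric(1))
  graph_block_impl(nuclei, desc, contr, patch_size, config)
}

## core of the graph block, reusing precomputed per-nucleus descriptors and
## Haralick contrasts
graph_block_impl <- function(nuclei, desc, contr, patch_size, config) {
  cent <- t(vapply(nuclei, function(x) x$centroid, numeric(2)))

  del <- delaunay_features(cent)
  ccg <- build_ccg(cent, patch_size, alpha = config$ccg_alpha,
                   r = config$ccg_r)
  shp <- ccg_neighborhood_shape(ccg, desc)
  cgt <- cgt_orientation(ccg, desc[, "orientation_theta"], cent,
                         n_bins = config$orientation_bins)

  xy <- cbind(cent[, 2], cent[, 1])
  keep_idx <- which(!duplicated(round(xy, 9)))
  rle_feats <- if (length(keep_idx) >= 4L) {
    pts <- xy[keep_idx, , drop = FALSE]
    tris <- delaunay_triangulate(pts)
    edges <- triangle_edges(tris)
    lens <- if (nrow(edges)) sqrt(rowSums((pts[edges[, 1], , drop = FALSE] -
                                           pts[edges[, 2], , drop = FALSE])^2))
            else numeric(0)
    bins_pts <- quantile_bins(desc[keep_idx, "area"], config$rle_bins)
    run_length_features(edges, lens, bins_pts, nrow(pts),
                        B = config$rle_bins, Lmax = config$rle_lmax)
  } else {
    structure(rep(NA_real_, 5),
              names = paste0("graph.rle.",
                             c("short_run_emphasis", "long_run_emphasis",
                               "bin_nonuniformity",
                               "run_length_nonuniformity",
                               "run_percentage")))
  }

  div_area <- ccm_diversity(ccg, quantile_bins(desc[, "area"],
                                               config$ccm_bins),
                            M = config$ccm_bins, prefix = "diversity.area")
  div_con <- ccm_diversity(ccg, quantile_bins(contr, config$ccm_bins),
                           M = config$ccm_bins,
                           prefix = "diversity.contrast")
  c(del, shp, cgt, rle_feats, div_area, div_con)
}
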