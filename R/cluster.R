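#' Hierarchical clustering of patient profiles
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances by
#' default) of z-scored patient feature profiles, cut to exactly `k`
#' clusters. Deterministic and input-order invariant.
#'
#' @param X Patients x features matrix (rownames = patient ids).
#' @param k Number of clusters (the downstream analyses use k = 3 to
#'   separate stage II, peritoneal and hematogenous archetypes).
#' @param linkage `hclust` method (default `"ward.D2"`).
#' @return List of class `nm_clustering`: `assignment` (named cluster id
#'   per patient), `tree` (hclust), `k`, `order` (leaf order).
#' @export
hierarchical_cluster <- function(X, k, linkage = "ward.D2") {
  stopif(k > nrow(X), "k exceeds the number of patients")
  stopif(k < 1, "k must be >= 1")
  Z <- scale_columns(X)
  tree <- hclust(dist(Z), method = linkage)
  assignment <- cutree(tree, k = k)
  names(assignment) <- rownames(X)
  structure(list(assignment = assignment, tree = tree, k = k,
                 order = tree$order),
            class = "nm_clustering")
}

## z-score columns, leaving constant columns at 0
scale_columns <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg < 1e-12] <- 1
  sweep(sweep(X, 2, mu), 2, sg, "/")
}

#' 2-D embedding of patient profiles
#'
#' UMAP (via uwot) when that package is installed, otherwise the first two
#' principal components; the method actually used is recorded in the
#' `method` attribute. Seeded and deterministic.
#'
#' @param X Patients x features matrix.
#' @param method `"umap"` or `"pca"`; `"umap"` silently falls back to PCA
#'   (with the attribute flagging it) when uwot is unavailable.
#' @param seed Integer seed.
#' @return n x 2 coordinate matrix with attribute `method`.
#' @export
embed_2d <- function(X, method = c("umap", "pca"), seed = 0) {
  method <- match.arg(method)
  stopif(nrow(X) < 3, "need at least 3 patients")
  Z <- scale_columns(X)
  if (method == "umap" && requireNamespace("uwot", quietly = TRUE)) {
    nn <- min(15, nrow(Z) - 1)
    co <- with_seed(seed, uwot::umap(Z, n_neighbors = nn, ret_model = FALSE))
    used <- "umap"
  } else {
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    co <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    if (ncol(co) < 2) co <- cbind(co, 0)
    used <- "pca"
  }
  co <- co[, 1:2, drop = FALSE]
  dimnames(co) <- list(rownames(X), c("dim1", "dim2"))
  attr(co, "method") <- used
  co
}

#' Cohort analysis report
#'
#' Writes the downstream summary artifacts for a clustered cohort: a
#' heatmap of the selected features with rows in dendrogram leaf order, a
#' violin summary of each selected feature by class, a 2-D embedding
#' scatter, Kaplan-Meier curves by risk group, and a JSON file carrying
#' every number shown.
#'
#' @param prof Patient profile list from [patient_profiles()].
#' @param selected Feature names to display (the model's top-k).
#' @param clustering `nm_clustering` from [hierarchical_cluster()].
#' @param embedding Matrix from [embed_2d()].
#' @param survival_df Optional data.frame: patient_id, time, event,
#'   risk_group.
#' @param dir Output directory.
#' @return Paths of written files, invisibly.
#' @export
cohort_report <- function(prof, selected, clustering, embedding,
                          survival_df = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- prof$profile[, selected, drop = FALSE]
  Z <- scale_columns(X)
  cls <- prof$patients$class
  paths <- character(0)

  ## heatmap, rows in dendrogram leaf order
  hp <- file.path(dir, "heatmap.png")
  png(hp, width = 700, height = 900)
  ord <- clustering$order
  par(mar = c(10, 6, 2, 2))
  image(t(Z[ord, , drop = FALSE]), axes = FALSE,
        col = hcl.colors(64, "RdBu", rev = TRUE),
        main = "Patient profiles (top features, z-scored)")
  axis(1, at = seq(0, 1, length.out = ncol(Z)), labels = colnames(Z),
       las = 2, cex.axis = 0.8)
  dev.off()
  paths <- c(paths, hp)

  ## violin (kernel-density outlines) per class per feature
  vp <- file.path(dir, "violins.png")
  png(vp, width = 300 * length(selected), height = 400)
  par(mfrow = c(1, length(selected)), mar = c(8, 4, 3, 1))
  classes <- sort(unique(cls))
  for (f in selected) {
    v <- X[, f]
    plot(NA, xlim = c(0.5, length(classes) + 0.5), ylim = range(v),
         xaxt = "n", xlab = "", ylab = f, main = f)
    axis(1, at = seq_along(classes), labels = classes, las = 2)
    for (ci in seq_along(classes)) {
      vv <- v[cls == classes[ci]]
      if (length(vv) > 2 && sd(vv) > 0) {
        d <- stats::density(vv)
        w <- d$y / max(d$y) * 0.35
        polygon(c(ci - w, rev(ci + w)), c(d$x, rev(d$x)),
                col = "grey80", border = "grey40")
      }
      points(rep(ci, length(vv)), vv, pch = 16, cex = 0.4)
    }
  }
  dev.off()
  paths <- c(paths, vp)

  ## embedding scatter
  sp <- file.path(dir, "embedding.png")
  png(sp, width = 600, height = 600)
  cols <- seq_along(classes)[match(cls, classes)]
  plot(embedding, col = cols, pch = 16,
       main = sprintf("2-D embedding (%s)", attr(embedding, "method")))
  legend("topright", legend = classes, col = seq_along(classes), pch = 16)
  dev.off()
  paths <- c(paths, sp)

  km_list <- NULL
  if (!is.null(survival_df)) {
    kp <- file.path(dir, "km.png")
    png(kp, width = 600, height = 600)
    groups <- sort(unique(survival_df$risk_group))
    first <- TRUE
    km_list <- list()
    for (gi in seq_along(groups)) {
      sel <- survival_df$risk_group == groups[gi]
      km <- km_estimate(survival_df$time[sel], survival_df$event[sel])
      km_list[[as.character(groups[gi])]] <-
        as.data.frame(unclass(km), stringsAsFactors = FALSE)
      plot(km, add = !first, col = gi,
           main = if (first) "Overall survival by risk group" else NULL)
      first <- FALSE
    }
    legend("topright", legend = groups, col = seq_along(groups), lty = 1)
    dev.off()
    paths <- c(paths, kp)
  }

  js <- file.path(dir, "summary.json")
  per_class_means <- lapply(split(as.data.frame(X), cls), colMeans)
  jsonlite::write_json(list(
    selected_features = selected,
    cluster_assignment = as.list(clustering$assignment),
    leaf_order = rownames(X)[clustering$order],
    embedding = cbind(data.frame(patient_id = rownames(X),
                                 class = cls), as.data.frame(embedding)),
    per_class_feature_means = per_class_means,
    km = km_list),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, js)
  invisible(paths)
}
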