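#' Wilcoxon rank-sum feature ranking
#'
#' Ranks every feature column by a two-sample Wilcoxon rank-sum
#' (Mann-Whitney U) test between the two class labels. For groups with
#' fewer than 9 observations each and no ties the two-sided p-value is
#' exact (null distribution of U); otherwise the tie-corrected normal
#' approximation with continuity correction is used. Features are ordered
#' by ascending p, then descending |z|, then feature name; constant
#' features get p = 1 and are flagged.
#'
#' @param X Patches x features numeric matrix with column names.
#' @param labels Two-level factor/character vector per row.
#' @return Data frame of class `nm_ranking`: `feature`, `U` (first level
#'   vs second), `z`, `p`, `flag`, `rank`, ordered by rank.
#' @export
wrst_rank <- function(X, labels) {
  labels <- as.factor(labels)
  stopif(nlevels(labels) != 2, "exactly two classes required")
  n1 <- sum(labels == levels(labels)[1])
  n2 <- sum(labels == levels(labels)[2])
  stopif(n1 < 2 || n2 < 2, "need >= 2 observations per class")
  g1 <- labels == levels(labels)[1]

  res <- lapply(colnames(X), function(f) {
    x <- X[, f]
    ok <- is.finite(x)
    if (sum(ok & g1) < 2 || sum(ok & !g1) < 2 || length(unique(x[ok])) == 1)
      return(data.frame(feature = f, U = NA_real_, z = 0, p = 1,
                        flag = "degenerate", stringsAsFactors = FALSE))
    w <- wrst_test(x[ok & g1], x[ok & !g1])
    data.frame(feature = f, U = w$U, z = w$z, p = w$p, flag = w$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ord <- order(out$p, -abs(out$z), out$feature)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("nm_ranking", "data.frame")
  out
}

## One two-sample Mann-Whitney test; returns U (of x vs y), z, two-sided p.
wrst_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  has_ties <- any(ties > 1)
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term))
  z <- if (sigma < 1e-12) 0 else (U - mu - sign(U - mu) * 0.5) / sigma
  if (min(n1, n2) < 9 && !has_ties) {
    p <- 2 * min(pwilcox(U, n1, n2), 1 - pwilcox(U - 1, n1, n2))
    p <- min(1, p)
    flag <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    flag <- "normal"
  }
  list(U = U, z = z, p = p, flag = flag)
}

#' Select the top-k ranked features
#'
#' @param ranking `nm_ranking` from [wrst_rank()].
#' @param k Number of features (default 5, the pipeline's candidate limit
#'   chosen to avoid dimensionality and overfitting in the classifier).
#' @return Character vector of k feature names in rank order.
#' @export
select_top_k <- function(ranking, k = 5) {
  stopif(k <= 0, "k must be positive")
  stopif(k > nrow(ranking), "k exceeds the number of features")
  ranking$feature[seq_len(k)]
}

#' Train the patch-level random forest
#'
#' Features are z-scored with training-split statistics (stored and reused
#' at prediction time); the forest itself is an off-the-shelf ensemble
#' (randomForest), seeded for reproducibility.
#'
#' @param X Training patches x selected features.
#' @param labels Two-level factor per row.
#' @param ntree,mtry Forest size and per-split feature count (defaults
#'   500 and floor(sqrt(p))).
#' @param seed Integer seed.
#' @return Object of class `nm_rf` wrapping the forest and the scaler.
#' @export
train_patch_classifier <- function(X, labels, ntree = 500, mtry = NULL,
                                   seed = 0) {
  labels <- droplevels(as.factor(labels))
  stopif(nlevels(labels) < 2, "training set contains a single class")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  mtry <- mtry %||% max(1, floor(sqrt(ncol(X))))
  fit <- with_seed(seed, randomForest::randomForest(
    x = Xs, y = labels, ntree = ntree, mtry = mtry))
  structure(list(forest = fit, center = center, scale = scale,
                 levels = levels(labels), seed = seed),
            class = "nm_rf")
}

#' @export
predict.nm_rf <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  Xs <- sweep(sweep(newdata[, names(object$center), drop = FALSE], 2,
                    object$center), 2, object$scale, "/")
  predict(object$forest, Xs, type = type)
}

#' Patient-level majority vote
#'
#' Tallies per-patch predicted classes within each patient and assigns
#' the majority class; an even split is broken toward the class with the
#' higher mean predicted probability.
#'
#' @param patch_class Predicted class per patch (factor/character).
#' @param patch_prob Predicted probability of the positive class per patch.
#' @param patient_ids Patient id per patch.
#' @param positive Name of the positive (tie-break) class.
#' @return Data frame: patient_id, n_patches, votes_positive, mean_prob
#'   (the patient risk score), predicted.
#' @export
classify_patient <- function(patch_class, patch_prob, patient_ids,
                             positive) {
  ids <- unique(patient_ids)
  rows <- lapply(ids, function(pid) {
    sel <- patient_ids == pid
    votes <- sum(patch_class[sel] == positive)
    npat <- sum(sel)
    mp <- mean(patch_prob[sel])
    pred <- if (votes * 2 > npat) positive
            else if (votes * 2 < npat) "other"
            else if (mp >= 0.5) positive else "other"
    data.frame(patient_id = pid, n_patches = npat, votes_positive = votes,
               mean_prob = mp, predicted = pred, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' ROC curve and AUC
#'
#' AUC by the trapezoidal rule over the empirical ROC, which equals the
#' concordant-pair fraction (ties counted one half, the Mann-Whitney
#' identity AUC = U/(n1 n2)).
#'
#' @param scores Numeric risk scores (higher = more positive).
#' @param labels Binary labels; `positive` names the positive class.
#' @param positive Positive class value (default: second sorted level).
#' @return List of class `nm_roc`: `points` (data.frame fpr, tpr,
#'   threshold), `auc`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  labels <- as.factor(labels)
  stopif(nlevels(labels) < 2, "both classes must be present")
  positive <- positive %||% levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  stopif(n1 == 0 || n0 == 0, "both classes must be present")

  ## rank formula (ties share average ranks -> half credit)
  rk <- rank(scores)
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    c(fpr = sum(scores[!pos] >= t) / n0, tpr = sum(scores[pos] >= t) / n1)
  }, numeric(2)))
  structure(list(points = data.frame(fpr = pts[, 1], tpr = pts[, 2],
                                     threshold = thr),
                 auc = auc),
            class = "nm_roc")
}

#' Fit the nuclear-morphometry stage classifier
#'
#' The package's central model: on a patient-level 80/20 split, features
#' are ranked by the Wilcoxon rank-sum test on training patches, the top
#' `k` are z-scored and fed to a random forest trained per patch, and
#' held-out patients are classified by patch-majority voting. The patient
#' risk score is the mean predicted positive-class probability over the
#' patient's patches.
#'
#' @param feats `nm_features` (or a list with `features` and `meta`).
#' @param k Number of selected features (default 5).
#' @param split Training fraction of patients (default 0.8), stratified by
#'   class.
#' @param seed Integer seed controlling the split and the forest.
#' @param ntree Forest size.
#' @param positive Positive class; defaults to the lexicographically
#'   second class label.
#' @param classes Optional two classes to model (rows of other classes are
#'   ignored).
#' @return Object of class `stage_model`: feature `ranking`, `selected`
#'   names, the fitted `classifier`, train/test patient ids, held-out
#'   per-patient `votes`, `roc` and `auc`.
#' @export
stage_model <- function(feats, k = 5, split = 0.8, seed = 0, ntree = 500,
                        positive = NULL, classes = NULL) {
  X <- feats$features
  meta <- feats$meta
  if (!is.null(classes)) {
    sel <- meta$class %in% classes
    X <- X[sel, , drop = FALSE]
    meta <- meta[sel, ]
  }
  cls <- sort(unique(meta$class))
  stopif(length(cls) != 2, "stage_model requires exactly two classes")
  positive <- positive %||% cls[2]

  ## patient-level stratified split
  pat <- unique(meta[, c("patient_id", "class")])
  train_ids <- with_seed(seed, unlist(lapply(cls, function(cl) {
    ids <- pat$patient_id[pat$class == cl]
    sample(ids, max(1, round(split * length(ids))))
  })))
  tr <- meta$patient_id %in% train_ids
  stopif(!any(tr) || all(tr), "degenerate patient split")

  ranking <- wrst_rank(X[tr, , drop = FALSE], meta$class[tr])
  selected <- select_top_k(ranking, k)
  clf <- train_patch_classifier(X[tr, selected, drop = FALSE],
                                meta$class[tr], ntree = ntree, seed = seed)

  te <- !tr
  prob <- predict(clf, X[te, selected, drop = FALSE], type = "prob")
  p_pos <- prob[, positive]
  pred_class <- colnames(prob)[max.col(prob, ties.method = "first")]
  votes <- classify_patient(pred_class, p_pos, meta$patient_id[te], positive)
  truth <- pat$class[match(votes$patient_id, pat$patient_id)]
  roc <- roc_auc(votes$mean_prob, factor(truth, levels = cls),
                 positive = positive)
  votes$true_class <- truth

  structure(list(ranking = ranking, selected = selected, classifier = clf,
                 positive = positive, classes = cls,
                 train_patients = sort(train_ids),
                 test_patients = setdiff(pat$patient_id, train_ids),
                 votes = votes, roc = roc, auc = roc$auc,
                 accuracy = mean((votes$predicted == positive) ==
                                 (truth == positive)),
                 k = k, seed = seed, call = match.call()),
            class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat("Nuclear morphometry stage classifier\n")
  cat(sprintf("  classes: %s vs %s (positive: %s)\n",
              x$classes[1], x$classes[2], x$positive))
  cat(sprintf("  top-%d features: %s\n", x$k,
              paste(x$selected, collapse = ", ")))
  cat(sprintf("  held-out patients: %d;  patch-vote accuracy %.3f;  AUC %.3f\n",
              nrow(x$votes), x$accuracy, x$auc))
  invisible(x)
}

#' @export
summary.stage_model <- function(object, ...) {
  cat("Feature ranking (top 10):\n")
  print(head(as.data.frame(object$ranking), 10))
  cat("\nHeld-out patient votes:\n")
  print(object$votes)
  print(object)
  invisible(object)
}

#' @export
predict.stage_model <- function(object, feats, ...) {
  prob <- predict(object$classifier,
                  feats$features[, object$selected, drop = FALSE],
                  type = "prob")
  p_pos <- prob[, object$positive]
  pred_class <- colnames(prob)[max.col(prob, ties.method = "first")]
  classify_patient(pred_class, p_pos, feats$meta$patient_id,
                   object$positive)
}

#' @export
plot.stage_model <- function(x, ...) {
  plot(x$roc$points$fpr, x$roc$points$tpr, type = "s",
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("Held-out patient ROC (AUC = %.3f)", x$auc), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}
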