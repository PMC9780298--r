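#' Principal-component analysis with a deterministic sign convention
#'
#' Column-centered PCA by singular value decomposition (via
#' [stats::prcomp()]). The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results reproducible across
#' platforms. "Principal-component genes" are those whose absolute loading
#' on component 1 or 2 reaches the given quantile (default: top 25%).
#'
#' @param x Samples x features numeric matrix, or an `alteration_matrix`
#'   (gene x sample; transposed internally).
#' @param n_components Number of components to keep; at most
#'   `min(n_samples - 1, n_features)`.
#' @param loading_quantile Quantile of |loading| above which a feature
#'   counts as a principal-component gene (default 0.75).
#' @param scale. Scale features to unit variance before PCA (default FALSE).
#' @return An object of class `pca_model`: `loadings` (feature x component),
#'   `explained_variance` (component variances, non-increasing),
#'   `explained_fraction`, `scores` (sample x component), `pc_genes`
#'   (list per component 1-2), `center`.
#' @export
fit_pca <- function(x, n_components = 2L, loading_quantile = 0.75,
                    scale. = FALSE) {
  if (inherits(x, "alteration_matrix")) x <- t(x$values)
  x <- as.matrix(x)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (n_components < 1L || n_components > max_comp) {
    stop(sprintf("n_components must be in [1, %d] for %d samples x %d features",
                 max_comp, nrow(x), ncol(x)), call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = n_components)
  load <- pr$rotation
  scores <- pr$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pr$sdev^2
  pc_genes <- lapply(seq_len(min(2L, ncol(load))), function(j) {
    al <- abs(load[, j])
    names(al)[al >= stats::quantile(al, loading_quantile)]
  })
  structure(
    list(loadings = load, explained_variance = ev[seq_len(n_components)],
         explained_fraction = ev[seq_len(n_components)] / sum(ev),
         scores = scores, pc_genes = pc_genes, center = pr$center,
         scaled = scale.),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components over %d features; explained fractions: %s\n",
              ncol(x$loadings), nrow(x$loadings),
              paste(sprintf("%.2f", x$explained_fraction), collapse = ", ")))
  invisible(x)
}

#' ROC AUC in the Mann-Whitney pairwise-probability form
#'
#' `AUC = mean over all (better, poor) pairs of [score_better > score_poor]
#' + 1/2 [score_better == score_poor]`, with "better" fixed as the positive
#' class. Exchangeable scores give 0.5; the statistic is invariant under any
#' strictly increasing transform of the scores.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param labels Character/factor vector with both levels "better" and
#'   "poor" present.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' discrimination_auc(c(0.8, 0.3, 0.5, 0.1),
#'                    c("better", "better", "poor", "poor")) # 0.75
discrimination_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == "better"]
  neg <- scores[labels == "poor"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes ('better' and 'poor') must be present", call. = FALSE)
  }
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

#' ROC curve points for a score against better/poor labels
#'
#' @param scores,labels As in [discrimination_auc()].
#' @return Data.frame with `threshold`, `tpr`, `fpr`, ordered for plotting.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.character(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pos <- labels == "better"
  data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  )
}

#' Two-means clustering of samples in PC space
#'
#' Deterministic k = 2 clustering: the two initial centers are the farthest
#' pair of points (Euclidean), refined by Lloyd iterations, so no random
#' seed is involved. When group labels are supplied the cluster/group
#' cross-tabulation, its best-matching agreement, and Fisher's exact test
#' are reported.
#'
#' @param scores Sample x d numeric matrix (>= 4 rows), typically the first
#'   two PC scores.
#' @param group Optional per-sample "better"/"poor" labels.
#' @return A list: `clusters` (1/2 per sample), `centers`, `degenerate`
#'   (TRUE when all points coincide: a single effective cluster, agreement
#'   undefined), and with `group`: `table`, `agreement`, `p_value`.
#' @export
cluster_samples <- function(scores, group = NULL) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 4L) stop("need at least 4 samples to cluster", call. = FALSE)
  d <- as.matrix(stats::dist(scores))
  if (max(d) == 0) {
    out <- list(clusters = rep(1L, nrow(scores)), centers = scores[1, , drop = FALSE],
                degenerate = TRUE)
    if (!is.null(group)) out$agreement <- NA_real_
    return(out)
  }
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  km <- stats::kmeans(scores, centers = scores[c(ij[1], ij[2]), , drop = FALSE],
                      algorithm = "Lloyd", iter.max = 100)
  out <- list(clusters = km$cluster, centers = km$centers, degenerate = FALSE)
  if (!is.null(group)) {
    tab <- table(cluster = km$cluster, group = as.character(group))
    out$table <- tab
    if (all(dim(tab) == c(2L, 2L))) {
      out$agreement <- max(sum(diag(tab)), sum(tab[cbind(1:2, 2:1)])) / sum(tab)
      out$p_value <- stats::fisher.test(tab)$p.value
    } else {
      out$agreement <- sum(apply(tab, 1, max)) / sum(tab)
      out$p_value <- NA_real_
    }
  }
  out
}
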