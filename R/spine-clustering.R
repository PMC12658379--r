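#' The 16-feature morphometric roster
#'
#' Fixed data dictionary of the features used for unsupervised clustering.
#' Nine are raw reconstruction exports (um): `length`, `head_max_diameter`,
#' `head_mean_diameter`, `head_length`, `neck_min_diameter`,
#' `neck_mean_diameter`, `neck_length`, `attachment_diameter`, `straightness`
#' (dimensionless). Seven are derived: `lwr` (length / head max diameter),
#' `frustum_height` (um), `surface_area` (um^2), `volume` (um^3),
#' `head_neck_ratio` (head max / neck mean diameter), `neck_length_fraction`
#' (neck length / length) and `area_volume_ratio` (1/um).
#'
#' @return character vector of the 16 feature names, in canonical order.
#' @export
spine_feature_names <- function() {
  c("length", "head_max_diameter", "head_mean_diameter", "head_length",
    "neck_min_diameter", "neck_mean_diameter", "neck_length",
    "attachment_diameter", "straightness",
    "lwr", "frustum_height", "surface_area", "volume",
    "head_neck_ratio", "neck_length_fraction", "area_volume_ratio")
}

#' Build the numeric feature matrix for clustering
#'
#' Computes the derived features (geometry via [spine_geometry()], LWR and the
#' ratio features) where absent and assembles the 16-column matrix in the
#' order of [spine_feature_names()]. Rows with any missing feature (e.g.
#' neckless records that survived refinement) are dropped with a warning.
#'
#' @param spines refined spine table with the nine raw feature columns.
#' @return numeric matrix, one row per spine, with a `spine_rows` attribute
#'   giving the retained row indices of `spines`.
#' @export
spine_feature_matrix <- function(spines) {
  raw <- spine_feature_names()[1:9]
  missing_cols <- setdiff(raw, names(spines))
  if (length(missing_cols) > 0L)
    stop("spine table missing feature columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(c("surface_area", "volume", "frustum_height") %in% names(spines)))
    spines <- spine_geometry(spines)
  if (!"lwr" %in% names(spines))
    spines$lwr <- spines$length / spines$head_max_diameter
  spines$head_neck_ratio <- spines$head_max_diameter / spines$neck_mean_diameter
  spines$neck_length_fraction <- spines$neck_length / spines$length
  spines$area_volume_ratio <- spines$surface_area / spines$volume
  m <- as.matrix(spines[, spine_feature_names()])
  ok <- stats::complete.cases(m) & apply(is.finite(m), 1, all)
  if (!all(ok))
    warning(sum(!ok), " spine(s) with missing/non-finite features dropped")
  m <- m[ok, , drop = FALSE]
  attr(m, "spine_rows") <- which(ok)
  m
}

#' Elbow-method selection of the number of k-means clusters
#'
#' Runs k-means for k = 1..max(k_range)+1 and picks the k in `k_range` where
#' the within-cluster inertia curve bends most sharply: the maximizer of the
#' discrete curvature W(k-1) - 2 W(k) + W(k+1), ties resolved toward the
#' smaller k.
#'
#' @param x numeric matrix of (standardized or PCA-score) features.
#' @param k_range candidate cluster counts (default 2:10).
#' @param nstart,iter.max passed to [stats::kmeans()].
#' @return list with `k` (the selected count) and `inertia` (named vector of
#'   total within-cluster sums of squares over the evaluated k).
#' @export
choose_k_elbow <- function(x, k_range = 2:10, nstart = 10, iter.max = 100) {
  ks <- sort(unique(c(1L, k_range, max(k_range) + 1L)))
  ks <- ks[ks <= nrow(x)]
  inertia <- vapply(ks, function(k) {
    if (k == 1L) sum(scale(x, scale = FALSE)^2)
    else stats::kmeans(x, centers = k, nstart = nstart,
                       iter.max = iter.max)$tot.withinss
  }, numeric(1))
  names(inertia) <- ks
  cand <- intersect(k_range, ks[ks > min(ks) & ks < max(ks)])
  curv <- vapply(cand, function(k) {
    inertia[as.character(k - 1)] - 2 * inertia[as.character(k)] +
      inertia[as.character(k + 1)]
  }, numeric(1))
  list(k = cand[which.max(curv)], inertia = inertia)
}

#' Cluster spines by z-score standardization, PCA, and k-means
#'
#' Standardizes each feature to mean 0 / sd 1 over the fitted set, projects
#' onto principal components (all components are retained for clustering; the
#' first two are conventionally used for plotting), and partitions the scores
#' with k-means (fixed seed, multiple restarts). If `k` is not given it is
#' chosen by the elbow method over 2..10 (see [choose_k_elbow()]).
#'
#' @param features numeric feature matrix (see [spine_feature_matrix()]), one
#'   row per spine.
#' @param k number of clusters, or `NULL` for elbow selection.
#' @param seed RNG seed controlling the k-means restarts.
#' @param nstart number of random restarts.
#' @return object of class `spine_clusters`: list with `cluster` (integer
#'   assignments), `k`, `centers` (in PCA-score space), `pca` (the `prcomp`
#'   fit), `explained_variance` (fractions per component), `scaling` (feature
#'   means and sds), `inertia` (elbow curve when k was selected), `totss`,
#'   `tot.withinss`.
#' @export
cluster_spines <- function(features, k = NULL, seed = 1L, nstart = 10) {
  features <- as.matrix(features)
  if (!is.null(k) && nrow(features) < k * 10)
    stop("need at least 10 spines per cluster (", k * 10, " for k = ", k, ")")
  mu <- colMeans(features)
  sdev <- apply(features, 2, stats::sd)
  if (all(sdev == 0)) {
    # degenerate input: every row identical, a single effective cluster
    warning("all feature rows identical; returning a single cluster")
    return(structure(list(cluster = rep(1L, nrow(features)), k = 1L,
                          centers = matrix(0, 1, 1), pca = NULL,
                          explained_variance = NA_real_,
                          scaling = list(mean = mu, sd = sdev),
                          inertia = c(`1` = 0), totss = 0, tot.withinss = 0),
                     class = "spine_clusters"))
  }
  constant <- sdev == 0
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) dropped before PCA: ",
            paste(colnames(features)[constant], collapse = ", "))
    features <- features[, !constant, drop = FALSE]
    mu <- mu[!constant]; sdev <- sdev[!constant]
  }
  z <- sweep(sweep(features, 2, mu), 2, sdev, `/`)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pca$x
  set.seed(seed)
  inertia <- NULL
  if (is.null(k)) {
    sel <- choose_k_elbow(scores)
    k <- sel$k
    inertia <- sel$inertia
    if (nrow(features) < k * 10)
      stop("elbow-selected k = ", k, " needs more spines than supplied")
  }
  km <- stats::kmeans(scores, centers = k, nstart = nstart, iter.max = 100)
  structure(list(cluster = km$cluster, k = k, centers = km$centers,
                 pca = pca,
                 explained_variance = pca$sdev^2 / sum(pca$sdev^2),
                 scaling = list(mean = mu, sd = sdev),
                 inertia = inertia, totss = km$totss,
                 tot.withinss = km$tot.withinss),
            class = "spine_clusters")
}

#' @export
print.spine_clusters <- function(x, ...) {
  cat("k-means spine clustering: k =", x$k, "on", length(x$cluster),
      "spines\n")
  cat("Cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = ", "), "\n")
  cat(sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  cat(sprintf("Within-cluster inertia: %.2f of total %.2f\n",
              x$tot.withinss, x$totss))
  invisible(x)
}

#' @export
summary.spine_clusters <- function(object, ...) {
  list(k = object$k,
       sizes = tabulate(object$cluster, object$k),
       proportions = tabulate(object$cluster, object$k) / length(object$cluster),
       explained_variance = object$explained_variance,
       tot.withinss = object$tot.withinss)
}

#' Plot spine clusters in PCA space
#'
#' Scatter of the first two principal-component scores, colored by cluster,
#' with explained-variance percentages on the axes.
#'
#' @param x a `spine_clusters` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spine_clusters <- function(x, ...) {
  s <- x$pca$x
  graphics::plot(s[, 1], s[, 2], col = x$cluster, pch = 16, cex = 0.6,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 ...)
  invisible(x)
}

#' Assign new spines to fitted clusters
#'
#' Applies the stored standardization and PCA rotation, then assigns each
#' spine to the nearest k-means centroid.
#'
#' @param object a `spine_clusters` fit.
#' @param newdata feature matrix with the same columns the fit used.
#' @param ... unused.
#' @return integer cluster assignments.
#' @export
predict.spine_clusters <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, names(object$scaling$mean), drop = FALSE]
  z <- sweep(sweep(newdata, 2, object$scaling$mean), 2, object$scaling$sd, `/`)
  scores <- z %*% object$pca$rotation
  d <- as.matrix(stats::dist(rbind(object$centers, scores)))
  d <- d[-seq_len(object$k), seq_len(object$k), drop = FALSE]
  unname(apply(d, 1, which.min))
}
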