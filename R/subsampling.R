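# k-means vertex subsampling.
#
# Clustering runs ONCE on the reference specimen's coordinates and the
# selected vertex indices are broadcast to every specimen — per-mesh
# clustering would destroy the vertex correspondence the registration just
# built. Representatives are real surface vertices (the member closest to
# each cluster mean), not the synthetic centroids themselves.

# k-means++ initial centers (Arthur & Vassilvitskii 2007); uses the current
# RNG stream.
kmeanspp_init <- function(pts, k) {
  n <- nrow(pts)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(pts, 2, pts[centers[1], ])^2)
  if (k > 1) for (j in 2:k) {
    tot <- sum(d2)
    centers[j] <- if (tot <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / tot)
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[centers[j], ])^2))
  }
  pts[centers, , drop = FALSE]
}

#' k-means partition of 3D points
#'
#' Lloyd iterations from k-means++ initializations, best of `n_restarts` by
#' total within-cluster sum of squares. At convergence every cluster center
#' is the mean of its member vertices.
#'
#' @param points n x 3 numeric matrix.
#' @param k number of clusters, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @param n_restarts independent k-means++ restarts (default 10).
#' @param max_iter Lloyd iteration cap (default 300).
#' @return A list with `assignments` (length n), `centroids` (k x 3) and
#'   `inertia` (total within-cluster sum of squares).
#' @export
kmeans_partition <- function(points, k, seed = 1L, n_restarts = 10L,
                             max_iter = 300L) {
  points <- as.matrix(points)
  n <- nrow(points)
  k <- as.integer(k)
  if (k < 1 || k > n) dm_stop("k must satisfy 1 <= k <= number of points")
  if (k == n) {
    return(list(assignments = seq_len(n), centroids = points, inertia = 0))
  }
  with_seed(seed, {
    best <- NULL
    attempts <- 0L
    while (attempts < n_restarts * 3L &&
             (is.null(best) || attempts < n_restarts)) {
      attempts <- attempts + 1L
      init <- kmeanspp_init(points, k)
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(points, centers = init,
                                       iter.max = max_iter,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)  # empty cluster: retry with a new init
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best)) dm_stop("k-means failed on every restart")
    list(assignments = as.integer(best$cluster),
         centroids = unname(best$centers),
         inertia = best$tot.withinss)
  })
}

#' Select one real vertex per cluster
#'
#' For each cluster, the member vertex with the smallest Euclidean distance
#' to the cluster mean (ties broken by lowest vertex index), ensuring the
#' subsample consists of actual surface vertices rather than artificial
#' centroid points.
#'
#' @param points n x 3 matrix clustered by [kmeans_partition()].
#' @param assignments,centroids clustering output.
#' @param seed seed recorded in the selection (provenance only).
#' @return An object of class `subsample_selection`: `k`, sorted
#'   `vertex_indices`, `inertia`, `seed`.
#' @export
select_representatives <- function(points, assignments, centroids, seed = NA_integer_) {
  points <- as.matrix(points)
  k <- nrow(centroids)
  reps <- integer(k)
  for (j in seq_len(k)) {
    members <- which(assignments == j)
    if (!length(members)) dm_stop(sprintf("cluster %d is empty", j))
    d2 <- rowSums(sweep(points[members, , drop = FALSE], 2, centroids[j, ])^2)
    reps[j] <- members[which.min(d2)]  # which.min takes the lowest index on ties
  }
  inertia <- sum((points - centroids[assignments, , drop = FALSE])^2)
  structure(list(k = k, vertex_indices = sort(reps), inertia = inertia,
                 seed = seed),
            class = "subsample_selection")
}

#' Subsample a registered sample to k corresponding vertices
#'
#' k-means clustering is computed once on the reference specimen's vertex
#' coordinates (raw, pre-GPA: subsampling happens inside the registration
#' step, before superimposition); the selected vertex indices are then
#' applied to every specimen's coordinate array, preserving correspondence.
#' Faces are dropped.
#'
#' @param sample a [registered_sample] (not already subsampled).
#' @param k subsample size, `1 <= k <=` vertex count.
#' @param seed integer RNG seed for the clustering.
#' @return A [registered_sample] with `subsample_indices` recorded. The
#'   [subsample_selection] is attached as attribute `"selection"`.
#' @export
subsample_registered <- function(sample, k, seed = 1L) {
  if (!is.null(sample$subsample_indices))
    dm_stop("sample is already subsampled; re-subsampling is not allowed")
  nv <- dim(sample$coordinates)[2]
  k <- as.integer(k)
  if (k < 1 || k > nv) dm_stop("k must satisfy 1 <= k <= vertex count")
  ref_idx <- match(sample$reference_id, sample$specimen_ids)
  pts <- sample$coordinates[ref_idx, , ]
  km <- kmeans_partition(pts, k, seed = seed)
  sel <- select_representatives(pts, km$assignments, km$centroids, seed = seed)
  out <- registered_sample(sample$reference_id, sample$specimen_ids,
                           sample$coordinates[, sel$vertex_indices, ,
                                              drop = FALSE],
                           faces = NULL,
                           subsample_indices = sel$vertex_indices,
                           seeds = sample$seeds, params = sample$params)
  attr(out, "selection") <- sel
  out
}
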