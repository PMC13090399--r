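# Generalized Procrustes Analysis, shape PCA, distances and allometry.
#
# Conventions: configurations are vertices x 3 matrices flattened in
# (x1,y1,z1,x2,...) order; GPA scales to unit centroid size and disallows
# reflections; PCA operates on Procrustes coordinates directly (no tangent
# projection by default); Procrustes distances are computed within the
# common superimposition, not pairwise re-fit.

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the points from their
#' centroid.
#' @param x vertices x 3 matrix.
#' @return Scalar.
#' @export
centroid_size <- function(x) {
  ctr <- sweep(x, 2, colMeans(x))
  sqrt(sum(ctr^2))
}

# optimal rotation R (det +1) minimizing ||A R - B||_F for centered A, B
rotation_onto <- function(A, B) {
  M <- crossprod(A, B)
  s <- svd(M)
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# deterministic principal-axes pose: output depends only on shape, not on
# the input's original rotation/translation/scale (used to seed GPA so the
# whole superimposition is invariant to input similarity transforms)
canonicalize_orientation <- function(x) {
  e <- eigen(crossprod(x), symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  y <- x %*% V
  flips <- 0L
  for (j in 1:3) {
    i <- which.max(abs(y[, j]))
    if (y[i, j] < 0) { y[, j] <- -y[, j]; flips <- flips + 1L }
  }
  if (flips %% 2L == 1L) y[, 3] <- -y[, 3]  # keep det(+1) overall
  y
}

#' Generalized Procrustes Analysis
#'
#' Iteratively centers each configuration, scales it to unit centroid size,
#' rotates it (optimal rotation, reflections disallowed) onto the running
#' mean, and updates the mean until it changes by less than `tol`
#' (Frobenius). The converged mean is re-scaled to unit centroid size. The
#' initial mean is the first configuration in a canonical principal-axes
#' pose, which makes the output invariant to similarity transforms of any
#' input.
#'
#' @param sample a [registered_sample] or a specimens x vertices x 3 array.
#' @param tol convergence tolerance on the mean (default 1e-10).
#' @param max_iter iteration cap.
#' @return An object of class `shape_space` with `procrustes_coords`
#'   (specimens x vertices x 3), `centroid_sizes` (mm), `mean_shape`
#'   (vertices x 3) and `specimen_ids`; PCA fields are added by
#'   [pca_shape()].
#' @export
gpa <- function(sample, tol = 1e-10, max_iter = 200L) {
  coords <- if (inherits(sample, "registered_sample")) sample$coordinates
  else sample
  ids <- if (inherits(sample, "registered_sample")) sample$specimen_ids
  else dimnames(coords)[[1]]
  n <- dim(coords)[1]; p <- dim(coords)[2]
  if (n < 2) dm_stop("GPA needs at least 2 specimens")
  if (p < 3) dm_stop("GPA needs at least 3 vertices")
  if (is.null(ids)) ids <- sprintf("spec%02d", seq_len(n))
  cs <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    xi <- coords[i, , ]
    ctr <- sweep(xi, 2, colMeans(xi))
    cs[i] <- sqrt(sum(ctr^2))
    if (cs[i] < 1e-12)
      dm_stop(sprintf("degenerate configuration (all points coincident): '%s'",
                      ids[i]))
    X[[i]] <- ctr / cs[i]
  }
  mean_shape <- canonicalize_orientation(X[[1]])
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  for (it in seq_len(max_iter)) {
    for (i in seq_len(n)) X[[i]] <- X[[i]] %*% rotation_onto(X[[i]], mean_shape)
    new_mean <- Reduce(`+`, X) / n
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  pc <- array(NA_real_, dim = c(n, p, 3),
              dimnames = list(ids, NULL, c("x", "y", "z")))
  for (i in seq_len(n)) pc[i, , ] <- X[[i]]
  structure(list(procrustes_coords = pc, centroid_sizes = cs,
                 mean_shape = mean_shape, specimen_ids = ids),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  d <- dim(x$procrustes_coords)
  cat(sprintf("shape_space: %d specimens x %d vertices%s\n", d[1], d[2],
              if (is.null(x$pc_scores)) "" else
                sprintf(", %d PCs", ncol(x$pc_scores))))
  invisible(x)
}

#' Shape PCA on Procrustes coordinates
#'
#' PCA of the flattened Procrustes coordinates, centered on the mean of the
#' fit subset. Components are ordered by variance; all `min(n_fit - 1, 3p)`
#' components are retained so variance fractions sum to 1 and PC-score
#' distance vectors equal distances in Procrustes coordinate space.
#'
#' @param space a `shape_space` from [gpa()].
#' @param fit_ids optional subset of specimen ids used to fit the PCA
#'   (e.g. everything except a projected focal specimen); scores are
#'   computed for the fit specimens, others via [project_specimen()].
#' @return The `shape_space` with fields `pc_scores` (fit specimens x
#'   components), `pc_vectors` (components x 3p), `variance_fraction`,
#'   `pc_sdev`, `pca_center` (3p) and `fit_ids` added.
#' @export
pca_shape <- function(space, fit_ids = NULL) {
  ids <- space$specimen_ids
  if (is.null(fit_ids)) fit_ids <- ids
  if (!all(fit_ids %in% ids)) dm_stop("fit_ids contains unknown specimens")
  if (length(fit_ids) < 2) dm_stop("PCA needs at least 2 fit specimens")
  sel <- match(fit_ids, ids)
  n <- length(sel); p <- dim(space$procrustes_coords)[2]
  Xf <- matrix(NA_real_, n, 3 * p)
  for (i in seq_len(n)) Xf[i, ] <- flatten_config(space$procrustes_coords[sel[i], , ])
  center <- colMeans(Xf)
  Xc <- sweep(Xf, 2, center)
  sv <- svd(Xc, nu = 0, nv = min(n - 1, 3 * p))
  ncomp <- min(n - 1, 3 * p)
  sdev <- sv$d[seq_len(ncomp)] / sqrt(n - 1)
  vectors <- t(sv$v[, seq_len(ncomp), drop = FALSE])
  scores <- Xc %*% t(vectors)
  rownames(scores) <- fit_ids
  colnames(scores) <- sprintf("PC%d", seq_len(ncomp))
  varfrac <- sdev^2 / sum(sdev^2)
  space$pc_scores <- scores
  space$pc_vectors <- vectors
  space$pc_sdev <- sdev
  space$variance_fraction <- varfrac
  space$pca_center <- center
  space$fit_ids <- fit_ids
  space
}

#' Project a superimposed configuration into an existing shape PCA
#'
#' Centers the flattened configuration on the fit mean and projects it onto
#' the PC vectors. The configuration must already be superimposed within the
#' same GPA (e.g. a row of `procrustes_coords` excluded from `fit_ids`).
#'
#' @param space a `shape_space` with PCA fields, or the id of a specimen in
#'   it via `specimen` as character.
#' @param specimen vertices x 3 matrix, or a specimen id present in the GPA.
#' @return Named numeric vector of PC scores.
#' @export
project_specimen <- function(space, specimen) {
  if (is.null(space$pc_vectors)) dm_stop("run pca_shape() first")
  x <- if (is.character(specimen)) {
    i <- match(specimen, space$specimen_ids)
    if (is.na(i)) dm_stop(sprintf("unknown specimen '%s'", specimen))
    space$procrustes_coords[i, , ]
  } else as.matrix(specimen)
  v <- flatten_config(x)
  if (length(v) != length(space$pca_center))
    dm_stop("configuration dimension does not match the PCA")
  drop((v - space$pca_center) %*% t(space$pc_vectors))
}

#' Mean-shape warp along a principal component
#'
#' `mean + multiplier * sd(PC scores) * PC vector`, reshaped to vertices x 3
#' — the standard +/-2 SD visualization of shape change along a PC.
#'
#' @param space a `shape_space` with PCA fields.
#' @param pc component index.
#' @param multiplier position along the PC in SD units.
#' @return vertices x 3 configuration.
#' @export
warp_along_pc <- function(space, pc, multiplier) {
  if (is.null(space$pc_vectors)) dm_stop("run pca_shape() first")
  if (pc < 1 || pc > nrow(space$pc_vectors)) dm_stop("pc out of range")
  s <- stats::sd(space$pc_scores[, pc])
  unflatten_config(space$pca_center + multiplier * s * space$pc_vectors[pc, ])
}

#' Procrustes distance between two superimposed configurations
#'
#' Euclidean norm of the coordinate-wise difference within the common GPA
#' superimposition (pairwise re-superimposition is deliberately not done;
#' see `full_procrustes_distance()` for the one-shot two-configuration
#' alternative).
#'
#' @param a,b vertices x 3 matrices with equal vertex counts.
#' @return Scalar distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) dm_stop("configurations differ in vertex count")
  sqrt(sum((a - b)^2))
}

#' One-shot full Procrustes distance between two configurations
#'
#' Centers both, scales to unit centroid size, finds the optimal rotation
#' (reflections disallowed) and returns the residual norm. Provided as the
#' pairwise-superimposition alternative and used as an independent oracle
#' for the two-configuration GPA.
#'
#' @param a,b vertices x 3 matrices.
#' @return Scalar distance.
#' @export
full_procrustes_distance <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); ac <- ac / sqrt(sum(ac^2))
  bc <- sweep(b, 2, colMeans(b)); bc <- bc / sqrt(sum(bc^2))
  sqrt(sum((ac %*% rotation_onto(ac, bc) - bc)^2))
}

#' Pairwise Procrustes distance report for a focal specimen
#'
#' Distances from the focal specimen to every other specimen, sorted
#' ascending within each group, with per-group mean and sample SD. Values
#' are kept at full precision; round on output (3 decimals is the
#' conventional table format).
#'
#' @param space a `shape_space`.
#' @param focal focal specimen id.
#' @param study data.frame with columns `specimen_id` and `group`.
#' @return An object of class `distance_report`: `focal_id`, `rows`
#'   (specimen_id, group, pd), `group_stats` (group, n, mean, sd).
#' @export
pd_report <- function(space, focal, study) {
  ids <- space$specimen_ids
  fi <- match(focal, ids)
  if (is.na(fi)) dm_stop(sprintf("unknown focal specimen '%s'", focal))
  others <- setdiff(ids, focal)
  grp <- study$group[match(others, study$specimen_id)]
  pd <- vapply(others, function(id) {
    procrustes_distance(space$procrustes_coords[fi, , ],
                        space$procrustes_coords[match(id, ids), , ])
  }, 0)
  rows <- data.frame(specimen_id = others, group = grp, pd = pd,
                     stringsAsFactors = FALSE, row.names = NULL)
  rows <- rows[order(rows$group, rows$pd), ]
  rownames(rows) <- NULL
  gs <- do.call(rbind, lapply(split(rows, rows$group), function(g) {
    data.frame(group = g$group[1], n = nrow(g), mean = mean(g$pd),
               sd = if (nrow(g) > 1) stats::sd(g$pd) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(gs) <- NULL
  structure(list(focal_id = focal, rows = rows, group_stats = gs),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise Procrustes distances from '%s'\n", x$focal_id))
  out <- x$rows
  out$pd <- round(out$pd, digits)
  print(out, row.names = FALSE)
  gs <- x$group_stats
  gs$mean <- round(gs$mean, digits); gs$sd <- round(gs$sd, digits)
  print(gs, row.names = FALSE)
  invisible(x)
}

#' Mahalanobis distances from a focal specimen to group means
#'
#' Computed in the leading-`m` PC-score subspace (the full vertex space is
#' singular for small groups). Per group: mean score vector and covariance
#' with shrinkage `lambda` towards its own diagonal,
#' `S* = (1 - lambda) S + lambda diag(S)`; the distance is the square root
#' of the standard quadratic form.
#'
#' @param space a `shape_space` with PCA fields.
#' @param focal focal specimen id (scores taken from the PCA if the focal
#'   was fit, otherwise via [project_specimen()]).
#' @param study data.frame with `specimen_id` and `group` (focal excluded
#'   automatically).
#' @param m subspace dimension (default 2); must be `<= n_g - 1` for every
#'   group.
#' @param lambda shrinkage weight in \[0, 1\] (default 0.1).
#' @return Named numeric vector of distances (one per group), with the
#'   choices `m` and `lambda` attached as attributes.
#' @export
mahalanobis_to_groups <- function(space, focal, study, m = 2L, lambda = 0.1) {
  if (is.null(space$pc_scores)) dm_stop("run pca_shape() first")
  m <- as.integer(m)
  focal_scores <- if (focal %in% rownames(space$pc_scores))
    space$pc_scores[focal, seq_len(m)]
  else project_specimen(space, focal)[seq_len(m)]
  groups <- setdiff(unique(study$group[study$specimen_id != focal]), NA)
  out <- setNames(numeric(length(groups)), groups)
  for (g in groups) {
    ids <- setdiff(study$specimen_id[study$group == g], focal)
    ids <- intersect(ids, rownames(space$pc_scores))
    if (length(ids) < 2) dm_stop(sprintf("group '%s' has fewer than 2 specimens", g))
    if (m > length(ids) - 1L)
      dm_stop(sprintf("m = %d too large for group '%s' (n = %d)", m, g, length(ids)))
    S <- space$pc_scores[ids, seq_len(m), drop = FALSE]
    mu <- colMeans(S)
    V <- stats::cov(S)
    V <- (1 - lambda) * V + lambda * diag(diag(V), m)
    d <- focal_scores - mu
    out[g] <- sqrt(drop(t(d) %*% solve(V, d)))
  }
  attr(out, "m") <- m
  attr(out, "lambda") <- lambda
  out
}

#' Surface area of a mesh in cm^2
#'
#' Sum of triangle areas (half cross-product norms) over all faces; vertex
#' coordinates are mm, so mm^2 are divided by 100.
#'
#' @param mesh a [tri_mesh].
#' @return Scalar cm^2.
#' @export
surface_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(row_norms(cr)) / 2 / 100
}

#' Static allometry test: PC score against log surface area
#'
#' Least-squares regression of the PC score on natural-log surface area with
#' a two-sided Pearson correlation test: `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`. The signed correlation `r` is reported as such (together
#' with `r^2`), significance at `alpha = 0.05`.
#'
#' @param scores per-specimen PC score vector.
#' @param areas per-specimen surface areas (cm^2, > 0).
#' @param pc_index which PC the scores belong to (bookkeeping only).
#' @return An object of class `allometry_result`: `pc_index`, `df`,
#'   `t_value`, `correlation_r`, `r_squared`, `slope`, `intercept`,
#'   `residual_se`, `p_value`, `significant`.
#' @export
allometry_test <- function(scores, areas, pc_index = NA_integer_) {
  n <- length(scores)
  if (n < 3) dm_stop("allometry test needs n >= 3")
  if (length(areas) != n) dm_stop("scores/areas length mismatch")
  if (any(areas <= 0)) dm_stop("areas must be > 0")
  x <- log(areas)
  if (stats::sd(x) == 0 || stats::sd(scores) == 0)
    dm_stop("zero variance: correlation undefined")
  r <- stats::cor(x, scores)
  df <- n - 2L
  t <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(t), df)
  fit <- stats::lm.fit(cbind(1, x), scores)
  rss <- sum(fit$residuals^2)
  structure(list(pc_index = pc_index, df = df, t_value = t,
                 correlation_r = r, r_squared = r^2,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 residual_se = sqrt(rss / df), p_value = p,
                 significant = p <= 0.05),
            class = "allometry_result")
}

#' @export
print.allometry_result <- function(x, digits = 3, ...) {
  cat(sprintf(paste0("allometry PC%s: df=%d t=%.*f r=%.*f slope=%.3g ",
                     "resid.SE=%.*f p=%.*f%s\n"),
              ifelse(is.na(x$pc_index), "?", x$pc_index), x$df,
              digits, x$t_value, digits, x$correlation_r, x$slope,
              digits, x$residual_se, digits, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
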