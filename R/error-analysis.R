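# Observer-error quantification: landmark placement error and its
# propagation to registered-mesh correspondence.

#' Pairwise landmark placement error
#'
#' All pairwise per-landmark Euclidean distances between repeated landmark
#' sets of one specimen, labelled intra- or inter-observer from the
#' `observer_id` metadata, with per-landmark min/max/mean summaries.
#'
#' @param repeats list of >= 2 [landmark_set] objects with identical
#'   landmark names.
#' @return An object of class `landmark_error_table`: `rows` (landmark,
#'   set_a, set_b, type, distance) and `summary` (landmark, min, max, mean).
#' @export
landmark_error <- function(repeats) {
  if (length(repeats) < 2) dm_stop("need at least 2 repeated landmark sets")
  nm <- rownames(repeats[[1]]$points)
  for (s in repeats)
    if (!identical(sort(rownames(s$points)), sort(nm)))
      dm_stop("landmark names differ between repeats")
  pairs <- utils::combn(length(repeats), 2)
  rows <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    a <- repeats[[i]]; b <- repeats[[j]]
    d <- row_norms(a$points[nm, , drop = FALSE] - b$points[nm, , drop = FALSE])
    lab <- function(s) paste(s$observer_id, s$session_id, sep = "/")
    rows[[p]] <- data.frame(
      landmark = nm, set_a = lab(a), set_b = lab(b),
      type = if (identical(a$observer_id, b$observer_id)) "intra" else "inter",
      distance = d, stringsAsFactors = FALSE, row.names = NULL)
  }
  rows <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(rows$distance, rows$landmark), function(d)
    data.frame(min = min(d), max = max(d), mean = mean(d))))
  summ <- data.frame(landmark = rownames(summ), summ, row.names = NULL,
                     stringsAsFactors = FALSE)
  structure(list(rows = rows, summary = summ), class = "landmark_error_table")
}

#' @export
print.landmark_error_table <- function(x, digits = 3, ...) {
  s <- x$summary
  s$min <- round(s$min, digits); s$max <- round(s$max, digits)
  s$mean <- round(s$mean, digits)
  cat(sprintf("landmark_error_table: %d pairwise rows\n", nrow(x$rows)))
  print(s, row.names = FALSE)
  invisible(x)
}

#' Correspondence error across registered meshes
#'
#' For every unordered mesh pair and every corresponding vertex, the
#' Euclidean displacement; counts exceedances of `threshold` out of
#' `(pairs) x (vertices)` combinations and exports the per-vertex mean
#' displacement field for heat maps.
#'
#' @param meshes list of >= 2 registered meshes sharing vertex
#'   correspondence ([tri_mesh] objects or vertices x 3 matrices, equal
#'   vertex counts).
#' @param threshold exceedance threshold in mm (default 1, the conventional
#'   reporting threshold).
#' @return An object of class `correspondence_error_report`:
#'   `n_pairs_total`, `n_exceeding`, `percent_exceeding`,
#'   `mean_displacement`, `per_vertex_mean`, `threshold`.
#' @export
correspondence_error <- function(meshes, threshold = 1) {
  V <- lapply(meshes, function(m) if (inherits(m, "tri_mesh")) m$vertices
              else as.matrix(m))
  if (length(V) < 2) dm_stop("need at least 2 meshes")
  nv <- nrow(V[[1]])
  for (v in V) if (nrow(v) != nv) dm_stop("vertex counts differ between meshes")
  pairs <- utils::combn(length(V), 2)
  n_pairs <- ncol(pairs)
  n_exceed <- 0L
  total <- 0
  per_vertex <- numeric(nv)
  for (p in seq_len(n_pairs)) {
    d <- row_norms(V[[pairs[1, p]]] - V[[pairs[2, p]]])
    n_exceed <- n_exceed + sum(d > threshold)
    total <- total + sum(d)
    per_vertex <- per_vertex + d
  }
  n_pairs_total <- n_pairs * nv
  structure(list(n_pairs_total = n_pairs_total,
                 n_exceeding = as.integer(n_exceed),
                 percent_exceeding = 100 * n_exceed / n_pairs_total,
                 mean_displacement = total / n_pairs_total,
                 per_vertex_mean = per_vertex / n_pairs,
                 threshold = threshold),
            class = "correspondence_error_report")
}

#' @export
print.correspondence_error_report <- function(x, ...) {
  cat(sprintf(paste0("correspondence_error: %d of %d vertex-pair combinations ",
                     "(%.2f%%) exceed %.3g mm; mean displacement %.4g mm\n"),
              x$n_exceeding, x$n_pairs_total, x$percent_exceeding,
              x$threshold, x$mean_displacement))
  invisible(x)
}

#' Propagate landmark placement error through the surface registration
#'
#' Runs the full registration once per repeated landmark set — the specimen's
#' own mesh acts as the target every time, so the only varying input is the
#' landmark placement — and measures the correspondence error across the
#' resulting deformed meshes. This quantifies how strongly landmark
#' uncertainty leaks into the dense coordinates.
#'
#' @param mesh the specimen [tri_mesh] (used as registration reference and
#'   as every target).
#' @param repeats list of repeated [landmark_set] objects for this specimen
#'   (the first one doubles as the reference landmarks).
#' @param params an [icp_params].
#' @param k optional subsample size applied before the error measurement.
#' @param threshold exceedance threshold in mm.
#' @return A list with `report` (a `correspondence_error_report`), `sample`
#'   (the [registered_sample] across repeats) and `meshes` (per-repeat
#'   vertex matrices).
#' @export
propagate_landmark_error <- function(mesh, repeats, params = icp_params(),
                                     k = NULL, threshold = 1) {
  if (length(repeats) < 2) dm_stop("need at least 2 repeated landmark sets")
  targets <- lapply(repeats, function(lm) list(mesh = mesh, landmarks = lm))
  s <- register_sample(mesh, repeats[[1]], targets, params, k = k,
                       validate = FALSE)
  # drop row 1: the undeformed reference copy is not a repeat outcome
  reps <- lapply(seq_along(repeats) + 1L, function(i) s$coordinates[i, , ])
  list(report = correspondence_error(reps, threshold = threshold),
       sample = s, meshes = reps)
}

#' Export a per-vertex scalar field as a colored PLY heat map
#'
#' Writes the field as the PLY `quality` property together with an RGB ramp
#' (blue -> cyan -> yellow -> red over the field range), plus a sidecar JSON
#' recording the colormap limits.
#'
#' @param mesh a [tri_mesh].
#' @param field numeric per-vertex scalar, length = vertex count.
#' @param path output PLY path (sidecar written to `<path>.json`).
#' @param binary write binary little-endian PLY (default) or ASCII.
#' @param limits optional colormap limits `c(lo, hi)`; default field range.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(mesh, field, path, binary = TRUE, limits = NULL) {
  if (length(field) != nrow(mesh$vertices))
    dm_stop("field length must equal vertex count")
  if (is.null(limits)) limits <- range(field)
  span <- limits[2] - limits[1]
  t <- if (span > 0) pmin(1, pmax(0, (field - limits[1]) / span)) else
    rep(0, length(field))
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  rgb <- ramp(t)
  write_ply(mesh, path, binary = binary, quality = field,
            color = round(rgb))
  jsonlite::write_json(list(limits = limits, colormap = "blue-cyan-yellow-red",
                            n_vertices = nrow(mesh$vertices)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
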