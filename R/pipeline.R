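# Registered-sample persistence and the end-to-end pipeline.
#
# A registered sample is stored as a directory: manifest.json (ids, seeds,
# subsample indices, ICP parameters), faces.csv, and one coordinates CSV per
# specimen (vertex_index,x,y,z). Everything is plain text and bit-stable in
# deterministic mode, so a manifest plus the inputs regenerates every output.

sanitize_id <- function(id) gsub("[^A-Za-z0-9_.-]", "_", id)

#' Write a registered sample to a directory
#'
#' @param sample a [registered_sample].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_registered_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(reference_id = sample$reference_id,
                   specimen_ids = sample$specimen_ids,
                   seeds = sample$seeds,
                   subsample_indices = sample$subsample_indices,
                   params = unclass(sample$params),
                   n_vertices = dim(sample$coordinates)[2])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(sample$faces))
    write.csv(data.frame(v1 = sample$faces[, 1], v2 = sample$faces[, 2],
                         v3 = sample$faces[, 3]),
              file.path(dir, "faces.csv"), row.names = FALSE)
  for (i in seq_along(sample$specimen_ids)) {
    m <- sample$coordinates[i, , ]
    write.csv(data.frame(vertex_index = seq_len(nrow(m)),
                         x = m[, 1], y = m[, 2], z = m[, 3]),
              file.path(dir, sprintf("coords_%s.csv",
                                     sanitize_id(sample$specimen_ids[i]))),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a registered sample from a directory
#'
#' Inverse of [write_registered_sample()].
#' @param dir sample directory.
#' @return A [registered_sample].
#' @export
read_registered_sample <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) dm_stop(sprintf("no manifest.json in '%s'", dir))
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  ids <- man$specimen_ids
  nv <- man$n_vertices
  coords <- array(NA_real_, dim = c(length(ids), nv, 3))
  for (i in seq_along(ids)) {
    df <- read.csv(file.path(dir, sprintf("coords_%s.csv", sanitize_id(ids[i]))))
    coords[i, , ] <- as.matrix(df[order(df$vertex_index), c("x", "y", "z")])
  }
  faces <- NULL
  if (file.exists(file.path(dir, "faces.csv")))
    faces <- as.matrix(read.csv(file.path(dir, "faces.csv")))
  params <- man$params
  if (!is.null(params)) class(params) <- "icp_params"
  sub <- man$subsample_indices
  if (!is.null(sub) && !length(sub)) sub <- NULL
  registered_sample(man$reference_id, ids, coords, faces,
                    subsample_indices = sub,
                    seeds = if (is.null(man$seeds)) integer() else man$seeds,
                    params = params)
}

read_targets_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "mesh", "landmarks")
  miss <- setdiff(req, names(df))
  if (length(miss))
    dm_stop_validation(sprintf("targets manifest '%s' missing column(s): %s",
                               path, paste(miss, collapse = ", ")))
  df
}

load_targets <- function(manifest, base_dir = ".") {
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  lapply(seq_len(nrow(manifest)), function(i) {
    mesh <- load_mesh(resolve(manifest$mesh[i]),
                      specimen_id = manifest$specimen_id[i])
    sets <- load_landmarks(resolve(manifest$landmarks[i]))
    sets <- Filter(function(s) s$specimen_id == manifest$specimen_id[i], sets)
    if (!length(sets))
      dm_stop_validation(sprintf("no landmarks for specimen '%s'",
                                 manifest$specimen_id[i]))
    list(mesh = mesh, landmarks = sets[[1]])
  })
}

#' Assemble and validate a run configuration
#'
#' @param config a named list or a JSON file path. Recognized fields:
#'   `reference_mesh`, `reference_landmarks`, `targets_manifest`,
#'   `output_dir` (paths); `icp` (list of [icp_params()] arguments); `k`
#'   (subsample size or `NULL`); `analysis` (list: `focal`, `project_focal`,
#'   `m_pcs`, `shrinkage`, `threshold`); `reference_group`; `seed` (master
#'   seed).
#' @return An object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      dm_stop_validation(sprintf("config file not found: '%s'", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  for (f in c("reference_mesh", "reference_landmarks", "targets_manifest",
              "output_dir"))
    if (is.null(config[[f]]))
      dm_stop_validation(sprintf("config missing required field '%s'", f))
  for (f in c("reference_mesh", "reference_landmarks", "targets_manifest"))
    if (!file.exists(config[[f]]))
      dm_stop_validation(sprintf("config path '%s' does not exist: %s",
                                 f, config[[f]]))
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$analysis)) config$analysis <- list()
  if (is.null(config$reference_group)) config$reference_group <- "reference"
  structure(config, class = "run_config")
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the full pipeline: validate, register, subsample, GPA, PCA, reports
#'
#' Executes every stage on the configured inputs and writes all result
#' tables, warped shapes and plots plus a manifest enabling bit-reproduction
#' in deterministic mode into `output_dir`.
#'
#' @param config a [run_config()] input (list or JSON path).
#' @return The output directory, invisibly; the computed objects are
#'   attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out, "run.log"), "w")
  on.exit(close(logf))

  pipeline_log(logf, "validate", "loading and validating inputs")
  reference <- load_mesh(cfg$reference_mesh)
  ref_lms <- load_landmarks(cfg$reference_landmarks)[[1]]
  manifest <- read_targets_manifest(cfg$targets_manifest)
  targets <- load_targets(manifest, dirname(cfg$targets_manifest))
  vrep <- validate_single_layer(reference)
  if (!vrep$passed)
    dm_stop_validation(sprintf("reference '%s' failed mesh validation",
                               reference$specimen_id))
  for (t in targets) {
    vr <- validate_single_layer(t$mesh)
    if (!vr$passed)
      dm_stop_validation(sprintf("target '%s' failed mesh validation",
                                 t$mesh$specimen_id))
  }

  icp_args <- if (is.null(cfg$icp)) list() else cfg$icp
  icp_args$seed <- cfg$seed
  params <- do.call(icp_params, icp_args)

  pipeline_log(logf, "register",
               sprintf("registering %d targets (%d reference vertices)",
                       length(targets), nrow(reference$vertices)))
  sample <- register_sample(reference, ref_lms, targets, params,
                            k = cfg$k, validate = FALSE)
  write_registered_sample(sample, file.path(out, "sample"))

  pipeline_log(logf, "gpa", "superimposing")
  space <- gpa(sample)

  study <- data.frame(
    specimen_id = c(reference$specimen_id, manifest$specimen_id),
    group = c(cfg$reference_group,
              if ("group" %in% names(manifest)) manifest$group
              else rep("unassigned", nrow(manifest))),
    stringsAsFactors = FALSE)
  areas <- c(surface_area(reference),
             vapply(targets, function(t) surface_area(t$mesh), 0))
  study$surface_area_cm2 <- areas

  focal <- cfg$analysis$focal
  project_focal <- isTRUE(cfg$analysis$project_focal)
  fit_ids <- if (!is.null(focal) && project_focal)
    setdiff(space$specimen_ids, focal) else NULL
  pipeline_log(logf, "pca", "computing shape PCA")
  space <- pca_shape(space, fit_ids = fit_ids)

  write.csv(data.frame(specimen_id = rownames(space$pc_scores),
                       space$pc_scores, check.names = FALSE),
            file.path(out, "scores.csv"), row.names = FALSE)
  write.csv(data.frame(component = seq_along(space$variance_fraction),
                       sdev = space$pc_sdev,
                       variance_fraction = space$variance_fraction),
            file.path(out, "variance.csv"), row.names = FALSE)
  write.csv(study, file.path(out, "study.csv"), row.names = FALSE)

  projected <- NULL
  if (!is.null(focal) && project_focal) {
    projected <- list()
    projected[[focal]] <- project_specimen(space, focal)
  }

  n_pc_plot <- min(3L, ncol(space$pc_scores))
  alo <- do.call(rbind, lapply(seq_len(n_pc_plot), function(pc) {
    sc <- space$pc_scores[, pc]
    a <- allometry_test(sc, study$surface_area_cm2[
      match(rownames(space$pc_scores), study$specimen_id)], pc_index = pc)
    data.frame(pc = pc, df = a$df, t_value = a$t_value,
               correlation_r = a$correlation_r, r_squared = a$r_squared,
               slope = a$slope, residual_se = a$residual_se,
               p_value = a$p_value, significant = a$significant)
  }))
  write.csv(alo, file.path(out, "allometry.csv"), row.names = FALSE)

  if (!is.null(focal)) {
    pd <- pd_report(space, focal, study)
    write.csv(pd$rows, file.path(out, "pd_report.csv"), row.names = FALSE)
    write.csv(pd$group_stats, file.path(out, "pd_groups.csv"),
              row.names = FALSE)
    md <- tryCatch({
      m <- if (is.null(cfg$analysis$m_pcs)) 2L else as.integer(cfg$analysis$m_pcs)
      lam <- if (is.null(cfg$analysis$shrinkage)) 0.1 else cfg$analysis$shrinkage
      mahalanobis_to_groups(space, focal, study, m = m, lambda = lam)
    }, dm_error = function(e) {
      pipeline_log(logf, "analyze", paste("Mahalanobis skipped:",
                                          conditionMessage(e)))
      NULL
    })
    if (!is.null(md))
      write.csv(data.frame(group = names(md), mahalanobis = as.numeric(md),
                           m = attr(md, "m"), lambda = attr(md, "lambda")),
                file.path(out, "mahalanobis.csv"), row.names = FALSE)
  }

  pipeline_log(logf, "report", "writing warps and plots")
  warp_dir <- file.path(out, "warps")
  dir.create(warp_dir, showWarnings = FALSE)
  faces <- sample$faces
  for (pc in seq_len(n_pc_plot)) {
    for (mult in c(-2, 2)) {
      w <- warp_along_pc(space, pc, mult)
      wm <- if (is.null(faces)) NULL else
        tri_mesh(w, faces, sprintf("PC%d_%+dSD", pc, mult))
      if (!is.null(wm))
        save_mesh(wm, file.path(warp_dir, sprintf("pc%d_%s2sd.ply", pc,
                                                  if (mult > 0) "plus" else "minus")))
      else
        write.csv(data.frame(x = w[, 1], y = w[, 2], z = w[, 3]),
                  file.path(warp_dir, sprintf("pc%d_%s2sd.csv", pc,
                                              if (mult > 0) "plus" else "minus")),
                  row.names = FALSE)
    }
  }
  if (ncol(space$pc_scores) >= 2)
    plot_pc_scatter(space, study, c(1, 2), file.path(out, "pca_pc1_pc2.svg"),
                    projected = projected)
  if (ncol(space$pc_scores) >= 3) {
    plot_pc_scatter(space, study, c(1, 3), file.path(out, "pca_pc1_pc3.svg"),
                    projected = projected)
    export_scatter3d_html(space, study, file.path(out, "pca_3d.html"))
  }

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_file <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_file)
  run_manifest <- list(
    package = "densemorph",
    version = as.character(utils::packageVersion("densemorph")),
    seed = cfg$seed,
    per_specimen_seeds = sample$seeds,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = sort(setdiff(list.files(out, recursive = TRUE), "run.log")))
  jsonlite::write_json(run_manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log(logf, "done", sprintf("outputs in %s", out))
  res <- structure(out, results = list(sample = sample, space = space,
                                       study = study, allometry = alo))
  invisible(res)
}
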