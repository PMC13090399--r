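test_that("landmark_error computes labelled pairwise distances", {
  lms <- random_landmarks("e")
  same <- perturb_landmarks(lms, 0, 3, seed = 1, n_observers = 2)
  tab <- landmark_error(same)
  expect_true(all(tab$rows$distance == 0))
  expect_setequal(unique(tab$rows$type), c("intra", "inter"))

  shifted <- list(lms, lms)
  shifted[[2]]$points <- lms$points + rep(c(3, 0, 0), each = 6)
  t2 <- landmark_error(shifted)
  expect_equal(t2$rows$distance, rep(3, 6), tolerance = 1e-12)
  expect_equal(t2$summary$mean, rep(3, 6), tolerance = 1e-12)

  bad <- shifted
  rownames(bad[[2]]$points)[1] <- "elsewhere"
  expect_error(landmark_error(bad), "names differ")
})

test_that("mean pairwise landmark distance matches the Monte Carlo oracle", {
  lms <- random_landmarks("mc")
  reps <- perturb_landmarks(lms, sd = 1, n_repeats = 46, seed = 7,
                            n_observers = 2)
  tab <- landmark_error(reps)   # 1035 pairs x 6 landmarks
  # difference of two independent N(0, I3) draws ~ N(0, 2 I3):
  # E distance = sqrt(2) * sqrt(8 / pi)
  expected <- sqrt(2) * sqrt(8 / pi)
  expect_lt(abs(mean(tab$rows$distance) - expected) / expected, 0.05)
})

test_that("correspondence_error counts exceedances over pairs x vertices", {
  base <- matrix(rnorm(300), ncol = 3)
  same <- list(base, base, base)
  r0 <- correspondence_error(same)
  expect_equal(r0$percent_exceeding, 0)
  expect_equal(r0$mean_displacement, 0)
  expect_equal(r0$n_pairs_total, 3L * 100L)

  moved <- base
  moved[17, ] <- moved[17, ] + c(2, 0, 0)
  r1 <- correspondence_error(list(base, moved), threshold = 1)
  expect_equal(r1$n_exceeding, 1L)
  expect_equal(r1$n_pairs_total, 100L)
  expect_equal(r1$percent_exceeding, 1)
  expect_equal(r1$per_vertex_mean[17], 2)
  expect_error(correspondence_error(list(base, moved[1:50, ])),
               "vertex counts differ")
})

test_that("the printed error arithmetic reproduces: 36/1500 and 673/77355", {
  # 6 meshes x 100 vertices -> 15 pairs x 100 = 1,500 combinations; engineer
  # exactly 36 exceedances: 4 vertices displaced in one mesh (4 x 5 pairs)
  # + 2 vertices displaced identically in two meshes (2 x 8 pairs)
  build <- function(nv, n_single, n_double) {
    base <- matrix(0, nv, 3)
    meshes <- replicate(6, base, simplify = FALSE)
    for (v in seq_len(n_single)) meshes[[1]][v, 1] <- 2
    for (v in seq_len(n_double)) {
      meshes[[2]][n_single + v, 1] <- 2
      meshes[[3]][n_single + v, 1] <- 2
    }
    meshes
  }
  r <- correspondence_error(build(100, 4, 2), threshold = 1)
  expect_equal(r$n_pairs_total, 1500L)
  expect_equal(r$n_exceeding, 36L)
  expect_equal(round(r$percent_exceeding, 1), 2.4)

  # 6 meshes x 5157 vertices -> 77,355 combinations; 673 = 133 x 5 + 1 x 8
  r2 <- correspondence_error(build(5157, 133, 1), threshold = 1)
  expect_equal(r2$n_pairs_total, 77355L)
  expect_equal(r2$n_exceeding, 673L)
  expect_equal(round(r2$percent_exceeding, 2), 0.87)
})

test_that("landmark error grows with noise and propagation stays bounded", {
  tpl <- make_template(shape_params(), 400, "prop")
  means <- vapply(c(0.2, 0.6, 1.2), function(s) {
    mean(landmark_error(perturb_landmarks(tpl$landmarks, s, 12,
                                          seed = 5))$rows$distance)
  }, 0)
  expect_true(all(diff(means) > 0))

  # propagation: registration from noisy landmark repeats of one specimen;
  # correspondence error bounded by the landmark error itself, and
  # concentrated at the mesh boundary
  reps <- perturb_landmarks(tpl$landmarks, sd = 0.5, n_repeats = 4, seed = 3,
                            n_observers = 2)
  prop <- propagate_landmark_error(tpl$mesh, reps,
                                   params = icp_params(n_iterations = 30))
  lm_err <- mean(landmark_error(reps)$rows$distance)
  expect_lt(prop$report$mean_displacement, lm_err)
  bd <- boundary_vertices(tpl$mesh)
  interior <- setdiff(seq_len(nrow(tpl$mesh$vertices)), bd)
  expect_gt(mean(prop$report$per_vertex_mean[bd]),
            mean(prop$report$per_vertex_mean[interior]))
})

test_that("export_heatmap writes quality values that round-trip", {
  tpl <- make_template(shape_params(), 120, "heat")
  field <- seq(0, 2, length.out = nrow(tpl$mesh$vertices))
  path <- tempfile(fileext = ".ply")
  export_heatmap(tpl$mesh, field, path)
  back <- load_mesh(path)
  expect_lt(max(abs(attr(back, "quality") - field)), 1e-6)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(sidecar$limits, c(0, 2))
  # constant field: uniform color (header contains RGB; all rows equal)
  path2 <- tempfile(fileext = ".ply")
  export_heatmap(tpl$mesh, rep(1, nrow(tpl$mesh$vertices)), path2,
                 binary = FALSE, limits = c(0, 2))
  txt <- readLines(path2)
  body <- txt[(which(txt == "end_header") + 1):(which(txt == "end_header") +
                                                  nrow(tpl$mesh$vertices))]
  cols <- unique(vapply(strsplit(body, " "),
                        function(x) paste(tail(x, 3), collapse = " "), ""))
  expect_length(cols, 1L)
  expect_error(export_heatmap(tpl$mesh, field[-1], tempfile()), "length")
  unlink(c(path, paste0(path, ".json"), path2))
})
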