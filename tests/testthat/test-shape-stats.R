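make_config_sample <- function(n = 6, p = 60, noise = 0.3, seed = 1) {
  set.seed(seed)
  base <- make_template(shape_params(), p)$mesh$vertices
  coords <- array(NA_real_, c(n, nrow(base), 3))
  for (i in seq_len(n))
    coords[i, , ] <- base + matrix(rnorm(length(base), 0, noise), ncol = 3)
  coords
}

rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

test_that("GPA superimposes exactly and is invariant to similarity transforms", {
  coords <- make_config_sample()
  n <- dim(coords)[1]
  sp <- gpa(coords)
  for (i in seq_len(n)) {
    cfg <- sp$procrustes_coords[i, , ]
    expect_lt(max(abs(colMeans(cfg))), 1e-9)
    expect_equal(centroid_size(cfg), 1, tolerance = 1e-9)
  }
  # a rotated/translated/scaled copy of a shape superimposes onto it
  pair <- coords[1:2, , ]
  pair[2, , ] <- 1.7 * coords[1, , ] %*% rand_rotation() +
    rep(c(3, -2, 8), each = dim(coords)[2])
  sp_pair <- gpa(pair)
  expect_lt(max(abs(sp_pair$procrustes_coords[1, , ] -
                      sp_pair$procrustes_coords[2, , ])), 1e-8)

  # full invariance: transforming any input leaves all outputs unchanged
  set.seed(8)
  coords2 <- coords
  for (i in c(1, 4)) {
    coords2[i, , ] <- runif(1, 0.5, 3) * coords[i, , ] %*% rand_rotation() +
      rep(rnorm(3, 0, 10), each = dim(coords)[2])
  }
  sp2 <- gpa(coords2)
  expect_lt(max(abs(sp$procrustes_coords - sp2$procrustes_coords)), 1e-8)
  expect_lt(max(abs(sp$mean_shape - sp2$mean_shape)), 1e-8)

  degenerate <- coords
  degenerate[3, , ] <- 1
  expect_error(gpa(degenerate), "spec03")
})

test_that("two-configuration GPA matches the one-shot full Procrustes oracle", {
  coords <- make_config_sample(n = 2, noise = 0.8, seed = 4)
  sp <- gpa(coords)
  d_gpa <- procrustes_distance(sp$procrustes_coords[1, , ],
                               sp$procrustes_coords[2, , ])
  d_oracle <- full_procrustes_distance(coords[1, , ], coords[2, , ])
  expect_equal(d_gpa, d_oracle, tolerance = 1e-6)
})

test_that("shape PCA: variance fractions, reconstruction, projection, warps", {
  coords <- make_config_sample(n = 8, seed = 2)
  sp <- pca_shape(gpa(coords))
  expect_equal(sum(sp$variance_fraction), 1, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(sp$pc_scores))), 1e-9)

  # reconstruction identity
  for (i in c(1, 5)) {
    rec <- sp$pca_center + drop(sp$pc_scores[i, ] %*% sp$pc_vectors)
    expect_lt(max(abs(rec - as.vector(t(sp$procrustes_coords[i, , ])))), 1e-8)
  }
  # projecting a fit specimen returns its own scores; the mean projects to 0
  expect_lt(max(abs(project_specimen(sp, sp$procrustes_coords[3, , ]) -
                      sp$pc_scores[3, ])), 1e-9)
  ctr_cfg <- matrix(sp$pca_center, ncol = 3, byrow = TRUE)
  expect_lt(max(abs(project_specimen(sp, ctr_cfg))), 1e-9)

  # warps: multiplier 0 gives the mean; +2/-2 symmetric about it
  w0 <- warp_along_pc(sp, 1, 0)
  expect_equal(w0, matrix(sp$pca_center, ncol = 3, byrow = TRUE),
               tolerance = 1e-12)
  wp <- warp_along_pc(sp, 1, 2); wm <- warp_along_pc(sp, 1, -2)
  expect_lt(max(abs((wp + wm) / 2 - w0)), 1e-9)
  # a specimen's standardized score reproduces its PC1-truncated reconstruction
  z <- sp$pc_scores[2, 1] / sd(sp$pc_scores[, 1])
  w2 <- warp_along_pc(sp, 1, z)
  trunc <- sp$pca_center + sp$pc_scores[2, 1] * sp$pc_vectors[1, ]
  expect_lt(max(abs(as.vector(t(w2)) - trunc)), 1e-9)

  # single deformation direction: PC1 carries all variance (built directly
  # in shape space; GPA re-superimposition would bend a linear family into
  # a curve and is not what this identity is about)
  base <- sp$mean_shape
  dir <- matrix(rnorm(length(base)), ncol = 3)
  one <- array(NA_real_, c(5, nrow(base), 3))
  for (i in 1:5) one[i, , ] <- base + (i - 3) * 0.05 * dir
  linear_space <- structure(list(procrustes_coords = one,
                                 specimen_ids = paste0("s", 1:5)),
                            class = "shape_space")
  sp1 <- pca_shape(linear_space)
  expect_gt(sp1$variance_fraction[1], 1 - 1e-9)

  # held-out specimen from the fit distribution lands inside the fit range
  coords9 <- make_config_sample(n = 9, seed = 3)
  sp9 <- gpa(coords9)
  ids <- sp9$specimen_ids
  sp9 <- pca_shape(sp9, fit_ids = ids[1:8])
  held <- project_specimen(sp9, ids[9])
  for (pc in 1:3) {
    rng <- range(sp9$pc_scores[, pc])
    pad <- diff(rng)  # generous: same distribution, small n
    expect_gt(held[pc], rng[1] - pad)
    expect_lt(held[pc], rng[2] + pad)
  }
})

test_that("PCA on the k = n subsample equals the unsubsampled PCA up to sign", {
  ref <- make_template(shape_params(), 150, "ref")
  targets <- lapply(1:3, function(i) {
    t <- make_template(shape_params(brow_prominence = i), 150, paste0("t", i))
    list(mesh = t$mesh, landmarks = t$landmarks)
  })
  s <- register_sample(ref$mesh, ref$landmarks, targets,
                       icp_params(n_iterations = 8, seed = 2))
  full <- pca_shape(gpa(s))
  sub <- pca_shape(gpa(subsample_registered(s, dim(s$coordinates)[2], seed = 1)))
  for (j in seq_len(ncol(full$pc_scores))) {
    sgn <- sign(sum(full$pc_scores[, j] * sub$pc_scores[, j]))
    expect_equal(full$pc_scores[, j], sgn * sub$pc_scores[, j],
                 tolerance = 1e-8)
  }
})

test_that("procrustes_distance is a metric on the common superimposition", {
  a <- matrix(rnorm(12), 4)
  b <- matrix(rnorm(12), 4)
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  # hand computation on a 4-point toy pair
  expect_equal(procrustes_distance(a, b), sqrt(sum((a - b)^2)))
  expect_error(procrustes_distance(a, b[1:3, ]), "vertex count")
})

test_that("pd_report sorts within groups and summarizes", {
  coords <- make_config_sample(n = 7, seed = 5)
  sp <- gpa(coords)
  study <- data.frame(specimen_id = sp$specimen_ids,
                      group = c("X", "X", "X", "Y", "Y", "Y", "Y"))
  rep <- pd_report(sp, sp$specimen_ids[1], study)
  expect_false(sp$specimen_ids[1] %in% rep$rows$specimen_id)
  expect_equal(nrow(rep$rows), 6L)
  for (g in unique(rep$rows$group))
    expect_false(is.unsorted(rep$rows$pd[rep$rows$group == g]))
  gm <- rep$group_stats
  for (g in gm$group) {
    v <- rep$rows$pd[rep$rows$group == g]
    expect_equal(gm$mean[gm$group == g], mean(v))
    expect_equal(gm$sd[gm$group == g], sd(v))
  }
  expect_error(pd_report(sp, "nope", study), "unknown focal")
})

test_that("mahalanobis_to_groups matches the manual quadratic form", {
  coords <- make_config_sample(n = 11, seed = 6)
  sp <- pca_shape(gpa(coords))
  ids <- sp$specimen_ids
  study <- data.frame(specimen_id = ids,
                      group = c("F", rep("P", 5), rep("Q", 5)))
  md <- mahalanobis_to_groups(sp, ids[1], study, m = 2, lambda = 0.1)
  # manual recomputation
  for (g in c("P", "Q")) {
    S <- sp$pc_scores[study$specimen_id[study$group == g], 1:2]
    V <- cov(S); V <- 0.9 * V + 0.1 * diag(diag(V), 2)
    d <- sp$pc_scores[ids[1], 1:2] - colMeans(S)
    expect_equal(unname(md[g]), sqrt(drop(t(d) %*% solve(V) %*% d)),
                 tolerance = 1e-12)
  }
  # focal at a group's mean has distance 0 to it (construct via lambda = 0
  # on a 2D toy with forced identity covariance -> Euclidean distance)
  toy <- list(pc_scores = rbind(F = c(1, 2), A1 = c(0, 0), A2 = c(2, 0),
                                A3 = c(0, 4), A4 = c(2, 4)),
              specimen_ids = c("F", "A1", "A2", "A3", "A4"),
              pc_vectors = diag(2), pca_center = c(0, 0))
  class(toy) <- "shape_space"
  st <- data.frame(specimen_id = toy$specimen_ids,
                   group = c("F", "A", "A", "A", "A"))
  md0 <- mahalanobis_to_groups(toy, "F", st, m = 2, lambda = 1)
  # group mean (1,2) == focal, shrunk-to-diagonal covariance stays PD
  expect_equal(unname(md0["A"]), 0)
  expect_error(mahalanobis_to_groups(sp, ids[1], study, m = 10), "too large")
})

test_that("surface_area sums triangle areas in cm^2", {
  tri <- tri_mesh(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                  rbind(c(1, 2, 3)), "tri")
  expect_equal(surface_area(tri), 0.5)
  tpl <- make_template(shape_params(), 200)$mesh
  s <- tpl; s$vertices <- 3 * s$vertices
  expect_equal(surface_area(s), 9 * surface_area(tpl), tolerance = 1e-9)
  # independent per-face summation oracle
  oracle <- sum(vapply(seq_len(nrow(tpl$faces)), function(i) {
    v <- tpl$vertices[tpl$faces[i, ], ]
    u <- v[2, ] - v[1, ]; w <- v[3, ] - v[1, ]
    sqrt(sum(c(u[2]*w[3]-u[3]*w[2], u[3]*w[1]-u[1]*w[3],
               u[1]*w[2]-u[2]*w[1])^2)) / 2
  }, 0)) / 100
  expect_equal(surface_area(tpl), oracle, tolerance = 1e-9)
})

test_that("allometry_test matches the analytic t <-> r identity", {
  set.seed(9)
  areas <- exp(rnorm(45, log(120), 0.2))
  scores <- 2 * log(areas)
  perfect <- allometry_test(scores, areas)
  expect_equal(perfect$df, 43L)           # n = 45 -> df = 43
  expect_equal(perfect$correlation_r, 1, tolerance = 1e-12)
  expect_lt(perfect$residual_se, 1e-12)
  expect_equal(perfect$slope, 2, tolerance = 1e-9)

  noisy <- scores + rnorm(45, 0, 3)
  a <- allometry_test(noisy, areas, pc_index = 1)
  r <- cor(log(areas), noisy)
  t <- r * sqrt(43 / (1 - r^2))
  expect_equal(a$t_value, t, tolerance = 1e-12)
  expect_equal(a$p_value, 2 * pt(-abs(t), 43), tolerance = 1e-12)
  expect_identical(a$significant, a$p_value <= 0.05)
  expect_error(allometry_test(rep(1, 10), areas[1:10]), "zero variance")
})
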