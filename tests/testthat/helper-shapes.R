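# Shared fixtures and independent oracles, all built in code.

# regular tetrahedron: 4 vertices, 4 faces, closed manifold
tetrahedron <- function(scale = 10) {
  v <- scale * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 2), c(1, 3, 4), c(2, 4, 3))
  tri_mesh(v, f, "tetra")
}

# random 6-landmark set in general position (non-coplanar by construction)
random_landmarks <- function(id = "rand", jitter = 0) {
  tpl <- make_template(shape_params(), 60, id)
  lms <- tpl$landmarks
  if (jitter > 0)
    lms$points <- lms$points + matrix(rnorm(18, 0, jitter), 6, 3)
  lms
}

# exact point-to-triangle distance: independent R implementation used as the
# brute-force oracle for the accelerated C++ closest-point search
pt_tri_dist <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(sqrt(sum((p - a)^2)))
  bp <- p - b; d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(sqrt(sum((p - b)^2)))
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    pt <- a + (d1 / (d1 - d3)) * ab
    return(sqrt(sum((p - pt)^2)))
  }
  cp <- p - cc; d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(sqrt(sum((p - cc)^2)))
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    pt <- a + (d2 / (d2 - d6)) * ac
    return(sqrt(sum((p - pt)^2)))
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    pt <- b + w * (cc - b)
    return(sqrt(sum((p - pt)^2)))
  }
  den <- va + vb + vc
  pt <- a + ab * (vb / den) + ac * (vc / den)
  sqrt(sum((p - pt)^2))
}

brute_force_closest <- function(q, mesh) {
  min(vapply(seq_len(nrow(mesh$faces)), function(i) {
    f <- mesh$faces[i, ]
    pt_tri_dist(q, mesh$vertices[f[1], ], mesh$vertices[f[2], ],
                mesh$vertices[f[3], ])
  }, 0))
}

# exhaustive k-means oracle: global minimum inertia over all assignments
exhaustive_kmeans_inertia <- function(pts, k) {
  n <- nrow(pts)
  best <- Inf
  assign_next <- function(assignment, i) {
    if (i > n) {
      if (length(unique(assignment)) < k) return(invisible())
      inertia <- 0
      for (g in unique(assignment)) {
        m <- pts[assignment == g, , drop = FALSE]
        ctr <- colMeans(m)
        inertia <- inertia + sum(sweep(m, 2, ctr)^2)
      }
      if (inertia < best) best <<- inertia
      return(invisible())
    }
    # canonical labelling avoids counting permutations of the same partition
    for (g in seq_len(min(k, max(assignment[seq_len(i - 1)], 0) + 1L))) {
      assignment[i] <- g
      assign_next(assignment, i + 1L)
    }
  }
  assign_next(integer(n), 1L)
  best
}

# two-group population spec used by the group-recovery experiments:
# groups differ ONLY in mean brow prominence, by 4 within-group brow SD
two_group_spec <- function(seed, n_per_group = 10, resolution = 350) {
  groups <- list(
    list(label = "A", mean = shape_params(squama_inclination = 0.3,
                                          brow_prominence = 1.0),
         sd = list(squama_inclination = 0.02, brow_prominence = 0.5,
                   size_scale = 0.05), n = n_per_group),
    list(label = "B", mean = shape_params(squama_inclination = 0.3,
                                          brow_prominence = 3.0),
         sd = list(squama_inclination = 0.02, brow_prominence = 0.5,
                   size_scale = 0.05), n = n_per_group))
  population_spec(groups, mesh_resolution = resolution, seed = seed)
}

# one seed of the group-recovery experiment: simulate 2x10 + a held-out focal
# from group A, register everything onto a mid-way reference template,
# subsample to k = 100, GPA + PCA. Returns what the assertions need.
group_recovery_experiment <- function(seed, icp_iterations = 30) {
  spec <- two_group_spec(seed)
  pop <- sample_population(spec)
  fspec <- population_spec(list(spec$groups[[1]]), mesh_resolution = 350,
                           seed = seed + 10000L)
  fp <- sample_population(fspec)
  fm <- fp$meshes[[1]]; fm$specimen_id <- "focal"
  fl <- fp$landmarks[[1]]; fl$specimen_id <- "focal"
  ref <- make_template(shape_params(squama_inclination = 0.3,
                                    brow_prominence = 2.0), 350, "ref")
  targets <- c(mapply(function(m, l) list(list(mesh = m, landmarks = l)),
                      pop$meshes, pop$landmarks),
               list(list(mesh = fm, landmarks = fl)))
  s <- register_sample(ref$mesh, ref$landmarks, targets,
                       icp_params(n_iterations = icp_iterations, seed = seed),
                       k = 100, validate = FALSE)
  sp <- pca_shape(gpa(s))
  study <- rbind(data.frame(specimen_id = "ref", group = "ref"),
                 pop$study[, c("specimen_id", "group")],
                 data.frame(specimen_id = "focal", group = "A"))
  sc <- sp$pc_scores[, 1]
  grp <- study$group[match(rownames(sp$pc_scores), study$specimen_id)]
  a <- sc[grp == "A" & rownames(sp$pc_scores) != "focal"]
  b <- sc[grp == "B"]
  pd <- pd_report(sp, "focal", study)
  # the undeformed reference is registration infrastructure, not one of the
  # 2 x 10 experimental specimens: exclude it from the nearest-PD candidates
  pdr <- pd$rows[pd$rows$group %in% c("A", "B"), ]
  list(space = sp, study = study,
       hulls_disjoint = max(min(a), min(b)) > min(max(a), max(b)),
       nearest_group = pdr$group[which.min(pdr$pd)])
}
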