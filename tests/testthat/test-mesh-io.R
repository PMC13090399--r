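test_that("meshes round-trip through PLY/OBJ/STL within 1e-6 mm", {
  set.seed(42)
  tpl <- make_template(shape_params(), 120, "rt")
  mesh <- tpl$mesh
  mesh$vertices <- mesh$vertices + matrix(rnorm(length(mesh$vertices), 0, 0.01),
                                          ncol = 3)
  for (case in list(c("ply", TRUE), c("ply", FALSE), c("obj", FALSE),
                    c("stl", TRUE), c("stl", FALSE))) {
    fmt <- case[1]; binary <- as.logical(case[2])
    path <- tempfile(fileext = paste0(".", fmt))
    save_mesh(mesh, path, binary = binary)
    back <- load_mesh(path)
    expect_equal(nrow(back$vertices), nrow(mesh$vertices),
                 info = paste(fmt, binary))
    expect_equal(nrow(back$faces), nrow(mesh$faces), info = paste(fmt, binary))
    # STL loses shared-vertex ordering (and binary STL stores float32, a
    # ~4e-6 mm quantization at this coordinate scale); match by nearest
    # vertex instead of by index
    if (fmt == "stl") {
      tol <- if (binary) 1e-5 else 1e-6
      cross <- outer(rowSums(back$vertices^2), rowSums(mesh$vertices^2), "+") -
        2 * back$vertices %*% t(mesh$vertices)
      expect_lt(max(sqrt(pmax(apply(cross, 1, min), 0))), tol)
    } else {
      expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
      expect_identical(back$faces, mesh$faces)
    }
    unlink(path)
  }
})

test_that("OBJ 1-based indices normalize to the same mesh as PLY", {
  tet <- tetrahedron()
  p1 <- tempfile(fileext = ".ply"); p2 <- tempfile(fileext = ".obj")
  save_mesh(tet, p1, binary = FALSE)
  save_mesh(tet, p2)
  m1 <- load_mesh(p1); m2 <- load_mesh(p2)
  expect_equal(m1$vertices, m2$vertices, tolerance = 1e-12)
  expect_identical(m1$faces, m2$faces)
  expect_equal(nrow(m1$vertices), 4L)
  expect_equal(nrow(m1$faces), 4L)
  unlink(c(p1, p2))
})

test_that("non-triangular faces are rejected with the face named", {
  quad_obj <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"),
             quad_obj)
  expect_error(load_mesh(quad_obj), "non-triangular face at row 1")
  quad_ply <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0", "element vertex 4",
               "property double x", "property double y", "property double z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header", "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3"),
             quad_ply)
  expect_error(load_mesh(quad_ply), "non-triangular face at row 1")
  unlink(c(quad_obj, quad_ply))
})

test_that("validate_single_layer classifies topology", {
  tpl <- make_template(shape_params(), 150, "patch")
  rep <- validate_single_layer(tpl$mesh)   # open hemisphere-like patch
  expect_true(rep$passed)
  expect_equal(rep$connected_components, 1L)
  expect_equal(rep$nonmanifold_edges, 0L)
  expect_equal(rep$boundary_loops, 1L)

  two <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                        c(5, 5, 5), c(6, 5, 5), c(5, 6, 5)),
                  rbind(c(1, 2, 3), c(4, 5, 6)), "two")
  rep2 <- validate_single_layer(two)
  expect_equal(rep2$connected_components, 2L)
  expect_false(rep2$passed)

  dup <- tetrahedron()
  dup$faces <- rbind(dup$faces, dup$faces[1, c(2, 1, 3)])
  rep3 <- validate_single_layer(dup)
  expect_equal(rep3$duplicate_faces, 1L)
  expect_false(rep3$passed)
  # the duplicated face also makes its three edges non-manifold
  expect_equal(rep3$nonmanifold_edges, 3L)
})

test_that("extract_submesh keeps only fully-retained faces, reindexed", {
  tet <- tetrahedron()
  all_kept <- extract_submesh(tet, 1:4)
  expect_equal(all_kept$vertices, tet$vertices)
  expect_identical(all_kept$faces, tet$faces)

  tri <- extract_submesh(tet, c(1, 2, 3))
  expect_equal(nrow(tri$vertices), 3L)
  expect_equal(nrow(tri$faces), 1L)

  set.seed(7)
  tpl <- make_template(shape_params(), 300, "half")
  keep <- sort(sample(nrow(tpl$mesh$vertices),
                      nrow(tpl$mesh$vertices) %/% 2))
  sub <- extract_submesh(tpl$mesh, keep)
  # no dangling indices, and every face's original vertices were kept
  expect_true(all(sub$faces >= 1 & sub$faces <= nrow(sub$vertices)))
  map <- attr(sub, "vertex_map")
  orig <- matrix(match(sub$faces, map[keep]), ncol = 3)  # identity check
  expect_true(all(matrix(keep[sub$faces], ncol = 3) %in% keep))
  expect_error(extract_submesh(tet, integer()), "non-empty")
})

test_that("reflect_across_plane is an isometric involution", {
  tet <- tetrahedron()
  # axis-aligned case: plane z = 0
  r <- reflect_across_plane(tri_mesh(rbind(c(2, 3, 5)), matrix(integer(), 0, 3)),
                            c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(r$vertices[1, ], c(2, 3, -5), tolerance = 1e-12)

  set.seed(3)
  p1 <- rnorm(3); p2 <- rnorm(3); p3 <- rnorm(3)
  refl <- reflect_across_plane(tet, p1, p2, p3)
  # vertex on the plane maps to itself
  onplane <- tri_mesh(rbind(p1, (p1 + p2) / 2), matrix(integer(), 0, 3))
  r2 <- reflect_across_plane(onplane, p1, p2, p3)
  expect_lt(max(abs(r2$vertices - onplane$vertices)), 1e-9)
  # involution
  back <- reflect_across_plane(refl, p1, p2, p3)
  expect_lt(max(abs(back$vertices - tet$vertices)), 1e-9)
  # isometry: all pairwise distances preserved
  expect_equal(as.vector(dist(refl$vertices)), as.vector(dist(tet$vertices)),
               tolerance = 1e-9)
  # face orientation flipped
  expect_identical(refl$faces[, 2], tet$faces[, 3])
  expect_error(reflect_across_plane(tet, c(0, 0, 0), c(1, 1, 1), c(2, 2, 2)),
               "collinear")
})

test_that("landmark CSV round-trips and missing landmarks are named", {
  lms <- random_landmarks("spec1")
  path <- tempfile(fileext = ".csv")
  save_landmarks(lms, path)
  back <- load_landmarks(path)
  expect_length(back, 1L)
  expect_equal(back[[1]]$points, lms$points, tolerance = 1e-12)
  expect_identical(rownames(back[[1]]$points), REGISTRATION_LANDMARKS)

  df <- read.csv(path)
  df <- df[df$landmark != "ophryon", ]
  write.csv(df, path, row.names = FALSE)
  short <- load_landmarks(path)[[1]]
  expect_error(validate_registration_landmarks(short), "ophryon")
  unlink(path)
})

test_that("plain-text landmark converter reads name x y z lines", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# comment", "bregma 1 2 3", "ophryon 4 5 6.5"), path)
  lm <- convert_landmark_text(path, "t")
  expect_equal(lm$points["ophryon", ], c(x = 4, y = 5, z = 6.5),
               ignore_attr = TRUE)
  unlink(path)
})

test_that("coplanar or coincident registration landmarks are rejected", {
  pts <- cbind(matrix(rnorm(12), 6, 2), 0)  # all in z = 0 plane
  rownames(pts) <- REGISTRATION_LANDMARKS
  expect_error(validate_registration_landmarks(landmark_set(pts, "flat")),
               "coplanar")
  lms <- random_landmarks("dup")
  lms$points[2, ] <- lms$points[1, ]
  expect_error(validate_registration_landmarks(lms), "coincident")
})
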