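# Mesh and landmark containers + file formats (PLY / OBJ / STL, landmark CSV).
#
# Face indices are 1-based internally (the R convention); 0-based dialects
# (PLY, STL) are converted at the file boundary. Coordinates are millimetres
# and pass through unmodified.

#' Canonical registration landmark names
#'
#' The six landmarks required for the initial thin-plate-spline registration,
#' in canonical order: bregma, ophryon, left/right frontotemporale and
#' left/right stephanion.
#' @export
REGISTRATION_LANDMARKS <- c("bregma", "ophryon",
                            "frontotemporale_L", "frontotemporale_R",
                            "stephanion_L", "stephanion_R")

#' Triangular surface mesh
#'
#' @param vertices numeric matrix, n x 3, coordinates in mm.
#' @param faces integer matrix, m x 3, 1-based vertex indices.
#' @param specimen_id character identifier.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, specimen_id = "unnamed") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) dm_stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L) dm_stop("faces must be an m x 3 matrix")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      dm_stop("face index out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      dm_stop("a face repeats a vertex")
  }
  structure(list(specimen_id = as.character(specimen_id),
                 vertices = vertices, faces = faces),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh '%s': %d vertices, %d faces\n",
              x$specimen_id, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Named landmark set
#'
#' @param points numeric matrix, k x 3, with rownames giving landmark names.
#' @param specimen_id,observer_id,session_id identifiers (the latter two
#'   optional, used by the observer-error tools).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, specimen_id = "unnamed",
                         observer_id = NA_character_,
                         session_id = NA_character_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) dm_stop("landmark points must be k x 3")
  if (is.null(rownames(points))) dm_stop("landmark points need rownames")
  structure(list(specimen_id = as.character(specimen_id),
                 points = points,
                 observer_id = as.character(observer_id),
                 session_id = as.character(session_id)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set '%s' (%d landmarks)\n",
              x$specimen_id, nrow(x$points)))
  invisible(x)
}

#' Check a landmark set for use in registration
#'
#' Requires exactly the six canonical landmarks (any order in the input;
#' reordered canonically), no coincident points, and non-coplanar geometry
#' (a 3D thin-plate spline is singular on coplanar controls).
#'
#' @param lms a [landmark_set].
#' @param tol coplanarity tolerance on the smallest singular value of the
#'   centered configuration, relative to the largest.
#' @return The landmark set with rows in canonical order (invisibly errors on
#'   failure).
#' @export
validate_registration_landmarks <- function(lms, tol = 1e-6) {
  nm <- rownames(lms$points)
  missing <- setdiff(REGISTRATION_LANDMARKS, nm)
  if (length(missing))
    dm_stop_validation(sprintf("specimen '%s': missing registration landmark(s): %s",
                               lms$specimen_id, paste(missing, collapse = ", ")))
  pts <- lms$points[REGISTRATION_LANDMARKS, , drop = FALSE]
  if (anyDuplicated(round(pts, 12)))
    dm_stop_validation(sprintf("specimen '%s': coincident landmarks", lms$specimen_id))
  ctr <- sweep(pts, 2, colMeans(pts))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < tol * sv[1])
    dm_stop_validation(sprintf("specimen '%s': landmarks are (near-)coplanar",
                               lms$specimen_id))
  lms$points <- pts
  lms
}

# ---- format detection ----

guess_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "stl")) return(ext)
  dm_stop(sprintf("cannot guess mesh format of '%s'; pass fmt explicitly", path))
}

#' Read a triangular mesh (PLY, OBJ or STL)
#'
#' ASCII and binary PLY/STL are accepted; OBJ is ASCII. All faces must be
#' triangles. Indices are normalized to the internal 1-based convention.
#'
#' @param path file path.
#' @param fmt `"auto"` (by extension), `"ply"`, `"obj"` or `"stl"`.
#' @param specimen_id identifier stored on the mesh; defaults to the file
#'   base name.
#' @return A [tri_mesh]. For PLY files carrying a per-vertex `quality`
#'   property the values are attached as attribute `"quality"`.
#' @export
load_mesh <- function(path, fmt = "auto", specimen_id = NULL) {
  if (!file.exists(path)) dm_stop(sprintf("mesh file not found: '%s'", path))
  if (identical(fmt, "auto")) fmt <- guess_mesh_format(path)
  if (is.null(specimen_id))
    specimen_id <- tools::file_path_sans_ext(basename(path))
  switch(fmt,
         ply = read_ply(path, specimen_id),
         obj = read_obj(path, specimen_id),
         stl = read_stl(path, specimen_id),
         dm_stop(sprintf("unknown mesh format '%s'", fmt)))
}

#' Write a triangular mesh (PLY, OBJ or STL)
#'
#' @param mesh a [tri_mesh].
#' @param path output path; format guessed from the extension unless given.
#' @param fmt `"auto"`, `"ply"`, `"obj"` or `"stl"`.
#' @param binary for PLY/STL: write binary little-endian (the default) or
#'   ASCII.
#' @param quality optional per-vertex scalar written as PLY `quality`.
#' @param color optional n x 3 integer matrix (0-255) written as PLY RGB.
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path, fmt = "auto", binary = TRUE,
                      quality = NULL, color = NULL) {
  if (identical(fmt, "auto")) fmt <- guess_mesh_format(path)
  switch(fmt,
         ply = write_ply(mesh, path, binary = binary, quality = quality,
                         color = color),
         obj = write_obj(mesh, path),
         stl = write_stl(mesh, path, binary = binary),
         dm_stop(sprintf("unknown mesh format '%s'", fmt)))
  invisible(path)
}

# ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_column <- function(raw, n, stride, offset, type, endian) {
  sz <- ply_type_size[[type]]
  idx <- as.vector(outer(seq_len(sz), (seq_len(n) - 1L) * stride + offset, "+"))
  bytes <- raw[idx]
  what <- if (type %in% c("float", "float32", "double", "float64")) "double" else "integer"
  readBin(bytes, what = what, n = n, size = sz, endian = endian,
          signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path, specimen_id) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) dm_stop(sprintf("'%s': truncated PLY header", path))
    header <- c(header, ln)
    if (identical(trimws(ln), "end_header")) break
    if (length(header) > 500) dm_stop(sprintf("'%s': no end_header found", path))
  }
  if (!grepl("^ply", header[1]))
    dm_stop(sprintf("'%s' is not a PLY file", path))
  fmt_line <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  # parse element/property declarations
  elements <- list(); cur <- NULL
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3], type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1L]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex)) dm_stop(sprintf("'%s': PLY has no vertex element", path))

  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    pos <- 0L
    out <- list()
    for (el in elements) {
      lines <- txt[pos + seq_len(el$count)]
      pos <- pos + el$count
      fields <- strsplit(trimws(lines), "\\s+")
      if (el$name == "vertex") {
        m <- matrix(as.numeric(unlist(fields)), nrow = el$count, byrow = TRUE)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        out$vertex <- m
      } else if (el$name == "face") {
        cnt <- vapply(fields, function(f) as.integer(f[1]), 0L)
        bad <- which(cnt != 3L)
        if (length(bad))
          dm_stop(sprintf("'%s': non-triangular face at row %d (%d vertices)",
                          path, bad[1], cnt[bad[1]]))
        out$face <- matrix(as.integer(unlist(lapply(fields, `[`, 2:4))),
                           ncol = 3, byrow = TRUE) + 1L
      }
    }
  } else {
    endian <- if (fmt == "binary_little_endian") "little" else "big"
    raw <- readBin(con, "raw", n = file.info(path)$size)
    off <- 0L
    out <- list()
    for (el in elements) {
      if (el$name == "vertex") {
        if (any(vapply(el$props, `[[`, TRUE, "list")))
          dm_stop(sprintf("'%s': list property on vertex element unsupported", path))
        sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 0L)
        stride <- sum(sizes)
        offs <- cumsum(c(0L, sizes[-length(sizes)]))
        m <- matrix(0, nrow = el$count, ncol = length(el$props))
        for (j in seq_along(el$props))
          m[, j] <- ply_read_column(raw, el$count, stride, off + offs[j],
                                    el$props[[j]]$type, endian)
        colnames(m) <- vapply(el$props, `[[`, "", "name")
        out$vertex <- m
        off <- off + el$count * stride
      } else if (el$name == "face") {
        p <- el$props[[1]]
        if (!p$list) dm_stop(sprintf("'%s': face element lacks list property", path))
        csz <- ply_type_size[[p$count_type]]
        isz <- ply_type_size[[p$type]]
        stride <- csz + 3L * isz
        cnt <- ply_read_column(raw, el$count, stride, off, p$count_type, endian)
        if (any(cnt != 3L)) {
          bad <- which(cnt != 3L)[1]
          dm_stop(sprintf("'%s': non-triangular face at row %d (%d vertices)",
                          path, bad, cnt[bad]))
        }
        f <- matrix(0L, nrow = el$count, ncol = 3L)
        for (j in 1:3)
          f[, j] <- ply_read_column(raw, el$count, stride,
                                    off + csz + (j - 1L) * isz, p$type, endian)
        out$face <- f + 1L
        off <- off + el$count * stride
      } else {
        dm_stop(sprintf("'%s': unsupported PLY element '%s' in binary file",
                        path, el$name))
      }
    }
  }
  v <- out$vertex
  mesh <- tri_mesh(v[, c("x", "y", "z"), drop = FALSE],
                   if (is.null(out$face)) matrix(integer(), 0, 3) else out$face,
                   specimen_id)
  if ("quality" %in% colnames(v)) attr(mesh, "quality") <- as.numeric(v[, "quality"])
  mesh
}

write_ply <- function(mesh, path, binary = TRUE, quality = NULL, color = NULL) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$faces)
  if (!is.null(quality) && length(quality) != n)
    dm_stop("quality length must equal vertex count")
  if (!is.null(color) && (nrow(color) != n || ncol(color) != 3))
    dm_stop("color must be an n x 3 matrix")
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment written by densemorph",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z")
  if (!is.null(quality)) hdr <- c(hdr, "property double quality")
  if (!is.null(color)) hdr <- c(hdr, "property uchar red",
                                "property uchar green", "property uchar blue")
  hdr <- c(hdr, sprintf("element face %d", m),
           "property list uchar int vertex_indices", "end_header")
  f0 <- mesh$faces - 1L
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    for (i in seq_len(n)) {
      writeBin(as.double(mesh$vertices[i, ]), con, size = 8, endian = "little")
      if (!is.null(quality))
        writeBin(as.double(quality[i]), con, size = 8, endian = "little")
      if (!is.null(color))
        writeBin(as.raw(color[i, ]), con)
    }
    for (i in seq_len(m)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4, endian = "little")
    }
  } else {
    vl <- apply(mesh$vertices, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
    if (!is.null(quality)) vl <- paste(vl, sprintf("%.17g", quality))
    if (!is.null(color))
      vl <- paste(vl, color[, 1], color[, 2], color[, 3])
    fl <- if (m) paste(3L, f0[, 1], f0[, 2], f0[, 3]) else character()
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

# ---- OBJ (ASCII, 1-based indices) ----

read_obj <- function(path, specimen_id) {
  txt <- readLines(path, warn = FALSE)
  vt <- txt[startsWith(txt, "v ")]
  ft <- txt[startsWith(txt, "f ")]
  v <- matrix(as.numeric(unlist(lapply(strsplit(trimws(vt), "\\s+"),
                                       function(x) x[2:4]))),
              ncol = 3, byrow = TRUE)
  ffields <- strsplit(trimws(ft), "\\s+")
  nv <- vapply(ffields, length, 0L) - 1L
  bad <- which(nv != 3L)
  if (length(bad))
    dm_stop(sprintf("'%s': non-triangular face at row %d (%d vertices)",
                    path, bad[1], nv[bad[1]]))
  # tolerate v/vt/vn references: keep the vertex index before the first slash
  fidx <- vapply(ffields, function(x) as.integer(sub("/.*$", "", x[2:4])),
                 integer(3))
  f <- t(fidx)
  f[f < 0] <- nrow(v) + 1L + f[f < 0]  # negative = relative indices
  tri_mesh(v, f, specimen_id)
}

write_obj <- function(mesh, path) {
  vl <- apply(mesh$vertices, 1,
              function(r) paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  fl <- if (nrow(mesh$faces))
    paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]) else character()
  writeLines(c("# written by densemorph", vl, fl), path)
  invisible(path)
}

# ---- STL (per-facet soup; duplicate vertices merged exactly on read) ----

read_stl <- function(path, specimen_id) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", n = min(80L, sz))
  is_binary <- FALSE
  if (sz >= 84) {
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(nt) && sz == 84 + 50 * as.double(nt)) is_binary <- TRUE
  }
  close(con)
  if (is_binary) {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    raw <- readBin(con, "raw", n = 50 * nt)
    # 50-byte records: 12 floats (normal + 3 vertices) + uint16 attribute
    rec <- matrix(raw, nrow = 50)
    fl <- readBin(as.vector(rec[1:48, ]), "double", size = 4, n = 12 * nt,
                  endian = "little")
    fl <- matrix(fl, ncol = 12, byrow = TRUE)
    tri <- fl[, 4:12, drop = FALSE]  # drop the normal
  } else {
    txt <- readLines(path, warn = FALSE)
    vt <- grep("^\\s*vertex\\s", txt, value = TRUE)
    nums <- as.numeric(unlist(lapply(strsplit(trimws(vt), "\\s+"),
                                     function(x) x[2:4])))
    if (length(nums) %% 9 != 0)
      dm_stop(sprintf("'%s': STL facet with vertex count != 3", path))
    tri <- matrix(nums, ncol = 9, byrow = TRUE)
  }
  nt <- nrow(tri)
  pts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
               tri[, 7:9, drop = FALSE])
  key <- paste(sprintf("%.17g", pts[, 1]), sprintf("%.17g", pts[, 2]),
               sprintf("%.17g", pts[, 3]))
  uid <- match(key, key[!duplicated(key)])
  v <- pts[!duplicated(key), , drop = FALSE]
  f <- cbind(uid[seq_len(nt)], uid[nt + seq_len(nt)], uid[2 * nt + seq_len(nt)])
  tri_mesh(v, f, specimen_id)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- pmax(row_norms(nrm), .Machine$double.eps)
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80)), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.double(c(nrm[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    fmtv <- function(p) sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3])
    lines <- c(sprintf("solid %s", mesh$specimen_id))
    for (i in seq_len(nrow(f))) {
      lines <- c(lines,
                 sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                 "    outer loop", fmtv(a[i, ]), fmtv(b[i, ]), fmtv(c_[i, ]),
                 "    endloop", "  endfacet")
    }
    writeLines(c(lines, sprintf("endsolid %s", mesh$specimen_id)), path)
  }
  invisible(path)
}

# ---- topology validation ----

mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Validate single-layer mesh topology
#'
#' Counts connected components (vertices joined through shared faces),
#' non-manifold edges (shared by more than two faces), duplicate faces (same
#' unordered vertex triple) and boundary loops. The mesh passes when it has
#' exactly one component, no non-manifold edges and no duplicate faces —
#' i.e. a clean single-layered surface.
#'
#' @param mesh a [tri_mesh].
#' @return An object of class `validation_report` (a list with counts and a
#'   `passed` flag), serializable via [jsonlite::toJSON].
#' @export
validate_single_layer <- function(mesh) {
  f <- mesh$faces
  n <- nrow(mesh$vertices)
  # duplicate faces: unordered vertex triples
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "-"))
  dup <- sum(duplicated(key))
  # union-find over vertices used by faces
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      r1 <- find(f[i, 1]); r2 <- find(f[i, 2]); r3 <- find(f[i, 3])
      parent[r2] <- r1; parent[find(r3)] <- find(r1)
    }
  }
  used <- sort(unique(as.vector(f)))
  comps <- if (length(used)) length(unique(vapply(used, find, 0L))) else 0L
  # edge face-counts
  ed <- mesh_edges(f)
  ekey <- paste(ed[, 1], ed[, 2])
  tab <- table(ekey)
  nonmanifold <- sum(tab > 2L)
  boundary_edges <- names(tab)[tab == 1L]
  # boundary loops: components of the boundary-edge graph
  loops <- 0L
  if (length(boundary_edges)) {
    be <- do.call(rbind, strsplit(boundary_edges, " "))
    be <- cbind(as.integer(be[, 1]), as.integer(be[, 2]))
    bparent <- seq_len(n)
    bfind <- function(x) { while (bparent[x] != x) { bparent[x] <<- bparent[bparent[x]]; x <- bparent[x] }; x }
    for (i in seq_len(nrow(be))) bparent[bfind(be[i, 1])] <- bfind(be[i, 2])
    bverts <- unique(as.vector(be))
    loops <- length(unique(vapply(bverts, bfind, 0L)))
  }
  structure(list(connected_components = comps,
                 nonmanifold_edges = as.integer(nonmanifold),
                 duplicate_faces = as.integer(dup),
                 boundary_loops = loops,
                 passed = comps == 1L && nonmanifold == 0L && dup == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("validation_report: components=%d nonmanifold_edges=%d ",
                     "duplicate_faces=%d boundary_loops=%d passed=%s\n"),
              x$connected_components, x$nonmanifold_edges, x$duplicate_faces,
              x$boundary_loops, x$passed))
  invisible(x)
}

#' Vertices on the mesh boundary
#'
#' @param mesh a [tri_mesh].
#' @return Sorted integer indices of vertices incident to a boundary edge
#'   (an edge used by exactly one face).
#' @export
boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh$faces)
  ekey <- paste(ed[, 1], ed[, 2])
  tab <- table(ekey)
  be <- names(tab)[tab == 1L]
  if (!length(be)) return(integer())
  m <- do.call(rbind, strsplit(be, " "))
  sort(unique(c(as.integer(m[, 1]), as.integer(m[, 2]))))
}

#' Mean edge length of a mesh (mm)
#'
#' Mean over unique (unordered) edges; used to set elastic-ICP bandwidth
#' defaults.
#' @param mesh a [tri_mesh].
#' @return Scalar mm.
#' @export
mean_edge_length <- function(mesh) {
  ed <- mesh_edges(mesh$faces)
  ed <- ed[!duplicated(paste(ed[, 1], ed[, 2])), , drop = FALSE]
  mean(row_norms(mesh$vertices[ed[, 1], , drop = FALSE] -
                   mesh$vertices[ed[, 2], , drop = FALSE]))
}

#' Extract a vertex-subset submesh
#'
#' Keeps faces whose three vertices are all in `keep` and reindexes
#' compactly. The old-to-new index mapping is attached as attribute
#' `"vertex_map"` (named integer vector, `NA` for dropped vertices).
#'
#' @param mesh a [tri_mesh].
#' @param keep integer vertex indices to retain (non-empty).
#' @return A [tri_mesh].
#' @export
extract_submesh <- function(mesh, keep) {
  keep <- sort(unique(as.integer(keep)))
  if (!length(keep)) dm_stop("keep must be a non-empty vertex index set")
  if (min(keep) < 1L || max(keep) > nrow(mesh$vertices))
    dm_stop("keep contains out-of-range vertex indices")
  map <- rep(NA_integer_, nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- mesh$faces
  ok <- !is.na(map[f[, 1]]) & !is.na(map[f[, 2]]) & !is.na(map[f[, 3]])
  newf <- matrix(map[f[ok, , drop = FALSE]], ncol = 3)
  out <- tri_mesh(mesh$vertices[keep, , drop = FALSE], newf, mesh$specimen_id)
  attr(out, "vertex_map") <- map
  out
}

#' Reflect a mesh across a plane through three points
#'
#' Used for midsagittal mirror reconstruction: the plane is defined by three
#' anatomical points (e.g. glabella, bregma, foramen caecum) and every vertex
#' is reflected across it. Face orientation is flipped so outward normals are
#' preserved.
#'
#' @param mesh a [tri_mesh].
#' @param p1,p2,p3 numeric length-3 points spanning the plane (non-collinear).
#' @return A [tri_mesh].
#' @export
reflect_across_plane <- function(mesh, p1, p2, p3) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  u <- p2 - p1; v <- p3 - p1
  n <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  nl <- sqrt(sum(n^2))
  if (nl < 1e-12 * max(sqrt(sum(u^2)), sqrt(sum(v^2)), 1))
    dm_stop("degenerate plane: the three points are collinear")
  n <- n / nl
  d <- as.vector(sweep(mesh$vertices, 2, p1) %*% n)
  refl <- mesh$vertices - 2 * outer(d, n)
  tri_mesh(refl, mesh$faces[, c(1, 3, 2), drop = FALSE], mesh$specimen_id)
}

# ---- landmark files ----

#' Read landmark sets from CSV
#'
#' Expects columns `specimen_id, landmark, x, y, z` and optionally
#' `observer_id, session_id`. Rows are grouped by
#' (specimen, observer, session); within each set, rows carrying the six
#' canonical registration landmarks are reordered canonically (extra
#' landmarks keep their input order after them).
#'
#' @param path CSV path.
#' @return A list of [landmark_set] objects.
#' @export
load_landmarks <- function(path) {
  if (!file.exists(path)) dm_stop(sprintf("landmark file not found: '%s'", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("specimen_id", "landmark", "x", "y", "z")
  miss <- setdiff(req, names(df))
  if (length(miss))
    dm_stop(sprintf("'%s': missing column(s): %s", path, paste(miss, collapse = ", ")))
  if (!"observer_id" %in% names(df)) df$observer_id <- NA_character_
  if (!"session_id" %in% names(df)) df$session_id <- NA_character_
  key <- paste(df$specimen_id, df$observer_id, df$session_id, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    ord <- order(match(g$landmark, REGISTRATION_LANDMARKS, nomatch = 1e6))
    g <- g[ord, , drop = FALSE]
    pts <- as.matrix(g[, c("x", "y", "z")])
    rownames(pts) <- g$landmark
    landmark_set(pts, g$specimen_id[1], g$observer_id[1], g$session_id[1])
  })
  unname(out)
}

#' Write landmark sets to CSV
#'
#' Inverse of [load_landmarks()].
#' @param sets a [landmark_set] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- do.call(rbind, lapply(sets, function(s) {
    data.frame(specimen_id = s$specimen_id, landmark = rownames(s$points),
               x = s$points[, 1], y = s$points[, 2], z = s$points[, 3],
               observer_id = s$observer_id, session_id = s$session_id,
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Convert simple "name x y z" landmark text to a landmark set
#'
#' A converter for plain text exports (one landmark per line: name then three
#' coordinates, whitespace-separated; `#` comments allowed).
#'
#' @param path text file path.
#' @param specimen_id identifier for the resulting set.
#' @return A [landmark_set].
#' @export
convert_landmark_text <- function(path, specimen_id = "unnamed") {
  txt <- readLines(path, warn = FALSE)
  txt <- trimws(txt)
  txt <- txt[nzchar(txt) & !startsWith(txt, "#")]
  tok <- strsplit(txt, "\\s+")
  pts <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
  rownames(pts) <- vapply(tok, `[[`, "", 1)
  landmark_set(pts, specimen_id)
}
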