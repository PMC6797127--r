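#' Solid triangle mesh
#'
#' A `solid_mesh` is a closed, consistently outward-oriented triangulated
#' surface representing a bone or implant solid. Coordinates are in mm.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in mm.
#' @param faces integer matrix (m x 3) of 1-based triangle vertex indices.
#' @param name optional label carried through reports.
#' @param clean if `TRUE` (default) merge duplicate vertices, drop degenerate
#'   triangles and fix global orientation so the signed volume is positive.
#' @return an object of class `solid_mesh`.
#' @export
solid_mesh <- function(vertices, faces, name = "solid", clean = TRUE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3,
                     dimnames = list(NULL, c("x", "y", "z")))
  faces <- matrix(as.integer(faces), ncol = 3)
  m <- structure(list(vertices = vertices, faces = faces, name = name),
                 class = "solid_mesh")
  if (clean && nrow(faces) > 0) m <- clean_mesh(m)
  m
}

#' @export
print.solid_mesh <- function(x, ...) {
  cat(sprintf("<solid_mesh '%s': %d vertices, %d faces", x$name,
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$faces) > 0) {
    wt <- is_watertight(x)
    cat(sprintf(", volume %.3f ml%s", volume(x),
                if (wt) "" else ", NOT watertight"))
  }
  cat(">\n")
  invisible(x)
}

#' Is a mesh empty (no faces)?
#' @param mesh a `solid_mesh`.
#' @export
is_empty_mesh <- function(mesh) nrow(mesh$faces) == 0

#' Merge duplicate vertices, drop degenerate faces, orient outward
#'
#' @param mesh a `solid_mesh`.
#' @param tol vertex merge tolerance in mm.
#' @param fill_hole_diameter boundary loops with diameter below this (mm) are
#'   fan-filled; larger holes are left for [assert_watertight()] to report.
#' @export
clean_mesh <- function(mesh, tol = 1e-6, fill_hole_diameter = 1) {
  V <- mesh$vertices
  F <- mesh$faces
  # merge duplicates on the tol lattice (lexicographic sort + run detection)
  ii <- round(V / tol)
  o <- order(ii[, 1], ii[, 2], ii[, 3])
  si <- ii[o, , drop = FALSE]
  new_grp <- c(TRUE, rowSums(abs(diff(si))) > 0)
  grp <- integer(nrow(V))
  grp[o] <- cumsum(new_grp)
  V <- V[o[new_grp], , drop = FALSE]
  F <- matrix(grp[F], ncol = 3)
  # drop faces with repeated vertices (degenerate after merge)
  ok <- F[, 1] != F[, 2] & F[, 2] != F[, 3] & F[, 1] != F[, 3]
  F <- F[ok, , drop = FALSE]
  # drop zero-area faces
  if (nrow(F) > 0) {
    a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
    cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
    area2 <- sqrt(rowSums(cr^2))
    F <- F[area2 > 1e-12, , drop = FALSE]
  }
  out <- structure(list(vertices = V, faces = F, name = mesh$name),
                   class = "solid_mesh")
  if (nrow(F) == 0) return(out)
  out <- fill_small_holes(out, fill_hole_diameter)
  if (signed_volume_mm3(out) < 0) out$faces <- out$faces[, c(1, 3, 2)]
  out
}

boundary_edges <- function(mesh) {
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  ek <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(ek)
  e[ek %in% names(cnt)[cnt == 1], , drop = FALSE]
}

# Fan-fill boundary loops whose spatial diameter is below `max_diam` mm.
fill_small_holes <- function(mesh, max_diam = 1) {
  be <- boundary_edges(mesh)
  if (nrow(be) == 0) return(mesh)
  # chain directed boundary edges into loops
  nxt <- split(be[, 2], be[, 1])
  used <- rep(FALSE, nrow(be))
  startmap <- split(seq_len(nrow(be)), be[, 1])
  V <- mesh$vertices
  newf <- list()
  newv <- list()
  for (s in seq_len(nrow(be))) {
    if (used[s]) next
    loop <- integer(0)
    cur <- be[s, 1]
    guard <- 0
    repeat {
      cand <- startmap[[as.character(cur)]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break
      used[cand[1]] <- TRUE
      loop <- c(loop, cur)
      cur <- be[cand[1], 2]
      guard <- guard + 1
      if (cur == be[s, 1] || guard > nrow(be)) break
    }
    if (length(loop) < 3 || cur != be[s, 1]) next
    pts <- V[loop, , drop = FALSE]
    diam <- max(dist(pts))
    if (diam > max_diam) next
    cen <- colMeans(pts)
    ci <- nrow(V) + length(newv) + 1
    newv[[length(newv) + 1]] <- cen
    # boundary edges are directed with the surface on their left; fill fans
    # with reversed direction to oppose them
    n <- length(loop)
    for (i in seq_len(n)) {
      a <- loop[i]
      b <- loop[if (i == n) 1 else i + 1]
      newf[[length(newf) + 1]] <- c(ci, b, a)
    }
  }
  if (length(newv) == 0) return(mesh)
  mesh$vertices <- rbind(V, do.call(rbind, newv))
  mesh$faces <- rbind(mesh$faces, do.call(rbind, newf))
  mesh
}

#' Watertightness check
#'
#' A mesh encloses a solid when every directed edge is balanced by its
#' reverse (the surface has no boundary). Manifold meshes then have every
#' undirected edge in exactly two faces; voxel-boundary meshes may
#' additionally contain balanced non-manifold edges where voxels touch
#' diagonally, which still bound a well-defined volume.
#' @param mesh a `solid_mesh`.
#' @return logical; attribute `"open_edges"` holds the count of unbalanced
#'   directed edges.
#' @export
is_watertight <- function(mesh) {
  if (is_empty_mesh(mesh)) return(structure(TRUE, open_edges = 0L))
  F <- mesh$faces
  e <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  nv <- nrow(mesh$vertices) + 1
  fwd <- sort(e[, 1] * nv + e[, 2])
  rev <- sort(e[, 2] * nv + e[, 1])
  # closed surface <=> the multiset of directed edges equals the multiset of
  # their reverses
  open <- sum(fwd != rev)
  structure(open == 0, open_edges = as.integer(open))
}

assert_watertight <- function(mesh, what = "mesh") {
  wt <- is_watertight(mesh)
  if (!wt)
    stop(sprintf("%s '%s' is not watertight: %d open edge(s)", what,
                 mesh$name, attr(wt, "open_edges")), call. = FALSE)
  invisible(mesh)
}

signed_volume_mm3 <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
      a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Enclosed volume of a watertight solid, in ml
#'
#' Computed as the signed-tetrahedron sum over faces (divergence theorem);
#' 1 ml = 1000 mm^3.
#' @param mesh a `solid_mesh`.
#' @export
volume <- function(mesh) {
  if (is_empty_mesh(mesh)) return(0)
  assert_watertight(mesh)
  abs(signed_volume_mm3(mesh)) / 1000
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh a `solid_mesh`.
#' @param rotation 3x3 matrix applied first.
#' @param translation length-3 offset applied after rotation.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  mesh$vertices <- sweep(mesh$vertices %*% t(rotation), 2, -translation)
  if (det(rotation) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Mirror a mesh across a plane
#' @param mesh a `solid_mesh`.
#' @param point a point on the mirror plane.
#' @param normal plane normal.
#' @export
mirror_mesh <- function(mesh, point, normal) {
  n <- normal / sqrt(sum(normal^2))
  d <- (mesh$vertices - matrix(point, nrow(mesh$vertices), 3,
                               byrow = TRUE)) %*% n
  mesh$vertices <- mesh$vertices - 2 * d %*% t(n)
  mesh$faces <- mesh$faces[, c(1, 3, 2)]  # reflection flips orientation
  mesh
}

#' Load a solid from STL or PLY
#'
#' Reads binary or ASCII STL and ASCII PLY. The mesh is cleaned on load:
#' duplicate vertices merged at 1e-6 mm, degenerate triangles dropped, holes
#' under 1 mm diameter filled, orientation fixed so the signed volume is
#' positive.
#'
#' @param path file path; format detected from extension and content.
#' @param repair if `FALSE`, skip hole filling.
#' @param name label; defaults to the file name.
#' @return a watertight `solid_mesh`; errors if the file is unreadable or the
#'   cleaned mesh still has open edges.
#' @export
load_solid <- function(path, repair = TRUE, name = NULL) {
  if (!file.exists(path)) stop("cannot read mesh file: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  raw <- if (ext == "ply") read_ply(path) else read_stl(path)
  m <- solid_mesh(raw$vertices, raw$faces, name = name, clean = FALSE)
  m <- clean_mesh(m, fill_hole_diameter = if (repair) 1 else 0)
  assert_watertight(m, "loaded solid")
  m
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  fsize <- file.size(path)
  is_binary <- length(ntri) == 1 && !is.na(ntri) &&
    fsize == 84 + 50 * as.numeric(ntri)
  if (is_binary) {
    buf <- readBin(con, "raw", 50 * ntri)
    # each record: 12 floats (48 bytes) + 2-byte attribute
    idx <- rep(seq_len(ntri) - 1, each = 48) * 50 +
      rep(seq_len(48), times = ntri)
    vals <- readBin(buf[idx], "numeric", n = 12 * ntri, size = 4,
                    endian = "little")
    vals <- matrix(vals, ncol = 12, byrow = TRUE)  # normal + 3 vertices
    V <- matrix(0, 3 * ntri, 3)
    V[seq(1, 3 * ntri, 3), ] <- vals[, 4:6, drop = FALSE]
    V[seq(2, 3 * ntri, 3), ] <- vals[, 7:9, drop = FALSE]
    V[seq(3, 3 * ntri, 3), ] <- vals[, 10:12, drop = FALSE]
    F <- matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE)
    return(list(vertices = V, faces = F))
  }
  # ASCII
  txt <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("cannot parse STL file: ", path, call. = FALSE)
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  list(vertices = V, faces = F)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  if (!grepl("^ply", txt[1])) stop("not a PLY file: ", path, call. = FALSE)
  if (!any(grepl("format ascii", txt)))
    stop("only ASCII PLY is supported: ", path, call. = FALSE)
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", txt, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", txt, value = TRUE)[1]))
  end <- grep("end_header", txt)[1]
  vlines <- txt[(end + 1):(end + nv)]
  V <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(p)
    as.numeric(p[1:3])))
  flines <- txt[(end + nv + 1):(end + nv + nf)]
  F <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(p) {
    p <- as.integer(p)
    if (p[1] != 3) stop("only triangle PLY faces are supported", call. = FALSE)
    p[2:4] + 1
  }))
  list(vertices = V, faces = F)
}

#' Write a solid to STL or PLY
#' @param mesh a `solid_mesh`.
#' @param path output path; format from extension (`.stl` binary unless
#'   `ascii = TRUE`, `.ply` ASCII).
#' @param ascii write ASCII STL instead of binary.
#' @export
write_solid <- function(mesh, path, ascii = FALSE) {
  ext <- tolower(sub(".*\\.", "", path))
  V <- mesh$vertices
  F <- mesh$faces
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1, F[, 2] - 1, F[, 3] - 1), con)
    return(invisible(path))
  }
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("solid %s", mesh$name), con)
    for (t in seq_len(nrow(F))) {
      p <- V[F[t, ], , drop = FALSE]
      writeLines(c("facet normal 0 0 0", "  outer loop",
                   sprintf("    vertex %.9g %.9g %.9g", p[, 1], p[, 2],
                           p[, 3]),
                   "  endloop", "endfacet"), con)
    }
    writeLines(sprintf("endsolid %s", mesh$name), con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (t in seq_len(nrow(F))) {
    p <- V[F[t, ], , drop = FALSE]
    writeBin(c(0, 0, 0, t(p)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}
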