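# Voxel Boolean engine: meshes are rasterized to a common occupancy grid by
# parity ray casting, combined voxel-wise, and re-meshed with a cuberille
# (voxel-face) surface whose enclosed volume equals voxel count * pitch^3
# exactly. The grid origin is jittered by an irrational fraction of the pitch
# so mesh features cannot sit exactly on ray lattices.

GRID_JITTER <- c(0.2137421, 0.3178509, 0.1415927)

#' Voxel grid container
#'
#' @param origin grid corner (mm); voxel centers sit at
#'   `origin + (index + 0.5) * pitch`.
#' @param pitch voxel edge length (mm), > 0.
#' @param dims integer grid dimensions.
#' @param occupancy raw vector of length `prod(dims)` (0/1).
#' @export
voxel_grid <- function(origin, pitch, dims, occupancy) {
  stopifnot(pitch > 0, length(dims) == 3,
            length(occupancy) == prod(dims))
  structure(list(origin = origin, pitch = pitch, dims = as.integer(dims),
                 occupancy = occupancy),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, pitch %.3g mm, %.3f ml occupied>\n",
              x$dims[1], x$dims[2], x$dims[3], x$pitch, grid_volume(x)))
  invisible(x)
}

#' Occupied volume of a voxel grid, in ml
#' @param grid a `voxel_grid`.
#' @export
grid_volume <- function(grid) {
  sum(grid$occupancy != 0) * grid$pitch^3 / 1000
}

# Common grid frame covering the bounding boxes of all meshes, padded by at
# least one voxel.
grid_frame <- function(meshes, pitch, pad = 2) {
  bb <- sapply(meshes, function(m) {
    if (is_empty_mesh(m)) return(c(Inf, Inf, Inf, -Inf, -Inf, -Inf))
    c(apply(m$vertices, 2, min), apply(m$vertices, 2, max))
  })
  lo <- apply(bb[1:3, , drop = FALSE], 1, min)
  hi <- apply(bb[4:6, , drop = FALSE], 1, max)
  if (any(!is.finite(lo))) stop("cannot grid empty meshes", call. = FALSE)
  origin <- lo - pad * pitch - GRID_JITTER * pitch
  dims <- as.integer(ceiling((hi - origin) / pitch)) + pad
  list(origin = origin, dims = dims)
}

#' Rasterize a mesh to an occupancy grid
#'
#' @param mesh a watertight `solid_mesh`.
#' @param pitch voxel edge length (mm).
#' @param frame optional list with `origin` and `dims` defining the grid; by
#'   default the mesh bounding box padded by two voxels.
#' @return a `voxel_grid`.
#' @export
voxelize <- function(mesh, pitch = 0.5, frame = NULL) {
  assert_watertight(mesh)
  if (is.null(frame)) frame <- grid_frame(list(mesh), pitch)
  occ <- voxelize_mesh_cpp(mesh$vertices, mesh$faces - 1L, frame$origin,
                           pitch, frame$dims)
  voxel_grid(frame$origin, pitch, frame$dims, occ)
}

#' Extract the boundary surface of a voxel grid as a mesh
#' @param grid a `voxel_grid`.
#' @param name label for the resulting mesh.
#' @return a watertight `solid_mesh` of axis-aligned voxel faces; its volume
#'   equals [grid_volume()] exactly.
#' @export
mesh_from_grid <- function(grid, name = "voxel-surface") {
  res <- cuberille_cpp(grid$occupancy, grid$dims, grid$origin, grid$pitch)
  solid_mesh(res$vertices, res$faces, name = name, clean = FALSE)
}

boolean_op <- function(a, b, op, method, pitch) {
  stopifnot(pitch > 0)
  method <- match.arg(method, c("voxel", "exact"))
  if (method == "exact") {
    # no exact mesh-Boolean kernel is implemented; per the operation contract
    # the call never fails on watertight input but falls back to voxels
    warning("exact Boolean kernel not available; falling back to voxel ",
            "method at pitch ", pitch, " mm", call. = FALSE)
  }
  assert_watertight(a, "operand a")
  assert_watertight(b, "operand b")
  frame <- grid_frame(list(a, b), pitch)
  ga <- voxelize(a, pitch, frame)
  gb <- voxelize(b, pitch, frame)
  occ <- occ_op_cpp(ga$occupancy, gb$occupancy,
                    c(difference = 1L, intersection = 2L, union = 3L)[[op]])
  g <- voxel_grid(frame$origin, pitch, frame$dims, occ)
  out <- mesh_from_grid(g, name = sprintf("%s(%s,%s)", op, a$name, b$name))
  attr(out, "grid") <- g
  out
}

#' Boolean difference of two solids (a minus b)
#'
#' Both solids are rasterized on a common voxel grid, the occupancies are
#' subtracted, and the result is re-meshed from the voxel boundary. The
#' volume error is bounded by O(pitch x shared surface area).
#'
#' @param a,b watertight `solid_mesh` objects.
#' @param method `"voxel"` (the implemented kernel) or `"exact"`, which warns
#'   and falls back to voxel so the call never fails on valid input.
#' @param pitch voxel edge length in mm.
#' @return a `solid_mesh` (possibly empty); the underlying `voxel_grid` is
#'   attached as attribute `"grid"`.
#' @export
boolean_difference <- function(a, b, method = c("voxel", "exact"),
                               pitch = 0.5) {
  boolean_op(a, b, "difference", match.arg(method), pitch)
}

#' Boolean intersection of two solids
#' @inheritParams boolean_difference
#' @export
boolean_intersection <- function(a, b, method = c("voxel", "exact"),
                                 pitch = 0.5) {
  boolean_op(a, b, "intersection", match.arg(method), pitch)
}

#' Boolean union of two solids
#' @inheritParams boolean_difference
#' @export
boolean_union <- function(a, b, method = c("voxel", "exact"), pitch = 0.5) {
  boolean_op(a, b, "union", match.arg(method), pitch)
}
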