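#' Periacetabular sector partition
#'
#' Partitions a spherical region of interest (ROI) around the native center
#' of rotation into four disjoint sectors: a Medial cap on the medial side of
#' a plane parallel to the acetabular plane, and three azimuthal wedges
#' (default 120 deg each) in the remaining lateral shell, centered on the
#' cranial direction (Cranial) and the adjacent anterior/posterior thirds
#' (Anterior, Posterior). The wedge azimuth is measured about the acetabular
#' plane normal, from the projected cranial direction toward anterior.
#'
#' @param frame an [build_frame()] result.
#' @param roi_radius_factor ROI radius as a multiple of the acetabular
#'   radius; must be > 1 (default 2).
#' @param medial_offset distance (mm) of the medial cut plane medial to the
#'   CoR (default 0).
#' @param wedge_centers named or ordered numeric vector of wedge center
#'   azimuths in degrees for Cranial, Anterior, Posterior (default 0, 120,
#'   -120).
#' @param wedge_widths wedge angular widths in degrees (default 120 each).
#'   Points in an azimuthal gap are assigned to the nearest wedge center, so
#'   the sectors always partition the ROI.
#' @return an object of class `sector_partition`.
#' @export
build_partition <- function(frame, roi_radius_factor = 2, medial_offset = 0,
                            wedge_centers = c(0, 120, -120),
                            wedge_widths = c(120, 120, 120)) {
  if (!inherits(frame, "anatomic_frame"))
    stop("frame must be an anatomic_frame", call. = FALSE)
  if (roi_radius_factor <= 1)
    stop("roi_radius_factor must be > 1", call. = FALSE)
  if (is.na(frame$acet_radius))
    stop("frame has no acetabular radius", call. = FALSE)
  structure(list(frame = frame,
                 roi_radius_factor = roi_radius_factor,
                 roi_radius = roi_radius_factor * frame$acet_radius,
                 medial_offset = medial_offset,
                 wedge_centers = as.numeric(wedge_centers),
                 wedge_halfwidths = as.numeric(wedge_widths) / 2),
            class = "sector_partition")
}

#' @export
print.sector_partition <- function(x, ...) {
  cat(sprintf(
    "<sector_partition: ROI %.1f mm (%.2g x acetabular radius), medial offset %.1f mm>\n",
    x$roi_radius, x$roi_radius_factor, x$medial_offset))
  invisible(x)
}

SECTORS <- c("Cranial", "Anterior", "Posterior", "Medial")

#' Sector of each point
#' @param partition a `sector_partition`.
#' @param points n x 3 matrix.
#' @return factor with levels Outside, Cranial, Anterior, Posterior, Medial.
#' @export
classify_points <- function(partition, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  f <- partition$frame
  code <- classify_points_cpp(points, f$cor, f$y_axis, f$z_axis,
                              f$acet_plane$normal, partition$roi_radius,
                              partition$medial_offset,
                              partition$wedge_centers,
                              partition$wedge_halfwidths)
  factor(c("Outside", SECTORS)[code + 1],
         levels = c("Outside", SECTORS))
}

# integer sector codes (0 outside, 1..4 = C,A,P,M) for all voxel centers
classify_grid <- function(partition, grid) {
  f <- partition$frame
  classify_voxels_cpp(grid$dims, grid$origin, grid$pitch, f$cor, f$y_axis,
                      f$z_axis, f$acet_plane$normal, partition$roi_radius,
                      partition$medial_offset, partition$wedge_centers,
                      partition$wedge_halfwidths)
}

#' Clip a solid to one sector region
#'
#' Voxel intersection of the mesh with the sector region (ROI sphere
#' intersected with the sector's cap/wedge).
#' @param mesh a watertight `solid_mesh`.
#' @param partition a `sector_partition`.
#' @param sector one of `"Cranial"`, `"Anterior"`, `"Posterior"`,
#'   `"Medial"`, or `"ROI"` for the whole region of interest.
#' @param pitch voxel pitch in mm.
#' @param method Boolean method; `"exact"` falls back to voxel with a
#'   warning.
#' @return a `solid_mesh` (possibly empty) with the `voxel_grid` attached as
#'   attribute `"grid"`.
#' @export
clip_to_sector <- function(mesh, partition, sector, method = "voxel",
                           pitch = 0.5) {
  if (!sector %in% c(SECTORS, "ROI"))
    stop("unknown sector label: ", sector, call. = FALSE)
  if (identical(method, "exact"))
    warning("exact Boolean kernel not available; using voxel method",
            call. = FALSE)
  g <- voxelize(mesh, pitch)
  codes <- classify_grid(partition, g)
  want <- if (sector == "ROI") 1:4 else match(sector, SECTORS)
  keep <- as.raw(ifelse(g$occupancy != 0 & codes %in% want, 1L, 0L))
  gc <- voxel_grid(g$origin, g$pitch, g$dims, keep)
  out <- mesh_from_grid(gc, name = paste0(mesh$name, ":", sector))
  attr(out, "grid") <- gc
  out
}
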