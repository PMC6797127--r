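# Shape and position parameters of the defect acetabulum: ovality, lateral
# center-edge (Wiberg) angle, implant migration, wall-defect flags.

#' Acetabular ovality
#'
#' Rim points of the defect acetabulum are projected onto the native
#' acetabular plane and a direct least-squares ellipse is fitted. Ovality is
#' the ratio of the major to the minor diameter; 1 means a circular
#' acetabulum.
#'
#' @param rim_points n x 3 matrix of defect rim points (>= 6).
#' @param frame an `anatomic_frame` providing the native acetabular plane.
#' @return list with `length` (major diameter, mm), `width` (minor diameter,
#'   mm) and `ovality` (length / width, >= 1).
#' @export
ovality <- function(rim_points, frame) {
  rim_points <- as.matrix(rim_points)
  if (nrow(rim_points) < 6)
    stop("ovality needs >= 6 rim points", call. = FALSE)
  pl <- frame$acet_plane
  basis <- plane_basis(pl$normal)
  uv <- sweep(rim_points, 2, pl$point) %*% basis
  fit <- fit_ellipse(uv)
  L <- 2 * fit$axes[1]
  W <- 2 * fit$axes[2]
  list(length = L, width = W, ovality = L / W, fit = fit)
}

#' Lateral center-edge (Wiberg) angle
#'
#' Signed angle between the line from the native CoR to the lateral edge of
#' the cranial roof and the body Z-axis, both projected onto the anterior
#' pelvic plane. Positive when the edge lies lateral of the CoR; negative
#' (medialized edge) is possible in severe defects.
#'
#' @param lateral_edge 3-vector: most lateral point of the cranial roof.
#' @param frame an `anatomic_frame`.
#' @return angle in degrees.
#' @export
lce_angle <- function(lateral_edge, frame) {
  v <- as.numeric(lateral_edge) - frame$cor
  if (sqrt(sum(v^2)) < 1e-9)
    stop("lateral edge coincides with the CoR", call. = FALSE)
  n <- frame$app_normal
  vp <- v - sum(v * n) * n
  if (sqrt(sum(vp^2)) < 1e-9)
    stop("projection degenerate: edge direction parallel to the APP normal",
         call. = FALSE)
  deg(atan2(sum(vp * frame$x_axis), sum(vp * frame$z_axis)))
}

deg <- function(rad) rad * 180 / pi

#' Classify an LCE angle against the Wiberg normality band
#'
#' Angles between 25 and 39 degrees (inclusive) count as normal roof
#' coverage; smaller angles as reduced, larger as increased.
#' @param theta LCE angle(s) in degrees.
#' @param band lower/upper bound of the normal range.
#' @return character vector: `"reduced"`, `"normal"` or `"increased"`.
#' @export
lce_classify <- function(theta, band = c(25, 39)) {
  ifelse(theta < band[1], "reduced",
         ifelse(theta > band[2], "increased", "normal"))
}

#' Implant migration from a sphere fit
#'
#' The implant center of rotation is obtained by least-squares sphere
#' fitting on the implant's articulating surface; migration is the vector
#' from the native CoR to the implant CoR, decomposed onto the body axes.
#'
#' @param implant a `solid_mesh` of the implant (all vertices are used with
#'   iterative trimming so non-spherical rim/backside points do not bias the
#'   fit) or an n x 3 matrix of points sampled on the articulating sphere.
#' @param frame an `anatomic_frame`.
#' @param radius_range plausible implant radius band (mm); a fit outside it
#'   warns.
#' @return list with `cor_implant`, `radius`, `vector` (implant CoR minus
#'   native CoR), signed `components` (`lateral`, `anterior`, `cranial`:
#'   positive lateral / anterior / cranial, negative medial / posterior /
#'   caudal), `total` (mm) and the `predominant` direction label.
#' @export
implant_migration <- function(implant, frame, radius_range = c(15, 45)) {
  if (inherits(implant, "solid_mesh")) {
    fit <- fit_sphere_trimmed(implant$vertices)
  } else {
    fit <- fit_sphere(as.matrix(implant))
  }
  if (fit$radius < radius_range[1] || fit$radius > radius_range[2])
    warning(sprintf("implausible implant radius %.1f mm", fit$radius),
            call. = FALSE)
  d <- fit$center - frame$cor
  comp <- c(lateral = sum(d * frame$x_axis),
            anterior = sum(d * frame$y_axis),
            cranial = sum(d * frame$z_axis))
  total <- sqrt(sum(comp^2))
  list(cor_implant = fit$center, radius = fit$radius, vector = d,
       components = comp, total = total,
       predominant = predominant_direction(comp))
}

# Direction labels ordered by clinical frequency; used to break exact ties.
MIGRATION_DIRECTIONS <- c("cranial", "posterior", "medial", "lateral",
                          "anterior", "caudal")

predominant_direction <- function(components) {
  named <- c(cranial = unname(components["cranial"]),
             posterior = -unname(components["anterior"]),
             medial = -unname(components["lateral"]),
             lateral = unname(components["lateral"]),
             anterior = unname(components["anterior"]),
             caudal = -unname(components["cranial"]))
  named <- named[MIGRATION_DIRECTIONS]
  mx <- max(named)
  MIGRATION_DIRECTIONS[which(named == mx)[1]]
}

#' Wall-defect flags per sector
#'
#' Two detectors, OR-combined per sector, both driven by the bone-loss
#' occupancy (native minus defect) near the acetabular rim:
#' \describe{
#'   \item{hole detector}{loss components restricted to a band around the
#'     native rim circle; a component flags its centroid's sector when its
#'     two smallest principal extents are both >= `min_dim` (the hole's
#'     length and width; the largest extent is typically the wall
#'     thickness).}
#'   \item{absent-rim detector}{the native rim circle is sampled at 1 deg
#'     steps; a contiguous arc (>= `min_arc_deg`) whose distance to the
#'     defect surface is >= `min_dim` flags the sector(s) containing it.}
#' }
#'
#' @param native,defect watertight `solid_mesh` objects.
#' @param partition a `sector_partition`.
#' @param frame an `anatomic_frame`.
#' @param min_dim hole size threshold in mm (default 5).
#' @param band_width rim band width in mm (default 10).
#' @param min_arc_deg minimum contiguous arc for the absent-rim detector.
#' @param pitch voxel pitch for the loss occupancy (default 0.25 mm).
#' @param loss optional precomputed loss result from [bone_volume_loss()] or
#'   [sector_volumetry()] (avoids re-voxelizing).
#' @param medial_deadband the rim circle lies on the Medial/wedge boundary
#'   plane; rim findings are attributed to Medial only when they lie at
#'   least this far (mm) medial of it, otherwise to the azimuthal wedge.
#' @return named logical vector over sectors, with detector details in
#'   attribute `"details"`.
#' @export
wall_defects <- function(native, defect, partition, frame, min_dim = 5,
                         band_width = 10, min_arc_deg = 5, pitch = 0.25,
                         loss = NULL, medial_deadband = 1.5) {
  if (is.null(loss)) {
    lv <- bone_volume_loss(native, defect, partition, pitch = pitch)
    occ <- attr(lv, "occupancy")
    grid <- attr(lv, "grid")
  } else if (is.data.frame(loss)) {
    occ <- attr(loss, "occupancy")
    grid <- attr(loss, "grid")
  } else {
    occ <- loss$loss_occupancy
    grid <- loss$grid
  }
  flags <- stats::setNames(rep(FALSE, 4), SECTORS)
  details <- list(holes = list(), arcs = list())
  # partition with the medial plane pushed medially for rim attribution
  rim_partition <- partition
  rim_partition$medial_offset <- partition$medial_offset + medial_deadband

  rim_center <- frame$acet_plane$point
  rim_normal <- frame$acet_plane$normal
  rim_radius <- frame$acet_radius

  # (i) hole detector on in-band loss components
  band <- rim_band_mask_cpp(grid$dims, grid$origin, grid$pitch, rim_center,
                            rim_normal, rim_radius, band_width / 2)
  inband <- occ_op_cpp(occ, band, 2L)
  if (sum(inband != 0) == 0 && sum(occ != 0) == 0)
    warning("empty defect band: no bone loss near the rim", call. = FALSE)
  lab <- label_components_cpp(inband, grid$dims)
  ncomp <- attr(lab, "n_components")
  if (ncomp > 0) {
    idx <- which(lab > 0L)
    comp <- lab[idx]
    coords <- arrayInd(idx, grid$dims)
    xyz <- sweep((coords - 0.5) * grid$pitch, 2, -grid$origin)
    for (l in seq_len(ncomp)) {
      pts <- xyz[comp == l, , drop = FALSE]
      if (nrow(pts) < 4) next
      pc <- svd(sweep(pts, 2, colMeans(pts)), nu = 0)
      proj <- sweep(pts, 2, colMeans(pts)) %*% pc$v
      extents <- apply(proj, 2, function(p) diff(range(p))) + grid$pitch
      extents <- sort(extents, decreasing = TRUE)
      hit <- extents[2] >= min_dim && extents[3] >= min_dim
      centroid <- colMeans(pts)
      sec <- as.character(classify_points(rim_partition, rbind(centroid)))
      details$holes[[length(details$holes) + 1]] <-
        list(sector = sec, extents = extents, voxels = nrow(pts),
             flagged = hit)
      if (hit && sec %in% SECTORS) flags[sec] <- TRUE
    }
  }

  # (ii) absent-rim detector: distance from native rim samples to the defect
  # surface
  th <- seq(0, 359) * pi / 180
  basis <- plane_basis(rim_normal)
  ring <- matrix(rim_center, 360, 3, byrow = TRUE) +
    rim_radius * (outer(cos(th), basis[, 1]) + outer(sin(th), basis[, 2]))
  # only triangles near the rim can decide the >= min_dim criterion; keep
  # everything within a conservative cutoff and clamp distances there
  cutoff <- max(4 * min_dim, 2 * band_width)
  cent <- (defect$vertices[defect$faces[, 1], , drop = FALSE] +
             defect$vertices[defect$faces[, 2], , drop = FALSE] +
             defect$vertices[defect$faces[, 3], , drop = FALSE]) / 3
  dc <- sweep(cent, 2, rim_center)
  ax <- dc %*% rim_normal
  rad <- sqrt(pmax(rowSums(dc^2) - ax^2, 0)) - rim_radius
  near <- sqrt(ax^2 + rad^2) <= cutoff
  faces <- if (any(near)) defect$faces[near, , drop = FALSE] else
    defect$faces
  d <- pmin(dist_points_to_mesh_cpp(ring, defect$vertices, faces - 1L),
            cutoff)
  far <- d >= min_dim
  if (any(far)) {
    runs <- rle(c(far, far))  # doubled to catch wrap-around runs
    pos <- cumsum(runs$lengths) - runs$lengths + 1
    for (r in which(runs$values & runs$lengths >= min_arc_deg)) {
      lo <- pos[r]
      if (lo > 360) next
      smp <- ((seq(lo, pos[r] + runs$lengths[r] - 1) - 1) %% 360) + 1
      secs <- unique(as.character(classify_points(rim_partition,
                                                  ring[smp, , drop = FALSE])))
      secs <- intersect(secs, SECTORS)
      details$arcs[[length(details$arcs) + 1]] <-
        list(sectors = secs, arc_deg = length(smp),
             max_distance = max(d[smp]))
      flags[secs] <- TRUE
    }
  }
  attr(flags, "details") <- details
  flags
}
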