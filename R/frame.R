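#' Anatomical coordinate frame of a hemipelvis
#'
#' Builds the body axes and acetabular reference geometry from pelvic
#' landmarks. The anterior pelvic plane (APP) passes through both anterior
#' superior iliac spines (ASIS) and the pubic symphysis. Axes: X along the
#' ASIS line pointing lateral for the analyzed side, Z cranial within the APP
#' orthogonal to X, Y = Z x X pointing anterior. Left-side landmark sets are
#' mirrored across the sagittal plane (through the ASIS midpoint and the
#' symphysis, normal along the ASIS line) so all downstream computations are
#' side-agnostic; the mirror plane is stored in the frame so case meshes can
#' be mirrored consistently with [apply_frame_mirror()].
#'
#' @param landmarks named list with 3-vectors `asis_left`, `asis_right`,
#'   `symphysis`, `cor` (native center of rotation), and either an
#'   `acetabular_rim` point matrix (>= 6 rim points) or explicit
#'   `acet_plane_point`, `acet_plane_normal`, `acet_radius`. Optional:
#'   `lateral_edge` (most lateral point of the cranial roof). See
#'   [read_landmarks()] for the JSON layout.
#' @param side `"R"` or `"L"`.
#' @return an object of class `anatomic_frame` with fields `cor`, `x_axis`,
#'   `y_axis`, `z_axis` (orthonormal, right-handed), `app_normal`,
#'   `acet_plane` (point + unit normal, lateral-pointing), `acet_radius`,
#'   `side`, `mirrored`, `mirror_plane`, `landmarks` (after mirroring).
#' @export
build_frame <- function(landmarks, side = c("R", "L")) {
  side <- match.arg(side)
  need <- c("asis_left", "asis_right", "symphysis")
  miss <- setdiff(need, names(landmarks))
  if (length(miss) > 0)
    stop("missing landmark(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lm <- lapply(landmarks, function(p)
    if (is.matrix(p)) p else as.numeric(p))

  mid <- (lm$asis_left + lm$asis_right) / 2
  mirror_normal <- normalize3(lm$asis_right - lm$asis_left)
  mirror_plane <- list(point = mid, normal = mirror_normal)
  mirrored <- side == "L"
  if (mirrored) {
    lm <- lapply(lm, mirror_points, point = mid, normal = mirror_normal)
    tmp <- lm$asis_left            # reflection swaps the ASIS labels
    lm$asis_left <- lm$asis_right
    lm$asis_right <- tmp
  }

  u <- lm$asis_right - lm$asis_left
  w <- lm$symphysis - lm$asis_left
  n0 <- pracma_cross(u, w)
  if (sqrt(sum(n0^2)) < 1e-9 * sqrt(sum(u^2)) * sqrt(sum(w^2)))
    stop("degenerate frame: ASIS and symphysis are collinear",
         call. = FALSE)
  app_normal <- normalize3(n0)
  x_axis <- normalize3(u)

  # acetabular geometry (needed to orient APP normal via the joint center)
  if (!is.null(lm$acetabular_rim)) {
    rim <- as.matrix(lm$acetabular_rim)
    if (nrow(rim) < 6)
      stop("need >= 6 acetabular rim points", call. = FALSE)
    pl <- fit_plane(rim)
    basis <- plane_basis(pl$normal)
    uv <- sweep(rim, 2, pl$point) %*% basis
    circ <- fit_circle2d(uv)
    acet_center <- pl$point + basis %*% circ$center
    acet_normal <- pl$normal
    acet_radius <- circ$radius
  } else if (!is.null(lm$acet_plane_point) &&
             !is.null(lm$acet_plane_normal)) {
    acet_center <- lm$acet_plane_point
    acet_normal <- normalize3(lm$acet_plane_normal)
    acet_radius <- if (!is.null(lm$acet_radius)) lm$acet_radius else NA_real_
  } else {
    stop("missing landmark(s): acetabular_rim (or explicit acetabular plane)",
         call. = FALSE)
  }
  # without an explicit CoR, use the fitted rim-circle center: for a
  # hemispherical socket whose rim is the equator this is the rotation
  # center (rim points alone cannot constrain a sphere fit)
  cor <- if (!is.null(lm$cor)) lm$cor else as.numeric(acet_center)

  # orient the APP normal anterior: the hip joint center lies posterior of
  # the APP
  if (sum(app_normal * (cor - lm$asis_left)) > 0) app_normal <- -app_normal
  # cranial within APP, orthogonal to the ASIS line; symphysis is caudal
  z_axis <- normalize3(pracma_cross(x_axis, app_normal))
  if (sum(z_axis * (mid - lm$symphysis)) < 0) z_axis <- -z_axis
  y_axis <- pracma_cross(z_axis, x_axis)
  # lateral orientation of the acetabular plane normal
  if (sum(acet_normal * x_axis) < 0) acet_normal <- -acet_normal
  if (!is.na(acet_radius) && acet_radius <= 0)
    stop("acetabular radius must be positive", call. = FALSE)

  structure(list(cor = as.numeric(cor), x_axis = x_axis, y_axis = y_axis,
                 z_axis = z_axis, app_normal = app_normal,
                 acet_plane = list(point = as.numeric(acet_center),
                                   normal = as.numeric(acet_normal)),
                 acet_radius = as.numeric(acet_radius), side = side,
                 mirrored = mirrored, mirror_plane = mirror_plane,
                 landmarks = lm),
            class = "anatomic_frame")
}

#' @export
print.anatomic_frame <- function(x, ...) {
  cat(sprintf(
    "<anatomic_frame side %s%s: CoR (%.1f, %.1f, %.1f) mm, radius %.1f mm>\n",
    x$side, if (x$mirrored) " (mirrored)" else "", x$cor[1], x$cor[2],
    x$cor[3], x$acet_radius))
  invisible(x)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# two orthonormal in-plane directions for a unit normal
plane_basis <- function(normal) {
  ref <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  b1 <- normalize3(pracma_cross(ref, normal))
  b2 <- pracma_cross(normal, b1)
  cbind(b1, b2)
}

#' Mirror points across a plane
#' @param points n x 3 matrix or a 3-vector.
#' @param point,normal plane definition.
#' @export
mirror_points <- function(points, point, normal) {
  n <- normalize3(normal)
  if (is.matrix(points)) {
    d <- sweep(points, 2, point) %*% n
    points - 2 * d %*% t(n)
  } else {
    points - 2 * sum((points - point) * n) * n
  }
}

#' Mirror a case mesh with the frame's sagittal mirror plane
#'
#' For left-side cases the frame was built from mirrored landmarks; meshes
#' must be mirrored with the same plane before any sector or volumetric
#' computation.
#' @param mesh a `solid_mesh`.
#' @param frame an `anatomic_frame`.
#' @export
apply_frame_mirror <- function(mesh, frame) {
  if (!frame$mirrored) return(mesh)
  mirror_mesh(mesh, frame$mirror_plane$point, frame$mirror_plane$normal)
}

#' Read landmarks from JSON
#'
#' The file is a JSON object with named 3-element arrays (mm) and optionally
#' an `acetabular_rim` array of points.
#' @param path JSON file path.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lm$acetabular_rim))
    lm$acetabular_rim <- matrix(unlist(lm$acetabular_rim), ncol = 3,
                                byrow = !is.matrix(lm$acetabular_rim))
  lm
}

#' Write landmarks to JSON
#' @param landmarks named list of 3-vectors / point matrices.
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
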