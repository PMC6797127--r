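# Parametric hemipelvis phantom: a spherical bone shell around a
# hemispherical acetabular cavity with a cylindrical lateral opening, carved
# defects with exact ground truth. The phantom is deliberately stylized --
# ground-truth exactness is prioritized over anatomical realism.
#
# Canonical (right-side) phantom frame: CoR at the origin, X lateral,
# Y anterior, Z cranial; the acetabular opening plane is x = 0 with the rim
# circle of the acetabular radius around the origin. The outer bone sphere
# is shifted laterally so the medial wall is thin and the lateral columns
# are thick, as in a real hemipelvis.

#' Phantom specification
#'
#' Defines one synthetic hemipelvis case. All geometry is expressed in the
#' canonical right-side frame (CoR at origin, X lateral, Y anterior,
#' Z cranial); left-side cases are produced by mirroring the finished scene.
#'
#' @param acetabular_radius cavity radius in mm (default 26).
#' @param shell_thickness outer-shell thickness lateral of the cavity, mm;
#'   the outer bone sphere has radius `acetabular_radius + shell_thickness`.
#' @param lateral_shift lateral offset of the outer sphere center, mm; must
#'   stay below `shell_thickness` so the medial wall is closed.
#' @param bites list of `list(center, radius)` spheres carved from the
#'   native bone (bone volume loss). Centers must lie inside native bone.
#' @param blobs list of `list(center, radius)` spheres of new bone added to
#'   the defect model (bone formation), typically on the outer cortex.
#' @param punches list of `list(azimuth, diameter, side)` cylindrical rim
#'   holes; azimuth in degrees from cranial toward anterior, `side`
#'   `"lateral"` (wedge sectors) or `"medial"`.
#' @param erosions list of `list(azimuth = c(from, to), depth)` rim erosion
#'   arcs: all bone within `depth` mm of the rim arc is removed.
#' @param implant `NULL`, or `list(radius, migration)` with the migration
#'   vector (lateral, anterior, cranial) in mm.
#' @param ovality_axes semi-axes (major, minor) of the defect rim ellipse in
#'   mm; equal values give a circular defect rim.
#' @param ovality_angle in-plane rotation of the rim ellipse, radians.
#' @param lce_deg true lateral center-edge angle in degrees.
#' @param pd_flag pelvic discontinuity (image-based input flag).
#' @param side analyzed side, `"R"` or `"L"`.
#' @param point_noise_sd isotropic Gaussian noise (mm) added to sampled rim
#'   and implant surface points; emulates landmarking/segmentation jitter.
#' @param mesh_pitch marching-tetrahedra sampling pitch for the emitted
#'   surface meshes, mm.
#' @param truth_pitch voxel pitch of the ground-truth volume oracle, mm.
#' @param seed RNG seed fixing the sampled points.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(acetabular_radius = 26, shell_thickness = 7,
                         lateral_shift = 6, bites = list(), blobs = list(),
                         punches = list(), erosions = list(), implant = NULL,
                         ovality_axes = c(26, 26), ovality_angle = 0,
                         lce_deg = 30, pd_flag = FALSE, side = "R",
                         point_noise_sd = 0.1, mesh_pitch = 0.5,
                         truth_pitch = 0.1, seed = 1) {
  stopifnot(acetabular_radius > 0, shell_thickness > 0,
            lateral_shift < shell_thickness, mesh_pitch > 0,
            truth_pitch > 0, length(ovality_axes) == 2)
  if (ovality_axes[1] < ovality_axes[2])
    ovality_axes <- rev(ovality_axes)
  structure(list(acetabular_radius = acetabular_radius,
                 shell_thickness = shell_thickness,
                 lateral_shift = lateral_shift, bites = bites, blobs = blobs,
                 punches = punches, erosions = erosions, implant = implant,
                 ovality_axes = ovality_axes, ovality_angle = ovality_angle,
                 lce_deg = lce_deg, pd_flag = isTRUE(pd_flag),
                 side = match.arg(side, c("R", "L")),
                 point_noise_sd = point_noise_sd, mesh_pitch = mesh_pitch,
                 truth_pitch = truth_pitch, seed = as.integer(seed)),
            class = "phantom_spec")
}

# geometry parameter list consumed by the C++ CSG evaluator
phantom_geom <- function(spec) {
  rac <- spec$acetabular_radius
  bites <- if (length(spec$bites)) do.call(rbind, lapply(spec$bites,
    function(b) c(b$center, b$radius))) else matrix(numeric(0), 0, 4)
  blobs <- if (length(spec$blobs)) do.call(rbind, lapply(spec$blobs,
    function(b) c(b$center, b$radius))) else matrix(numeric(0), 0, 4)
  punches <- if (length(spec$punches)) do.call(rbind, lapply(spec$punches,
    function(p) {
      dir <- c(0, sin(p$azimuth * pi / 180), cos(p$azimuth * pi / 180))
      xoff <- if (identical(p$side, "medial")) -3 else 3
      a <- c(xoff, (rac - 2) * dir[2:3])
      b <- c(xoff, (rac + 6) * dir[2:3])
      c(a, b, p$diameter / 2)
    })) else matrix(numeric(0), 0, 7)
  erosions <- if (length(spec$erosions)) do.call(rbind,
    lapply(spec$erosions, function(e)
      c(e$azimuth[1], e$azimuth[2], e$depth, rac))) else
    matrix(numeric(0), 0, 4)
  imp <- if (!is.null(spec$implant))
    c(spec$implant$migration, spec$implant$radius) else numeric(0)
  list(outer_center = c(spec$lateral_shift, 0, 0),
       outer_radius = rac + spec$shell_thickness,
       acetabular_radius = rac, bites = bites, punches = punches,
       erosions = erosions, blobs = blobs, implant = imp)
}

# canonical-frame sector parameters used by the truth oracle
phantom_sector_args <- function(spec, roi_radius_factor = 2,
                                medial_offset = 0) {
  list(cor = c(0, 0, 0), yaxis = c(0, 1, 0), zaxis = c(0, 0, 1),
       normal = c(1, 0, 0),
       roi_radius = roi_radius_factor * spec$acetabular_radius,
       medial_offset = medial_offset,
       wedge_centers = c(0, 120, -120), wedge_halfwidths = c(60, 60, 60))
}

phantom_bbox <- function(geom, pad) {
  lo <- geom$outer_center - geom$outer_radius
  hi <- geom$outer_center + geom$outer_radius
  if (nrow(geom$blobs) > 0) {
    lo <- pmin(lo, apply(geom$blobs[, 1:3, drop = FALSE] -
                           geom$blobs[, 4], 2, min))
    hi <- pmax(hi, apply(geom$blobs[, 1:3, drop = FALSE] +
                           geom$blobs[, 4], 2, max))
  }
  list(lo = lo - pad, hi = hi + pad)
}

mesh_from_sdf <- function(geom, what, pitch, bbox, name) {
  # irrational origin offset keeps SDF zero level sets off the node lattice
  lo <- bbox$lo - pitch * GRID_JITTER
  ndim <- as.integer(ceiling((bbox$hi - lo) / pitch)) + 2L
  field <- phantom_field_cpp(lo, pitch, ndim, geom, what)
  res <- marching_tets_cpp(field, ndim, lo, pitch, 0)
  solid_mesh(res$vertices, res$faces, name = name, clean = FALSE)
}

# axis-aligned boxes around the carved regions (loss can only occur there);
# overlapping boxes are merged so the oracle never double-counts
carve_boxes <- function(geom, pad = 1.5) {
  boxes <- list()
  addbox <- function(lo, hi)
    boxes[[length(boxes) + 1]] <<- list(lo = lo - pad, hi = hi + pad)
  if (nrow(geom$bites) > 0)
    for (i in seq_len(nrow(geom$bites)))
      addbox(geom$bites[i, 1:3] - geom$bites[i, 4],
             geom$bites[i, 1:3] + geom$bites[i, 4])
  if (nrow(geom$punches) > 0)
    for (i in seq_len(nrow(geom$punches)))
      addbox(pmin(geom$punches[i, 1:3], geom$punches[i, 4:6]) -
               geom$punches[i, 7],
             pmax(geom$punches[i, 1:3], geom$punches[i, 4:6]) +
               geom$punches[i, 7])
  if (nrow(geom$erosions) > 0)
    for (i in seq_len(nrow(geom$erosions))) {
      th <- seq(geom$erosions[i, 1], geom$erosions[i, 2],
                length.out = 32) * pi / 180
      ring <- cbind(0, geom$erosions[i, 4] * sin(th),
                    geom$erosions[i, 4] * cos(th))
      addbox(apply(ring, 2, min) - geom$erosions[i, 3],
             apply(ring, 2, max) + geom$erosions[i, 3])
    }
  merge_boxes(boxes)
}

blob_boxes <- function(geom, pad = 1.5) {
  boxes <- list()
  if (nrow(geom$blobs) > 0)
    for (i in seq_len(nrow(geom$blobs)))
      boxes[[length(boxes) + 1]] <-
        list(lo = geom$blobs[i, 1:3] - geom$blobs[i, 4] - pad,
             hi = geom$blobs[i, 1:3] + geom$blobs[i, 4] + pad)
  merge_boxes(boxes)
}

merge_boxes <- function(boxes) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i < length(boxes)) {
      j <- i + 1
      while (j <= length(boxes)) {
        a <- boxes[[i]]
        b <- boxes[[j]]
        if (all(a$lo <= b$hi) && all(b$lo <= a$hi)) {
          boxes[[i]] <- list(lo = pmin(a$lo, b$lo), hi = pmax(a$hi, b$hi))
          boxes[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  boxes
}

truth_tally <- function(boxes, geom, sector, pitch) {
  loss <- numeric(5)
  form <- numeric(5)
  for (b in boxes) {
    t <- phantom_truth_cpp(b$lo, b$hi, pitch, geom, sector)
    loss <- loss + t$loss_mm3
    form <- form + t$formation_mm3
  }
  list(loss_ml = loss[2:5] / 1000, formation_ml = form[2:5] / 1000)
}

# full-domain native tally (per-sector native bone volume, ml)
native_truth <- function(geom, sector, pitch = 0.2) {
  bb <- phantom_bbox(geom, pad = 1)
  phantom_truth_cpp(bb$lo, bb$hi, pitch, geom, sector)$native_mm3[2:5] / 1000
}

fibonacci_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Generate one phantom case
#'
#' Builds the native and defect solids (and, if specified, the implant) as
#' watertight triangle meshes, the landmark set, sampled rim and implant
#' surface points, and the exact ground truth for every pipeline parameter.
#' Ground-truth volumes come from the generator's own fine-pitch voxel
#' oracle evaluated on the constructive solid geometry, independent of the
#' mesh pipeline under test. Fully reproducible from the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param native_ml_cache optional precomputed per-sector native volumes
#'   (ml), reused across a cohort sharing one bone geometry.
#' @param meshes if `FALSE`, skip surface meshing and return landmarks and
#'   truth only (used when assembling cohort truth tables).
#' @param truth if `FALSE`, skip the ground-truth oracle (used when a
#'   cohort truth table already holds it).
#' @param native_mesh_cache optional precomputed native `solid_mesh` in the
#'   canonical (right-side) frame, reused across a cohort sharing one bone
#'   geometry. Only valid when the bone and blob bounding box match the
#'   spec; [analyze_cohort()] manages this internally.
#' @return list with `native`, `defect`, `implant` (or `NULL`),
#'   `landmarks` (including the native `acetabular_rim` and the
#'   `defect_rim` and `implant_points` matrices), `truth`, and `spec`.
#' @export
generate_phantom <- function(spec, native_ml_cache = NULL, meshes = TRUE,
                             native_mesh_cache = NULL, truth = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  geom <- phantom_geom(spec)
  sector <- phantom_sector_args(spec)
  rac <- spec$acetabular_radius

  # validate carve placement: bite centers must lie inside native bone
  if (nrow(geom$bites) > 0) {
    sd <- phantom_sdf_cpp(geom$bites[, 1:3, drop = FALSE], geom, "native")
    if (any(sd >= 0))
      stop("bite center(s) outside the native bone: ",
           paste(which(sd >= 0), collapse = ", "), call. = FALSE)
  }

  native <- defect <- implant <- NULL
  if (meshes) {
    bbox <- phantom_bbox(geom, pad = 2 * spec$mesh_pitch)
    native <- if (is.null(native_mesh_cache))
      mesh_from_sdf(geom, "native", spec$mesh_pitch, bbox, "native") else
      native_mesh_cache
    defect <- mesh_from_sdf(geom, "defect", spec$mesh_pitch, bbox, "defect")
  }
  implant_points <- NULL
  if (!is.null(spec$implant)) {
    ic <- spec$implant$migration
    ir <- spec$implant$radius
    if (meshes) {
      ib <- list(lo = ic - ir - 2, hi = ic + ir + 2)
      implant <- mesh_from_sdf(geom, "implant", 0.35, ib, "implant")
    }
    dirs <- fibonacci_dirs(600)
    dirs <- dirs[dirs[, 1] < -0.05, , drop = FALSE][1:240, , drop = FALSE]
    implant_points <- sweep(ir * dirs, 2, -ic) +
      matrix(stats::rnorm(720, 0, spec$point_noise_sd), ncol = 3)
  }

  # native rim circle and defect rim ellipse samples
  th <- seq(0, 2 * pi, length.out = 73)[-73]
  native_rim <- cbind(0, rac * sin(th), rac * cos(th)) +
    matrix(stats::rnorm(216, 0, spec$point_noise_sd), ncol = 3)
  a <- spec$ovality_axes[1]
  b <- spec$ovality_axes[2]
  psi <- spec$ovality_angle
  e1 <- c(0, sin(psi), cos(psi))
  e2 <- c(0, cos(psi), -sin(psi))
  defect_rim <- outer(a * cos(th), e1) + outer(b * sin(th), e2) +
    matrix(stats::rnorm(216, 0, spec$point_noise_sd), ncol = 3)

  lce <- spec$lce_deg * pi / 180
  lateral_edge <- 45 * c(sin(lce), 0, cos(lce)) + c(0, 4, 0)

  landmarks <- list(asis_right = c(112, 30, 10), asis_left = c(-108, 30, 10),
                    symphysis = c(2, 30, -80), cor = c(0, 0, 0),
                    lateral_edge = lateral_edge,
                    acetabular_rim = native_rim, defect_rim = defect_rim)
  if (!is.null(implant_points)) landmarks$implant_points <- implant_points

  # ground truth (skippable when a cohort truth table already exists)
  truth_out <- NULL
  if (truth) {
  native_ml <- if (is.null(native_ml_cache))
    native_truth(geom, sector) else native_ml_cache
  tal <- truth_tally(merge_boxes(c(carve_boxes(geom), blob_boxes(geom))),
                     geom, sector, spec$truth_pitch)
  rv <- ifelse(native_ml > 0, 100 * tal$loss_ml / native_ml, NA_real_)
  rf <- ifelse(native_ml > 0, 100 * tal$formation_ml / native_ml, NA_real_)
  wall <- stats::setNames(rep(FALSE, 4), SECTORS)
  for (p in spec$punches) {
    if (p$diameter < 5) next
    if (identical(p$side, "medial")) wall["Medial"] <- TRUE
    else wall[wedge_of_azimuth(p$azimuth)] <- TRUE
  }
  for (e in spec$erosions) {
    if (e$depth < 5) next
    wall[unique(vapply(seq(e$azimuth[1], e$azimuth[2], by = 5),
                       wedge_of_azimuth, character(1)))] <- TRUE
  }
  mig <- NULL
  if (!is.null(spec$implant)) {
    comp <- c(lateral = spec$implant$migration[1],
              anterior = spec$implant$migration[2],
              cranial = spec$implant$migration[3])
    mig <- list(vector = spec$implant$migration, components = comp,
                total = sqrt(sum(comp^2)),
                predominant = predominant_direction(comp))
  }
  truth_out <- list(native_ml = stats::setNames(native_ml, SECTORS),
                loss_ml = stats::setNames(tal$loss_ml, SECTORS),
                formation_ml = stats::setNames(tal$formation_ml, SECTORS),
                loss_pct = stats::setNames(rv, SECTORS),
                formation_pct = stats::setNames(rf, SECTORS),
                ovality = a / b, lce_deg = spec$lce_deg, migration = mig,
                wall = wall, pd_flag = spec$pd_flag,
                group = assign_group(rv, spec$pd_flag))
  }

  out <- list(native = native, defect = defect, implant = implant,
              landmarks = landmarks, truth = truth_out, spec = spec)
  if (spec$side == "L") out <- mirror_phantom(out)
  out
}

wedge_of_azimuth <- function(azimuth) {
  a <- ((azimuth + 180) %% 360) - 180
  if (abs(a) <= 60) "Cranial" else if (a > 0) "Anterior" else "Posterior"
}

# mirror a finished canonical (right) phantom into a left-side case
mirror_phantom <- function(ph) {
  pl <- list(point = c(0, 0, 0), normal = c(1, 0, 0))
  mir <- function(p) mirror_points(p, pl$point, pl$normal)
  if (!is.null(ph$native))
    ph$native <- mirror_mesh(ph$native, pl$point, pl$normal)
  if (!is.null(ph$defect))
    ph$defect <- mirror_mesh(ph$defect, pl$point, pl$normal)
  if (!is.null(ph$implant))
    ph$implant <- mirror_mesh(ph$implant, pl$point, pl$normal)
  lm <- lapply(ph$landmarks, mir)
  tmp <- lm$asis_left            # anatomical labels swap under reflection
  lm$asis_left <- lm$asis_right
  lm$asis_right <- tmp
  ph$landmarks <- lm
  ph
}

#' Write a phantom case to disk
#'
#' STL meshes, a landmark JSON and a truth CSV, in the layout consumed by
#' [analyze_case()].
#' @param ph a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @param id case identifier used as the file stem.
#' @return the case directory, invisibly.
#' @export
write_phantom <- function(ph, dir, id = "case") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_solid(ph$native, file.path(dir, paste0(id, "_native.stl")))
  write_solid(ph$defect, file.path(dir, paste0(id, "_defect.stl")))
  if (!is.null(ph$implant))
    write_solid(ph$implant, file.path(dir, paste0(id, "_implant.stl")))
  write_landmarks(ph$landmarks, file.path(dir, paste0(id, "_landmarks.json")))
  tr <- ph$truth
  if (!is.null(tr)) {
    df <- data.frame(sector = SECTORS, native_ml = tr$native_ml,
                     loss_ml = tr$loss_ml, loss_pct = tr$loss_pct,
                     formation_ml = tr$formation_ml,
                     formation_pct = tr$formation_pct)
    utils::write.csv(df, file.path(dir, paste0(id, "_truth.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
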