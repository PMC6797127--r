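# Synthetic cohort generator: phantom cases spanning the defect groups, with
# per-sector loss targets met by solving bite radii against the generator's
# own voxel oracle.

# canonical bite sites per sector: unit directions and center radii in the
# canonical frame; chosen mid-shell, clear of the rim band and of the wedge
# boundaries
bite_sites <- function() {
  lat <- function(phi_deg) {
    phi <- phi_deg * pi / 180
    c(sin(18 * pi / 180), cos(18 * pi / 180) * sin(phi),
      cos(18 * pi / 180) * cos(phi))
  }
  med <- function(v) v / sqrt(sum(v^2))
  list(
    Cranial = list(dirs = lapply(c(-28, 0, 28), lat), t = 30, rmax = 7.2),
    Anterior = list(dirs = lapply(c(92, 120, 148), lat), t = 30, rmax = 7.2),
    Posterior = list(dirs = lapply(c(-92, -120, -148), lat), t = 30,
                     rmax = 7.2),
    Medial = list(dirs = list(med(c(-0.45, 0.60, 0.66)),
                              med(c(-0.45, -0.60, 0.66)),
                              med(c(-0.50, 0, -0.87)),
                              med(c(-0.45, 0.78, -0.43)),
                              med(c(-0.45, -0.78, -0.43))), t = 28,
                  rmax = 9.5))
}

# candidate formation blob directions (from the outer-sphere center), one
# per sector, away from the bite sites and the rim band
blob_sites <- function() {
  nrm <- function(v) v / sqrt(sum(v^2))
  list(Cranial = nrm(c(0.30, 0.15, 0.94)),
       Anterior = nrm(c(0.10, 0.80, -0.59)),
       Posterior = nrm(c(0.05, -0.80, -0.60)),
       # the medial site sits where the medial wall is thickest so surface
       # blobs do not breach into the acetabular cavity
       Medial = nrm(c(-0.35, 0.75, 0.56)))
}

# loss (ml) inside one sector for bites of common radius r at given centers,
# evaluated with the oracle over merged boxes around the sites
sector_bite_loss <- function(geom, centers, r, sector_args, sector_idx,
                             pitch = 0.35) {
  geom$bites <- rbind(geom$bites,
                      cbind(do.call(rbind, centers), r))
  boxes <- merge_boxes(lapply(centers, function(c)
    list(lo = c - r - 1.5, hi = c + r + 1.5)))
  truth_tally(boxes, geom, sector_args, pitch)$loss_ml[sector_idx]
}

# bisect the common bite radius so the sector loss hits target_ml
solve_bite_radius <- function(geom, centers, target_ml, sector_args,
                              sector_idx, rmax) {
  if (target_ml <= 0) return(NULL)
  hi_loss <- sector_bite_loss(geom, centers, rmax, sector_args, sector_idx)
  if (hi_loss <= target_ml) return(rmax)
  lo <- 0.8
  hi <- rmax
  for (i in 1:14) {
    mid <- (lo + hi) / 2
    if (sector_bite_loss(geom, centers, mid, sector_args,
                         sector_idx) < target_ml) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# the 16 sector combinations in canonical order (All intact first)
sector_combos <- function() {
  unlist(lapply(0:4, function(k)
    utils::combn(SECTORS, k, simplify = FALSE)), recursive = FALSE)
}

#' Generate a synthetic cohort of phantom cases
#'
#' Builds `n` phantom case specifications with known ground truth. In
#' coverage mode the first 17 cases realize every defect group (the 16
#' sector combinations plus one pelvic-discontinuity case); further cases
#' draw random group patterns. Per-sector relative-loss targets are drawn
#' well clear of the relevance thresholds (flagged sectors aim at roughly
#' 28-38\%, unflagged at 3-12\%) and bite radii are solved against the
#' generator's voxel oracle so each case lands in its intended group.
#'
#' @param n number of cases.
#' @param seed cohort seed; fixes targets, patterns and all per-case seeds.
#' @param coverage guarantee all 17 groups when `n >= 17`.
#' @param implant_rate fraction of cases with a segmentable implant.
#' @param left_rate fraction of left-side cases.
#' @return object of class `phantom_cohort`: list with `specs` (length-n
#'   list of [phantom_spec()]), `truth` (per-case metrics table in the
#'   cohort layout) and `native_ml` (shared per-sector native volumes).
#' @export
generate_cohort <- function(n = 20, seed = 1, coverage = TRUE,
                            implant_rate = 0.64, left_rate = 0.4) {
  stopifnot(n >= 1)
  set.seed(seed)
  sites <- bite_sites()
  bsites <- blob_sites()
  base_spec <- phantom_spec(seed = seed)
  geom0 <- phantom_geom(base_spec)
  sector_args <- phantom_sector_args(base_spec)
  native_ml <- native_truth(geom0, sector_args)

  combos <- sector_combos()
  case_seeds <- sample.int(10^8, n)
  specs <- vector("list", n)
  rows <- vector("list", n)

  for (i in seq_len(n)) {
    pd <- FALSE
    if (coverage && i <= 17) {
      if (i <= 16) flagged <- combos[[i]]
      else {
        flagged <- c("Cranial", "Posterior", "Medial")
        pd <- TRUE
      }
    } else {
      flagged <- combos[[sample.int(16, 1)]]
      pd <- stats::runif(1) < 0.1
    }

    # per-sector relative-loss targets (percent of native sector volume)
    targ <- vapply(SECTORS, function(s) {
      if (s %in% flagged) {
        if (s == "Posterior") stats::runif(1, 24, 32)
        else if (s == "Medial") stats::runif(1, 28, 34)
        else stats::runif(1, 29, 38)
      } else {
        if (s == "Posterior") stats::runif(1, 3, 8)
        else stats::runif(1, 6, 12)
      }
    }, numeric(1))

    # wall pattern: flagged sectors get a clear hole (or an erosion arc for
    # Cranial in some cases); a few unflagged sectors get sub-threshold
    # holes that must not trip the detector
    punches <- list()
    erosions <- list()
    wall_azimuth <- c(Cranial = 0, Anterior = 120, Posterior = -120)
    for (s in SECTORS) {
      if (s %in% flagged) {
        if (s == "Cranial" && stats::runif(1) < 0.3) {
          erosions[[length(erosions) + 1]] <-
            list(azimuth = c(-25, 25), depth = 7)
        } else if (s == "Medial") {
          # azimuths in the gaps between the lateral punch bands so nearby
          # medial/lateral tubes cannot merge into one loss component
          punches[[length(punches) + 1]] <-
            list(azimuth = sample(c(-70, -50, 50, 70), 1) +
                   stats::runif(1, -5, 5),
                 diameter = 7, side = "medial")
        } else {
          punches[[length(punches) + 1]] <-
            list(azimuth = wall_azimuth[[s]] + stats::runif(1, -20, 20),
                 diameter = 7, side = "lateral")
        }
      } else if (s != "Medial" && stats::runif(1) < 0.3) {
        punches[[length(punches) + 1]] <-
          list(azimuth = wall_azimuth[[s]] + stats::runif(1, -20, 20),
               diameter = 3.5, side = "lateral")
      }
    }

    # formation blobs on the outer cortex (1-2 sectors)
    blobs <- list()
    for (s in sample(SECTORS, sample(1:2, 1))) {
      ctr <- geom0$outer_center + geom0$outer_radius * bsites[[s]]
      rmax_blob <- if (s == "Medial") 5 else 6.5
      blobs[[length(blobs) + 1]] <-
        list(center = ctr, radius = stats::runif(1, 4, rmax_blob))
    }

    implant <- NULL
    if (stats::runif(1) < implant_rate)
      implant <- list(radius = 24,
                      migration = c(stats::runif(1, -8, 8),
                                    stats::runif(1, -12, 6),
                                    stats::runif(1, 6, 30)))

    ov <- stats::runif(1, 1.0, 1.7)
    spec_i <- phantom_spec(
      bites = list(), blobs = blobs, punches = punches, erosions = erosions,
      implant = implant,
      ovality_axes = c(base_spec$acetabular_radius * ov,
                       base_spec$acetabular_radius),
      ovality_angle = stats::runif(1, 0, pi),
      lce_deg = stats::runif(1, 12, 55), pd_flag = pd,
      side = if (stats::runif(1) < left_rate) "L" else "R",
      seed = case_seeds[i])

    # solve bite radii sector by sector against the oracle, with all fixed
    # carves and blobs already in the geometry
    geom_i <- phantom_geom(spec_i)
    bites <- list()
    for (s in SECTORS) {
      si <- sites[[s]]
      centers <- lapply(si$dirs, function(d) si$t * d)
      target_ml <- targ[[s]] / 100 * native_ml[match(s, SECTORS)]
      r <- solve_bite_radius(geom_i, centers, target_ml, sector_args,
                             match(s, SECTORS), si$rmax)
      if (is.null(r)) next
      for (ctr in centers) bites[[length(bites) + 1]] <-
        list(center = ctr, radius = r)
      geom_i$bites <- rbind(geom_i$bites,
                            cbind(do.call(rbind, centers), r))
    }
    spec_i$bites <- bites
    specs[[i]] <- spec_i

    ph <- generate_phantom(spec_i, native_ml_cache = native_ml,
                           meshes = FALSE)
    rows[[i]] <- phantom_truth_row(i, ph)
  }

  structure(list(specs = specs, truth = do.call(rbind, rows),
                 native_ml = native_ml, seed = seed),
            class = "phantom_cohort")
}

phantom_truth_row <- function(id, ph) {
  tr <- ph$truth
  mig <- tr$migration
  df <- data.frame(id = id, side = ph$spec$side,
                   group = tr$group$label,
                   pelvic_discontinuity = tr$pd_flag,
                   ovality = tr$ovality, lce_deg = tr$lce_deg,
                   migration_total = if (is.null(mig)) NA_real_ else
                     mig$total,
                   migration_lateral = if (is.null(mig)) NA_real_ else
                     mig$components[["lateral"]],
                   migration_anterior = if (is.null(mig)) NA_real_ else
                     mig$components[["anterior"]],
                   migration_cranial = if (is.null(mig)) NA_real_ else
                     mig$components[["cranial"]])
  for (s in SECTORS) {
    i <- match(s, SECTORS)
    df[[paste0("native_ml_", s)]] <- tr$native_ml[[i]]
    df[[paste0("loss_ml_", s)]] <- tr$loss_ml[[i]]
    df[[paste0("loss_pct_", s)]] <- tr$loss_pct[[i]]
    df[[paste0("formation_ml_", s)]] <- tr$formation_ml[[i]]
    df[[paste0("formation_pct_", s)]] <- tr$formation_pct[[i]]
    df[[paste0("wall_", s)]] <- tr$wall[[i]]
  }
  df
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort: %d cases, %d groups represented>\n",
              length(x$specs), length(unique(x$truth$group))))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-case STL + landmark JSON + truth CSV plus a YAML manifest consumable
#' by [analyze_cohort()].
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  nat <- cohort_native_mesh(cohort)
  for (i in seq_along(cohort$specs)) {
    id <- sprintf("case%02d", i)
    ph <- generate_phantom(cohort$specs[[i]],
                           native_ml_cache = cohort$native_ml,
                           native_mesh_cache = nat, truth = FALSE)
    write_phantom(ph, file.path(dir, id), id)
    entries[[i]] <- list(
      id = id, side = ph$spec$side,
      pelvic_discontinuity = ph$spec$pd_flag,
      native = file.path(id, paste0(id, "_native.stl")),
      defect = file.path(id, paste0(id, "_defect.stl")),
      implant = if (is.null(ph$implant)) NULL else
        file.path(id, paste0(id, "_implant.stl")),
      landmarks = file.path(id, paste0(id, "_landmarks.json")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(seed = cohort$seed, cases = entries), manifest)
  invisible(manifest)
}

# the cohort shares one bone geometry: mesh the native solid once (in the
# canonical right-side frame; per-case mirroring happens downstream)
cohort_native_mesh <- function(cohort) {
  base <- cohort$specs[[1]]
  empty <- phantom_spec(acetabular_radius = base$acetabular_radius,
                        shell_thickness = base$shell_thickness,
                        lateral_shift = base$lateral_shift,
                        mesh_pitch = base$mesh_pitch, seed = base$seed)
  geom <- phantom_geom(empty)
  mesh_from_sdf(geom, "native", empty$mesh_pitch,
                phantom_bbox(geom, pad = 2 * empty$mesh_pitch), "native")
}
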