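# Case and cohort orchestration: frame -> partition -> volumetry ->
# morphometrics -> grouping, with JSON/CSV reporting.

#' Default pipeline configuration
#'
#' All tunables in one list: voxel pitch (mm), Boolean method, relevance
#' thresholds (percent), sector geometry (ROI factor, medial offset, wedge
#' centers/widths in degrees), wall-defect parameters (mm) and the minimum
#' connected-component volume (ml). Every report embeds the resolved
#' configuration for reproducibility.
#' @export
default_config <- function() {
  list(pitch = 0.25, boolean_method = "voxel",
       thresholds = as.list(default_thresholds()),
       roi_radius_factor = 2, medial_offset = 0,
       wedge_centers = c(0, 120, -120), wedge_widths = c(120, 120, 120),
       wall_min_dim = 5, wall_band_width = 10, min_component_ml = 0.05)
}

#' Read a pipeline configuration YAML
#'
#' Missing entries fall back to [default_config()].
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg
}

#' Analyze one defect case
#'
#' Runs the full quantification pipeline on a paired native/defect
#' hemipelvis: builds the anatomical frame from the landmarks (mirroring
#' left-side cases), partitions the periacetabular region into four sectors,
#' computes per-sector bone volume loss and new bone formation, the
#' acetabular ovality, LCE angle, implant migration and wall-defect flags,
#' and assigns the defect group.
#'
#' @param native,defect `solid_mesh` objects or file paths (STL/PLY).
#' @param landmarks landmark list or JSON path; see [build_frame()]. The
#'   optional entries `defect_rim` (for ovality), `lateral_edge` (for the
#'   LCE angle) and `implant_points` (articulating-surface samples for the
#'   migration sphere fit) enable the corresponding parameters.
#' @param side analyzed side, `"R"` or `"L"`.
#' @param implant optional implant `solid_mesh` or path; used for the
#'   migration fit when `implant_points` are not provided.
#' @param pd_flag pelvic discontinuity (image-based diagnosis, input flag).
#' @param config pipeline configuration, see [default_config()].
#' @param id case identifier.
#' @return object of class `case_report`.
#' @export
analyze_case <- function(native, defect, landmarks, side = "R",
                         implant = NULL, pd_flag = FALSE,
                         config = default_config(), id = "case") {
  if (is.character(native)) native <- load_solid(native)
  if (is.character(defect)) defect <- load_solid(defect)
  if (is.character(implant)) implant <- load_solid(implant)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)

  frame <- build_frame(landmarks, side)
  native <- apply_frame_mirror(native, frame)
  defect <- apply_frame_mirror(defect, frame)
  if (!is.null(implant)) implant <- apply_frame_mirror(implant, frame)
  lm <- frame$landmarks  # landmarks after side normalization

  partition <- build_partition(frame, config$roi_radius_factor,
                               config$medial_offset, config$wedge_centers,
                               config$wedge_widths)
  vol <- sector_volumetry(native, defect, partition, pitch = config$pitch,
                          min_component_ml = config$min_component_ml)

  ov <- NULL
  if (!is.null(lm$defect_rim))
    ov <- ovality(lm$defect_rim, frame)
  lce <- NULL
  if (!is.null(lm$lateral_edge)) {
    theta <- lce_angle(lm$lateral_edge, frame)
    lce <- list(angle_deg = theta, classification = lce_classify(theta))
  }
  mig <- NULL
  if (!is.null(lm$implant_points)) {
    mig <- implant_migration(lm$implant_points, frame)
  } else if (!is.null(implant)) {
    mig <- implant_migration(implant, frame)
  }
  wall <- wall_defects(native, defect, partition, frame,
                       min_dim = config$wall_min_dim,
                       band_width = config$wall_band_width,
                       pitch = config$pitch, loss = vol)

  rv <- stats::setNames(vol$table$loss_pct, SECTORS)
  thresholds <- unlist(config$thresholds)[SECTORS]
  group <- assign_group(rv, pd_flag, thresholds)

  structure(list(id = id, side = side, volumetry = vol$table,
                 totals = vol$totals, ovality = ov, lce = lce,
                 migration = mig,
                 wall = as.logical(wall)[seq_len(4)] |>
                   stats::setNames(SECTORS),
                 wall_details = attr(wall, "details"), group = group,
                 spider = spider_plot_data(rv, group),
                 pd_flag = isTRUE(pd_flag), config = config),
            class = "case_report")
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report '%s' (%s): group '%s'>\n", x$id, x$side,
              x$group$label))
  v <- x$volumetry
  for (i in seq_len(nrow(v)))
    cat(sprintf("  %-9s loss %5.1f ml (%5.1f%%)  formation %5.1f ml\n",
                v$sector[i], v$loss_ml[i], v$loss_pct[i],
                v$formation_ml[i]))
  if (!is.null(x$ovality))
    cat(sprintf("  ovality %.2f (L %.1f / W %.1f mm)\n", x$ovality$ovality,
                x$ovality$length, x$ovality$width))
  if (!is.null(x$lce))
    cat(sprintf("  LCE angle %.1f deg (%s)\n", x$lce$angle_deg,
                x$lce$classification))
  if (!is.null(x$migration))
    cat(sprintf("  implant migration %.1f mm, predominantly %s\n",
                x$migration$total, x$migration$predominant))
  cat(sprintf("  wall defects: %s\n",
              if (any(x$wall)) paste(SECTORS[x$wall], collapse = ", ")
              else "none"))
  invisible(x)
}

#' Flatten a case report to one metrics row
#' @param report a `case_report`.
#' @return one-row data frame in the cohort metrics layout.
#' @export
case_metrics_row <- function(report) {
  mig <- report$migration
  df <- data.frame(
    id = report$id, side = report$side, group = report$group$label,
    paprosky = if (is.na(report$group$paprosky)) NA_character_ else
      report$group$paprosky,
    pelvic_discontinuity = report$pd_flag,
    length_mm = if (is.null(report$ovality)) NA_real_ else
      report$ovality$length,
    width_mm = if (is.null(report$ovality)) NA_real_ else
      report$ovality$width,
    ovality = if (is.null(report$ovality)) NA_real_ else
      report$ovality$ovality,
    lce_deg = if (is.null(report$lce)) NA_real_ else report$lce$angle_deg,
    migration_total = if (is.null(mig)) NA_real_ else mig$total,
    migration_lateral = if (is.null(mig)) NA_real_ else
      mig$components[["lateral"]],
    migration_anterior = if (is.null(mig)) NA_real_ else
      mig$components[["anterior"]],
    migration_cranial = if (is.null(mig)) NA_real_ else
      mig$components[["cranial"]])
  v <- report$volumetry
  for (i in seq_len(4)) {
    s <- SECTORS[i]
    df[[paste0("native_ml_", s)]] <- v$native_ml[i]
    df[[paste0("defect_ml_", s)]] <- v$defect_ml[i]
    df[[paste0("loss_ml_", s)]] <- v$loss_ml[i]
    df[[paste0("loss_pct_", s)]] <- v$loss_pct[i]
    df[[paste0("formation_ml_", s)]] <- v$formation_ml[i]
    df[[paste0("formation_pct_", s)]] <- v$formation_pct[i]
    df[[paste0("wall_", s)]] <- unname(report$wall[s])
  }
  df
}

#' Write a case report to JSON
#' @param report a `case_report`.
#' @param path output JSON path.
#' @export
write_case_report <- function(report, path) {
  out <- report
  out$volumetry <- as.list(report$volumetry)
  out$wall_details <- NULL
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Analyze a cohort
#'
#' Runs [analyze_case()] over every case of a cohort and assembles the
#' metrics table, descriptive statistics, pairwise sector-loss tests,
#' banded correlations, group counts and per-case spider-plot data.
#'
#' @param cohort either a [generate_cohort()] result (cases are regenerated
#'   from their specs) or the path to a manifest YAML listing per-case
#'   files (`native`, `defect`, `landmarks`, optional `implant`, `side`,
#'   `pelvic_discontinuity`).
#' @param config pipeline configuration.
#' @param out_dir optional output directory for CSV/JSON reports.
#' @param progress print one line per case.
#' @return object of class `cohort_report` with `metrics`, `stats`,
#'   `correlations`, `group_counts`, `reports`.
#' @export
analyze_cohort <- function(cohort, config = default_config(),
                           out_dir = NULL, progress = FALSE) {
  reports <- list()
  if (inherits(cohort, "phantom_cohort")) {
    nat <- cohort_native_mesh(cohort)
    for (i in seq_along(cohort$specs)) {
      ph <- generate_phantom(cohort$specs[[i]],
                             native_ml_cache = cohort$native_ml,
                             native_mesh_cache = nat, truth = FALSE)
      reports[[i]] <- analyze_case(ph$native, ph$defect, ph$landmarks,
                                   side = ph$spec$side,
                                   pd_flag = ph$spec$pd_flag,
                                   config = config,
                                   id = sprintf("case%02d", i))
      if (progress)
        message(sprintf("case %d/%d: %s", i, length(cohort$specs),
                        reports[[i]]$group$label))
    }
  } else {
    man <- yaml::read_yaml(cohort)
    base <- dirname(cohort)
    for (i in seq_along(man$cases)) {
      cs <- man$cases[[i]]
      reports[[i]] <- analyze_case(
        file.path(base, cs$native), file.path(base, cs$defect),
        file.path(base, cs$landmarks),
        side = if (is.null(cs$side)) "R" else cs$side,
        implant = if (is.null(cs$implant)) NULL else
          file.path(base, cs$implant),
        pd_flag = isTRUE(cs$pelvic_discontinuity), config = config,
        id = if (is.null(cs$id)) sprintf("case%02d", i) else cs$id)
      if (progress)
        message(sprintf("case %d/%d: %s", i, length(man$cases),
                        reports[[i]]$group$label))
    }
  }
  metrics <- do.call(rbind, lapply(reports, case_metrics_row))
  stats <- cohort_statistics(metrics)
  correlations <- tryCatch(correlation_matrix(metrics),
                           error = function(e) NULL)
  counts <- table(factor(metrics$group, levels = enumerate_groups()))
  group_counts <- data.frame(group = names(counts),
                             paprosky = paprosky_map(names(counts)),
                             n = as.integer(counts))
  out <- structure(list(metrics = metrics, stats = stats,
                        correlations = correlations,
                        group_counts = group_counts, reports = reports,
                        config = config),
                   class = "cohort_report")
  if (!is.null(out_dir)) write_cohort_report(out, out_dir)
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: %d cases>\n", nrow(x$metrics)))
  print(x$group_counts[x$group_counts$n > 0, ])
  invisible(x)
}

#' Write cohort report tables
#'
#' Volumetry table (per-sector native/defect volumes, absolute and relative
#' loss and formation), morphometrics table (length, width, ovality, LCE,
#' migration split by direction, wall flags), correlation table (variable
#' pair, R, band) and test-results table, plus group counts and per-case
#' JSON reports.
#' @param report a `cohort_report`.
#' @param dir output directory.
#' @export
write_cohort_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volumetry_table(report$metrics, file.path(dir, "volumetry.csv"))
  write_morphometrics_table(report$metrics,
                            file.path(dir, "morphometrics.csv"))
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$correlations))
    write_correlation_table(report$correlations,
                            file.path(dir, "correlations.csv"))
  if (!is.null(report$stats$pairwise))
    utils::write.csv(report$stats$pairwise, file.path(dir, "tests.csv"),
                     row.names = FALSE)
  utils::write.csv(report$group_counts, file.path(dir, "group_counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$config, file.path(dir, "config.json"),
                       digits = NA, auto_unbox = TRUE)
  for (r in report$reports)
    write_case_report(r, file.path(dir, paste0(r$id, "_report.json")))
  invisible(dir)
}
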