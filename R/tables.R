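# Cohort table layouts mirroring the supplementary raw-data files of
# published defect-quantification studies: a volumetry table (per-sector
# native/defect volumes in mm^3 with absolute and relative loss/formation),
# a morphometrics table (ovality, LCE, migration by direction, wall flags)
# and a correlation table (variable pair, R, band). CSV only.

#' Write the cohort volumetry table
#'
#' One row per case; per sector: native and defect volume (mm^3), absolute
#' loss (mm^3), relative loss (%), absolute formation (mm^3), relative
#' formation (%).
#' @param metrics cohort metrics table (from [analyze_cohort()]).
#' @param path output CSV.
#' @export
write_volumetry_table <- function(metrics, path) {
  out <- data.frame(case = metrics$id)
  for (s in SECTORS)
    out[[paste0("native_mm3_", s)]] <-
      metrics[[paste0("native_ml_", s)]] * 1000
  for (s in SECTORS)
    out[[paste0("defect_mm3_", s)]] <-
      metrics[[paste0("defect_ml_", s)]] * 1000
  for (s in SECTORS)
    out[[paste0("loss_mm3_", s)]] <- metrics[[paste0("loss_ml_", s)]] * 1000
  for (s in SECTORS)
    out[[paste0("loss_pct_", s)]] <- metrics[[paste0("loss_pct_", s)]]
  for (s in SECTORS)
    out[[paste0("formation_mm3_", s)]] <-
      metrics[[paste0("formation_ml_", s)]] * 1000
  for (s in SECTORS)
    out[[paste0("formation_pct_", s)]] <-
      metrics[[paste0("formation_pct_", s)]]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort volumetry table
#'
#' Accepts the layout written by [write_volumetry_table()] and converts it
#' back to the internal metrics column names (volumes in ml).
#' @param path CSV path.
#' @export
read_volumetry_table <- function(path) {
  raw <- utils::read.csv(path, check.names = TRUE)
  out <- data.frame(id = raw[[1]])
  for (s in SECTORS) {
    out[[paste0("native_ml_", s)]] <- raw[[paste0("native_mm3_", s)]] / 1000
    out[[paste0("defect_ml_", s)]] <- raw[[paste0("defect_mm3_", s)]] / 1000
    out[[paste0("loss_ml_", s)]] <- raw[[paste0("loss_mm3_", s)]] / 1000
    out[[paste0("loss_pct_", s)]] <- raw[[paste0("loss_pct_", s)]]
    out[[paste0("formation_ml_", s)]] <-
      raw[[paste0("formation_mm3_", s)]] / 1000
    out[[paste0("formation_pct_", s)]] <- raw[[paste0("formation_pct_", s)]]
  }
  out
}

#' Write the cohort morphometrics table
#'
#' One row per case: acetabular length and width (mm), ovality, LCE angle
#' (deg), total migration and its six directional components (mm; each
#' direction non-negative, the opposite direction zero), wall-defect flags
#' (0/1 per sector). Missing migration (no segmentable implant) stays
#' empty.
#' @inheritParams write_volumetry_table
#' @export
write_morphometrics_table <- function(metrics, path) {
  pospart <- function(x) ifelse(is.na(x), NA_real_, pmax(x, 0))
  out <- data.frame(
    case = metrics$id,
    length_mm = metrics$length_mm, width_mm = metrics$width_mm,
    ovality = metrics$ovality, lce_deg = metrics$lce_deg,
    migration_total = metrics$migration_total,
    migration_medial = pospart(-metrics$migration_lateral),
    migration_lateral = pospart(metrics$migration_lateral),
    migration_anterior = pospart(metrics$migration_anterior),
    migration_posterior = pospart(-metrics$migration_anterior),
    migration_cranial = pospart(metrics$migration_cranial),
    migration_distal = pospart(-metrics$migration_cranial))
  for (s in SECTORS)
    out[[paste0("wall_", s)]] <- as.integer(metrics[[paste0("wall_", s)]])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort morphometrics table
#'
#' Accepts the layout written by [write_morphometrics_table()]; signed
#' migration components are reconstructed from the paired direction
#' columns.
#' @param path CSV path.
#' @export
read_morphometrics_table <- function(path) {
  raw <- utils::read.csv(path)
  signed <- function(pos, neg) {
    p <- raw[[pos]]
    n <- raw[[neg]]
    ifelse(is.na(p) & is.na(n), NA_real_,
           ifelse(is.na(n) | (!is.na(p) & p >= n), p, -n))
  }
  out <- data.frame(id = raw[[1]], length_mm = raw$length_mm,
                    width_mm = raw$width_mm, ovality = raw$ovality,
                    lce_deg = raw$lce_deg,
                    migration_total = raw$migration_total,
                    migration_lateral = signed("migration_lateral",
                                               "migration_medial"),
                    migration_anterior = signed("migration_anterior",
                                                "migration_posterior"),
                    migration_cranial = signed("migration_cranial",
                                               "migration_distal"))
  for (s in SECTORS) {
    col <- paste0("wall_", s)
    if (!is.null(raw[[col]])) out[[col]] <- raw[[col]] != 0
  }
  out
}

#' Write the banded correlation table
#' @param correlations result of [correlation_matrix()].
#' @param path output CSV.
#' @export
write_correlation_table <- function(correlations, path) {
  utils::write.csv(correlations, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-case metrics table from CSV
#' @param path CSV path.
#' @export
read_metrics_table <- function(path) {
  utils::read.csv(path)
}
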