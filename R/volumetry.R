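# Per-sector bone volume loss and new bone formation.
#
# Native and defect solids are rasterized once on a common grid; the loss
# (native AND NOT defect) and formation (defect AND NOT native) occupancies
# are filtered for small connected components (shell artefacts from imperfect
# surface reconstructions) and tallied per sector. Relative values are always
# with respect to the native bone volume in the same sector.

sector_diff_volumes <- function(occ_x, occ_y, codes, grid,
                                min_component_ml = 0.05) {
  diffocc <- occ_op_cpp(occ_x, occ_y, 1L)
  if (min_component_ml > 0) {
    lab <- label_components_cpp(diffocc, grid$dims)
    ncomp <- attr(lab, "n_components")
    if (ncomp > 0) {
      sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
      keep <- sizes * grid$pitch^3 / 1000 >= min_component_ml
      if (!all(keep)) diffocc <- keep_components_cpp(lab, keep)
    }
  }
  counts <- tally_codes_cpp(diffocc, codes)  # codes 0..4
  list(ml = counts[2:5] * grid$pitch^3 / 1000, occupancy = diffocc)
}

volumetry_core <- function(native, defect, partition, pitch,
                           min_component_ml) {
  assert_watertight(native, "native solid")
  assert_watertight(defect, "defect solid")
  frame <- grid_frame(list(native, defect), pitch)
  gn <- voxelize(native, pitch, frame)
  gd <- voxelize(defect, pitch, frame)
  codes <- classify_grid(partition, gn)
  vnat <- tally_codes_cpp(gn$occupancy, codes)[2:5] * pitch^3 / 1000
  loss <- sector_diff_volumes(gn$occupancy, gd$occupancy, codes, gn,
                              min_component_ml)
  form <- sector_diff_volumes(gd$occupancy, gn$occupancy, codes, gn,
                              min_component_ml)
  list(grid = gn, grid_defect = gd, codes = codes, native_ml = vnat,
       loss_ml = loss$ml, formation_ml = form$ml,
       loss_occupancy = loss$occupancy,
       formation_occupancy = form$occupancy)
}

relative_pct <- function(abs_ml, native_ml) {
  out <- ifelse(native_ml > 0, 100 * abs_ml / native_ml, NA_real_)
  if (any(native_ml <= 0))
    warning("sector(s) with zero native volume: ",
            paste(SECTORS[native_ml <= 0], collapse = ", "),
            "; relative values reported as missing", call. = FALSE)
  out
}

sector_table <- function(native_ml, abs_ml, rel_pct, what) {
  df <- data.frame(sector = SECTORS, native_ml = native_ml, abs_ml = abs_ml,
                   rel_pct = rel_pct, row.names = NULL)
  names(df)[3:4] <- paste0(what, c("_ml", "_pct"))
  df
}

#' Per-sector bone volume loss
#'
#' Loss in each sector is the volume of (native minus defect) restricted to
#' the sector region, as absolute ml and relative to the native bone volume
#' in that sector.
#'
#' @param native,defect watertight `solid_mesh` objects in the same frame.
#' @param partition a [build_partition()] result.
#' @param pitch voxel pitch in mm (default 0.25).
#' @param min_component_ml connected components of the difference smaller
#'   than this volume (ml) are discarded as reconstruction shell artefacts;
#'   default 0.05 ml, well below any clinically reported sector loss.
#' @return data frame with columns `sector`, `native_ml`, `loss_ml`,
#'   `loss_pct`; totals in attribute `"totals"`; the filtered loss occupancy
#'   and grid in attributes `"occupancy"` and `"grid"`.
#' @export
bone_volume_loss <- function(native, defect, partition, pitch = 0.25,
                             min_component_ml = 0.05) {
  core <- volumetry_core(native, defect, partition, pitch, min_component_ml)
  rv <- relative_pct(core$loss_ml, core$native_ml)
  out <- sector_table(core$native_ml, core$loss_ml, rv, "loss")
  attr(out, "totals") <- c(native_ml = sum(core$native_ml),
                           loss_ml = sum(core$loss_ml),
                           loss_pct = 100 * sum(core$loss_ml) /
                             sum(core$native_ml))
  attr(out, "occupancy") <- core$loss_occupancy
  attr(out, "grid") <- core$grid
  out
}

#' Per-sector new bone formation
#'
#' Formation is the volume of (defect minus native) per sector, relative to
#' the native bone volume in that sector. Exactly symmetric to
#' [bone_volume_loss()] with the operands swapped.
#' @inheritParams bone_volume_loss
#' @return data frame with columns `sector`, `native_ml`, `formation_ml`,
#'   `formation_pct`; attributes as in [bone_volume_loss()].
#' @export
new_bone_formation <- function(native, defect, partition, pitch = 0.25,
                               min_component_ml = 0.05) {
  core <- volumetry_core(native, defect, partition, pitch, min_component_ml)
  rf <- relative_pct(core$formation_ml, core$native_ml)
  out <- sector_table(core$native_ml, core$formation_ml, rf, "formation")
  attr(out, "totals") <- c(native_ml = sum(core$native_ml),
                           formation_ml = sum(core$formation_ml),
                           formation_pct = 100 * sum(core$formation_ml) /
                             sum(core$native_ml))
  attr(out, "occupancy") <- core$formation_occupancy
  attr(out, "grid") <- core$grid
  out
}

#' Combined per-sector volumetry
#'
#' One voxelization pass returning native volume, loss and formation per
#' sector (absolute and relative), used by [analyze_case()].
#' @inheritParams bone_volume_loss
#' @return list with `table` (data frame: sector, native_ml, defect_ml,
#'   loss_ml, loss_pct, formation_ml, formation_pct), `totals`, and internal
#'   grids for downstream detectors.
#' @export
sector_volumetry <- function(native, defect, partition, pitch = 0.25,
                             min_component_ml = 0.05) {
  core <- volumetry_core(native, defect, partition, pitch, min_component_ml)
  vdef <- tally_codes_cpp(core$grid_defect$occupancy,
                          core$codes)[2:5] * pitch^3 / 1000
  tab <- data.frame(sector = SECTORS,
                    native_ml = core$native_ml,
                    defect_ml = vdef,
                    loss_ml = core$loss_ml,
                    loss_pct = relative_pct(core$loss_ml, core$native_ml),
                    formation_ml = core$formation_ml,
                    formation_pct = relative_pct(core$formation_ml,
                                                 core$native_ml),
                    row.names = NULL)
  totals <- c(native_ml = sum(core$native_ml),
              defect_ml = sum(vdef),
              loss_ml = sum(core$loss_ml),
              formation_ml = sum(core$formation_ml))
  list(table = tab, totals = totals, grid = core$grid,
       codes = core$codes, loss_occupancy = core$loss_occupancy,
       formation_occupancy = core$formation_occupancy)
}
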