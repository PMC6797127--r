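# Threshold-based defect grouping: relevance flags per sector, the 17 defect
# groups, the Paprosky correspondence, and spider-plot export.

#' Default relevance thresholds for clinically relevant bone loss
#'
#' Strict ("greater than") thresholds on relative bone volume loss:
#' 25\% in Cranial, Anterior and Medial; 15\% in Posterior, reflecting the
#' posterior column's importance for implant stability.
#' @export
default_thresholds <- function() {
  c(Cranial = 25, Anterior = 25, Posterior = 15, Medial = 25)
}

check_thresholds <- function(thresholds) {
  stopifnot(length(thresholds) == 4)
  if (is.null(names(thresholds))) names(thresholds) <- SECTORS
  thresholds <- thresholds[SECTORS]
  if (any(!is.finite(thresholds)) || any(thresholds <= 0) ||
      any(thresholds >= 100))
    stop("thresholds must lie strictly between 0 and 100 percent",
         call. = FALSE)
  thresholds
}

as_rv <- function(rv) {
  if (is.null(names(rv))) names(rv) <- SECTORS
  rv <- rv[SECTORS]
  if (any(is.na(rv)) || any(rv < 0 | rv > 100))
    stop("relative loss values must lie in [0, 100] percent, got (",
         paste(round(rv, 3), collapse = ", "), ")", call. = FALSE)
  rv
}

#' Sectors with clinically relevant bone loss
#'
#' A sector is flagged iff its relative bone volume loss strictly exceeds
#' its threshold; boundary values are not relevant.
#' @param rv named (or C, A, P, M ordered) vector of relative loss in
#'   percent.
#' @param thresholds per-sector thresholds in percent.
#' @return character vector of flagged sector names (possibly empty).
#' @export
relevance_flags <- function(rv, thresholds = default_thresholds()) {
  rv <- as_rv(rv)
  thresholds <- check_thresholds(thresholds)
  SECTORS[rv > thresholds]
}

group_label <- function(flagged) {
  flagged <- intersect(SECTORS, flagged)  # canonical C, A, P, M order
  if (length(flagged) == 0) return("All intact")
  if (length(flagged) == 4) return("All sectors")
  paste(flagged, collapse = "-")
}

#' Assign a case to its defect group
#'
#' The group is named after the sectors with relevant bone loss, in fixed
#' Cranial, Anterior, Posterior, Medial order; no flagged sector gives
#' "All intact", all four give "All sectors". A pelvic discontinuity (an
#' image-based diagnosis supplied as input) overrides the sector label.
#'
#' @inheritParams relevance_flags
#' @param pd_flag pelvic discontinuity present (logical).
#' @return object of class `defect_group`: list with `label`,
#'   `flagged_sectors`, `pelvic_discontinuity`, `paprosky`.
#' @export
assign_group <- function(rv, pd_flag = FALSE,
                         thresholds = default_thresholds()) {
  flagged <- relevance_flags(rv, thresholds)
  label <- if (isTRUE(pd_flag)) "Pelvic discontinuity" else
    group_label(flagged)
  out <- structure(list(label = label, flagged_sectors = flagged,
                        pelvic_discontinuity = isTRUE(pd_flag),
                        paprosky = NA_character_),
                   class = "defect_group")
  out$paprosky <- paprosky_map(out)
  out
}

#' @export
print.defect_group <- function(x, ...) {
  cat(sprintf("<defect_group '%s'%s>\n", x$label,
              if (!is.na(x$paprosky))
                paste0(" (Paprosky ", x$paprosky, ")") else ""))
  invisible(x)
}

#' All 17 defect group labels
#'
#' The 16 sector combinations (including "All intact" and "All sectors")
#' plus the separate "Pelvic discontinuity" group.
#' @return character vector of length 17.
#' @export
enumerate_groups <- function() {
  combos <- unlist(lapply(0:4, function(k)
    utils::combn(SECTORS, k, group_label, simplify = FALSE)),
    use.names = FALSE)
  c(combos, "Pelvic discontinuity")
}

#' Paprosky correspondence of a defect group
#'
#' Five groups have a published Paprosky counterpart: All intact -> 1/2A,
#' Cranial -> 2B, Medial -> 2C, Cranial-Medial -> 3A, All sectors -> 3B.
#' All other groups (including Pelvic discontinuity) have none.
#' @param group a `defect_group` or a group label.
#' @return the Paprosky label, or `NA` if unmapped.
#' @export
paprosky_map <- function(group) {
  label <- if (inherits(group, "defect_group")) group$label else group
  map <- c("All intact" = "1/2A", "Cranial" = "2B", "Medial" = "2C",
           "Cranial-Medial" = "3A", "All sectors" = "3B")
  unname(map[label])
}

#' Spider-plot data for one case
#'
#' Radial axes in fixed order Cranial, Anterior, Posterior, Medial; the case
#' polyline carries the relative loss values, the group polygon extends to
#' 100\% on flagged sectors and to 0 elsewhere (so "All intact" has zero
#' area).
#' @inheritParams relevance_flags
#' @param group optional precomputed `defect_group`.
#' @param pd_flag pelvic discontinuity flag (used if `group` is missing).
#' @return list with `axes`, `case` (rv polyline), `group_area`, `label`;
#'   serializable to JSON.
#' @export
spider_plot_data <- function(rv, group = NULL, pd_flag = FALSE,
                             thresholds = default_thresholds()) {
  rv <- as_rv(rv)
  if (is.null(group)) group <- assign_group(rv, pd_flag, thresholds)
  area <- ifelse(SECTORS %in% group$flagged_sectors, 100, 0)
  list(axes = SECTORS, case = unname(rv), group_area = unname(area),
       label = group$label, paprosky = group$paprosky)
}

#' Spider plot of relative bone loss and defect group
#' @param spider a [spider_plot_data()] result.
#' @return a ggplot object.
#' @export
plot_spider <- function(spider) {
  df <- data.frame(axis = factor(spider$axes, levels = spider$axes),
                   case = spider$case, area = spider$group_area)
  dfc <- rbind(df, df[1, ])
  dfc$ord <- c(seq_len(nrow(df)), nrow(df) + 1)
  ggplot2::ggplot(dfc, ggplot2::aes(x = ord)) +
    ggplot2::geom_area(ggplot2::aes(y = area), fill = "steelblue",
                       alpha = 0.4) +
    ggplot2::geom_line(ggplot2::aes(y = case), color = "red",
                       linewidth = 1) +
    ggplot2::geom_point(ggplot2::aes(y = case), color = "red") +
    ggplot2::scale_x_continuous(breaks = seq_len(nrow(df)),
                                labels = levels(df$axis)) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(title = spider$label, x = NULL,
                  y = "relative bone volume loss [%]") +
    ggplot2::theme_minimal()
}
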