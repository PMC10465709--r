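#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_polygon
#'   geom_point geom_tile geom_col scale_fill_gradient2 scale_fill_manual
#'   coord_equal facet_wrap labs theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot a phase field
#'
#' Raster of the phase field, masked to the domain when one is attached.
#' Low `phi` (dense fibrillar collagen) plots dark.
#'
#' @param object A [phase_field()].
#' @param mask Optional [domain_mask()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot phase_field
#' @export
autoplot.phase_field <- function(object, mask = NULL, ...) {
  dx <- object$grid$dx
  df <- tidyr::expand_grid(i = seq_len(object$grid$nx),
                           j = seq_len(object$grid$ny))
  df$phi <- as.vector(object$values)
  if (!is.null(mask)) df$phi[!as.vector(mask$mask)] <- NA
  df$x <- (df$i - 0.5) * dx
  df$y <- (df$j - 0.5) * dx
  ggplot(df, aes(.data$x, .data$y, fill = .data$phi)) +
    geom_raster() +
    scale_fill_gradient2(low = "#08306b", mid = "#f7f7f7", high = "#b2182b",
                         midpoint = 0, na.value = "grey85") +
    coord_equal() +
    labs(x = "x", y = "y", fill = expression(phi),
         title = sprintf("phase field, t = %g", object$time)) +
    theme_minimal()
}

#' Plot the observable series of a trajectory
#'
#' Free energy, protomer availability, crystallized fraction (and defect
#' proportion when recorded) against time, faceted on free scales.
#'
#' @param object A `pfc_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pfc_trajectory
#' @export
autoplot.pfc_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object$series, -"time",
                              names_to = "observable", values_to = "value")
  long <- long[!is.na(long$value), ]
  ggplot(long, aes(.data$time, .data$value)) +
    geom_line(linewidth = 0.4) +
    facet_wrap(~observable, scales = "free_y") +
    labs(x = "time (dimensionless)", y = NULL) +
    theme_minimal()
}

#' Voronoi defect map of a fibril pattern
#'
#' The conventional defect coloring: Voronoi cells of interior fibrils are
#' clear for six neighbors, red for five, blue for seven, gray otherwise;
#' peripheral fibrils are left uncolored.
#'
#' @param object A [defect_report()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot defect_report
#' @export
autoplot.defect_report <- function(object, ...) {
  pts <- object$points
  dl <- deldir::deldir(pts$x_nm, pts$y_nm, suppressMsge = TRUE)
  tiles <- deldir::tile.list(dl)
  polys <- purrr::imap_dfr(tiles, function(tl, k) {
    tibble(x = tl$x, y = tl$y, id = k, label = pts$label[k])
  })
  polys <- polys[polys$label != "peripheral", ]
  cols <- c(five = "#d7301f", six = "white", seven = "#0570b0",
            other = "grey60")
  ggplot(polys, aes(.data$x, .data$y, group = .data$id, fill = .data$label)) +
    geom_polygon(color = "grey30", linewidth = 0.2) +
    geom_point(data = dplyr::mutate(pts, id = dplyr::row_number()),
               aes(.data$x_nm, .data$y_nm, group = .data$id),
               inherit.aes = FALSE, size = 0.4) +
    scale_fill_manual(values = cols) +
    coord_equal() +
    labs(x = "x (nm)", y = "y (nm)", fill = "neighbors",
         title = sprintf("defect proportion d = %.3f", object$defect_proportion)) +
    theme_minimal()
}

#' Fold-change heatmap
#'
#' Heatmap of log2 fold changes relative to E12.5, one row per protein,
#' optionally grouped by annotation category.
#'
#' @param fc A fold-change table from [log2_fold_change()].
#' @param annotation Optional annotation, see [fold_change_long()].
#' @return A ggplot.
#' @export
plot_fold_change <- function(fc, annotation = NULL) {
  long <- fold_change_long(fc, annotation)
  p <- ggplot(long, aes(.data$timepoint, .data$protein, fill = .data$log2fc)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0) +
    labs(x = NULL, y = NULL, fill = "log2 FC vs E12.5") +
    theme_minimal()
  if (!is.null(annotation) && "category" %in% names(long)) {
    p <- p + facet_wrap(~category, scales = "free_y")
  }
  p
}
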