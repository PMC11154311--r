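# ggplot2 views of each result type. Colors for the distance traces follow
# the conventional coding: O12-Og blue, OH32-O18 green, OG35-Mg violet,
# OH32-Og red, OH32-OH40 yellow.

dist_palette <- function() {
  c(d_O12_Og = "#2166ac", d_OH32_O18 = "#1b7837", d_OG35_Mg = "#762a83",
    d_OH32_Og = "#b2182b", d_OH32_OH40 = "#e6ab02")
}

state_palette <- function() {
  c(S1 = "#777777", S2_OX = "#2166ac", S2_OY = "#1b7837",
    S2_OZ = "#b2182b", UNASSIGNED = "#d9d9d9")
}

#' Time-evolution plot of the five classifier distances
#' @param object A `ras_features` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_features <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), cols = feature_cols(),
                              names_to = "distance", values_to = "value_A")
  ggplot(long, aes(x = .data$frame, y = .data$value_A,
                   colour = .data$distance)) +
    geom_line(linewidth = 0.3) +
    scale_colour_manual(values = dist_palette()) +
    labs(x = "frame", y = "distance (Å)", colour = NULL) +
    theme_minimal()
}

#' State ribbon of a label series
#' @param object A `ras_labels` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_labels <- function(object, ...) {
  seg <- label_segments(object)
  ggplot(seg) +
    geom_rect(aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5,
                  ymin = 0, ymax = 1, fill = .data$label)) +
    scale_fill_manual(values = state_palette(), drop = FALSE) +
    labs(x = "frame", y = NULL, fill = "state") +
    theme_minimal() +
    theme(axis.text.y = element_blank())
}

#' Occupancy bar chart
#' @param object A `ras_occupancy` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_occupancy <- function(object, ...) {
  d <- dplyr::mutate(as_tibble(object), label = state_factor(.data$label))
  ggplot(d, aes(x = .data$label, y = 100 * .data$fraction,
                fill = .data$label)) +
    geom_col(show.legend = FALSE) +
    scale_fill_manual(values = state_palette()) +
    labs(x = NULL, y = "occupancy (%)") +
    theme_minimal()
}

#' Per-residue RMSF profile with switch regions marked
#' @param object A `ras_rmsf` tibble (possibly several states stacked).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_rmsf <- function(object, ...) {
  sw <- switch_residues()
  ggplot(as_tibble(object),
         aes(x = .data$resno, y = .data$rmsf_A, colour = .data$state)) +
    annotate("rect", xmin = min(sw$si), xmax = max(sw$si),
             ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "cyan3") +
    annotate("rect", xmin = min(sw$sii), xmax = max(sw$sii),
             ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "magenta3") +
    geom_line() +
    scale_colour_manual(values = state_palette()) +
    labs(x = "residue", y = "RMSF (Å)", colour = "state") +
    theme_minimal()
}

#' Per-residue mobility of the leading PCA modes
#' @param object A `ras_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_pca <- function(object, ...) {
  ggplot(object$mobility,
         aes(x = .data$resno, y = .data$mobility_A,
             colour = factor(.data$mode))) +
    geom_line() +
    labs(x = "residue", y = "mode mobility (Å)", colour = "mode",
         title = paste0("state ", object$state)) +
    theme_minimal()
}

#' Cross-correlation heatmap
#' @param object A `ras_dccm` matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ras_dccm <- function(object, ...) {
  m <- unclass(object)
  d <- tidyr::expand_grid(i = as.integer(rownames(m)),
                          j = as.integer(colnames(m)))
  d$c <- as.numeric(t(m))
  ggplot(d, aes(x = .data$i, y = .data$j, fill = .data$c)) +
    geom_raster() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    labs(x = "residue", y = "residue", fill = "C(i,j)") +
    coord_equal() +
    theme_minimal()
}

#' Reaction-coordinate 2D histogram (contour-style)
#'
#' @param analysis A `ras_analysis` of a membrane-bound system, or a
#'   histogram grid from [histogram2d()].
#' @return A ggplot.
#' @export
plot_rc_histogram <- function(analysis) {
  grid <- if (inherits(analysis, "ras_analysis")) analysis$rc_hist else analysis
  if (is.null(grid)) abort("no reaction-coordinate histogram (solution-only system?)")
  ab <- attr(grid, "angle_breaks"); db <- attr(grid, "dist_breaks")
  d <- tidyr::expand_grid(
    angle = (head(ab, -1) + tail(ab, -1)) / 2,
    dist = (head(db, -1) + tail(db, -1)) / 2
  )
  d$count <- as.numeric(t(unclass(grid)))
  ggplot(dplyr::filter(d, .data$count > 0),
         aes(x = .data$angle, y = .data$dist, fill = .data$count)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "β1 tilt angle (deg)", y = "E132–L184 distance (Å)",
         fill = "frames") +
    theme_minimal()
}
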