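# ggplot2 views of the main result types.

#' Plot a 2D composite of an image stack
#'
#' Minimum-intensity (or mean / clipped-sum) projection rendered as a raster
#' in physical coordinates.
#'
#' @param object an [image_stack()].
#' @param method projection method, see [composite_projection()].
#' @param ... ignored.
#' @return A ggplot.
#' @export
autoplot.image_stack <- function(object, method = "min", ...) {
  proj <- composite_projection(object, method = method)
  sp <- object$spacing
  df <- tidyr::expand_grid(
    y = (seq_len(nrow(proj)) - 1) * sp[["dy"]],
    x = (seq_len(ncol(proj)) - 1) * sp[["dx"]]
  )
  df$intensity <- as.vector(t(proj))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", fill = "I") +
    ggplot2::theme_minimal()
}

#' Plot the class distribution of a spine table
#'
#' @param object a `spine_table` from [classify_spines()].
#' @param ... ignored.
#' @return A ggplot bar chart of spine classes.
#' @export
autoplot.spine_table <- function(object, ...) {
  df <- count(as_tibble(object), .data$class)
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "spine class", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot spine positions along the dendritic arclength
#'
#' One point per spine at its arclength position, coloured by class —
#' a quick view of spine distribution and grouping along the shaft.
#'
#' @param spines a `spine_table`.
#' @return A ggplot.
#' @export
plot_spine_positions <- function(spines) {
  ggplot2::ggplot(as_tibble(spines),
                  ggplot2::aes(.data$branch_arclen_um, .data$class,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "arclength along dendrite (µm)", y = NULL) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot the shaft radius profile
#'
#' @param axis a `shaft_axis` from [extract_shaft_axis()].
#' @return A ggplot of radius against arclength.
#' @export
plot_axis_profile <- function(axis) {
  ggplot2::ggplot(as_tibble(axis), ggplot2::aes(.data$arclen, .data$radius)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "arclength (µm)", y = "radius (µm)") +
    ggplot2::theme_minimal()
}
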