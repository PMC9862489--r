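#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_path geom_polygon
#'   geom_smooth labs theme_minimal coord_equal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a Procrustes alignment
#'
#' Scatter of all superimposed landmarks with the consensus shape overlaid,
#' the standard visual check that the superimposition behaved.
#'
#' @param object A `"wing_gpa"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wing_gpa
#' @export
autoplot.wing_gpa <- function(object, ...) {
  ggplot(object$aligned, aes(x = .data$x, y = .data$y)) +
    geom_point(aes(colour = .data$species), size = 0.5, alpha = 0.4) +
    geom_point(data = object$mean_shape, colour = "black", size = 2) +
    geom_path(data = object$mean_shape, colour = "black", linewidth = 0.3) +
    coord_equal() +
    theme_minimal() +
    labs(title = "Procrustes superimposition",
         x = "aligned x", y = "aligned y", colour = "species")
}

#' Plot the discriminant space
#'
#' First two canonical axes with one convex polygon per species — the
#' usual "factor map" display of wing-shape discrimination.
#'
#' @param object A `"wing_cva"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wing_cva
#' @export
autoplot.wing_cva <- function(object, ...) {
  sc <- object$canonical_scores
  if (!"CV2" %in% names(sc)) sc$CV2 <- 0
  hulls <- sc |>
    group_by(.data$species) |>
    group_modify(function(d, ...) d[grDevices::chull(d$CV1, d$CV2), ]) |>
    ungroup()
  ggplot(sc, aes(x = .data$CV1, y = .data$CV2, colour = .data$species)) +
    geom_polygon(data = hulls, aes(fill = .data$species),
                 alpha = 0.15, linewidth = 0.3) +
    geom_point(size = 1) +
    theme_minimal() +
    labs(title = "Discriminant space (canonical axes)",
         x = "discriminant axis 1", y = "discriminant axis 2")
}

#' Plot the allometric relation
#'
#' Shape score (first discriminant axis) against centroid size with the
#' least-squares line.
#'
#' @param object A `"wing_allometry"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wing_allometry
#' @export
autoplot.wing_allometry <- function(object, ...) {
  ggplot(object$data, aes(x = .data$csize, y = .data$shape_score)) +
    geom_point(size = 1, alpha = 0.7) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linetype = "dashed", colour = "darkorange") +
    theme_minimal() +
    labs(title = sprintf("Allometry: r² = %.2f, p = %.3g",
                         object$r_squared, object$p_value),
         x = "wing centroid size", y = "wing shape (discriminant axis 1)")
}

#' Superimposed species mean shapes
#'
#' Overlays the Procrustes mean shape of each species (landmarks joined in
#' index order), the wireframe-style comparison of average wing shapes.
#'
#' @param alignment A `"wing_gpa"` object with species labels.
#' @return A ggplot.
#' @export
plot_mean_shapes <- function(alignment) {
  if (!inherits(alignment, "wing_gpa")) {
    wc_abort("`alignment` must come from gpa_align().")
  }
  means <- alignment$aligned |>
    filter(!is.na(.data$species)) |>
    group_by(.data$species, .data$landmark) |>
    summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ggplot(means, aes(x = .data$x, y = .data$y, colour = .data$species)) +
    geom_path(linewidth = 0.4) +
    geom_point(size = 1.5) +
    coord_equal() +
    theme_minimal() +
    labs(title = "Species mean shapes (superimposed)",
         x = "aligned x", y = "aligned y")
}
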