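# ggplot2 visualisations of pipeline results.

#' Plot a planar distortion-energy field
#'
#' Raster of the distortion-energy density on the apex top plane with the
#' section centroid, focus point and projected sacrum line overlaid.
#'
#' @param object A `planar_field`.
#' @param plateau_tol Passed to [focus_point()] for the overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot planar_field
#' @export
autoplot.planar_field <- function(object, plateau_tol = 0.02, ...) {
  df <- as_tibble.planar_field(object)
  fp <- tryCatch(focus_point(object, plateau_tol), error = function(e) NULL)
  ell <- object$ell
  span <- max(abs(c(object$x, object$y)))
  line_df <- tibble::tibble(
    x = object$centroid[1L] + c(-1, 1) * span * ell[1L],
    y = object$centroid[2L] + c(-1, 1) * span * ell[2L])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$energy_density)) +
    ggplot2::geom_line(data = line_df, linetype = "dashed",
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "U_d (MPa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "in-plane x (mm)", y = "in-plane y (mm)",
                  title = "Distortion energy on the apex top plane")
  if (!is.null(fp)) {
    pts <- tibble::tibble(x = c(object$centroid[1L], fp$point[1L]),
                          y = c(object$centroid[2L], fp$point[2L]),
                          what = c("section centroid", "focus point"))
    p <- p + ggplot2::geom_point(data = pts,
                                 ggplot2::aes(shape = .data$what),
                                 colour = "red", size = 3) +
      ggplot2::labs(shape = NULL)
  }
  p
}

#' Plot cohort correlations per load-state
#'
#' Response angle against apex rotation, one panel per basic load-state,
#' annotated with the per-state correlation.
#'
#' @param responses Long response tibble (see [run_cohort()]).
#' @param report Optional `cohort_report` for the correlation labels.
#' @return A ggplot object.
#' @export
plot_cohort <- function(responses, report = NULL) {
  iso <- responses[responses$shear == "none" &
                     responses$material == "isotropic", ]
  p <- ggplot2::ggplot(iso, ggplot2::aes(x = .data$apex_rotation_deg,
                                         y = .data$response_angle_deg)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey50") +
    ggplot2::facet_wrap(~state) +
    ggplot2::labs(x = "apex rotation (deg)",
                  y = "apex top response angle (deg)")
  if (!is.null(report)) {
    lab <- report$correlations
    lab$label <- sprintf("rho == %.2f", lab$rho)
    p <- p + ggplot2::geom_text(
      data = lab, parse = TRUE,
      ggplot2::aes(label = .data$label), x = -Inf, y = Inf,
      hjust = -0.1, vjust = 1.5, inherit.aes = FALSE)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
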