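## ggplot2 displays for the result types ----------------------------------

#' Contour display of a two-band R-squared surface
#'
#' @param object An `r2_surface`.
#' @param ... Unused.
#' @return A ggplot: filled raster of R^2 over (lambda1, lambda2).
#' @method autoplot r2_surface
#' @export
autoplot.r2_surface <- function(object, ...) {
  df <- tidy.r2_surface(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda2, .data$lambda1,
                                   fill = .data$r2)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = expression(R^2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(lambda[2] ~ "(nm)"), y = expression(lambda[1] ~ "(nm)"),
      title = sprintf("%s two-band surface, VZA %s°",
                      object$index_type, format(object$vza))) +
    ggplot2::theme_minimal()
}

#' Angular accuracy profile plot
#'
#' R^2 (or RMSE) against view zenith angle, one line per method.
#'
#' @param profile Result tibble from [evaluate_vza()].
#' @param metric `"r2"` or `"rmse"`.
#' @param set Evaluation set to show (default "validation").
#' @return A ggplot.
#' @export
plot_angular_profile <- function(profile, metric = c("r2", "rmse"),
                                 set = "validation") {
  metric <- match.arg(metric)
  df <- profile[profile$set == set, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$vza, .data[[metric]],
                                   colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "view zenith angle (°)",
                  y = if (metric == "r2") expression(R^2) else "RMSE (LAI)",
                  colour = NULL,
                  title = sprintf("%s-set accuracy across view angles", set)) +
    ggplot2::theme_minimal()
}

#' Loading spectra of a PLSR fit
#'
#' @param object A `plsr_fit`.
#' @param components Components to draw (default: first three).
#' @return A ggplot of loading value against wavelength.
#' @export
plot_loadings <- function(object, components = seq_len(min(3, object$ncomp))) {
  df <- plsr_loadings(object, components)
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$loading,
                                   colour = factor(.data$component))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "loading",
                  colour = "latent variable") +
    ggplot2::theme_minimal()
}

#' Cross-validated RMSE curve of a latent-variable selection
#'
#' @param object A `plsr_selection`.
#' @param ... Unused.
#' @return A ggplot of CV RMSE against the number of latent variables,
#'   with the chosen value marked.
#' @method autoplot plsr_selection
#' @export
autoplot.plsr_selection <- function(object, ...) {
  df <- tidy.plsr_selection(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$ncomp, .data$rmse_cv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "latent variables", y = "cross-validated RMSE (LAI)") +
    ggplot2::theme_minimal()
}
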