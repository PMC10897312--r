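#' Plot a grid as a map
#'
#' @param object An [mf_grid()].
#' @param name Legend title.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mf_grid <- function(object, name = "value", ...) {
  df <- grid_to_tibble(object, drop_na = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' @export
plot.mf_grid <- function(x, ...) print(autoplot.mf_grid(x, ...))

#' Diagnostic plots for a fitted LAI model
#'
#' `type = "importance"` draws the LMG relative-importance shares;
#' `type = "fit"` the observed-vs-predicted scatter with the 1:1 line
#' (training data required, so not available for models restored from
#' JSON).
#'
#' @param object A `lai_model`.
#' @param type `"importance"` or `"fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lai_model <- function(object, type = c("importance", "fit"), ...) {
  type <- match.arg(type)
  if (type == "importance") {
    if (is.null(object$importance_pct)) {
      stop("model has no importance decomposition; use fit_lai_model()",
           call. = FALSE)
    }
    df <- object$importance_pct
    df$predictor <- stats::reorder(df$predictor, df$importance_pct)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$importance_pct,
                                       y = .data$predictor)) +
        ggplot2::geom_col(fill = "#2c7fb8") +
        ggplot2::labs(x = "relative importance (% of model R²)",
                      y = NULL) +
        ggplot2::theme_minimal()
    )
  }
  if (is.null(object$fit)) {
    stop("fit plot needs the training fit; model was restored from JSON",
         call. = FALSE)
  }
  df <- tibble::tibble(
    observed = object$data[[object$response]],
    predicted = stats::fitted(object$fit)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed,
                                   y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(paste("field LAI (", m^2, " ", m^-2, ")")),
                  y = "predicted LAI") +
    ggplot2::theme_minimal()
}

#' Diurnal course of leaf-level net photosynthesis
#'
#' Scatter of records through the day, coloured by area, with a loess
#' smoother for visual guidance only (the carbon upscaling uses the plain
#' mean, never this curve).
#'
#' @param records Leaf-flux tibble.
#' @param smooth Add the loess guide curve?
#' @return A ggplot.
#' @export
plot_diurnal_flux <- function(records, smooth = TRUE) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$local_time,
                                    y = .data$a_umol_m2_s)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$area_label),
                        alpha = 0.7) +
    ggplot2::labs(x = "local time (h)",
                  y = expression(paste("A (", mu, "mol CO"[2], " ",
                                       m^-2, " ", s^-1, ")")),
                  colour = "area") +
    ggplot2::theme_minimal()
  if (smooth && nrow(records) >= 10) {
    p <- p + ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                                  se = FALSE, colour = "black")
  }
  p
}
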