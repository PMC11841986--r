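# ggplot2 displays for maps, SACs, variability and decoding results.

map_to_df <- function(values, bin_size) {
  nx <- nrow(values); ny <- ncol(values)
  tibble(
    x = rep((seq_len(nx) - 0.5) * bin_size, ny),
    y = rep((seq_len(ny) - 0.5) * bin_size, each = nx),
    value = as.vector(values)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_map <- function(object, ...) {
  df <- map_to_df(object$values, object$bin_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Hz", na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)", title = "Firing-rate map")
}

#' @exportS3Method ggplot2::autoplot
autoplot.grid_sac <- function(object, ...) {
  half <- (nrow(object$values) - 1) / 2
  df <- map_to_df(object$values, object$bin_size)
  df$x <- df$x - (half + 0.5) * object$bin_size
  df$y <- df$y - (half + 0.5) * object$bin_size
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(name = "r", limits = c(-1, 1),
                                  na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lag x (cm)", y = "lag y (cm)",
                  title = "Spatial autocorrelogram")
}

#' @exportS3Method ggplot2::autoplot
autoplot.grid_variability <- function(object, which = c("theta", "lambda"),
                                      ...) {
  which <- match.arg(which)
  cells <- object$cells[object$cells$accepted, ]
  if (which == "theta") {
    p <- ggplot2::ggplot(cells, ggplot2::aes(.data$mean_within_dtheta,
                                             .data$mean_between_dtheta)) +
      ggplot2::labs(x = "mean within-cell Δθ (deg)",
                    y = "mean between-cell Δθ (deg)")
  } else {
    p <- ggplot2::ggplot(cells, ggplot2::aes(.data$mean_within_dlambda,
                                             .data$mean_between_dlambda)) +
      ggplot2::labs(x = "mean within-cell Δλ (cm)",
                    y = "mean between-cell Δλ (cm)")
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.decoding_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$n_cells, .data$mean_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_error - .data$sd_error,
                                      ymax = .data$mean_error + .data$sd_error),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$chance_error, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of grid cells",
                  y = "mean decoding error (cm)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.sigma_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$sigma_theta, .data$sigma_lambda,
                                       fill = .data$mean_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "error (cm)") +
    ggplot2::labs(x = expression(sigma[theta] ~ "(deg)"),
                  y = expression(sigma[lambda] ~ "(cm)"))
}
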