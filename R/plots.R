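# ggplot2 views of the package's objects. All return ggplot objects so the
# caller can restyle them.

#' Plot a grayscale image or mask
#'
#' @param img Numeric matrix (rows = y, columns = x), y drawn downwards.
#' @return A ggplot object.
#' @export
plot_image <- function(img) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)),
    y = rep(seq_len(nrow(img)), times = ncol(img)),
    value = as.vector(img))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Quiver plot of a force field
#'
#' @param V A `vector_field`.
#' @param every Subsampling stride in pixels (default 2).
#' @param scale Arrow length multiplier.
#' @return A ggplot object.
#' @export
plot_field <- function(V, every = 2L, scale = 0.8) {
  h <- nrow(V$u); w <- ncol(V$u)
  ys <- seq(1L, h, by = every); xs <- seq(1L, w, by = every)
  df <- tibble::tibble(
    x = rep(xs, each = length(ys)),
    y = rep(ys, times = length(xs)),
    u = as.vector(V$u[ys, xs]),
    v = as.vector(V$v[ys, xs]))
  mag <- sqrt(df$u^2 + df$v^2)
  mmax <- max(mag, 1e-12)
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x + scale * every * .data$u / mmax,
                   yend = .data$y + scale * every * .data$v / mmax),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.04, "inches")),
      linewidth = 0.2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' @rdname plot_field
#' @param object A `vector_field`.
#' @param ... Passed to [plot_field()].
#' @export
autoplot.vector_field <- function(object, ...) plot_field(object, ...)

#' Plot a snake fit over an image
#'
#' @param object A `snake_fit`.
#' @param image Optional background image matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snake_fit <- function(object, image = NULL, ...) {
  cont <- rbind(object$contour, object$contour[1, ])
  p <- if (is.null(image)) {
    ggplot2::ggplot() + ggplot2::scale_y_reverse() +
      ggplot2::coord_fixed() + ggplot2::theme_minimal()
  } else plot_image(image)
  p + ggplot2::geom_path(data = cont,
                         ggplot2::aes(x = .data$x, y = .data$y),
                         colour = "red", linewidth = 0.6)
}

#' Convergence plot of a snake fit
#'
#' @param fit A `snake_fit`.
#' @return A ggplot object of mean displacement per iteration.
#' @export
plot_displacement <- function(fit) {
  ggplot2::ggplot(fit$history,
                  ggplot2::aes(x = .data$iteration,
                               y = .data$mean_displacement)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "mean displacement (px)") +
    ggplot2::theme_minimal()
}

#' Plot a tau sweep
#'
#' @param object A tibble from [sweep_tau()].
#' @return A ggplot object of mean F1 against tau.
#' @export
plot_tau_sweep <- function(object) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$mean_f1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = "mean F1") +
    ggplot2::theme_minimal()
}
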