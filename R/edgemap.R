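#' Read a PNG or TIFF image as a grayscale matrix
#'
#' Reads an 8- or 16-bit raster, converts multi-channel data to luma and
#' rescales to \[0, 1\]. Rows are image rows (y, top to bottom) and columns
#' are x.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix in \[0, 1\].
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3L) arr <- to_grayscale(arr) else arr <- as.matrix(arr)
  clip01(arr)
}

#' Convert an RGB array to grayscale
#'
#' Applies the Rec. 601 luma weights (0.299, 0.587, 0.114). An optional
#' alpha channel is ignored.
#'
#' @param rgb A numeric array `H x W x 3` (or `H x W x 4`), values in
#'   \[0, 1\].
#' @return A numeric `H x W` matrix in \[0, 1\].
#' @export
#' @examples
#' to_grayscale(array(1, c(2, 2, 3)))  # pure white -> 1
to_grayscale <- function(rgb) {
  d <- dim(rgb)
  if (length(d) != 3L || !(d[3] %in% c(3L, 4L)))
    stop("`rgb` must be an H x W x 3 (or x4, with alpha) array", call. = FALSE)
  y <- 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
  clip01(matrix(y, d[1], d[2]))
}

#' Central-difference gradient of a grid
#'
#' Central differences in the interior; at the borders the grid is
#' replicated (Neumann rule), so the boundary difference is one-sided and
#' halved. `gx` differentiates along columns (x), `gy` along rows (y, which
#' increases downwards).
#'
#' @param m Numeric matrix, at least 2x2.
#' @return A list with matrices `gx` and `gy`.
#' @export
#' @examples
#' g <- gradient2d(matrix(rep(1:5, each = 4), 4, 5))  # ramp in x
#' g$gx[2, 3]  # 1 in the interior
gradient2d <- function(m) {
  assert_grid(m, "m", min_dim = 2L)
  list(gx = (shift_xp(m) - shift_xm(m)) / 2,
       gy = (shift_yp(m) - shift_ym(m)) / 2)
}

#' Edge map of a grayscale image
#'
#' Computes the edge graph `f` that seeds every gradient-vector-flow field:
#' the gradient magnitude of the (optionally Gaussian-smoothed) image, or
#' its square, normalized so that the maximum is 1 whenever the image is
#' non-constant. Normalization makes the edge-intensity threshold `tau` of
#' the convex-coefficient field comparable across images.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param sigma Gaussian pre-smoothing standard deviation in pixels;
#'   `0` (default for clean synthetic images) means no smoothing. Use around
#'   1 for noisy images.
#' @param squared If `TRUE` use the squared gradient magnitude
#'   (the classical snake edge energy); default `FALSE` keeps the plain
#'   magnitude, which preserves weak-edge contrast better.
#' @param normalize Rescale to max 1 (default `TRUE`).
#' @return A numeric matrix, the edge map `f` (class unchanged: plain
#'   matrix), with attribute `normalized`.
#' @export
edge_map <- function(img, sigma = 0, squared = FALSE, normalize = TRUE) {
  assert_grid(img, "img", min_dim = 2L)
  if (min(img) < 0 || max(img) > 1)
    stop("`img` must lie in [0, 1]; rescale before computing the edge map",
         call. = FALSE)
  assert_scalar(sigma, "sigma", lower = 0)
  sm <- gaussian_smooth(img, sigma)
  g <- gradient2d(sm)
  f <- sqrt(g$gx^2 + g$gy^2)
  if (squared) f <- f^2
  if (normalize && max(f) > 0) f <- f / max(f)
  attr(f, "normalized") <- normalize
  f
}
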