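#' Specify a synthetic test phantom
#'
#' Builds a validated specification for the standard snake-benchmark
#' phantoms: a disk, a square, a U-shape (square blob with a wide opening)
#' and an LTI image (square blob with a long, thin indentation of even
#' pixel width — the classical failure case for gradient-vector-flow
#' fields).
#'
#' @param kind One of `"disk"`, `"square"`, `"ushape"`, `"lti"`.
#' @param height,width Canvas size in pixels, at least 16.
#' @param fg,bg Foreground / background intensities in \[0, 1\], distinct.
#' @param radius Disk radius in pixels (`kind = "disk"`).
#' @param side Blob side length in pixels (`square`, `ushape`, `lti`).
#' @param arm_width Arm width of the U-shape in pixels.
#' @param indent_width Width of the LTI indentation in pixels; must be an
#'   even count (the even-width slot is what defeats the classical fields).
#' @param indent_depth Depth of the indentation; defaults to 60% of `side`.
#' @param center Optional `(x, y)` center; defaults to the canvas center.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()]
#' @export
phantom_spec <- function(kind = c("disk", "square", "ushape", "lti"),
                         height = 64, width = 64, fg = 1, bg = 0,
                         radius = 20, side = 40,
                         arm_width = 10, indent_width = 4,
                         indent_depth = NULL, center = NULL) {
  kind <- match.arg(kind)
  assert_scalar(height, "height", lower = 16)
  assert_scalar(width, "width", lower = 16)
  assert_scalar(fg, "fg", lower = 0, upper = 1)
  assert_scalar(bg, "bg", lower = 0, upper = 1)
  if (fg == bg) stop("`fg` and `bg` intensities must be distinct", call. = FALSE)
  if (is.null(center)) center <- c((width + 1) / 2, (height + 1) / 2)
  if (kind == "disk") {
    assert_scalar(radius, "radius", lower = 0, strict_lower = TRUE)
    if (2 * radius > min(height, width))
      stop("disk `radius` ", radius, " does not fit the ", height, "x", width,
           " canvas", call. = FALSE)
  } else {
    assert_scalar(side, "side", lower = 1)
    if (side > min(height, width))
      stop("blob `side` ", side, " does not fit the ", height, "x", width,
           " canvas", call. = FALSE)
  }
  if (kind == "ushape") {
    assert_scalar(arm_width, "arm_width", lower = 1)
    if (2 * arm_width >= side)
      stop("`arm_width` ", arm_width, " leaves no opening in a blob of side ",
           side, call. = FALSE)
  }
  if (kind == "lti") {
    assert_scalar(indent_width, "indent_width", lower = 2)
    if (indent_width %% 2 != 0)
      stop("`indent_width` must be an even number of pixels, got ",
           indent_width, call. = FALSE)
    if (indent_width >= side)
      stop("`indent_width` ", indent_width, " is as wide as the blob side ",
           side, call. = FALSE)
    if (is.null(indent_depth)) indent_depth <- round(0.6 * side)
    assert_scalar(indent_depth, "indent_depth", lower = 1)
    if (indent_depth >= side)
      stop("`indent_depth` ", indent_depth, " exceeds the blob side ", side,
           call. = FALSE)
  } else indent_depth <- NA_real_
  structure(list(kind = kind, height = as.integer(height),
                 width = as.integer(width), fg = fg, bg = bg,
                 radius = radius, side = side, arm_width = arm_width,
                 indent_width = indent_width, indent_depth = indent_depth,
                 center = center),
            class = "phantom_spec")
}

#' Generate a phantom image and its ground-truth mask
#'
#' Renders the binary phantom described by a [phantom_spec()]: the image
#' holds exactly the two intensity levels `fg` and `bg`, and the mask marks
#' the foreground pixels (the segmentation ground truth `Gseg`).
#'
#' @param spec A `phantom_spec`.
#' @return A list with `image` (numeric matrix) and `mask` (0/1 integer
#'   matrix) of size `height x width`.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("disk", radius = 20))
#' sum(ph$mask)  # pixel centers within 20 px of the canvas center
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  x <- matrix(rep(seq_len(w), each = h), h, w)
  y <- matrix(rep(seq_len(h), times = w), h, w)
  cx <- spec$center[1]; cy <- spec$center[2]
  mask <- switch(spec$kind,
    disk = (x - cx)^2 + (y - cy)^2 <= spec$radius^2,
    square = blob_mask(x, y, cx, cy, spec$side),
    ushape = {
      m <- blob_mask(x, y, cx, cy, spec$side)
      top <- cy - spec$side / 2
      open_w <- spec$side - 2 * spec$arm_width
      open_d <- round(0.6 * spec$side)
      notch <- abs(x - cx) < open_w / 2 & y >= top & y < top + open_d
      m & !notch
    },
    lti = {
      m <- blob_mask(x, y, cx, cy, spec$side)
      top <- cy - spec$side / 2
      slot <- abs(x - cx) < spec$indent_width / 2 &
        y >= top & y < top + spec$indent_depth
      m & !slot
    }
  )
  mask <- matrix(as.integer(mask), h, w)
  image <- spec$bg + (spec$fg - spec$bg) * mask
  list(image = image, mask = mask, spec = spec)
}

#' @noRd
blob_mask <- function(x, y, cx, cy, side) {
  abs(x - cx) <= side / 2 & abs(y - cy) <= side / 2
}

#' Specify an image noise model
#'
#' Two corruption models used when stress-testing segmentation: salt–pepper
#' impulse noise at density `D` (exactly `round(D * N)` distinct pixels are
#' forced to 0 or 1 with equal probability, a deterministic-count variant of
#' the usual per-pixel convention), and zero-mean multiplicative (speckle)
#' noise `I + n * I` with `n` uniform of variance `V`, clipped to \[0, 1\].
#'
#' @param kind `"salt_pepper"` or `"multiplicative"`.
#' @param density Fraction `D` of corrupted pixels (salt–pepper), in
#'   \[0, 1\].
#' @param variance Variance `V` of the multiplicative noise, `>= 0`.
#' @param seed Integer seed; the same seed reproduces the corruption
#'   bit-for-bit.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("salt_pepper", "multiplicative"),
                       density = 0.001, variance = 0.01, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "salt_pepper") assert_scalar(density, "density", lower = 0, upper = 1)
  else assert_scalar(variance, "variance", lower = 0)
  assert_scalar(seed, "seed")
  structure(list(kind = kind, density = density, variance = variance,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt an image with a specified noise model
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param spec A [noise_spec()].
#' @return The corrupted image, same shape, clipped to \[0, 1\].
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("disk"))
#' noisy <- add_noise(ph$image, noise_spec("salt_pepper", density = 0.001))
add_noise <- function(img, spec) {
  assert_grid(img, "img")
  stopifnot(inherits(spec, "noise_spec"))
  if (min(img) < 0 || max(img) > 1)
    stop("`img` must lie in [0, 1]", call. = FALSE)
  n_pix <- length(img)
  with_local_seed(spec$seed, {
    if (spec$kind == "salt_pepper") {
      k <- round(spec$density * n_pix)
      if (k == 0) return(img)
      idx <- sample.int(n_pix, k)
      img[idx] <- sample(c(0, 1), k, replace = TRUE)
      img
    } else {
      if (spec$variance == 0) return(img)
      a <- sqrt(3 * spec$variance)  # Uniform(-a, a) has variance a^2 / 3
      n <- matrix(stats::runif(n_pix, -a, a), nrow(img), ncol(img))
      clip01(img + n * img)
    }
  })
}

#' Build an initial snake contour
#'
#' Generates a closed rectangle or ellipse polyline with approximately
#' uniform arc-length spacing, ordered counterclockwise in Cartesian
#' convention (x right, y up; with image rows increasing downwards the
#' points advance clockwise on screen).
#'
#' @param shape `"rectangle"` or `"ellipse"`.
#' @param center `(x, y)` center in pixel coordinates.
#' @param size `(w, h)` full width and height of the shape.
#' @param n_points Number of contour points, at least 16.
#' @param domain Optional `(width, height)` of the image the contour must
#'   fit inside; if supplied, a contour leaving the domain is rejected.
#' @return A tibble with columns `x`, `y`; the polyline is closed
#'   implicitly (last point connects to the first).
#' @export
#' @examples
#' make_initial_contour("ellipse", center = c(32, 32), size = c(20, 20))
make_initial_contour <- function(shape = c("ellipse", "rectangle"),
                                 center, size, n_points = 64,
                                 domain = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(center) == 2L, length(size) == 2L)
  assert_scalar(n_points, "n_points", lower = 16)
  if (any(size <= 0)) stop("`size` must be positive", call. = FALSE)
  n_points <- as.integer(n_points)
  if (shape == "ellipse") {
    th <- seq(0, 2 * pi, length.out = 4L * n_points + 1L)[-1]
    px <- center[1] + size[1] / 2 * cos(th)
    py <- center[2] - size[2] / 2 * sin(th)  # y down: negate for CCW
    dense <- cbind(px, py)
  } else {
    hw <- size[1] / 2; hh <- size[2] / 2
    corners <- rbind(c(center[1] + hw, center[2] + hh),
                     c(center[1] + hw, center[2] - hh),
                     c(center[1] - hw, center[2] - hh),
                     c(center[1] - hw, center[2] + hh))
    dense <- densify_polygon(corners, per_edge = 2L * n_points)
  }
  pts <- resample_closed(dense, n_points)
  if (!is.null(domain)) {
    if (min(pts[, 1]) < 1 || max(pts[, 1]) > domain[1] ||
        min(pts[, 2]) < 1 || max(pts[, 2]) > domain[2])
      stop("initial contour of size ", size[1], "x", size[2],
           " exceeds the ", domain[1], "x", domain[2], " image bounds",
           call. = FALSE)
  }
  tibble::tibble(x = pts[, 1], y = pts[, 2])
}

#' @noRd
densify_polygon <- function(corners, per_edge) {
  n <- nrow(corners)
  out <- lapply(seq_len(n), function(i) {
    a <- corners[i, ]; b <- corners[if (i == n) 1L else i + 1L, ]
    t <- seq(0, 1, length.out = per_edge + 1L)[-(per_edge + 1L)]
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  })
  do.call(rbind, out)
}

# Resample a closed polyline to n points at uniform arc length, starting at
# the first vertex; linear interpolation along segments.
#' @noRd
resample_closed <- function(pts, n) {
  closed <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(diff(closed[, 1])^2 + diff(closed[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate polyline: zero perimeter", call. = FALSE)
  keep <- c(TRUE, seg > 0)  # drop zero-length duplicates for approx()
  cum_u <- cum[keep]; xs <- closed[keep, 1]; ys <- closed[keep, 2]
  s <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(stats::approx(cum_u, xs, xout = s)$y,
        stats::approx(cum_u, ys, xout = s)$y)
}

#' Perimeter of a closed contour
#'
#' @param contour A tibble or matrix with columns `x`, `y`.
#' @return Total arc length including the closing segment.
#' @export
contour_perimeter <- function(contour) {
  p <- as.matrix(contour[, c("x", "y")])
  q <- rbind(p, p[1, , drop = FALSE])
  sum(sqrt(diff(q[, 1])^2 + diff(q[, 2])^2))
}

#' Write a phantom or mask as an 8-bit PNG
#'
#' @param img Numeric matrix in \[0, 1\] (masks are written as 0/1).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clip01(img), path)
  invisible(path)
}
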