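#' Configure the snake (active contour) evolution
#'
#' @param alpha Tension (elasticity) weight, `>= 0`; penalizes contour
#'   length.
#' @param beta Rigidity weight, `>= 0`; penalizes curvature.
#' @param gamma Viscosity / implicit step parameter, `> 0`.
#' @param kappa External-force weight, `> 0`. With a unit-normalized field
#'   the explicit external step is `kappa / gamma` pixels per iteration;
#'   the default 0.5 keeps it inside the ~1 px edge transition so the
#'   contour can settle to subpixel accuracy.
#' @param n_iter Maximum number of iterations.
#' @param resample_every Resample the contour to uniform spacing every this
#'   many iterations.
#' @param target_spacing Target point spacing in pixels after resampling.
#' @param tol Convergence threshold on the mean point displacement per
#'   iteration, in pixels.
#' @return An object of class `snake_config`.
#' @export
snake_config <- function(alpha = 0.1, beta = 0.1, gamma = 1, kappa = 0.5,
                         n_iter = 100L, resample_every = 5L,
                         target_spacing = 1, tol = 0.05) {
  assert_scalar(alpha, "alpha", lower = 0)
  assert_scalar(beta, "beta", lower = 0)
  assert_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  assert_scalar(kappa, "kappa", lower = 0)
  assert_scalar(n_iter, "n_iter", lower = 1)
  assert_scalar(resample_every, "resample_every", lower = 1)
  assert_scalar(target_spacing, "target_spacing", lower = 0, strict_lower = TRUE)
  assert_scalar(tol, "tol", lower = 0, strict_lower = TRUE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
                 n_iter = as.integer(n_iter),
                 resample_every = as.integer(resample_every),
                 target_spacing = target_spacing, tol = tol),
            class = "snake_config")
}

#' Sample a vector field at subpixel points
#'
#' Bilinear interpolation of the field components at arbitrary subpixel
#' `(x, y)` positions. Points outside the field domain are clamped to the
#' nearest boundary pixel (with a warning).
#'
#' @param V A `vector_field` (or list with matrices `u`, `v`).
#' @param points A tibble/matrix with columns `x`, `y` (1-based pixel
#'   coordinates).
#' @return A tibble with columns `fx`, `fy`.
#' @export
interpolate_field <- function(V, points) {
  p <- unname(as.matrix(points[, c("x", "y")]))
  h <- nrow(V$u); w <- ncol(V$u)
  x <- p[, 1]; y <- p[, 2]
  if (any(x < 1 | x > w | y < 1 | y > h)) {
    warning("contour points outside the field domain were clamped to the boundary")
    x <- pmin(pmax(x, 1), w)
    y <- pmin(pmax(y, 1), h)
  }
  x0 <- pmin(floor(x), w - 1); y0 <- pmin(floor(y), h - 1)
  tx <- x - x0; ty <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  bil <- function(m) {
    (1 - ty) * ((1 - tx) * m[i00] + tx * m[i01]) +
      ty * ((1 - tx) * m[i10] + tx * m[i11])
  }
  tibble::tibble(fx = bil(V$u), fy = bil(V$v))
}

# Cyclic internal-force system matrix (gamma I + A) with the classical
# pentadiagonal rows [beta, -alpha - 4 beta, 2 alpha + 6 beta, ...].
#' @noRd
internal_matrix <- function(n, alpha, beta, gamma) {
  a2 <- beta
  a1 <- -alpha - 4 * beta
  a0 <- 2 * alpha + 6 * beta
  A <- matrix(0, n, n)
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  A[cbind(seq_len(n), idx(0))] <- A[cbind(seq_len(n), idx(0))] + a0
  A[cbind(seq_len(n), idx(1))] <- A[cbind(seq_len(n), idx(1))] + a1
  A[cbind(seq_len(n), idx(-1))] <- A[cbind(seq_len(n), idx(-1))] + a1
  A[cbind(seq_len(n), idx(2))] <- A[cbind(seq_len(n), idx(2))] + a2
  A[cbind(seq_len(n), idx(-2))] <- A[cbind(seq_len(n), idx(-2))] + a2
  M <- A + diag(gamma, n)
  tryCatch(solve(M), error = function(e)
    stop("internal-force system is singular (alpha = beta = 0 needs gamma > 0)",
         call. = FALSE))
}

#' Evolve a snake under an external force field
#'
#' Semi-implicit evolution of a closed parametric contour: the internal
#' tension/rigidity forces are treated implicitly through a precomputed
#' cyclic pentadiagonal solve, the external force explicitly as
#' `kappa * V(contour)` sampled by bilinear interpolation. The contour is
#' periodically resampled to uniform arc-length spacing and the iteration
#' stops when the mean point displacement drops below `tol`.
#'
#' @param contour Tibble/matrix with columns `x`, `y` (closed polyline,
#'   at least 16 points).
#' @param V A `vector_field` on the same image domain.
#' @param cfg A [snake_config()].
#' @param normalize Normalize the field to unit vectors before use
#'   (default `TRUE`; see [normalize_field()]).
#' @return An object of class `snake_fit`: list with the final `contour`
#'   (tibble), `history` (tibble of per-iteration mean displacements),
#'   `iterations`, `converged`, and the configs.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("disk"))
#' f <- edge_map(ph$image)
#' V <- solve_field(f, field_config("gvf", n_iter = 200))
#' init <- make_initial_contour("ellipse", c(32.5, 32.5), c(56, 56))
#' fit <- evolve_snake(init, V, snake_config(n_iter = 150))
evolve_snake <- function(contour, V, cfg = snake_config(), normalize = TRUE) {
  stopifnot(inherits(cfg, "snake_config"))
  p <- as.matrix(contour[, c("x", "y")])
  if (nrow(p) < 16) stop("contour must have at least 16 points", call. = FALSE)
  if (normalize) V <- normalize_field(V, eps = 1e-8)
  h <- nrow(V$u); w <- ncol(V$u)
  clamp <- function(m) cbind(pmin(pmax(m[, 1], 1), w), pmin(pmax(m[, 2], 1), h))
  p <- clamp(p)
  Minv <- internal_matrix(nrow(p), cfg$alpha, cfg$beta, cfg$gamma)
  disp <- numeric(cfg$n_iter)
  converged <- FALSE
  it <- 0L
  while (it < cfg$n_iter) {
    it <- it + 1L
    fext <- interpolate_field(V, tibble::tibble(x = p[, 1], y = p[, 2]))
    newp <- cbind(Minv %*% (cfg$gamma * p[, 1] + cfg$kappa * fext$fx),
                  Minv %*% (cfg$gamma * p[, 2] + cfg$kappa * fext$fy))
    newp <- clamp(newp)
    disp[it] <- mean(sqrt(rowSums((newp - p)^2)))
    p <- newp
    if (disp[it] < cfg$tol) { converged <- TRUE; break }
    if (it %% cfg$resample_every == 0L) {
      n_new <- max(16L, round(contour_perimeter(
        tibble::tibble(x = p[, 1], y = p[, 2])) / cfg$target_spacing))
      p <- resample_closed(p, n_new)
      p <- clamp(p)
      if (nrow(p) != nrow(Minv))
        Minv <- internal_matrix(nrow(p), cfg$alpha, cfg$beta, cfg$gamma)
    }
  }
  structure(list(
    contour = tibble::tibble(x = p[, 1], y = p[, 2]),
    history = tibble::tibble(iteration = seq_len(it),
                             mean_displacement = disp[seq_len(it)]),
    iterations = it, converged = converged,
    snake_config = cfg, field_config = V$config),
    class = "snake_fit")
}

#' Rasterize a closed contour into a binary mask
#'
#' Marks every pixel center inside the polygon under the even–odd rule;
#' centers lying exactly on an edge count as inside. A degenerate polygon
#' (shoelace area below half a pixel) yields an empty mask.
#'
#' @param contour Tibble/matrix with columns `x`, `y`.
#' @param shape `(height, width)` of the output mask.
#' @return A 0/1 integer matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  p <- as.matrix(contour[, c("x", "y")])
  n <- nrow(p)
  h <- shape[1]; w <- shape[2]
  area <- abs(sum(p[, 1] * p[c(2:n, 1), 2] - p[c(2:n, 1), 1] * p[, 2])) / 2
  if (area < 0.5) return(matrix(0L, h, w))
  gx <- matrix(rep(seq_len(w), each = h), h, w)
  gy <- matrix(rep(seq_len(h), times = w), h, w)
  inside <- matrix(FALSE, h, w)
  on_edge <- matrix(FALSE, h, w)
  eps <- 1e-9
  for (i in seq_len(n)) {
    x1 <- p[i, 1]; y1 <- p[i, 2]
    j <- if (i == n) 1L else i + 1L
    x2 <- p[j, 1]; y2 <- p[j, 2]
    if (y1 != y2) {
      crosses <- (y1 > gy) != (y2 > gy)
      xint <- x1 + (gy - y1) * (x2 - x1) / (y2 - y1)
      inside <- xor(inside, crosses & (gx < xint))
    }
    # centers exactly on the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((gx - x1) * dx + (gy - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (gx - (x1 + t * dx))^2 + (gy - (y1 + t * dy))^2
      on_edge <- on_edge | d2 < eps
    }
  }
  matrix(as.integer(inside | on_edge), h, w)
}

#' @export
print.snake_fit <- function(x, ...) {
  cat(sprintf("<snake_fit> %d points, %d iterations, %s (final mean displacement %.4g px)\n",
              nrow(x$contour), x$iterations,
              if (x$converged) "converged" else "iteration limit reached",
              x$history$mean_displacement[x$iterations]))
  invisible(x)
}

#' Tidy a snake fit into its contour points
#'
#' @param x A `snake_fit`.
#' @param ... Unused.
#' @return A tibble with columns `point`, `x`, `y`.
#' @export
tidy.snake_fit <- function(x, ...) {
  cont <- x$contour
  tibble::tibble(point = seq_len(nrow(cont)), x = cont$x, y = cont$y)
}

#' One-row summary of a snake fit
#'
#' @param x A `snake_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n_points`, `iterations`, `converged`,
#'   `final_displacement`, `perimeter`.
#' @export
glance.snake_fit <- function(x, ...) {
  tibble::tibble(
    n_points = nrow(x$contour),
    iterations = x$iterations,
    converged = x$converged,
    final_displacement = x$history$mean_displacement[x$iterations],
    perimeter = contour_perimeter(x$contour))
}
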