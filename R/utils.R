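# Internal grid helpers shared by the edge-map and force-field code.
# Convention throughout: a "grid" is a numeric matrix with rows = y (down)
# and columns = x (right); pixel centers sit at integer (x, y), 1-based.

#' @noRd
assert_grid <- function(m, name = deparse(substitute(m)), min_dim = 1L) {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  if (nrow(m) < min_dim || ncol(m) < min_dim)
    stop(sprintf("`%s` must be at least %dx%d, got %dx%d",
                 name, min_dim, min_dim, nrow(m), ncol(m)), call. = FALSE)
  if (!all(is.finite(m)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(m)
}

#' @noRd
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    stop(sprintf("`%s` = %g is outside the admissible range %s%g, %g]",
                 name, x, if (strict_lower) "(" else "[", lower, upper),
         call. = FALSE)
  invisible(x)
}

#' @noRd
clip01 <- function(m) {
  m[m < 0] <- 0
  m[m > 1] <- 1
  m
}

# Neighbour shifts with replicate (Neumann) boundary handling.
#' @noRd
shift_xp <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]  # x + 1
#' @noRd
shift_xm <- function(m) m[, c(1L, 1:(ncol(m) - 1L)), drop = FALSE] # x - 1
#' @noRd
shift_yp <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]  # y + 1
#' @noRd
shift_ym <- function(m) m[c(1L, 1:(nrow(m) - 1L)), , drop = FALSE] # y - 1

# 5-point discrete Laplacian, replicate boundary.
#' @noRd
laplacian5 <- function(m) {
  shift_xp(m) + shift_xm(m) + shift_yp(m) + shift_ym(m) - 4 * m
}

# Separable Gaussian smoothing with replicate padding; sigma = 0 is identity.
#' @noRd
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(m); w <- ncol(m)
  idx_clamp <- function(i, n) pmin(pmax(i, 1L), n)
  # rows (y), then columns (x)
  out <- matrix(0, h, w)
  for (j in seq_along(k)) {
    out <- out + k[j] * m[idx_clamp(seq_len(h) + (j - r - 1L), h), , drop = FALSE]
  }
  out2 <- matrix(0, h, w)
  for (j in seq_along(k)) {
    out2 <- out2 + k[j] * out[, idx_clamp(seq_len(w) + (j - r - 1L), w), drop = FALSE]
  }
  out2
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards (so package code never clobbers it).
#' @noRd
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}
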