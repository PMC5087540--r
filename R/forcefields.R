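#' Configure a gradient-vector-flow-family force field
#'
#' Collects the parameters of the external-force PDE and validates the ones
#' the chosen method actually uses. All five solvers iterate an explicit
#' forward-Euler scheme on the unit pixel grid starting from `V = grad f`.
#'
#' @param method One of `"gvf"`, `"ggvf"`, `"ngvf"`, `"nbgvf"`,
#'   `"proposed"` (the convex-coefficient field).
#' @param mu Smoothness weight (`gvf`, `ngvf`, `nbgvf`); increase with
#'   image noise. Default 0.2, the customary gradient-vector-flow setting.
#' @param K Decay constant of the `g`/`h` weights (`ggvf`, `proposed`) or of
#'   the normal bias (`nbgvf`); larger K = stronger smoothing.
#' @param tau Edge-intensity threshold of the convex coefficients
#'   (`proposed`), in (0, 1\].
#' @param n_iter Number of PDE iterations, default 100.
#' @param dt Time step; `NULL` (default) picks 90% of the von Neumann
#'   stability bound `2 / (8 Dmax + Bmax)` of the combined
#'   diffusion + data explicit update (`Dmax`, `Bmax` the maximal
#'   diffusion and data coefficients). A supplied `dt` with
#'   `dt * Dmax > 1/4` is rejected.
#' @param eps Degenerate-gradient threshold for the normal/tangent
#'   decomposition.
#' @return An object of class `field_config`.
#' @export
field_config <- function(method = c("gvf", "ggvf", "ngvf", "nbgvf", "proposed"),
                         mu = 0.2, K = 1, tau = 1, n_iter = 100L,
                         dt = NULL, eps = 1e-10) {
  method <- match.arg(method)
  if (method %in% c("gvf", "ngvf", "nbgvf"))
    assert_scalar(mu, "mu", lower = 0)
  if (method %in% c("ggvf", "nbgvf", "proposed"))
    assert_scalar(K, "K", lower = 0, strict_lower = TRUE)
  if (method == "proposed")
    assert_scalar(tau, "tau", lower = 0, upper = 1, strict_lower = TRUE)
  assert_scalar(n_iter, "n_iter", lower = 0)
  if (!is.null(dt)) assert_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  assert_scalar(eps, "eps", lower = 0, strict_lower = TRUE)
  structure(list(method = method, mu = mu, K = K, tau = tau,
                 n_iter = as.integer(n_iter), dt = dt, eps = eps),
            class = "field_config")
}

#' @export
print.field_config <- function(x, ...) {
  pars <- switch(x$method,
    gvf = sprintf("mu = %g", x$mu),
    ggvf = sprintf("K = %g", x$K),
    ngvf = sprintf("mu = %g", x$mu),
    nbgvf = sprintf("mu = %g, K = %g", x$mu, x$K),
    proposed = sprintf("K = %g, tau = %g", x$K, x$tau))
  cat(sprintf("<field_config> method = %s (%s), n_iter = %d, dt = %s\n",
              x$method, pars, x$n_iter,
              if (is.null(x$dt)) "auto" else format(x$dt)))
  invisible(x)
}

#' Normal/tangent decomposition of the Laplacian
#'
#' Splits the discrete Laplacian of a scalar grid into its second
#' directional derivatives along the gradient (normal, `nn`) and
#' perpendicular to it (tangent, `tt`):
#' `nn = (Vx^2 Vxx + 2 Vx Vy Vxy + Vy^2 Vyy) / |grad V|^2` and
#' `tt = (Vy^2 Vxx - 2 Vx Vy Vxy + Vx^2 Vyy) / |grad V|^2`, so
#' `nn + tt` equals the 5-point Laplacian wherever the gradient is
#' non-degenerate. Where `|grad V|^2 < eps` both parts are set to half the
#' Laplacian, preserving the sum identity everywhere.
#'
#' @param V Numeric matrix, at least 3x3.
#' @param eps Degeneracy threshold on the squared gradient magnitude.
#' @return A list with matrices `nn` and `tt`.
#' @export
decompose_nn_tt <- function(V, eps = 1e-10) {
  assert_grid(V, "V", min_dim = 3L)
  vx <- (shift_xp(V) - shift_xm(V)) / 2
  vy <- (shift_yp(V) - shift_ym(V)) / 2
  vxx <- shift_xp(V) + shift_xm(V) - 2 * V
  vyy <- shift_yp(V) + shift_ym(V) - 2 * V
  vxy <- (shift_yp(shift_xp(V)) - shift_ym(shift_xp(V)) -
          shift_yp(shift_xm(V)) + shift_ym(shift_xm(V))) / 4
  mag2 <- vx^2 + vy^2
  lap <- vxx + vyy
  denom <- mag2
  denom[denom == 0] <- 1  # masked below
  nn <- (vx^2 * vxx + 2 * vx * vy * vxy + vy^2 * vyy) / denom
  tt <- (vy^2 * vxx - 2 * vx * vy * vxy + vx^2 * vyy) / denom
  deg <- mag2 < eps
  nn[deg] <- lap[deg] / 2
  tt[deg] <- lap[deg] / 2
  list(nn = nn, tt = tt)
}

# Resolve the coefficient grids, diffusion bound and data bound for a
# method; used by the iterator, the residual and the dt check.
#' @noRd
field_terms <- function(f, cfg, gs = NULL, hs = NULL,
                        g = NULL, h = NULL) {
  gr <- gradient2d(f)
  grad_mag <- sqrt(gr$gx^2 + gr$gy^2)
  tm <- list(fx = gr$gx, fy = gr$gy)
  tm[c("g", "h", "gs", "hs", "beta", "b")] <- list(NULL)
  switch(cfg$method,
    gvf = {
      tm$b <- grad_mag^2
      tm$diff_max <- cfg$mu
      tm$data_max <- max(tm$b)
    },
    ggvf = {
      tm$g <- if (is.null(g)) coeff_g(grad_mag, cfg$K) else g
      tm$h <- if (is.null(h)) coeff_h(grad_mag, cfg$K) else h
      tm$diff_max <- max(tm$g)
      tm$data_max <- max(tm$h)
    },
    ngvf = {
      tm$b <- grad_mag^2
      tm$diff_max <- cfg$mu
      tm$data_max <- max(tm$b)
    },
    nbgvf = {
      tm$beta <- nbgvf_beta(grad_mag, cfg$K)
      tm$b <- grad_mag^2
      tm$diff_max <- cfg$mu * max(1, max(tm$beta))
      tm$data_max <- max(tm$b)
    },
    proposed = {
      tm$g <- coeff_g(grad_mag, cfg$K)
      tm$h <- coeff_h(grad_mag, cfg$K)
      fn <- if (isTRUE(attr(f, "normalized")) || max(f) <= 1) f else f / max(f)
      tm$gs <- if (is.null(gs)) coeff_gs(fn, cfg$tau) else gs
      tm$hs <- if (is.null(hs)) coeff_hs(fn, cfg$tau) else hs
      tm$diff_max <- max(tm$g * pmax(tm$gs, tm$hs))
      tm$data_max <- max(tm$h)
    })
  tm
}

# One explicit Euler right-hand side for both components.
#' @noRd
field_rhs <- function(u, v, tm, cfg) {
  rhs_one <- function(w, target) {
    switch(cfg$method,
      gvf = cfg$mu * laplacian5(w) - tm$b * (w - target),
      ggvf = tm$g * laplacian5(w) - tm$h * (w - target),
      ngvf = {
        d <- decompose_nn_tt(w, cfg$eps)
        cfg$mu * d$nn - tm$b * (w - target)
      },
      nbgvf = {
        d <- decompose_nn_tt(w, cfg$eps)
        cfg$mu * (d$tt + tm$beta * d$nn) - tm$b * (w - target)
      },
      proposed = {
        d <- decompose_nn_tt(w, cfg$eps)
        tm$g * (tm$gs * d$nn + tm$hs * d$tt) - tm$h * (w - target)
      })
  }
  list(ru = rhs_one(u, tm$fx), rv = rhs_one(v, tm$fy))
}

#' Solve a gradient-vector-flow-family external force field
#'
#' Iterates the evolution PDE of the configured method, starting from
#' `V = grad f`, with replicate boundaries and explicit forward-Euler time
#' stepping. The per-iteration root-mean-square of the PDE right-hand side
#' (the equilibrium residual) is recorded in the result.
#'
#' @param f Edge map (normalized nonnegative matrix), at least 3x3.
#' @param cfg A [field_config()].
#' @param gs,hs Optional override grids for the convex coefficients
#'   (`proposed` only) — diagnostic hooks for reduction tests.
#' @param g,h Optional override grids for the smoothing/data weights
#'   (`ggvf` only), same purpose.
#' @return An object of class `vector_field`: list with component matrices
#'   `u`, `v`, the `config`, and `residuals` (one value per iteration,
#'   computed before each update).
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("disk"))
#' f <- edge_map(ph$image)
#' V <- solve_field(f, field_config("gvf", mu = 0.2, n_iter = 50))
solve_field <- function(f, cfg, gs = NULL, hs = NULL, g = NULL, h = NULL) {
  assert_grid(f, "f", min_dim = 3L)
  stopifnot(inherits(cfg, "field_config"))
  tm <- field_terms(f, cfg, gs = gs, hs = hs, g = g, h = h)
  dt <- cfg$dt
  if (is.null(dt)) {
    # von Neumann bound for the combined explicit update: the worst
    # amplification factor is 1 - dt * (8 * Dmax + Bmax) on the unit grid,
    # so dt < 2 / (8 Dmax + Bmax); take 90% of it.
    denom <- 8 * tm$diff_max + tm$data_max
    dt <- if (denom > 0) 1.8 / denom else 1
  } else if (tm$diff_max > 0 && dt * tm$diff_max > 0.25 + 1e-9) {
    stop(sprintf(
      "dt = %g is unstable for method '%s': explicit scheme requires dt <= %g",
      dt, cfg$method, 0.25 / tm$diff_max), call. = FALSE)
  }
  u <- tm$fx
  v <- tm$fy
  res <- numeric(cfg$n_iter)
  for (it in seq_len(cfg$n_iter)) {
    r <- field_rhs(u, v, tm, cfg)
    res[it] <- sqrt(mean(r$ru^2 + r$rv^2))
    u <- u + dt * r$ru
    v <- v + dt * r$rv
  }
  structure(list(u = u, v = v, config = cfg, dt = dt, residuals = res),
            class = "vector_field")
}

#' @rdname solve_field
#' @param ... Passed on to [solve_field()].
#' @export
solve_gvf <- function(f, cfg = field_config("gvf"), ...) {
  cfg$method <- "gvf"; solve_field(f, cfg, ...)
}

#' @rdname solve_field
#' @export
solve_ggvf <- function(f, cfg = field_config("ggvf"), ...) {
  cfg$method <- "ggvf"; solve_field(f, cfg, ...)
}

#' @rdname solve_field
#' @export
solve_ngvf <- function(f, cfg = field_config("ngvf"), ...) {
  cfg$method <- "ngvf"; solve_field(f, cfg, ...)
}

#' @rdname solve_field
#' @export
solve_nbgvf <- function(f, cfg = field_config("nbgvf"), ...) {
  cfg$method <- "nbgvf"; solve_field(f, cfg, ...)
}

#' @rdname solve_field
#' @export
solve_proposed <- function(f, cfg = field_config("proposed"), ...) {
  cfg$method <- "proposed"; solve_field(f, cfg, ...)
}

#' Equilibrium residual of a force field
#'
#' Root-mean-square over pixels of the steady-state equation's left-hand
#' side (the PDE right-hand side) of the configured method, evaluated at
#' the given field. Zero at an exact equilibrium.
#'
#' @param V A `vector_field` or a list with matrices `u`, `v`.
#' @param f The edge map the field was solved on.
#' @param cfg A [field_config()]; defaults to the field's own config.
#' @return A nonnegative scalar.
#' @export
field_residual <- function(V, f, cfg = NULL) {
  if (is.null(cfg)) cfg <- V$config
  stopifnot(inherits(cfg, "field_config"))
  tm <- field_terms(f, cfg)
  r <- field_rhs(V$u, V$v, tm, cfg)
  sqrt(mean(r$ru^2 + r$rv^2))
}

#' Normalize a force field to unit vectors
#'
#' Magnitude-normalized external forces are the standard input to a
#' gradient-vector-flow snake: they decouple the snake's step size from the
#' local field strength. Vectors shorter than `eps` are zeroed.
#'
#' @param V A `vector_field`.
#' @param eps Magnitude below which a vector is treated as zero.
#' @return The normalized `vector_field`.
#' @export
normalize_field <- function(V, eps = 1e-8) {
  mag <- sqrt(V$u^2 + V$v^2)
  scale <- ifelse(mag > eps, 1 / pmax(mag, eps), 0)
  V$u <- V$u * scale
  V$v <- V$v * scale
  V
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %dx%d, method = %s, %d iterations, final residual %.3g\n",
              nrow(x$u), ncol(x$u), x$config$method,
              length(x$residuals),
              if (length(x$residuals)) x$residuals[length(x$residuals)] else NA))
  invisible(x)
}
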