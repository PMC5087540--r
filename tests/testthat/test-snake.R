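test_that("bilinear interpolation is exact at nodes, cell centers and on linear fields", {
  u <- matrix(rnorm(30), 5, 6)
  v <- matrix(rnorm(30), 5, 6)
  V <- list(u = u, v = v)
  at <- interpolate_field(V, tibble::tibble(x = 3, y = 2))
  expect_equal(at$fx, u[2, 3])
  expect_equal(at$fy, v[2, 3])
  mid <- interpolate_field(V, tibble::tibble(x = 2.5, y = 2.5))
  expect_equal(mid$fx, mean(u[2:3, 2:3]))
  lin <- list(u = matrix(rep(1:6, each = 5), 5, 6),
              v = matrix(rep(1:5, times = 6), 5, 6))  # u = x, v = y
  at2 <- interpolate_field(lin, tibble::tibble(x = 3.25, y = 4.5))
  expect_equal(at2$fx, 3.25)
  expect_equal(at2$fy, 4.5)
  expect_warning(interpolate_field(V, tibble::tibble(x = 10, y = 2)),
                 "clamped")
})

test_that("pure tension shrinks a circle; zero forces are a fixed point", {
  zero <- list(u = matrix(0, 64, 64), v = matrix(0, 64, 64),
               config = field_config("gvf"))
  circ <- centered_circle(15)
  cfg <- snake_config(alpha = 0.5, beta = 0, kappa = 0, n_iter = 1,
                      resample_every = 1000, tol = 1e-12)
  p <- circ
  radii <- numeric(6)
  radii[1] <- mean(sqrt((p$x - 32.5)^2 + (p$y - 32.5)^2))
  for (i in 2:6) {
    p <- evolve_snake(p, zero, cfg)$contour
    radii[i] <- mean(sqrt((p$x - 32.5)^2 + (p$y - 32.5)^2))
  }
  expect_true(all(diff(radii) < 0))
  fix <- evolve_snake(circ, zero,
                      snake_config(alpha = 0, beta = 0, kappa = 1,
                                   n_iter = 10, tol = 1e-9))
  expect_equal(as.matrix(fix$contour), as.matrix(circ), tolerance = 1e-9)
  expect_true(fix$converged)
})

test_that("a snake on the GVF field recovers the disk to high overlap", {
  ph <- disk64()
  f <- edge_map(ph$image)
  V <- solve_field(f, field_config("gvf", mu = 0.2, n_iter = 400))
  fit <- evolve_snake(centered_circle(28), V, snake_config(n_iter = 200))
  mask <- contour_to_mask(fit$contour, dim(ph$mask))
  expect_gte(evaluate_mask(mask, ph$mask)$f1, 0.95)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_identical(nrow(glance(fit)), 1L)
  expect_true(glance(fit)$perimeter > 0)
})

test_that("resampling preserves shape up to the target spacing", {
  rect <- make_initial_contour("rectangle", c(40, 40), c(50, 30),
                               n_points = 40)
  res <- gvfsnakes:::resample_closed(as.matrix(rect), 97)
  # every resampled point lies on the original polygon boundary
  d_max <- 0
  orig <- as.matrix(rect)
  n <- nrow(orig)
  for (i in seq_len(nrow(res))) {
    dmin <- Inf
    for (j in seq_len(n)) {
      a <- orig[j, ]; b <- orig[if (j == n) 1 else j + 1, ]
      ab <- b - a; t <- sum((res[i, ] - a) * ab) / max(sum(ab^2), 1e-12)
      t <- min(max(t, 0), 1)
      dmin <- min(dmin, sqrt(sum((res[i, ] - (a + t * ab))^2)))
    }
    d_max <- max(d_max, dmin)
  }
  expect_lt(d_max, 1)
})

test_that("contour rasterization follows the boundary-inclusive even-odd rule", {
  sq <- tibble::tibble(x = c(10, 20, 20, 10), y = c(10, 10, 20, 20))
  mask <- contour_to_mask(sq, c(32, 32))
  expect_identical(sum(mask), 121L)  # 11 x 11 including boundary centers
  # shoelace consistency on a triangle with area >= 400
  tri <- tibble::tibble(x = c(5, 45, 25), y = c(5, 8, 40))
  n <- nrow(tri)
  area <- abs(sum(tri$x * tri$y[c(2:n, 1)] - tri$x[c(2:n, 1)] * tri$y)) / 2
  m <- contour_to_mask(tri, c(50, 50))
  expect_lt(abs(sum(m) - area) / area, 0.05)
  # degenerate collinear contour rasterizes to nothing
  flat <- tibble::tibble(x = c(10, 15, 20), y = c(10, 10, 10))
  expect_identical(sum(contour_to_mask(flat, c(32, 32))), 0L)
})

test_that("rasterization agrees with an independent point-in-polygon oracle", {
  poly <- withr::with_seed(8, {
    th <- sort(runif(12, 0, 2 * pi))
    r <- runif(12, 8, 14)
    tibble::tibble(x = 20 + r * cos(th), y = 20 + r * sin(th))
  })
  mask <- contour_to_mask(poly, c(40, 40))
  gx <- rep(1:40, each = 40); gy <- rep(1:40, times = 40)
  oracle <- pracma::inpolygon(gx, gy, poly$x, poly$y, boundary = TRUE)
  expect_identical(as.vector(mask) == 1, as.vector(oracle))
})

test_that("snake configuration rejects degenerate settings", {
  expect_error(snake_config(gamma = 0), "gamma")
  expect_error(snake_config(tol = 0), "tol")
  zero <- list(u = matrix(0, 32, 32), v = matrix(0, 32, 32))
  expect_error(evolve_snake(tibble::tibble(x = c(5, 10, 7), y = c(5, 5, 9)),
                            zero, snake_config()), "16 points")
})
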