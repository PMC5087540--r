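test_that("g/h weights satisfy their definitions and complement identity", {
  gm <- matrix(c(0, 0.5, 1, 2), 2, 2)
  g <- coeff_g(gm, K = 0.5)
  expect_equal(g, exp(-gm / 0.5))
  expect_equal(coeff_g(matrix(1), K = 1)[1, 1], exp(-1))
  expect_equal(g + coeff_h(gm, K = 0.5), matrix(1, 2, 2))
  expect_equal(coeff_g(0, 1), 1)
  expect_error(coeff_g(gm, K = 0), "K")
  expect_error(coeff_g(gm - 3, K = 1), "nonnegative")
})

test_that("convex coefficients follow the piecewise cubic with its jump at 0", {
  expect_equal(coeff_hs(0, tau = 1), 0)
  expect_equal(coeff_gs(0, tau = 1), 1)
  expect_equal(coeff_hs(1, tau = 1), 1)       # -1/8 + 5/8 + 1/2
  expect_equal(coeff_hs(0.5, tau = 1), 0.796875)  # -1/64 + 5/16 + 1/2
  for (tau in c(0.2, 0.5, 1)) {
    f <- seq(0.001, tau - 0.001, length.out = 200)
    hs <- coeff_hs(f, tau)
    expect_true(all(diff(hs) > 0))                 # strictly increasing
    expect_lt(1 - coeff_hs(tau * (1 - 1e-9), tau), 1e-6)  # continuous at tau
    expect_true(all(coeff_hs(seq(tau, 1, length.out = 20), tau) == 1))
    expect_equal(coeff_gs(f, tau) + hs, rep(1, 200))
  }
  expect_error(coeff_hs(0.5, tau = 0), "tau")
  expect_error(coeff_hs(0.5, tau = 1.5), "tau")
  expect_error(coeff_hs(2, tau = 1), "edge map")
})

test_that("normally biased weight is a Gaussian in the gradient magnitude", {
  expect_equal(nbgvf_beta(0, 1), 1)
  expect_equal(nbgvf_beta(1, 1), exp(-1))
  expect_equal(nbgvf_beta(matrix(2), 2)[1, 1], exp(-1))
  x <- seq(0, 3, length.out = 50)
  expect_true(all(diff(nbgvf_beta(x, 0.7)) < 0))
  expect_error(nbgvf_beta(1, K = -1), "K")
})

test_that("normal/tangent split is exact on quadratics and sums to the Laplacian", {
  xs <- matrix(rep(1:9, each = 9), 9, 9)
  d <- decompose_nn_tt(xs^2)  # V = x^2: all curvature is normal
  expect_equal(d$nn[2:8, 2:8], matrix(2, 7, 7))
  expect_equal(d$tt[2:8, 2:8], matrix(0, 7, 7))
  dc <- decompose_nn_tt(matrix(5, 6, 6))
  expect_equal(dc$nn + dc$tt, matrix(0, 6, 6))
  for (s in 1:10) {
    m <- random_grid(32, 32, seed = s)
    d <- decompose_nn_tt(m, eps = 1e-10)
    lap <- gvfsnakes:::laplacian5(m)
    expect_lt(max(abs(d$nn + d$tt - lap)), 1e-6)
  }
  expect_error(decompose_nn_tt(matrix(1, 2, 2)), "3x3")
})

test_that("constant edge maps leave every solver at the zero field", {
  f <- matrix(0, 16, 16)
  for (m in c("gvf", "ggvf", "ngvf", "nbgvf", "proposed")) {
    V <- solve_field(f, field_config(m, mu = 0.2, K = 1, tau = 0.5,
                                     n_iter = 25))
    expect_equal(V$u, matrix(0, 16, 16))
    expect_equal(V$v, matrix(0, 16, 16))
  }
})

test_that("zero iterations return the edge-map gradient and bad dt is rejected", {
  ph <- disk64()
  f <- edge_map(ph$image)
  g <- gradient2d(f)
  V <- solve_field(f, field_config("gvf", mu = 0.2, n_iter = 0))
  expect_identical(V$u, g$gx)
  expect_identical(V$v, g$gy)
  expect_error(solve_field(f, field_config("gvf", mu = 0.2, dt = 5)),
               "dt <=")
})

test_that("gradient vector flow extends the capture range of an edge impulse", {
  f <- matrix(0, 64, 64); f[32, 32] <- 1
  V <- solve_field(f, field_config("gvf", mu = 0.2, n_iter = 80))
  mag <- sqrt(V$u^2 + V$v^2)
  xs <- matrix(rep(1:64, each = 64), 64, 64)
  ys <- matrix(rep(1:64, times = 64), 64, 64)
  dist <- sqrt((xs - 32)^2 + (ys - 32)^2)
  expect_gte(max(dist[mag > 1e-6]), 10)
  expect_true(all(is.finite(V$u)) && all(is.finite(V$v)))
})

test_that("solver reductions hold at the iterate level", {
  ph <- disk64()
  f <- edge_map(ph$image)
  gr <- gradient2d(f); b <- gr$gx^2 + gr$gy^2
  ones <- matrix(1, 64, 64)
  Vg <- solve_field(f, field_config("gvf", mu = 0.2, n_iter = 50))
  Vr <- solve_ggvf(f, field_config("ggvf", K = 1, n_iter = 50),
                   g = matrix(0.2, 64, 64), h = b)
  expect_lt(max(abs(Vr$u - Vg$u)), 1e-12)
  expect_lt(max(abs(Vr$v - Vg$v)), 1e-12)
  Vgg <- solve_field(f, field_config("ggvf", K = 1, n_iter = 50))
  Vp <- solve_proposed(f, field_config("proposed", K = 1, tau = 0.5,
                                       n_iter = 50), gs = ones, hs = ones)
  expect_lt(max(abs(Vp$u - Vgg$u)), 1e-12)
  expect_lt(max(abs(Vp$v - Vgg$v)), 1e-12)
  # beta -> 1 turns the normally biased field into plain GVF
  Vnb <- solve_field(f, field_config("nbgvf", mu = 0.2, K = 1e8, n_iter = 50))
  expect_lt(max(abs(Vnb$u - Vg$u)), 1e-10)
})

test_that("fields are deterministic and bounded on phantom inputs", {
  ph <- ushape64()
  f <- edge_map(ph$image)
  cfg <- field_config("proposed", K = 0.1, tau = 1, n_iter = 150)
  V1 <- solve_field(f, cfg)
  V2 <- solve_field(f, cfg)
  expect_identical(V1$u, V2$u)
  expect_identical(V1$v, V2$v)
  gmax <- max(sqrt(gradient2d(f)$gx^2 + gradient2d(f)$gy^2))
  expect_lt(max(abs(V1$u)), gmax + 1)
  expect_lt(max(abs(V1$v)), gmax + 1)
})

test_that("equilibrium residual vanishes at the fixed point and decays on the disk", {
  fz <- matrix(0, 16, 16)
  Vz <- solve_field(fz, field_config("ggvf", K = 1, n_iter = 5))
  expect_equal(field_residual(Vz, fz), 0)
  ph <- disk64()
  f <- edge_map(ph$image)
  cfg100 <- field_config("ggvf", K = 1, n_iter = 100)
  cfg200 <- field_config("ggvf", K = 1, n_iter = 200)
  V100 <- solve_field(f, cfg100)
  V200 <- solve_field(f, cfg200)
  r100 <- field_residual(V100, f, cfg100)
  r200 <- field_residual(V200, f, cfg200)
  expect_gte(r100, 0)
  expect_lte(r200, r100)
})

test_that("interior NGVF vectors point toward the nearest edge on the U-shape", {
  ph <- ushape64()
  f <- edge_map(ph$image)
  V <- solve_field(f, field_config("ngvf", mu = 0.2, n_iter = 800))
  edgepx <- which(f > 0.5, arr.ind = TRUE)
  interior <- which(ph$mask == 1 & f < 1e-9, arr.ind = TRUE)
  ok <- 0L
  for (i in seq_len(nrow(interior))) {
    r <- interior[i, 1]; cl <- interior[i, 2]
    j <- which.min((edgepx[, 1] - r)^2 + (edgepx[, 2] - cl)^2)
    dot <- (edgepx[j, 2] - cl) * V$u[r, cl] + (edgepx[j, 1] - r) * V$v[r, cl]
    if (dot > 0) ok <- ok + 1L
  }
  expect_gte(ok / nrow(interior), 0.9)
})

test_that("only the convex-coefficient field points down the full LTI slot", {
  ph <- lti64()
  f <- edge_map(ph$image)
  slot_rows <- 15:34  # between the mouth and bottom attraction zones
  Vp <- solve_field(f, field_config("proposed", K = 1, tau = 0.5,
                                    n_iter = 2000))
  # y increases downwards, so v > 0 points toward the slot bottom
  expect_true(all(Vp$v[slot_rows, 32] > 0))
  expect_true(all(Vp$v[slot_rows, 33] > 0))
  for (m in c("gvf", "ngvf", "nbgvf")) {
    Vb <- solve_field(f, field_config(m, mu = 0.2, K = 1, n_iter = 2000))
    expect_true(any(Vb$v[slot_rows, 32] < 0))
  }
})

test_that("field configuration validates method-specific parameters", {
  expect_error(field_config("proposed", tau = 0), "tau")
  expect_error(field_config("ggvf", K = -1), "K")
  expect_error(field_config("gvf", mu = -0.1), "mu")
  expect_s3_class(field_config("gvf"), "field_config")
  expect_output(print(field_config("proposed", K = 1, tau = 0.5)), "proposed")
})
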