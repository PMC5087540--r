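# Shared fixtures, built in code. Kept small so individual test files stay
# fast; anything bigger is constructed where it is used.

disk64 <- function() make_phantom(phantom_spec("disk", radius = 20))

ushape64 <- function() {
  make_phantom(phantom_spec("ushape", height = 64, width = 64,
                            side = 40, arm_width = 10))
}

lti64 <- function() {
  make_phantom(phantom_spec("lti", height = 64, width = 64,
                            side = 40, indent_width = 4))
}

# deterministic pseudo-random grid without touching the global RNG stream
# at helper definition time
random_grid <- function(h, w, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(h * w), h, w))
}

centered_circle <- function(radius, n = 100, center = c(32.5, 32.5)) {
  make_initial_contour("ellipse", center = center,
                       size = c(2 * radius, 2 * radius), n_points = n)
}
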