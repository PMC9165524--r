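test_that("ray_coordinate projects points onto the detector axis", {
  expect_equal(ray_coordinate(1, 0, 0), 1)
  expect_equal(ray_coordinate(0, 1, pi / 2), 1)
  expect_equal(ray_coordinate(3, 4, atan2(4, 3)), 5)
})

test_that("geometry uses centered detector bins and warns on short detectors", {
  g <- proj_geometry(M = 10, K = 5, d = 0.7)
  expect_equal(g$t, c(-2, -1, 0, 1, 2) * 0.7)
  expect_equal(g$theta, (0:9) * pi / 10)
  expect_warning(proj_geometry(M = 10, K = 5, d = 0.1), "truncated")
  expect_error(proj_geometry(M = 10, K = 5, d = 0.7, Delta = pi / 2), "half-turn")
})

test_that("analytic projection of a centered disc gives exact chords", {
  disc <- phantom(list(ellipse(0, 0, 0.5, 0.5, rho = 1)))
  g <- standard_geometry(64, M = 12)
  sino <- radon_analytic(disc, g)
  i0 <- which(g$t == 0)
  expect_equal(sino$values[, i0], rep(1, 12))          # diameter chord
  expect_true(all(sino$values[, abs(g$t) > 0.5] == 0)) # rays missing support
  expect_true(all(sino$values >= 0))
})

test_that("analytic projection matches dense quadrature for a rotated ellipse", {
  ph <- phantom(list(ellipse(0.25, -0.15, 0.35, 0.12, phi = 0.6, rho = 1.3)))
  set.seed(5)
  ts <- runif(10, -0.7, 0.7)
  thetas <- runif(10, 0, pi)
  for (k in 1:10) {
    p_exact <- parbeam:::.ellipse_projection(ph$ellipses[[1]], ts[k], thetas[k])
    p_quad <- oracle_line_integral(ph, ts[k], thetas[k], n = 1e6)
    expect_equal(p_exact, p_quad, tolerance = 1e-5)
  }
})

test_that("mass is conserved across view angles for an analytic sinogram", {
  ph <- shepp_logan_phantom()
  g <- standard_geometry(128, M = 36)
  sino <- radon_analytic(ph, g)
  masses <- rowSums(sino$values) * g$d
  expect_lt((max(masses) - min(masses)) / mean(masses), 0.005)
})

test_that("centrally symmetric phantoms give symmetric projections", {
  ph <- phantom(list(ellipse(0, 0, 0.5, 0.25, phi = 0.4, rho = 1),
                     ellipse(0, 0, 0.2, 0.2, rho = 0.5)))
  g <- standard_geometry(64, M = 36)
  sino <- radon_analytic(ph, g)
  # p(t, theta) = p(-t, theta) for every row of a centrally symmetric object
  for (m in c(1, 10, 20, 36))
    expect_equal(sino$values[m, ], rev(sino$values[m, ]), tolerance = 1e-12)
})

test_that("split_ray decomposes ray offsets per the interpolation contract", {
  g <- proj_geometry(M = 4, K = 9, d = 0.35)
  # exactly on bin 5 (0-based index 4, the center)
  st <- split_ray(0, 0.35, 9)
  expect_identical(st$n0, 4L)
  expect_equal(st$delta, 0)
  expect_false(st$out_of_range)
  # midway between bins 3 and 4
  tmid <- (g$t[4] + g$t[5]) / 2
  st2 <- split_ray(tmid, 0.35, 9)
  expect_identical(st2$n0, 3L)
  expect_equal(st2$delta, 0.5)
  # reconstruction identity t = (n0 + delta - (K-1)/2) * d
  set.seed(2)
  tt <- runif(20, -1, 1)
  st3 <- split_ray(tt, 0.35, 9)
  expect_equal((st3$n0 + st3$delta - 4) * 0.35, tt)
  # beyond the last bin
  expect_true(split_ray(1.45, 0.35, 9)$out_of_range)
  expect_true(split_ray(-1.6, 0.35, 9)$out_of_range)
})

test_that("interp_projection blends neighbouring bins linearly", {
  row <- c(5, 2, 4, 1, 5)
  expect_equal(interp_projection(row, split_ray(0, 1, 5)), row[3])
  st <- list(n0 = 1L, delta = 0.5, out_of_range = FALSE)
  expect_equal(interp_projection(row, st), 3)
  st2 <- list(n0 = 0L, delta = 0.25, out_of_range = FALSE)
  expect_equal(interp_projection(c(1, 5, 0, 0, 0), st2), 2)
  expect_equal(interp_projection(row, split_ray(10, 1, 5)), 0)
})

test_that("discrete projector concentrates a center pixel at t = 0", {
  N <- 15                                 # odd: a pixel sits exactly at (0,0)
  img <- image_grid(N)
  img$values[8, 8] <- 1
  g <- standard_geometry(N, M = 10)
  sino <- radon_discrete(img, g)
  i0 <- which(g$t == 0)
  expect_equal(sino$values[, i0], rep(1, 10))
  expect_equal(rowSums(sino$values), rep(1, 10))
  # zero image maps to zero sinogram
  expect_true(all(radon_discrete(image_grid(N), g)$values == 0))
})

test_that("discrete projector and back-projector are adjoint", {
  set.seed(42)
  g <- proj_geometry(M = 12, K = 25, d = 2 / 16)
  f <- image_grid(matrix(runif(256), 16, 16))
  p <- matrix(runif(12 * 25), 12, 25)
  lhs <- sum(radon_discrete(f, g)$values * p)
  rhs <- g$M * sum(f$values * back_project(sinogram(p, g), N = 16)$values)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("discrete projection converges to the analytic Radon transform", {
  ph <- shepp_logan_phantom()
  errs <- vapply(c(64, 128, 256), function(N) {
    g <- standard_geometry(64, M = 18)   # fixed geometry, finer images
    sino_a <- radon_analytic(ph, g)
    img <- rasterize(ph, N)
    sino_d <- radon_discrete(img, g)
    scale <- img$spacing^2 / g$d         # weight-sum to line-integral units
    sqrt(mean((sino_d$values * scale - sino_a$values)^2))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("sinogram noise is seeded, unbiased and sized correctly", {
  ph <- shepp_logan_phantom()
  g <- proj_geometry(M = 180, K = 256, d = 2 / 180)
  sino <- radon_analytic(ph, g)
  expect_identical(add_noise(sino, 0, seed = 1)$values, sino$values)
  n1 <- add_noise(sino, 0.1, seed = 9)
  n2 <- add_noise(sino, 0.1, seed = 9)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(sino, 0.1, seed = 10)$values, n1$values))
  expect_equal(sd(n1$values - sino$values), 0.1, tolerance = 0.05)
  expect_error(add_noise(sino, -0.1), "sigma")
  # caller RNG state untouched
  set.seed(123); a <- runif(1)
  set.seed(123); invisible(add_noise(sino, 0.2, seed = 4)); b <- runif(1)
  expect_identical(a, b)
})
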