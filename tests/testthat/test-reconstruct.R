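test_that("back-projection matches its defining accumulation bit-for-bit", {
  set.seed(8)
  g <- proj_geometry(M = 4, K = 25, d = 2 / 16)
  sino <- sinogram(matrix(runif(4 * 25), 4, 25), g)
  expect_identical(back_project(sino, N = 16)$values,
                   oracle_back_project(sino, 16))
})

test_that("back-projection of simple sinograms behaves as an average", {
  g <- standard_geometry(32, M = 24)
  zero <- sinogram(matrix(0, 24, g$K), g)
  expect_true(all(back_project(zero, N = 32)$values == 0))
  const <- sinogram(matrix(3.7, 24, g$K), g)
  bp <- back_project(const, N = 32)
  # pixels whose rays all land on the detector average to exactly c
  tmax <- max(g$t)
  inner <- circle_mask(32, tmax - g$d)
  expect_equal(bp$values[inner], rep(3.7, sum(inner)), tolerance = 1e-12)
})

test_that("filtered back-projection is linear and amplitude-correct", {
  ph <- shepp_logan_phantom()
  g <- standard_geometry(64, M = 60)
  p <- radon_analytic(ph, g)
  q <- add_noise(p, 0.2, seed = 3)
  a <- 1.7; b <- -0.6
  mix <- sinogram(a * p$values + b * q$values, g)
  rec_mix <- fbp_reconstruct(mix, "ram-lak", N = 64)
  rec_lin <- a * fbp_reconstruct(p, "ram-lak", N = 64)$values +
    b * fbp_reconstruct(q, "ram-lak", N = 64)$values
  expect_equal(rec_mix$values, rec_lin, tolerance = 1e-10)
  # zero in, zero out
  z <- sinogram(matrix(0, 60, g$K), g)
  expect_true(all(fbp_reconstruct(z, "shepp-logan", N = 64)$values == 0))
  # amplitude: a constant disc's interior level is recovered within 2%
  disc <- phantom(list(ellipse(0, 0, 0.8, 0.8, rho = 1)))
  rec <- fbp_reconstruct(radon_analytic(disc, standard_geometry(128, M = 180)),
                         "ram-lak", N = 128)
  expect_equal(mean(rec$values[circle_mask(128, 0.7)]), 1, tolerance = 0.02)
})

test_that("reconstruction circle masking zeroes the uncovered corners", {
  g <- standard_geometry(32, M = 12)
  sino <- sinogram(matrix(1, 12, g$K), g)
  rec <- fbp_reconstruct(sino, "ram-lak", N = 32, circle = TRUE)
  expect_true(all(rec$values[!circle_mask(32)] == 0))
})

test_that("direct Fourier inversion approximates the disc phantom", {
  disc <- phantom(list(ellipse(0, 0, 0.5, 0.5, rho = 1)))
  truth <- rasterize(disc, 128)
  g <- standard_geometry(128, M = 180)
  sino <- radon_analytic(disc, g)
  mask <- circle_mask(128, 0.95)
  err_f <- rmse(fourier_reconstruct(sino, N = 128), truth, mask)
  err_fbp <- rmse(fbp_reconstruct(sino, "ram-lak", N = 128), truth, mask)
  expect_lt(err_f, 2 * err_fbp)
  # zero in, zero out
  z <- sinogram(matrix(0, 180, g$K), g)
  expect_true(all(fourier_reconstruct(z, N = 64)$values == 0))
  expect_error(fourier_reconstruct(sinogram(matrix(1, 1, g$K),
                                            proj_geometry(M = 1, K = g$K, d = g$d))),
               "at least 2 angles")
})

test_that("SIRT solves a one-pixel system exactly in one iteration", {
  g <- proj_geometry(M = 1, K = 3, d = 4)   # unit weight, unit scale
  sino <- sinogram(matrix(c(0, 3, 0), 1, 3), g)
  rec0 <- sirt_reconstruct(sino, n_iters = 0, N = 1, circle = FALSE)
  expect_identical(rec0$values, matrix(0, 1, 1))
  rec1 <- sirt_reconstruct(sino, n_iters = 1, relax = 1, N = 1, circle = FALSE)
  expect_equal(rec1$values[1, 1], 3)
  expect_error(sirt_reconstruct(sino, relax = 0), "relax")
  expect_error(sirt_reconstruct(sino, relax = 2.5), "relax")
})

test_that("SIRT residuals decrease monotonically on consistent data", {
  N <- 16
  g <- standard_geometry(N, M = 24)
  xs <- grid_coords(N)
  f0 <- outer(xs, xs, function(x, y) exp(-(x^2 + y^2) / 0.35^2))
  p <- radon_discrete(image_grid(f0), g)
  rec <- sirt_reconstruct(p, n_iters = 50, N = N)
  res <- attr(rec, "residuals")
  expect_true(all(diff(res) <= 1e-12))
  expect_lt(res[50], 0.01 * sqrt(sum(p$values^2)))
})

test_that("the reconstruct() dispatcher routes to every method", {
  ph <- phantom(list(ellipse(0, 0, 0.5, 0.5, rho = 1)))
  g <- standard_geometry(32, M = 24)
  sino <- radon_analytic(ph, g)
  for (m in c("fbp", "bp", "fourier", "sirt")) {
    img <- reconstruct(sino, method = m, n_iters = 5, N = 32)
    expect_s3_class(img, "image_grid")
    expect_equal(img$N, 32)
  }
  expect_error(reconstruct(sino, method = "art"))
})
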