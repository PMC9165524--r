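test_that("shepp-logan phantom evaluates correctly at known points", {
  ph <- shepp_logan_phantom()
  expect_length(ph$ellipses, 10)
  # outside every ellipse
  expect_identical(phantom_value(ph, 0, 0.95), 0)
  # dense feature region near (0, -0.605): skull + brain + one small ellipse
  tab <- phantom_table(ph)
  expect_equal(phantom_value(ph, 0, -0.605),
               oracle_point_value(tab, 0, -0.605))
  expect_equal(phantom_value(ph, 0, -0.605), 1.03)
  # cross-check a scatter of random points against the point oracle
  set.seed(11)
  xs <- runif(50, -1, 1); ys <- runif(50, -1, 1)
  expect_equal(phantom_value(ph, xs, ys),
               vapply(seq_along(xs), function(k)
                 oracle_point_value(tab, xs[k], ys[k]), numeric(1)))
})

test_that("a mirror-symmetric sub-phantom evaluates symmetrically", {
  # the two outer ellipses are centered on the y axis
  ph <- phantom(shepp_logan_phantom()$ellipses[1:2])
  set.seed(4)
  xs <- runif(40, -1, 1); ys <- runif(40, -1, 1)
  expect_equal(phantom_value(ph, xs, ys), phantom_value(ph, -xs, ys))
})

test_that("phantom evaluation is rotation covariant", {
  ells <- list(ellipse(0.3, -0.2, 0.4, 0.15, phi = 0.3, rho = 1.5),
               ellipse(-0.1, 0.4, 0.2, 0.2, phi = 0, rho = -0.5))
  ph <- phantom(ells)
  phi <- 0.77
  rotated <- phantom(lapply(ells, function(e) {
    cc <- cos(phi) * e$cx - sin(phi) * e$cy
    ss <- sin(phi) * e$cx + cos(phi) * e$cy
    ellipse(cc, ss, e$a, e$b, phi = e$phi + phi, rho = e$rho)
  }))
  set.seed(7)
  xs <- runif(60, -0.9, 0.9); ys <- runif(60, -0.9, 0.9)
  xr <- cos(phi) * xs - sin(phi) * ys
  yr <- sin(phi) * xs + cos(phi) * ys
  expect_equal(phantom_value(rotated, xr, yr), phantom_value(ph, xs, ys),
               tolerance = 1e-12)
})

test_that("rasterization is additive, linear, and area-accurate", {
  e1 <- ellipse(0.2, 0.1, 0.3, 0.2, rho = 1)
  e2 <- ellipse(-0.3, -0.2, 0.25, 0.4, phi = 0.5, rho = 0.7)
  r_both <- rasterize(phantom(list(e1, e2)), 64)
  r1 <- rasterize(phantom(list(e1)), 64)
  r2 <- rasterize(phantom(list(e2)), 64)
  expect_identical(r_both$values, r1$values + r2$values)

  # empty phantom and intensity linearity
  expect_true(all(rasterize(phantom(list()), 32)$values == 0))
  e1d <- ellipse(0.2, 0.1, 0.3, 0.2, rho = 2)
  expect_identical(rasterize(phantom(list(e1d)), 64)$values, 2 * r1$values)

  # pixel-count area of a centered disc of radius 0.5 at N = 256
  disc <- rasterize(phantom(list(ellipse(0, 0, 0.5, 0.5, rho = 1))), 256)
  frac <- mean(disc$values > 0)
  expect_equal(frac, pi * 0.25 / 4, tolerance = 0.02)
})

test_that("image grid uses the centered coordinate convention", {
  xs <- grid_coords(5)
  expect_equal(xs, c(-2, -1, 0, 1, 2) * 2 / 5)
  expect_equal(grid_coords(4), c(-1.5, -0.5, 0.5, 1.5) * 2 / 4)
  expect_equal(mean(grid_coords(17)), 0)
  img <- image_grid(8)
  expect_equal(img$spacing, 2 / 8)
  expect_true(all(img$values == 0))
})

test_that("supersampled rasterization softens edges but preserves interiors", {
  ph <- phantom(list(ellipse(0, 0, 0.5, 0.5, rho = 1)))
  r1 <- rasterize(ph, 64)
  r4 <- rasterize(ph, 64, supersample = 4)
  # deep interior identical; edge pixels take fractional values
  inner <- circle_mask(64, 0.3)
  expect_equal(r4$values[inner], r1$values[inner])
  expect_true(any(r4$values > 0 & r4$values < 1))
})

test_that("vessel phantom honours the stenosis contract", {
  vp0 <- vessel_phantom(stenosis_pct = 0)
  expect_equal(vp0$truth$stenosis_pct, 0)
  expect_equal(vp0$truth$lumen_minimal_diameter,
               vp0$truth$lumen_reference_diameter)

  vp50 <- vessel_phantom(reference_diameter = 0.4, stenosis_pct = 50)
  expect_equal(vp50$truth$lumen_minimal_diameter, 0.2)

  # ground truth recomputed from the returned ellipse geometry: the
  # indentation pair spans [minimal/2, reference/2] in |y|
  notch <- vp50$phantom$ellipses[[3]]
  minimal_geom <- 2 * (notch$cy - notch$b)
  expect_equal(100 * (1 - minimal_geom / 0.4), 50, tolerance = 1e-9)

  # calcified plaque is brighter than the lumen in the analytic phantom
  vp70 <- vessel_phantom(stenosis_pct = 70, plaque = "calcified")
  tr <- vp70$truth
  plaque_val <- phantom_value(vp70$phantom, 0, tr$plaque_center_y)
  lumen_val <- phantom_value(vp70$phantom, 0.5, 0)
  expect_gt(plaque_val, lumen_val)
  # noncalcified plaque sits between background and lumen
  vpn <- vessel_phantom(stenosis_pct = 70, plaque = "noncalcified")
  pn <- phantom_value(vpn$phantom, 0, -vpn$truth$plaque_center_y)
  expect_gt(pn, vpn$truth$background)
  expect_lt(pn, lumen_val)

  expect_error(vessel_phantom(stenosis_pct = 100), "stenosis_pct")
  expect_error(vessel_phantom(stenosis_pct = -5), "stenosis_pct")
  expect_error(vessel_phantom(reference_diameter = 1.2), "reference_diameter")
})
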