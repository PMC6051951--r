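test_that("matched filter FWHM follows Gaussian quadrature", {
  expect_identical(matched_filter_fwhm(7.0, 7.0), 0)
  expect_identical(matched_filter_fwhm(0.0, 7.0), 7)
  expect_equal(matched_filter_fwhm(6.3, 7.0), sqrt(49 - 39.69))
  expect_error(matched_filter_fwhm(7.0, 6.3), "cannot sharpen")
  expect_error(matched_filter_fwhm(-1, 7), ">= 0")
})

test_that("Gaussian smoothing: identity at zero, constant fields invariant", {
  g <- pet_grid(c(41, 41, 41), 1.5)
  v <- activity_volume(array(stats::runif(41^3), g$shape), g)
  expect_identical(gaussian_smooth(v, 0), v)
  expect_error(gaussian_smooth(v, -2), ">= 0")

  u <- activity_volume(array(7.5, g$shape), g)
  su <- gaussian_smooth(u, 6)
  # interior: > 5 sigma from every border
  expect_equal(su[21, 21, 21], 7.5, tolerance = 1e-6)
  expect_lt(max(abs(su[15:27, 15:27, 15:27] - 7.5)), 1e-6)
})

test_that("two-stage smoothing equals one quadrature-FWHM smoothing", {
  g <- pet_grid(c(41, 41, 41), 1.0)
  point <- array(0, g$shape); point[21, 21, 21] <- 1
  v <- activity_volume(point, g)
  for (f in list(c(4, 3), c(5, 6), c(7, 2))) {
    two <- gaussian_smooth(gaussian_smooth(v, f[1]), f[2])
    one <- gaussian_smooth(v, sqrt(f[1]^2 + f[2]^2))
    expect_lt(max(abs(two - one)), 1e-4 * max(one))
  }
})

test_that("trilinear resampling is exact at sample points and on affine fields", {
  g <- pet_grid(c(12, 11, 10), c(1.4, 1.6, 2.0), origin = c(1, 2, 3))
  vals <- array(stats::rnorm(12 * 11 * 10), g$shape)
  v <- suppressWarnings(activity_volume(vals, g))
  expect_identical(resample_to_grid(v, g), v)

  # a + b . x is reproduced exactly at interior target centers
  ax <- grid_axes(g)
  ramp <- outer(outer(2 + 0.3 * ax[[1]], 0.5 * ax[[2]], "+"), -0.2 * ax[[3]], "+")
  vr <- suppressWarnings(activity_volume(ramp, g))
  tg <- pet_grid(c(5, 5, 5), c(1.9, 2.1, 2.3), origin = c(2.3, 3.1, 4.7))
  out <- resample_to_grid(vr, tg)
  tax <- grid_axes(tg)
  want <- outer(outer(2 + 0.3 * tax[[1]], 0.5 * tax[[2]], "+"), -0.2 * tax[[3]], "+")
  expect_equal(as.vector(out), as.vector(want), tolerance = 1e-9)

  expect_error(resample_to_grid(v, pet_grid(c(2, 2, 2), -1)), "positive")
})

test_that("trilinear interpolation matches the 8-corner hand computation", {
  set.seed(11)
  g <- pet_grid(c(8, 8, 8), 1.0)
  vals <- array(stats::rnorm(512), g$shape)
  for (rep in 1:25) {
    idx <- stats::runif(3, 0.2, 6.8)
    got <- petharm:::trilinear_at_index(vals, matrix(idx, 1))
    expect_equal(got, trilinear_oracle(vals, idx), tolerance = 1e-12)
  }
})

test_that("PGC correction divides the imaged AC by the recovery factor", {
  expect_equal(pgc_correct(8.0, 0.8), 10.0)
  expect_equal(pgc_correct(9.0, 0.9), 10.0)
  expect_identical(pgc_correct(5.5, 1.0), 5.5)
  expect_error(pgc_correct(1, 0), "pgc_factor")
  expect_error(pgc_correct(1, 1.1), "pgc_factor")

  # scaling commutes with smoothing and resampling
  g <- pet_grid(c(16, 16, 16), 1.2)
  v <- activity_volume(array(stats::runif(16^3), g$shape), g)
  tg <- pet_grid(c(7, 7, 7), 2.0, origin = c(1, 1, 1))
  a <- resample_to_grid(gaussian_smooth(pgc_correct(v, 0.8), 4), tg)
  b <- pgc_correct(resample_to_grid(gaussian_smooth(v, 4), tg), 0.8)
  expect_lt(max(abs(a - b)), 1e-9)
})

test_that("harmonization of two scanners viewing the same uniform field agrees", {
  g <- pet_grid(c(71, 71, 71), 1.0)
  truth <- activity_volume(array(10, g$shape), g, ground_truth = TRUE)
  sc1 <- scanner_model("a", c(1.73, 1.73, 2.43), 6.7, pgc_factor = 0.8)
  sc2 <- scanner_model("b", c(2.09, 2.09, 2.03), 6.3, pgc_factor = 0.9)
  o1 <- simulate_scan(truth, sc1, 1)
  o2 <- simulate_scan(truth, sc2, 2)
  tgt <- harmonization_target()
  tgrid <- pet_grid(c(11, 11, 9), tgt$target_spacing, origin = c(22, 22, 22))
  h1 <- harmonize_volume(o1, sc1, tgt, target_grid = tgrid)
  h2 <- harmonize_volume(o2, sc2, tgt, target_grid = tgrid)
  expect_lt(max(abs(h1 - 10)), 1e-6)
  expect_lt(max(abs(h2 - 10)), 1e-6)
})

test_that("scanner already at target with unit PGC passes through unchanged", {
  g <- pet_grid(c(15, 15, 15), c(2.1, 2.1, 2.4))
  v <- activity_volume(array(stats::runif(15^3), g$shape), g)
  sc <- scanner_model("attarget", c(2.1, 2.1, 2.4), 7.0, pgc_factor = 1)
  h <- harmonize_volume(v, sc, harmonization_target(), target_grid = g)
  expect_equal(as.vector(h), as.vector(v), tolerance = 1e-12)
})

test_that("imaging at 6.3 mm then harmonizing matches direct imaging at 7.0 mm", {
  g <- pet_grid(c(80, 80, 80), 1.0)
  les <- lesion_manifest("L", 40, 40, 40, diameter_mm = 14, ac_kbq_ml = 100,
                         trachea_distance_mm = 10)
  truth <- build_ground_truth(les, 0, g)
  sharp <- scanner_model("sharp", c(2.0, 2.0, 2.0), 6.3, pgc_factor = 1)
  attgt <- scanner_model("attgt", c(2.0, 2.0, 2.0), 7.0, pgc_factor = 1)
  tgrid <- pet_grid(c(21, 21, 21), 2.0, origin = c(19, 19, 19))
  h <- harmonize_volume(simulate_scan(truth, sharp, 1), sharp,
                        harmonization_target(target_spacing = 2.0),
                        target_grid = tgrid)
  d <- resample_to_grid(simulate_scan(truth, attgt, 1), tgrid)
  expect_lt(max(abs(h - d)), 0.01 * 100)
})

test_that("harmonization is linear in the input values", {
  g <- pet_grid(c(25, 25, 25), 1.5)
  v <- activity_volume(array(stats::runif(25^3), g$shape), g)
  sc <- scanner_model("s", c(2.1, 2.1, 2.4), 6.0, pgc_factor = 0.9)
  tgrid <- pet_grid(c(8, 8, 8), c(2.1, 2.1, 2.4), origin = c(4, 4, 4))
  h1 <- harmonize_volume(v, sc, target_grid = tgrid)
  v3 <- activity_volume(unclass(v) * 3, g)
  h3 <- harmonize_volume(v3, sc, target_grid = tgrid)
  expect_equal(as.vector(h3), 3 * as.vector(h1), tolerance = 1e-12)
})
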