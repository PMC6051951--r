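test_that("ground truth paints voxel-center-in-sphere membership exactly", {
  g <- pet_grid(c(25, 25, 25), 1.0)

  # no lesions: uniform background
  empty <- lesion_manifest(character(0), numeric(0), numeric(0), numeric(0),
                           numeric(0), numeric(0), numeric(0))
  tr <- build_ground_truth(empty, 0.1, g)
  expect_true(all(tr == 0.1))

  # lesion centered on a voxel center: that voxel carries the lesion AC
  les <- lesion_manifest("L1", 12, 12, 12, diameter_mm = 10, ac_kbq_ml = 100,
                         trachea_distance_mm = 3)
  tr <- build_ground_truth(les, 0, g)
  expect_identical(tr[13, 13, 13], 100)

  # voxel count equals the exhaustive count of integer lattice points within
  # 5 mm of the center (1-mm isotropic grid)
  n_inside <- 0L
  for (i in -5:5) for (j in -5:5) for (k in -5:5) {
    if (i^2 + j^2 + k^2 <= 25) n_inside <- n_inside + 1L
  }
  expect_identical(sum(tr == 100), n_inside)
  expect_identical(sum(tr == 0), length(tr) - n_inside)
})

test_that("overlapping or out-of-grid lesions are rejected by name", {
  g <- pet_grid(c(30, 30, 30), 1.0)
  overlapping <- lesion_manifest(c("a", "b"), c(10, 14), c(10, 10), c(10, 10),
                                 diameter_mm = c(8, 8), ac_kbq_ml = c(1, 2),
                                 trachea_distance_mm = c(1, 1))
  expect_error(build_ground_truth(overlapping, 0, g), "'a' and 'b'")
  outside <- lesion_manifest("edge", 28, 10, 10, diameter_mm = 10,
                             ac_kbq_ml = 5, trachea_distance_mm = 1)
  expect_error(build_ground_truth(outside, 0, g), "outside")
})

test_that("identity forward model reproduces the truth exactly", {
  g <- pet_grid(c(20, 20, 20), 1.0)
  les <- lesion_manifest("L", 10, 10, 10, 8, 50, 2)
  truth <- build_ground_truth(les, 0.2, g)
  sc <- scanner_model("ideal", 1.0, resolution_fwhm = 0, pgc_factor = 1,
                      noise_coeff = 0)
  obs <- simulate_scan(truth, sc, seed = 1)
  expect_identical(dim(obs), dim(truth))
  expect_equal(max(abs(obs - truth)), 0)
})

test_that("uniform truth is imaged uniformly at pgc_factor * value", {
  g <- pet_grid(c(61, 61, 61), 1.0)
  truth <- activity_volume(array(10, g$shape), g, ground_truth = TRUE)
  sc <- scanner_model("blurry", 1.0, resolution_fwhm = 7, pgc_factor = 0.8,
                      noise_coeff = 0)
  obs <- simulate_scan(truth, sc, seed = 1)
  # center voxel is ~4 FWHM from every border: zero-padding influence gone
  expect_equal(obs[31, 31, 31], 8.0, tolerance = 1e-6)
})

test_that("noise-free blur + resampling conserves total activity for interior lesions", {
  g <- pet_grid(c(70, 70, 70), 1.0)
  les <- lesion_manifest("L", 35, 35, 35, diameter_mm = 12, ac_kbq_ml = 100,
                         trachea_distance_mm = 10)
  truth <- build_ground_truth(les, 0, g)  # lesion center ~5 FWHM from borders
  sc <- scanner_model("s", 1.0, resolution_fwhm = 7, pgc_factor = 1,
                      noise_coeff = 0)
  obs <- simulate_scan(truth, sc, seed = 1)
  mass <- function(v) sum(v) * prod(vol_grid(v)$spacing)
  expect_equal(mass(obs), mass(truth), tolerance = 0.01)
})

test_that("simulated scans are deterministic in the seed and linear in the truth", {
  g <- pet_grid(c(24, 24, 24), 1.0)
  les <- lesion_manifest("L", 12, 12, 12, 8, 40, 2)
  truth <- build_ground_truth(les, 0.5, g)
  sc <- scanner_model("noisy", c(2, 2, 2), 6, pgc_factor = 0.9, noise_coeff = 0.5)
  a <- simulate_scan(truth, sc, seed = 42)
  b <- simulate_scan(truth, sc, seed = 42)
  expect_identical(as.vector(a), as.vector(b))
  c_ <- simulate_scan(truth, sc, seed = 43)
  expect_false(identical(as.vector(a), as.vector(c_)))

  # noise-free observation scales exactly with the truth
  sc0 <- scanner_model("quiet", c(2, 2, 2), 6, pgc_factor = 0.9, noise_coeff = 0)
  scaled <- build_ground_truth(
    lesion_manifest("L", 12, 12, 12, 8, 3 * 40, 2), 3 * 0.5, g)
  expect_equal(as.vector(simulate_scan(scaled, sc0, 1)),
               3 * as.vector(simulate_scan(truth, sc0, 1)), tolerance = 1e-12)
})

test_that("scanner and lesion constructors enforce their invariants", {
  expect_error(scanner_model("s", 1, 6, pgc_factor = 0), "pgc_factor")
  expect_error(scanner_model("s", 1, 6, pgc_factor = 1.2), "pgc_factor")
  expect_error(scanner_model("s", 1, -1), "resolution_fwhm")
  expect_error(scanner_model("s", 1, 6, noise_coeff = -0.1), "noise_coeff")
  expect_error(lesion_manifest("L", 1, 1, 1, -5, 10, 1), "diameters")
  expect_error(lesion_manifest("L", 1, 1, 1, 5, -1, 1), "ACs")
  expect_error(lesion_manifest("L", 1, 1, 1, 5, 10, -1), "trachea")
})

test_that("sampled lesion populations are reproducible, interior, and disjoint", {
  g <- pet_grid(c(120, 120, 100), 1.0)
  a <- sample_lesions(20, g, seed = 7)
  b <- sample_lesions(20, g, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 20)
  # building the truth validates interiority and pairwise disjointness
  expect_no_error(build_ground_truth(a, 0.05, g))
  expect_true(all(a$ac_kbq_ml >= 0.2 & a$ac_kbq_ml <= 800))
})
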