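test_that("decay constants and the two-point fit invert each other", {
  expect_equal(decay_constant(log(2)), 1.0)
  expect_equal(decay_constant(100.22), log(2) / 100.22)
  for (t in c(5, 48, 192.6)) expect_equal(decay_constant(t) * t, log(2))
  expect_error(decay_constant(0), "> 0")

  expect_equal(effective_lambda_two_point(10, 10), 0)
  expect_equal(effective_lambda_two_point(10, 5), log(2) / 96)
  # ACs generated from a known lambda recover it to machine precision
  for (lam in c(-0.003, 0, 0.005, 0.02)) {
    a24 <- 37
    a120 <- a24 * exp(-lam * 96)
    expect_equal(effective_lambda_two_point(a24, a120), lam, tolerance = 1e-14)
  }
  expect_error(effective_lambda_two_point(-1, 5), "> 0")
  expect_error(effective_lambda_two_point(10, 5, 120, 24), "exceed")
})

test_that("projection to 131-I swaps the physical decay, keeps the biology", {
  cst <- nuclide_constants()
  lp124 <- decay_constant(cst$t_half_phys_124)
  lp131 <- decay_constant(cst$t_half_phys_131)
  # zero biological clearance: pure physical decay of the therapy nuclide
  expect_equal(project_lambda_to_i131(lp124, cst), lp131)
  # flat measured curve: projected curve rises (131-I decays slower)
  expect_equal(project_lambda_to_i131(0, cst), lp131 - lp124)
  expect_lt(project_lambda_to_i131(0, cst), 0)
  # closed form at a 48-h effective 124-I half-life
  expect_equal(project_lambda_to_i131(log(2) / 48, cst),
               log(2) / 48 - log(2) / 100.22 + log(2) / 192.6)
})

test_that("TIAC contribution matches adaptive quadrature of the projected curve", {
  cst <- nuclide_constants()
  lp124 <- decay_constant(cst$t_half_phys_124)
  lp131 <- decay_constant(cst$t_half_phys_131)
  for (t_eff in c(20, 48, 96, 500)) {
    lam124 <- decay_constant(t_eff)
    got <- i131_tiac_contribution(50, lam124, constants = cst)
    b24 <- 50 * exp((lp124 - lp131) * 24)
    l131 <- project_lambda_to_i131(lam124, cst)
    want <- stats::integrate(function(t) b24 * exp(-l131 * (t - 24)), 24, 120,
                             rel.tol = 1e-10)$value
    expect_equal(got, want, tolerance = 1e-8)
  }
  # negative projected decay (rising curve) integrates correctly too
  lam_rising <- lp124 - lp131 - 0.001  # gives l131 = -0.001
  got <- i131_tiac_contribution(50, lam_rising, constants = cst)
  b24 <- 50 * exp((lp124 - lp131) * 24)
  want <- stats::integrate(function(t) b24 * exp(0.001 * (t - 24)), 24, 120,
                           rel.tol = 1e-10)$value
  expect_equal(got, want, tolerance = 1e-8)

  # flat-curve analytic limit and continuity across the switch
  lam_flat <- lp124 - lp131          # exactly l131 = 0
  expect_equal(i131_tiac_contribution(10, lam_flat, constants = cst),
               10 * exp((lp124 - lp131) * 24) * 96)
  eps <- 1e-13 / 96
  lo <- i131_tiac_contribution(10, lam_flat - eps, constants = cst)
  hi <- i131_tiac_contribution(10, lam_flat + eps, constants = cst)
  expect_lt(abs(lo - hi), 1e-9)

  # homogeneity in the measured AC
  expect_equal(i131_tiac_contribution(20, 0.01), 2 * i131_tiac_contribution(10, 0.01))
  expect_error(i131_tiac_contribution(0, 0.01), "> 0")
})

test_that("the Monte-Carlo TIAC uncertainty is reproducible and scale-invariant", {
  cfg <- tiacsim_config(t_eff_124 = 48, rel_sd_ac = 0.2, n_draws = 5000, seed = 9)
  a <- simulate_tiac_uncertainty(cfg)
  b <- simulate_tiac_uncertainty(cfg)
  expect_identical(a$rel_sd_tiac, b$rel_sd_tiac)

  # invariance to the reference AC under identical seeds
  c1 <- simulate_tiac_uncertainty(tiacsim_config(a24_ref = 1, t_eff_124 = 48,
                                                 rel_sd_ac = 0.2, n_draws = 5000,
                                                 seed = 9))
  c1000 <- simulate_tiac_uncertainty(tiacsim_config(a24_ref = 1000, t_eff_124 = 48,
                                                    rel_sd_ac = 0.2, n_draws = 5000,
                                                    seed = 9))
  expect_equal(c1$rel_sd_tiac, c1000$rel_sd_tiac, tolerance = 1e-12)
  expect_equal(c1000$tiac_ref, 1000 * c1$tiac_ref, tolerance = 1e-9)

  # no noise in, no noise out
  quiet <- simulate_tiac_uncertainty(tiacsim_config(rel_sd_ac = 0, n_draws = 1000))
  expect_identical(quiet$rel_sd_tiac, 0)
  expect_identical(quiet$n_resampled, 0L)

  expect_error(tiacsim_config(rel_sd_ac = 1), "rel_sd_ac")
  expect_error(tiacsim_config(n_draws = 10), "n_draws")
})

test_that("small-noise simulation matches first-order error propagation", {
  for (t_eff in c(24, 48, 72, 96)) {
    sim <- simulate_tiac_uncertainty(tiacsim_config(t_eff_124 = t_eff,
                                                    rel_sd_ac = 0.02,
                                                    n_draws = 2e5, seed = 17))
    delta <- tiac_delta_oracle(t_eff, 0.02)
    expect_equal(sim$rel_sd_tiac, delta, tolerance = 0.1)
    # two equal independent relative errors with exponents summing to one:
    # the ratio lives in [1/sqrt(2), 1]
    ratio <- sim$rel_sd_tiac / 2  # rel_sd_ac = 2%
    expect_gte(ratio, 1 / sqrt(2) - 0.02)
    expect_lte(ratio, 1 + 0.02)
  }
})

test_that("the sweep grid reduces to single runs and behaves monotonically", {
  base <- tiacsim_config(n_draws = 5000, seed = 11)
  one <- sweep_tiac_uncertainty(0.15, 48, base)
  expect_equal(nrow(one), 1)
  direct <- simulate_tiac_uncertainty(tiacsim_config(t_eff_124 = 48,
                                                     rel_sd_ac = 0.15,
                                                     n_draws = 5000,
                                                     seed = one$seed))
  expect_equal(one$rel_sd_tiac_pct, direct$rel_sd_tiac)

  sw <- sweep_tiac_uncertainty(c(0.05, 0.10, 0.15, 0.20, 0.25), c(24, 96),
                               tiacsim_config(n_draws = 2e4, seed = 13))
  expect_equal(nrow(sw), 10)
  # non-decreasing in the AC noise along each half-life row (2 MC SEs slack)
  for (te in c(24, 96)) {
    y <- sw$rel_sd_tiac_pct[sw$t_eff_h == te]
    se <- y / sqrt(2 * 2e4)
    expect_true(all(diff(y) > -2 * (se[-1] + se[-length(se)])))
  }
  expect_error(sweep_tiac_uncertainty(numeric(0), 48), "non-empty")
})
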