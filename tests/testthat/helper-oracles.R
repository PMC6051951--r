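# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own vectorized implementations.

# trilinear interpolation of a 3D array at one continuous 0-based index,
# written as the explicit 8-corner weighted sum
trilinear_oracle <- function(values, idx) {
  i0 <- floor(idx)
  f <- idx - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[1] else 1 - f[1]) *
         (if (dy) f[2] else 1 - f[2]) *
         (if (dz) f[3] else 1 - f[3])
    acc <- acc + w * values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# all 0-based voxel indices of `grid` whose centers lie within `radius` mm of
# `center`, by exhaustive triple loop
sphere_members_oracle <- function(grid, center, radius) {
  out <- NULL
  for (i in 0:(grid$shape[1] - 1)) for (j in 0:(grid$shape[2] - 1))
    for (k in 0:(grid$shape[3] - 1)) {
      w <- grid$origin + c(i, j, k) * grid$spacing
      if (sqrt(sum((w - center)^2)) <= radius + 1e-12) out <- rbind(out, c(i, j, k))
    }
  out
}

# Lin's concordance by direct evaluation of the moment formula
ccc_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# exact two-sided Mann-Whitney p by full enumeration of all group labelings
mw_perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(ia) {
    ranks <- rank(pooled)
    sum(ranks[ia]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, u_of)
  mu <- na * (length(b)) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# first-order (delta-method) relative SD of the two-point TIAC, from
# numerical log-derivatives of the closed-form TIAC in the two measured ACs
tiac_delta_oracle <- function(t_eff_124, rel_sd_ac, t_early = 24, t_late = 120,
                              constants = nuclide_constants()) {
  a24 <- 100
  a_late <- a24 * exp(-decay_constant(t_eff_124) * (t_late - t_early))
  tiac_of <- function(ae, al) {
    lam <- effective_lambda_two_point(ae, al, t_early, t_late)
    i131_tiac_contribution(ae, lam, t_early, t_late, constants)
  }
  eps <- 1e-6
  d_early <- (log(tiac_of(a24 * (1 + eps), a_late)) -
                log(tiac_of(a24 * (1 - eps), a_late))) / (2 * eps)
  d_late <- (log(tiac_of(a24, a_late * (1 + eps))) -
               log(tiac_of(a24, a_late * (1 - eps)))) / (2 * eps)
  100 * rel_sd_ac * sqrt(d_early^2 + d_late^2)
}

# small deterministic phantom pair used by several tests: two noise-free
# scanners with equal PGC but different resolution/grid, fully harmonized
make_harmonized_pair <- function(grid_shape = c(110, 110, 90)) {
  g <- pet_grid(grid_shape, 1.0)
  les <- lesion_manifest(
    c("A", "B", "C", "D"),
    center_x_mm = c(30, 80, 30, 78), center_y_mm = c(30, 30, 80, 80),
    center_z_mm = c(30, 45, 45, 62),
    diameter_mm = c(10, 13, 16, 20),
    ac_kbq_ml = c(10, 50, 200, 800),
    trachea_distance_mm = c(3, 10, 20, 8)
  )
  truth <- build_ground_truth(les, 0.05, g)
  sc_test <- scanner_model("mr", c(2.09, 2.09, 2.03), 6.3, pgc_factor = 0.9)
  sc_ref <- scanner_model("ct", c(1.73, 1.73, 2.43), 6.8, pgc_factor = 0.9)
  obs_test <- simulate_scan(truth, sc_test, 1)
  obs_ref <- simulate_scan(truth, sc_ref, 2)
  target <- harmonization_target()
  tgrid <- petharm:::common_target_grid(obs_ref, obs_test, target)
  list(
    lesions = les, truth = truth,
    ref = harmonize_volume(obs_ref, sc_ref, target, target_grid = tgrid),
    test = harmonize_volume(obs_test, sc_test, target, target_grid = tgrid)
  )
}
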