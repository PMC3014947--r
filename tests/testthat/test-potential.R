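test_that("pair acceptance matches the exact hard-cube result at every shift", {
  cube <- matrix(c(0L, 0L, 0L), 1, 3)
  shifts <- as.matrix(expand.grid(x = -3:3, y = -3:3, z = -3:3))
  got <- dl_superpose_at_shift(cube, cube, shifts)
  want <- apply(shifts, 1, function(s) oracle_cubes_disjoint(c(0, 0, 0), s))
  expect_equal(got, unname(want))
})

test_that("single-monomer pairs give the exact potential limits", {
  cube <- matrix(c(0L, 0L, 0L), 1, 3)
  ens <- replicate(1, cube, simplify = FALSE)
  set.seed(12)
  suppressWarnings({
    pot <- dl_estimate_potential(ens, ens, r_grid = c(0, 2, 10),
                                 trials_per_bin = 400)
  })
  # r = 0: identical cubes always clash -> censored lower bound
  expect_true(pot$censored[1])
  expect_equal(pot$u_eff[1], log(400))
  # r = 2 and beyond: cubes never share a site -> u_eff = 0 exactly
  expect_equal(pot$u_eff[2], 0)
  expect_equal(pot$u_eff[3], 0)
  expect_equal(pot$n_accepted[2], pot$n_total[2])
})

test_that("superposition trials hit the target separation and accept far pairs", {
  conf <- random_conf(16, seed = 31)
  set.seed(13)
  far <- dl_superpose(conf, conf, target_r = 500)
  expect_true(far$accepted)
  expect_lt(abs(far$realized_r - 500), 1)
  expect_error(dl_superpose(conf, conf, target_r = -1))
})

test_that("SAW potentials are repulsive, monotone and vanish at large r", {
  ens <- saw_ensemble(32)
  rg <- ens$rg_iso
  set.seed(14)
  suppressWarnings(
    pot <- dl_estimate_potential(ens, ens, r_grid = rg * c(0, 0.5, 1, 2, 4),
                                 trials_per_bin = 3000))
  expect_true(all(pot$u_eff >= 0))
  expect_false(any(pot$censored))
  # non-increasing within statistical resolution
  for (k in seq_len(nrow(pot) - 1)) {
    slack <- 2 * sqrt(pot$stderr[k]^2 + pot$stderr[k + 1]^2)
    expect_lte(pot$u_eff[k + 1], pot$u_eff[k] + slack)
  }
  expect_lt(pot$u_eff[nrow(pot)], 0.05)
  # acceptance fraction non-decreasing in r
  f <- pot$n_accepted / pot$n_total
  expect_true(all(diff(f) > -0.02))
})

test_that("the estimator is symmetric under swapping the two ensembles", {
  a <- saw_ensemble(32)
  b <- saw_ensemble(32, seed = 1999)
  grid <- a$rg_iso * c(0.3, 1, 2)
  set.seed(15)
  suppressWarnings(u_ab <- dl_estimate_potential(a, b, grid, trials_per_bin = 4000))
  set.seed(16)
  suppressWarnings(u_ba <- dl_estimate_potential(b, a, grid, trials_per_bin = 4000))
  z <- abs(u_ab$u_eff - u_ba$u_eff) /
    sqrt(u_ab$stderr^2 + u_ba$stderr^2)
  # per-bin agreement at the 2-sigma level, allowing the usual multiple-
  # comparison slack at 3 sigma
  expect_true(all(z < 3))
  expect_gte(sum(z < 2), nrow(u_ab) - 1)
})

test_that("potential ratios propagate errors and handle degenerate bins", {
  curve <- data.frame(r = c(2, 4, 8), r_over_rg = c(0.5, 1, 2),
                      u_eff = c(2, 1, 0.5), stderr = c(0.1, 0.05, 0.02),
                      censored = FALSE)
  class(curve) <- c("dl_potential", class(curve))
  q <- dl_potential_ratio(curve, curve)
  expect_equal(q$q, rep(1, 3))
  expect_equal(q$stderr, sqrt(2) * curve$stderr / curve$u_eff * 1)

  weak <- curve
  weak$u_eff <- c(2, 1, 0.01)
  weak$stderr <- c(0.1, 0.05, 0.05)   # last bin consistent with zero
  expect_message(q2 <- dl_potential_ratio(curve, weak), "dropping")
  expect_equal(nrow(q2), 2)
})

test_that("overlap fractions follow the bin-wise minimum rule", {
  expect_equal(dl_overlap_fraction(c(0.5, 0.5, 0), c(0.5, 0.5, 0)), 1)
  expect_equal(dl_overlap_fraction(c(1, 0), c(0, 1)), 0)
  expect_equal(dl_overlap_fraction(c(0.5, 0.5, 0), c(0, 0.5, 0.5)), 0.5)
  expect_error(dl_overlap_fraction(c(1, 0), c(0, 0, 1)), "mismatched")
  expect_error(dl_overlap_fraction(c(2, 0), c(0, 1)), "normalized")
})

test_that("accepted-pair profiles recover the isolated references at large r", {
  ens <- saw_ensemble(32)
  set.seed(17)
  suppressWarnings(
    prof <- dl_pair_shape_profile(ens, ens, r_grid = ens$rg_iso * c(0.2, 6),
                                  trials_per_bin = 3000))
  far <- prof[2, ]
  expect_lt(abs(far$alpha - 1), 0.03)
  expect_lt(abs(far$asph_ratio - 1), 0.06)
  expect_lt(abs(far$beta_deg - 57.2958), 3 * far$beta_se + 0.5)
  expect_lt(far$overlap, 0.02)
  # conditioning at short distance swells and elongates the chains
  near <- prof[1, ]
  expect_gt(near$alpha, 1)
  expect_gt(near$asph_ratio, 1)
  expect_gt(near$overlap, 0.5)
  # each projected density integrates to one
  dens <- attr(prof, "densities")[[1]]
  expect_equal(sum(dens$density_a), 1, tolerance = 1e-9)
  expect_equal(sum(dens$density_b), 1, tolerance = 1e-9)
})
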