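allowed_keys <- local({
  bv <- unclass(dl_allowed_bond_vectors())
  paste(bv[, 1], bv[, 2], bv[, 3], sep = ",")
})

test_that("chain initialization produces valid conformations of any length", {
  one <- dl_init_chain(1)
  expect_equal(nrow(one), 1L)
  expect_true(dl_validate_conformation(one))
  two <- dl_init_chain(2)
  expect_true(dl_validate_conformation(two))
  expect_true(dl_bond_allowed(two[2, ] - two[1, ]))
  expect_error(dl_init_chain(0), "N must be")

  # odd and even snake box sides, including plane-boundary bonds
  for (N in c(5L, 16L, 24L, 27L, 100L))
    expect_true(oracle_conf_valid(dl_init_chain(N), allowed_keys))

  c1 <- dl_init_chain(64, seed = 1, relax_sweeps = 300)
  c2 <- dl_init_chain(64, seed = 2, relax_sweeps = 300)
  expect_false(identical(c1, c2))
  expect_true(oracle_conf_valid(c1, allowed_keys))
  expect_true(oracle_conf_valid(c2, allowed_keys))
  # determinism under the same seed
  expect_identical(c1, dl_init_chain(64, seed = 1, relax_sweeps = 300))
})

test_that("trial moves enforce bond, excluded-volume and loop conditions", {
  # dimer with bond (3,0,0): stretching it to (4,0,0) leaves the bond set
  dimer <- rbind(c(0L, 0L, 0L), c(3L, 0L, 0L))
  res <- dl_trial_move(dimer, 2, c(1, 0, 0))
  expect_false(res$accepted)
  expect_equal(res$positions, dimer, ignore_attr = TRUE)

  # dimer with bond (2,0,0): a transverse step keeps an allowed bond
  dimer2 <- rbind(c(0L, 0L, 0L), c(2L, 0L, 0L))
  res2 <- dl_trial_move(dimer2, 2, c(0, 1, 0))
  expect_true(res2$accepted)
  expect_equal(res2$positions[2, ], c(2L, 1L, 0L), ignore_attr = TRUE)

  # excluded volume: moving monomer 1 next to monomer 3's cube is rejected
  # even though both bonds stay allowed
  tri <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 1L, 0L))
  expect_true(dl_validate_conformation(tri))
  res3 <- dl_trial_move(tri, 1, c(1, 0, 0))
  expect_false(res3$accepted)
  # same move with the blocking monomer absent is fine
  res4 <- dl_trial_move(tri[1:2, ], 1, c(1, 0, 0))
  expect_true(res4$accepted)

  # an active loop vetoes moves that break co-localization
  chain <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 0L))
  loops <- dl_loopset(1, 3, lifetime = 10)   # pair at sqrt(8) < 3
  res5 <- dl_trial_move(chain, 3, c(1, 0, 0), loops = loops)  # -> distance 3
  expect_false(res5$accepted)
  res6 <- dl_trial_move(chain, 3, c(1, 0, 0))                 # no loop: fine
  expect_true(res6$accepted)
})

test_that("accepted moves are reversible (detailed-balance precondition)", {
  set.seed(11)
  dirs <- rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  conf <- random_conf(8, seed = 3)
  n_acc <- 0
  for (k in 1:300) {
    m <- sample(8, 1); d <- dirs[sample(6, 1), ]
    res <- dl_trial_move(conf, m, d)
    if (res$accepted) {
      n_acc <- n_acc + 1
      back <- dl_trial_move(res$positions, m, -d)
      expect_true(back$accepted)
      expect_equal(back$positions, conf, ignore_attr = TRUE)
      conf <- res$positions
    }
  }
  expect_gt(n_acc, 50)  # the walk actually moved
})

test_that("a single free monomer accepts every move", {
  run <- dl_run_sweeps(dl_init_chain(1), 200)
  expect_true(all(run$acceptance == 1))
})

test_that("sweeps preserve all conformation invariants, with and without loops", {
  set.seed(21)
  run <- dl_run_sweeps(random_conf(32, seed = 5), 10000, p = 0,
                       store_every = 250, record_every = 50)
  expect_true(all(run$acceptance >= 0 & run$acceptance <= 1))
  for (snap in run$stored)
    expect_true(oracle_conf_valid(snap, allowed_keys))

  set.seed(22)
  run2 <- dl_run_sweeps(random_conf(32, seed = 6), 5000, p = 0.5, lambda = 200,
                        store_every = 500, record_every = 50)
  for (snap in run2$stored)
    expect_true(oracle_conf_valid(snap, allowed_keys))
  # every active loop pair is co-localized in the final state
  if (nrow(run2$loops) > 0) {
    d2 <- rowSums((run2$positions[run2$loops[, 1], , drop = FALSE] -
                   run2$positions[run2$loops[, 2], , drop = FALSE])^2)
    expect_true(all(d2 < 9))
    expect_true(all(abs(run2$loops[, 1] - run2$loops[, 2]) >= 2))
  }
})

test_that("equilibrated self-avoiding walks have the canonical mean bond length", {
  ens <- saw_ensemble(32)
  expect_gt(ens$mean_bond_length, 2.6)
  expect_lt(ens$mean_bond_length, 2.8)
})

test_that("conformation validation catches broken inputs", {
  expect_error(dl_validate_conformation(rbind(c(0, 0, 0), c(1, 0, 0))),
               "not an allowed bond")
  expect_error(dl_validate_conformation(rbind(c(0, 0, 0), c(0.5, 0, 0))),
               "integer")
})
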