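test_that("co-localized partners respect distance and chain-neighbour rules", {
  straight <- cbind(x = 2L * (0:8), y = 0L, z = 0L)
  expect_identical(dl_colocalized_partners(straight, 5), integer(0))
  expect_identical(dl_colocalized_partners(straight, 5, threshold = 0), integer(0))

  # hand-built square hairpin: monomer 1 sees 3 (sqrt 8) and 4 (distance 2);
  # its bonded neighbour 2 is excluded by the |i - j| >= 2 rule
  hairpin <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 0L),
                   c(2L, 0L, 0L))
  expect_error(dl_validate_conformation(hairpin), NA)
  expect_identical(dl_colocalized_partners(hairpin, 1), c(3L, 4L))
  expect_identical(dl_colocalized_partners(hairpin, 4), c(1L, 2L))
})

test_that("loop formation follows the co-localization/probability rule", {
  hairpin <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 0L), c(2L, 0L, 0L))
  # p = 0: the loop set never grows
  set.seed(1)
  loops <- dl_loopset()
  for (k in 1:50)
    loops <- dl_attempt_loop_event(hairpin, loops, p = 0, lambda = 5)
  expect_equal(nrow(loops), 0L)
  # p = 1: a loop forms as soon as a monomer with free partners is drawn
  set.seed(2)
  loops <- dl_attempt_loop_event(hairpin, dl_loopset(), p = 1, lambda = 5)
  attempts <- 1
  while (nrow(loops) == 0 && attempts < 50) {
    loops <- dl_attempt_loop_event(hairpin, loops, p = 1, lambda = 5)
    attempts <- attempts + 1
  }
  expect_equal(nrow(loops), 1L)
  expect_gte(loops$j - loops$i, 2L)
  d2 <- sum((hairpin[loops$i, ] - hairpin[loops$j, ])^2)
  expect_lt(d2, 9)
})

test_that("drawn lifetimes have the Poisson mean", {
  hairpin <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 0L), c(2L, 0L, 0L))
  set.seed(3)
  lifetimes <- replicate(2000, {
    l <- dl_loopset()
    while (nrow(l) == 0) l <- dl_attempt_loop_event(hairpin, l, p = 1, lambda = 50)
    l$lifetime
  })
  se <- sd(lifetimes) / sqrt(length(lifetimes))
  expect_lt(abs(mean(lifetimes) - 50), 3 * se + 1e-9)
})

test_that("loop decay matches the lifetime distribution's survival curve", {
  loops <- dl_loopset(seq(1, 300, by = 3), seq(3, 302, by = 3),
                      lifetime = local({ set.seed(4); rpois(100, 10) }))
  expect_identical(dl_decay_loops(loops, 0), loops)

  one <- dl_loopset(1, 3, lifetime = 3)
  expect_equal(nrow(dl_decay_loops(one, 3)), 0L)

  # sweep-by-sweep decay of many loops against the Poisson upper tail
  set.seed(5)
  n0 <- 600
  big <- dl_loopset(seq_len(n0) * 3 - 2, seq_len(n0) * 3, rpois(n0, 10))
  cur <- big
  for (t in 1:12) {
    cur <- dl_decay_loops(cur, 1)
    p_surv <- ppois(t, 10, lower.tail = FALSE)   # lifetime > t
    tol <- 4 * sqrt(p_surv * (1 - p_surv) / n0) + 2 / n0
    expect_lt(abs(nrow(cur) / n0 - p_surv), tol + 1e-12)
  }
})

test_that("the enforcement constraint uses a strict 3-lattice-unit bound", {
  chain8 <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 0L))
  chain9 <- rbind(c(0L, 0L, 0L), c(0L, 2L, 0L), c(2L, 2L, 1L))
  expect_true(dl_loop_constraint_ok(chain8, dl_loopset()))
  expect_true(dl_loop_constraint_ok(chain8, dl_loopset(1, 3, 5)))   # sqrt(8)
  expect_false(dl_loop_constraint_ok(chain9, dl_loopset(1, 3, 5)))  # exactly 3
})

test_that("mean loop count behaves on trivial series and grows with p", {
  expect_error(dl_mean_loop_count(integer(0)), "empty")
  expect_equal(dl_mean_loop_count(c(5, 5, 5))$mean, 5)

  conf <- random_conf(32, seed = 9)
  counts <- vapply(c(0, 0.002, 0.2), function(p) {
    set.seed(31)
    run <- dl_run_sweeps(conf, 6000, p = p, lambda = 150, record_every = 10)
    n <- length(run$loop_count)
    mean(run$loop_count[(n %/% 2):n])
  }, numeric(1))
  expect_equal(counts[1], 0)
  expect_true(all(diff(counts) > 0))
})

test_that("loop tables reject malformed input", {
  expect_error(dl_loopset(1, 2, 5), ">= 2")
  expect_error(dl_loopset(c(1, 1), c(4, 4), c(5, 5)), "duplicate")
  expect_error(dl_loopset(1, 4, -1), "non-negative")
})
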