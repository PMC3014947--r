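test_that("model MSD curves start at the bond scale and grow monotonically", {
  ens <- saw_ensemble(32)
  curve <- dl_model_msd_curve(ens, kb_per_bead = 400)
  expect_equal(curve$genomic_kb[1], 400)
  # lag-1 value is the mean squared bond length of the move set
  expect_gt(curve$msd[1], 6.8)
  expect_lt(curve$msd[1], 7.8)
  # SAW internal distances grow with genomic separation (no leveling-off)
  expect_true(all(diff(curve$msd) > -2))
  expect_gt(curve$msd[31] / curve$msd[1], 10)
})

test_that("synthetic FISH curves follow the stated saturating form", {
  g <- c(1000, 5000, 25000)
  clean <- dl_synthesize_fish_curve(g, plateau = 8, crossover = 5000,
                                    noise = 0, seed = 1)
  expect_equal(clean$msd[2], 8 * (1 - exp(-1)))
  expect_equal(clean$msd[3], 8 * (1 - exp(-5)))
  a <- dl_synthesize_fish_curve(g, 8, 5000, noise = 0.1, seed = 1)
  b <- dl_synthesize_fish_curve(g, 8, 5000, noise = 0.1, seed = 1)
  c <- dl_synthesize_fish_curve(g, 8, 5000, noise = 0.1, seed = 2)
  expect_identical(a, b)
  expect_false(identical(a, c))
  expect_error(dl_synthesize_fish_curve(g, plateau = -1), "positive")
})

test_that("a known spatial scale is recovered from self-generated data", {
  # plateaued 'model' curve in lattice units
  model <- dl_synthesize_fish_curve(seq(400, 40000, 400), plateau = 160,
                                    crossover = 3000, noise = 0, seed = 3)
  model$source <- "model"
  true_scale <- 0.177  # um per lattice unit
  fish <- model
  fish$msd <- model$msd * true_scale^2
  fish$source <- "synthetic-fish"

  fit <- dl_fit_spatial_scale(model, fish)
  expect_equal(fit$nm_per_lattice_unit, 1000 * true_scale, tolerance = 0.01)

  # identical curves (already matching units) give scale 1
  fit1 <- dl_fit_spatial_scale(model, model)
  expect_equal(fit1$nm_per_lattice_unit, 1000, tolerance = 1e-6)

  # robust to subsampling the genomic grid by factors up to 4
  for (k in c(2, 4)) {
    sub <- fish[seq(1, nrow(fish), by = k), ]
    fitk <- dl_fit_spatial_scale(model, sub)
    expect_equal(fitk$nm_per_lattice_unit, 1000 * true_scale, tolerance = 0.01)
  }

  # noisy data still recovers the scale to a few percent
  noisy <- dl_synthesize_fish_curve(seq(400, 40000, 400), plateau = 160 * true_scale^2,
                                    crossover = 3000, noise = 0.05, seed = 4)
  fitn <- dl_fit_spatial_scale(model, noisy)
  expect_equal(fitn$nm_per_lattice_unit, 1000 * true_scale, tolerance = 0.05)
})

test_that("plateau-less model curves are rejected unless forced", {
  rising <- data.frame(genomic_kb = seq(400, 12800, 400))
  rising$msd <- (rising$genomic_kb / 400)^1.18 * 7
  fish <- rising
  fish$msd <- fish$msd * 0.04
  expect_error(dl_fit_spatial_scale(rising, fish), "plateau")
  fit <- dl_fit_spatial_scale(rising, fish, force = TRUE)
  expect_equal(fit$nm_per_lattice_unit, 200, tolerance = 0.01)

  apart <- data.frame(genomic_kb = c(1e6, 2e6), msd = c(1, 1))
  expect_error(dl_fit_spatial_scale(rising, apart), "overlap")
})

test_that("physical distances convert through the mapping", {
  expect_equal(dl_um_to_lattice(2, 177), 2000 / 177)
})
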