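test_that("the gyration tensor matches hand computations", {
  pts <- matrix(rep(c(1, 2, 3), each = 4), ncol = 3)  # coincident points
  expect_equal(dl_gyration_tensor(pts), matrix(0, 3, 3))

  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(dl_gyration_tensor(two), diag(c(1, 0, 0)))

  set.seed(6)
  cloud <- matrix(rnorm(30), ncol = 3)
  tr <- sum(diag(dl_gyration_tensor(cloud)))
  ctr <- sweep(cloud, 2, colMeans(cloud))
  expect_equal(tr, mean(rowSums(ctr^2)))
})

test_that("asphericity has the sphere/rod limits and known intermediate value", {
  expect_equal(dl_asphericity(c(3, 3, 3)), 0)
  expect_equal(dl_asphericity(c(5, 0, 0)), 1)
  # (2,1,1): pair differences 1, 0, 1 over 2 (2+1+1)^2 -> 1/16, which also
  # equals the relative shape anisotropy kappa^2 for these eigenvalues
  expect_equal(dl_asphericity(c(2, 1, 1)), 1 / 16)
  expect_error(dl_asphericity(c(0, 0, 0)), "undefined")
})

test_that("asphericity is invariant under rotation and scaling of coordinates", {
  set.seed(7)
  for (k in 1:10) {
    cloud <- matrix(rnorm(45), ncol = 3)
    rot <- qr.Q(qr(matrix(rnorm(9), 3)))
    a0 <- dl_shape_stats(cloud)$asphericity
    a1 <- dl_shape_stats(3.7 * cloud %*% rot)$asphericity
    expect_equal(a0, a1, tolerance = 1e-10)
    s <- dl_shape_stats(cloud)
    expect_equal(s$rg2, sum(s$eigenvalues), tolerance = 1e-10)
  }
})

test_that("principal-axis angles are headless, symmetric and bounded", {
  expect_equal(dl_principal_axis_angle(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(dl_principal_axis_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  a <- c(0.3, -1, 2); b <- c(1.5, 0.2, -0.4)
  expect_equal(dl_principal_axis_angle(a, b), dl_principal_axis_angle(b, a))
  expect_equal(dl_principal_axis_angle(-a, b), dl_principal_axis_angle(a, b))
  expect_error(dl_principal_axis_angle(c(0, 0, 0), b), "zero")
})

test_that("tau_int recovers white-noise and AR(1) references", {
  set.seed(8)
  white <- rnorm(50000)
  expect_lt(abs(dl_autocorrelation_time(white)$tau_int - 0.5), 0.1)

  phi <- 0.9
  x <- oracle_ar1(1e6, phi, seed = 9)
  tau <- dl_autocorrelation_time(x)$tau_int
  expect_lt(abs(tau / ((1 + phi) / (2 * (1 - phi))) - 1), 0.10)

  expect_error(dl_autocorrelation_time(rep(1, 500)), "constant")
  expect_error(dl_autocorrelation_time(rnorm(10)), "too short")
})

test_that("thinning keeps the prescribed spacing and decorrelates snapshots", {
  stored <- as.list(1:100)
  thin <- dl_thin_ensemble(stored, seq(10, 1000, by = 10), tau_int = 5)
  expect_lte(length(thin$conformations), 100)
  expect_true(all(diff(thin$kept_at) >= 10))
  expect_error(dl_thin_ensemble(list(), integer(0), 5), "empty")

  ens <- saw_ensemble(32)
  rg2 <- vapply(ens$conformations, function(m) sum(scale(m, scale = FALSE)^2) / nrow(m),
                numeric(1))
  rho1 <- cor(rg2[-1], rg2[-length(rg2)])
  expect_lt(abs(rho1), 0.25)
})
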