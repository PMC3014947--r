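test_that("the allowed bond-vector set has exactly 108 members", {
  bv <- dl_allowed_bond_vectors()
  expect_equal(nrow(bv), 108L)
  expect_equal(nrow(unique(unclass(bv))), 108L)
})

test_that("the set is closed under permutation/sign symmetry and matches an
           independent enumeration", {
  bv <- unclass(dl_allowed_bond_vectors())
  keys <- paste(bv[, 1], bv[, 2], bv[, 3], sep = ",")
  expect_setequal(keys, oracle_bond_set())
  # closure: applying any axis permutation and sign flip stays inside
  flipped <- cbind(-bv[, 2], bv[, 3], bv[, 1])
  expect_setequal(paste(flipped[, 1], flipped[, 2], flipped[, 3], sep = ","), keys)
  expect_setequal(sort(unique(rowSums(bv^2))), c(4, 5, 6, 9, 10))
})

test_that("membership queries agree with the enumerated set over all small vectors", {
  expect_true(dl_bond_allowed(c(2, 0, 0)))
  expect_false(dl_bond_allowed(c(1, 0, 0)))   # shorter than 2: cubes would overlap
  expect_false(dl_bond_allowed(c(2, 2, 2)))   # not generated by any base class
  expect_false(dl_bond_allowed(c(3, 1, 1)))
  grid <- as.matrix(expand.grid(x = -4:4, y = -4:4, z = -4:4))
  keys <- paste(grid[, 1], grid[, 2], grid[, 3], sep = ",")
  expect_equal(dl_bond_allowed(grid), keys %in% oracle_bond_set())
})
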