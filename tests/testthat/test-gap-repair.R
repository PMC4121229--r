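test_that("angular_shift_value follows the reference-anchored geometry", {
  expect_equal(angular_shift_value(0, 10, 5, 4), 8)
  expect_equal(angular_shift_value(100, 102, 2, 1), 101)   # stays on y = 100 + x
  expect_equal(angular_shift_value(7, 19, 4, 4), 19)       # identity
  # symmetric handling before the reference (negative offsets)
  expect_equal(angular_shift_value(0, -10, -5, -4), -8)

  expect_error(angular_shift_value(0, 1, 3, 0), "collapse")
  expect_error(angular_shift_value(0, 1, 0, 1), "nonzero")
  expect_error(angular_shift_value(0, 1, 3, 4), "magnitude")
  expect_error(angular_shift_value(0, 1, 3, -2), "sign")
})

test_that("angular shift preserves lines through the reference", {
  set.seed(5)
  for (i in 1:30) {
    ref <- runif(1, -50, 50)
    d <- runif(1, -10, 10)
    o <- sample(2:20, 1)
    new <- sample(seq_len(o), 1)
    val <- ref + d * o
    expect_equal(angular_shift_value(ref, val, o, new), ref + d * new,
                 tolerance = 1e-12)
  }
})

test_that("compact_after_removals recalculates from original values", {
  line <- indexed_series(0:4, c(100, 101, 102, 103, 104))
  cs <- compact_after_removals(removal_ledger(line, removed = 2))
  expect_equal(cs$values, c(100, 101, 102, 103))
  expect_identical(cs$indices, 0:3)
  expect_identical(attr(cs, "original_indices"), c(0L, 1L, 3L, 4L))

  # removing the last element shifts nothing
  cs <- compact_after_removals(removal_ledger(iseries(tab$ds3), removed = 4))
  expect_equal(cs$values, c(100, 101, 102, 103))

  # the derived hand-worked case: 40 at offset 4 -> offset 3 -> 30
  s <- indexed_series(0:4, c(0, 10, 20, 31, 40))
  cs <- compact_after_removals(removal_ledger(s, removed = 3))
  expect_equal(cs$values, c(0, 10, 20, 30))

  # initial gaps compact the same way as removals
  g <- indexed_series(c(0, 1, 3, 4), c(100, 101, 103, 104))
  expect_equal(compact_after_removals(g)$values, c(100, 101, 102, 103))
})

test_that("compaction is removal-order independent and protects the reference", {
  set.seed(9)
  base <- indexed_series(0:9, 50 + 3 * (0:9) + rnorm(10))
  rem <- c(2L, 6L, 7L)
  for (perm in list(rem, rev(rem), rem[c(2, 1, 3)])) {
    cs <- compact_after_removals(removal_ledger(base, removed = perm))
    ref_cs <- compact_after_removals(removal_ledger(base, removed = sort(rem)))
    expect_equal(cs$values, ref_cs$values)
  }
  expect_error(removal_ledger(base, removed = c(0, 2)), "reference")
  expect_error(removal_ledger(base, removed = c(2, 2)), "duplicate")
  expect_error(
    compact_after_removals(removal_ledger(indexed_series(0:2, 1:3),
                                          removed = 1:2)),
    "fewer than 2")
})

test_that("compaction with an interior reference shifts both sides", {
  # line y = 10 + 2x, reference at index 2, remove one point on each side
  s <- indexed_series(0:5, 10 + 2 * (0:5), reference = 2)
  cs <- compact_after_removals(removal_ledger(s, removed = c(1, 4)))
  # survivors 0,2,3,5 -> contiguous 0..3, reference value unchanged,
  # everything still on a line with slope 2 through the reference
  expect_equal(cs$values, c(12, 14, 16, 18))
  expect_identical(cs$reference, 1L)
})

test_that("constant_transform reproduces the printed transform column", {
  expect_equal(constant_transform(iseries(tab$ds6)),
               c(0, 0.06, 0.12, 0.42, 0.24), tolerance = 1e-9)
})

test_that("constant_transform maps lines to zero, gaps included", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    keep <- sort(sample(0:(2 * n), n))
    d <- runif(1, -5, 5)
    c0 <- runif(1, -100, 100)
    s <- indexed_series(keep, c0 + d * keep)
    expect_equal(constant_transform(s), rep(0, n), tolerance = 1e-9)
  }
  expect_equal(constant_transform(indexed_series(c(0, 1, 3, 4),
                                                 2 * c(0, 1, 3, 4))),
               rep(0, 4))
})

test_that("constant_transform is non-negative, zero at the reference, and trend invariant", {
  set.seed(33)
  for (i in 1:25) {
    n <- sample(4:15, 1)
    idx <- sort(sample(0:(3 * n), n))
    v <- rnorm(n, sd = 10)
    s <- indexed_series(idx, v)
    tt <- constant_transform(s)
    expect_true(all(tt >= 0))
    expect_identical(tt[1], 0)
    cc <- runif(1, -5, 5)
    dd <- runif(1, -50, 50)
    t2 <- constant_transform(indexed_series(idx, v + cc * idx + dd))
    expect_equal(t2, tt, tolerance = 1e-7)
  }
})

test_that("constant_transform rejects a zero relative index sum", {
  s <- indexed_series(0:2, c(1, 2, 3), reference = 1)
  expect_error(constant_transform(s), "zero index sum")
})
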