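test_that("the generator is deterministic under a seed", {
  spec <- simulation_spec(n = 50, outlier_fraction = 0.3, seed = 99)
  a <- make_series(spec)
  b <- make_series(spec)
  expect_identical(a$series$values, b$series$values)
  expect_identical(as.character(a$truth$label), as.character(b$truth$label))
})

test_that("truth labels are consistent with the contamination performed", {
  sim <- make_series(simulation_spec(n = 80, trend = "decreasing",
                                     outlier_fraction = 0.4, seed = 4))
  base <- 1050 - (0:79)
  out <- sim$truth$index[sim$truth$label == "outlier"]
  clean <- sim$truth$index[sim$truth$label == "nonoutlier"]
  expect_identical(length(out), 32L)
  at <- match(out, sim$series$indices)
  expect_true(all(sim$series$values[at] != base[out + 1]))
  expect_equal(sim$series$values[match(clean, sim$series$indices)],
               base[clean + 1])
  # protected reference stays clean
  expect_identical(as.character(sim$truth$label[sim$truth$index ==
    sim$series$reference]), "nonoutlier")
})

test_that("a zero outlier fraction yields a labelled exact AP", {
  sim <- make_series(simulation_spec(n = 10, outlier_fraction = 0, seed = 1))
  expect_true(all(sim$truth$label == "nonoutlier"))
  expect_equal(mms_max(sim$series), 0.2)
  expect_true(all(fit <- detect_outliers(sim$series)$labels$label ==
                    "nonoutlier"))
})

test_that("missing regions are removed from the series and labelled", {
  regions <- list(c(100, 50), c(300, 100), c(550, 100), c(800, 50))
  sim <- make_series(simulation_spec(n = 1000, missing_regions = regions,
                                     seed = 2))
  expect_identical(length(sim$series), 700L)
  expect_identical(sum(sim$truth$label == "missing"), 300L)
  expect_false(any(sim$series$indices %in% 300:399))
  expect_error(
    simulation_spec(n = 100, missing_regions = list(c(10, 5), c(12, 3))),
    "disjoint")
  expect_error(simulation_spec(n = 100, missing_regions = list(c(90, 20))),
               "within")
})

test_that("gaussian contamination is additive and mild", {
  sim <- make_series(simulation_spec(n = 100, outlier_mode = "gaussian",
                                     seed = 6))
  out <- sim$truth$index[sim$truth$label == "outlier"]
  base <- 1050 + out
  dev <- sim$series$values[match(out, sim$series$indices)] - base
  expect_true(all(dev != 0))
  # sigma is 5% of the range (99): essentially all draws within 5 sigma
  expect_true(all(abs(dev) < 5 * 0.05 * 99))
  # constant trend falls back to a sigma from the intercept
  cs <- make_series(simulation_spec(n = 20, trend = "constant",
                                    outlier_mode = "gaussian", seed = 8))
  expect_true(any(cs$series$values != 1050))
})

test_that("evaluate_labels counts the four percentages correctly", {
  t4 <- outlier_labels(0:9, rep(c("nonoutlier", "outlier"), c(6, 4)))
  same <- evaluate_labels(t4, t4)
  expect_equal(same$correct_nonoutlier_pct, 100)
  expect_equal(same$false_nonoutlier_pct, 0)
  expect_equal(same$correct_outlier_pct, 100)
  expect_equal(same$false_outlier_pct, 0)

  # flag 2 of the 4 true outliers and nothing else
  half <- outlier_labels(0:9, rep(c("nonoutlier", "significant_outlier",
                                    "nonoutlier"), c(6, 2, 2)))
  m <- evaluate_labels(half, t4)
  expect_equal(m$correct_outlier_pct, 50)
  expect_equal(m$false_outlier_pct, 0)
  expect_equal(m$n_missed, 2L)

  # flag nothing at all
  none <- outlier_labels(0:9, rep("nonoutlier", 10))
  expect_equal(evaluate_labels(none, t4)$correct_outlier_pct, 0)
  # no true outliers: outlier percentages are undefined
  expect_true(is.na(evaluate_labels(none, none)$correct_outlier_pct))

  expect_error(evaluate_labels(outlier_labels(0:3, rep("nonoutlier", 4)), t4),
               "differ")
})

test_that("the validation suite covers the grid and behaves on clean data", {
  res <- run_validation_suite(sizes = 10, reps = 2, seed = 5,
                              outlier_fraction = 0)
  expect_identical(nrow(res), 6L)  # 3 trends x 2 modes
  expect_true(all(res$correct_nonoutlier_pct == 100))
  expect_true(all(res$false_outlier_pct == 0 | is.na(res$false_outlier_pct)))
  expect_true(all(is.na(res$correct_outlier_pct)))

  # contaminated case at a comfortable size: perfect detection
  res <- run_validation_suite(sizes = 100, reps = 2, seed = 11,
                              modes = "non_gaussian")
  expect_true(all(res$correct_outlier_pct == 100))
  expect_true(all(res$false_outlier_pct == 0))
})

test_that("generator guards against impossible specifications", {
  expect_error(make_series(simulation_spec(n = 4, outlier_fraction = 0.75)),
               "fewer than 3 clean")
  expect_error(simulation_spec(n = 10, outlier_fraction = 1), "outlier_fraction")
  expect_error(simulation_spec(n = 10, trend = "constant", intercept = 0),
               "nonzero intercept")
})
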