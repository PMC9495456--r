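# Dice similarity: closed-form cases, symmetry, the global vs per-case
# divergence, and the empty-mask conventions.

test_that("dice matches direct evaluation and conventions", {
  a <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  b <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3)
  expect_equal(dice(a, b), 0.5)   # |A|=4, |B|=4, overlap 2
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, 1 - a), 0)
  z <- matrix(0, 2, 3)
  expect_equal(dice(z, z), 1)     # both empty: perfect agreement
  expect_equal(dice(a, z), 0)     # exactly one empty
  expect_error(dice(a, matrix(0, 3, 3)), "extent")
})

test_that("dice is symmetric and 1 - dice behaves like a distance on fixtures", {
  set.seed(61)
  ms <- replicate(6, disc_mask(32, runif(2, 8, 24), runif(1, 3, 9)),
                  simplify = FALSE)
  for (i in 1:5) {
    expect_equal(dice(ms[[i]], ms[[i + 1]]), dice(ms[[i + 1]], ms[[i]]))
  }
  # empirical triangle inequality for 1 - dice on this fixture family
  for (i in 1:4) {
    d_ab <- 1 - dice(ms[[i]], ms[[i + 1]])
    d_bc <- 1 - dice(ms[[i + 1]], ms[[i + 2]])
    d_ac <- 1 - dice(ms[[i]], ms[[i + 2]])
    expect_lte(d_ac, d_ab + d_bc + 1e-12)
  }
})

test_that("global and per-case dice diverge as the pooled counts dictate", {
  m <- array(0, c(2, 8, 8)); m[, 2:5, 2:5] <- 1
  perfect <- m
  wrong <- array(0, c(2, 8, 8)); wrong[, 6:8, 6:8] <- 1  # equal-ish mass, no overlap
  rep_ <- evaluate_volumes(list(a = perfect, b = wrong),
                           list(a = m, b = m))
  expect_equal(rep_$per_case$dice, c(1, 0))
  expect_equal(rep_$per_case_mean, 0.5)
  inter <- sum(perfect & m)
  tot <- sum(perfect) + sum(wrong) + 2 * sum(m)
  expect_equal(rep_$global_dice, 2 * inter / tot)
  # identical predictions: both views are exactly 1
  rep2 <- evaluate_volumes(list(a = m), list(a = m))
  expect_equal(rep2$global_dice, 1)
  expect_equal(rep2$per_case_mean, 1)
  expect_error(evaluate_volumes(list(), list()), "no predictions")
  expect_error(evaluate_volumes(list(a = m), list(b = m)), "ids")
})

test_that("global equals per-case mean for equal-size equal-score volumes", {
  set.seed(62)
  g <- array(0, c(2, 10, 10)); g[, 3:6, 3:6] <- 1
  p <- g; p[1, 3, 3:4] <- 0  # same error pattern in both volumes
  p2 <- g; p2[1, 3, 3:4] <- 0
  rep_ <- evaluate_volumes(list(a = p, b = p2), list(a = g, b = g))
  expect_equal(rep_$global_dice, rep_$per_case_mean)
})

test_that("predictions at working resolution are upsampled before scoring", {
  gt <- array(0, c(1, 64, 64)); gt[1, 17:48, 17:48] <- 1
  pred <- array(0, c(1, 32, 32)); pred[1, 9:24, 9:24] <- 1
  rep_ <- evaluate_volumes(list(v = pred), list(v = gt))
  expect_gt(rep_$global_dice, 0.9)
})

test_that("dice reports serialize to a table and a JSON summary", {
  m <- array(0, c(1, 4, 4)); m[1, 1:2, 1:2] <- 1
  rep_ <- evaluate_volumes(list(a = m), list(a = m))
  d <- withr::local_tempdir()
  paths <- write_dice_report(rep_, d)
  tb <- read.delim(paths[1])
  expect_equal(tb$dice, 1)
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$global_dice, 1)
})
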