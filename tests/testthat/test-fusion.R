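# Weighted decision fusion: the voting semantics, its monotonicity, BCE
# weight training, and the error-overlap diagnostic.

test_that("equal weights under the threshold rule vote 2-of-4 (exhaustive)", {
  pats <- as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))
  for (r in seq_len(nrow(pats))) {
    masks <- lapply(pats[r, ], function(v) matrix(v, 1, 1))
    fused <- fuse(masks, rep(0.25, 4))
    expect_equal(fused[1, 1], as.numeric(sum(pats[r, ]) >= 2),
                 info = paste(pats[r, ], collapse = ""))
  }
})

test_that("the literal sigmoid-round rule fires on any single positive vote", {
  masks <- list(matrix(1, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1),
                matrix(0, 1, 1))
  expect_equal(fuse(masks, rep(0.25, 4), rule = "sigmoid_round")[1, 1], 1)
  expect_equal(fuse(masks, rep(0.25, 4), rule = "threshold")[1, 1], 0)
  zero <- lapply(1:4, function(i) matrix(0, 1, 1))
  expect_equal(fuse(zero, rep(0.25, 4), rule = "sigmoid_round")[1, 1], 0)
})

test_that("fusion is monotone in each candidate for nonnegative weights", {
  set.seed(71)
  for (i in 1:20) {
    w <- runif(4)
    masks <- replicate(4, matrix(rbinom(16, 1, 0.5), 4, 4),
                       simplify = FALSE)
    base <- fuse(masks, w)
    k <- sample(4, 1)
    zeros <- which(masks[[k]] == 0)
    if (length(zeros) == 0) next
    flip <- sample(zeros, 1)
    masks[[k]][flip] <- 1
    up <- fuse(masks, w)
    expect_true(all(up >= base))
  }
})

test_that("candidate extent mismatches are rejected", {
  masks <- c(replicate(3, matrix(0, 4, 4), simplify = FALSE),
             list(matrix(0, 5, 4)))
  expect_error(fuse(masks, rep(0.25, 4)), "extents")
})

test_that("training on identical candidates preserves weight symmetry", {
  set.seed(72)
  m <- disc_mask(24, c(12, 12), 7)
  gt <- m; on <- which(m == 1); gt[sample(on, 20)] <- 0
  samples <- rep(list(list(m, m, m, m)), 96)
  fw <- train_fusion_weights(samples, rep(list(gt), 96), seed = 5)
  # exact gradient symmetry: equality holds at every recorded epoch
  for (h in fw$history) expect_equal(diff(range(h)), 0)
  expect_equal(fw$scaled, rep(0.25, 4))
})

test_that("a flat objective returns the initial weights with a warning", {
  z <- matrix(0, 4, 4)
  samples <- rep(list(list(z, z, z, z)), 3)
  expect_warning(fw <- train_fusion_weights(samples, rep(list(z), 3)),
                 "flat")
  expect_equal(fw$w, rep(0.25, 4))
})

test_that("a clearly worse network receives the strictly smallest weight", {
  set.seed(73)
  gt0 <- disc_mask(48, c(24, 22), 11)
  rates <- c(0.05, 0.30, 0.05, 0.05)
  samples <- lapply(1:16, function(k) {
    lapply(rates, function(r) {
      flip <- matrix(runif(48 * 48) < r, 48)
      out <- gt0; out[flip] <- 1 - out[flip]; out
    })
  })
  fw <- train_fusion_weights(samples, rep(list(gt0), 16), seed = 9)
  expect_equal(which.min(fw$w), 2L)
  expect_true(all(fw$w[-2] > fw$w[2]))
})

test_that("fusion weights round-trip through their table form", {
  fw <- liverseg:::new_fusion_weights(c(0.3, 0.1, 0.35, 0.25), list())
  p <- withr::local_tempfile(fileext = ".tsv")
  write_fusion_weights(fw, p)
  back <- read_fusion_weights(p)
  expect_equal(back$w, fw$w, tolerance = 1e-12)
  expect_equal(back$network_ids, fusion_network_ids)
})

test_that("error-overlap matrix follows the pooled error-set Dice", {
  g <- disc_mask(16, c(8, 8), 4)
  same <- g * 0; same[1:2, 1:2] <- 1          # error block A
  other <- g * 0; other[10:12, 10:12] <- 1    # disjoint error block B
  p_same1 <- abs(g - same); p_same2 <- abs(g - same)
  p_other <- abs(g - other)
  per_net <- list(list(p_same1), list(p_same2), list(p_other), list(g))
  M <- error_overlap_matrix(per_net, list(g))
  expect_equal(M[1, 2], 1)      # identical error sets
  expect_equal(M[1, 3], 0)      # disjoint error sets
  expect_equal(M[4, 4], 0)      # error-free model: empty-set convention
  expect_equal(M[1, 4], 0)
  expect_equal(M[1, 1], 1)
  expect_equal(M, t(M))
})
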