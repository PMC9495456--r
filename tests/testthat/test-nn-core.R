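# The tensor engine under the networks: convolution against a direct
# nested-loop oracle, pooling, resizing, and gradient correctness by
# finite differences.

test_that("GEMM convolution matches the direct oracle across geometries", {
  set.seed(11)
  x <- rand_arr(7, 9, 3)
  w <- rand_arr(3, 3, 3, 4)
  b <- rnorm(4)
  for (stride in 1:2) for (dil in 1:2) for (pad in 0:2) {
    got <- liverseg:::conv2d_fwd(x, w, b, stride, dil, pad, 1L)$out
    want <- naive_conv2d(x, w, b, stride, dil, pad)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # asymmetric kernels and pads (the inception factorizations)
  w17 <- rand_arr(1, 7, 3, 2)
  got <- liverseg:::conv2d_fwd(x, w17, NULL, 1L, 1L, c(0L, 3L), 1L)$out
  expect_equal(got, naive_conv2d(x, w17, NULL, pad = c(0L, 3L)),
               tolerance = 1e-12)
})

test_that("grouped convolution equals per-group dense convolutions", {
  set.seed(12)
  x <- rand_arr(6, 6, 4)
  w <- rand_arr(3, 3, 2, 6)   # 2 groups: 2 in / 3 out channels each
  got <- liverseg:::conv2d_fwd(x, w, NULL, 1L, 1L, 1L, 2L)$out
  w1 <- w[, , , 1:3, drop = FALSE]
  w2 <- w[, , , 4:6, drop = FALSE]
  want1 <- naive_conv2d(x[, , 1:2, drop = FALSE], w1, pad = 1L)
  want2 <- naive_conv2d(x[, , 3:4, drop = FALSE], w2, pad = 1L)
  expect_equal(got[, , 1:3], want1, tolerance = 1e-12)
  expect_equal(got[, , 4:6], want2, tolerance = 1e-12)
})

test_that("parameter and input gradients agree with finite differences", {
  set.seed(13)
  x <- liverseg:::ag_param(rand_arr(6, 8, 2))
  w1 <- liverseg:::ag_param(rand_arr(3, 3, 2, 3))
  w2 <- liverseg:::ag_param(rand_arr(1, 1, 3, 1))
  gmm <- liverseg:::ag_param(rep(1, 3))
  bt <- liverseg:::ag_param(numeric(3))
  target <- array(rbinom(6 * 8, 1, 0.5), c(6, 8, 1))
  fwd <- function() {
    y <- liverseg:::ag_conv2d(x, w1, NULL, stride = 1L, pad = "same")
    y <- liverseg:::ag_bn(y, gmm, bt, rep(0.1, 3), rep(0.9, 3))
    y <- liverseg:::ag_relu(y)
    y <- liverseg:::ag_pool(y, 2L, 2L, 0L, "max")
    y <- liverseg:::ag_bilinear(y, 6L, 8L)
    y <- liverseg:::ag_conv2d(y, w2, NULL)
    liverseg:::ag_bce_with_logits(y, target)
  }
  loss <- fwd()
  liverseg:::backprop(loss)
  eps <- 1e-6
  for (p in list(x, w1, w2, gmm, bt)) {
    for (idx in unique(pmin(c(1L, 3L, length(p$v)), length(p$v)))) {
      old <- p$v[idx]
      p$v[idx] <- old + eps; up <- fwd()$v
      p$v[idx] <- old - eps; dn <- fwd()$v
      p$v[idx] <- old
      expect_equal(p$grad[idx], (up - dn) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("average pooling and global pooling match direct computation", {
  set.seed(14)
  x <- rand_arr(4, 4, 2)
  got <- liverseg:::node_value(liverseg:::ag_pool(liverseg:::ag_const(x), 2L, 2L, 0L,
                                       "avg"))
  expect_equal(got[1, 1, 1], mean(x[1:2, 1:2, 1]))
  expect_equal(got[2, 2, 2], mean(x[3:4, 3:4, 2]))
  g <- liverseg:::node_value(liverseg:::ag_gap(liverseg:::ag_const(x)))
  expect_equal(as.vector(g), c(mean(x[, , 1]), mean(x[, , 2])))
})

test_that("bilinear resize is linear-consistent and cross-checks EBImage", {
  set.seed(15)
  x <- matrix(runif(64 * 64), 64, 64)
  got <- liverseg:::resize_rect(x, 32, 32)
  ref <- as.matrix(EBImage::resize(x, w = 32, h = 32))
  expect_lt(max(abs(got - ref)), 1e-8)
  # constancy is preserved exactly
  const <- matrix(0.37, 50, 50)
  expect_equal(resize_image(const, 21), matrix(0.37, 21, 21),
               tolerance = 1e-12)
})
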