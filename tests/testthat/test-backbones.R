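# Block-level equation oracles for the four families, the convolution
# cost identities, and backbone geometry at reduced scale (full-size
# geometry is exercised in the acceptance suite).

test_that("residual bottleneck block matches its closed form", {
  set.seed(21)
  x <- rand_arr(5, 5, 4)
  # zero parameters: the transform vanishes and the block is ReLU
  zero <- list(w1 = array(0, c(1, 1, 4, 2)), w2 = array(0, c(3, 3, 2, 2)),
               w3 = array(0, c(1, 1, 2, 4)))
  expect_equal(resnet_block_forward(x, zero), pmax(x, 0))
  # nonnegative input + zero parameters: exact identity
  xp <- abs(x)
  expect_equal(resnet_block_forward(xp, zero), xp)
  # random instance against a direct evaluation of the formula
  p <- rand_bottleneck_params(4, 2)
  got <- resnet_block_forward(x, p)
  y <- pmax(naive_conv2d(x, p$w1, p$b1), 0)
  y <- pmax(naive_conv2d(y, p$w2, p$b2, pad = 1L), 0)
  want <- pmax(x + naive_conv2d(y, p$w3, p$b3), 0)
  expect_equal(got, want, tolerance = 1e-12)
  # mismatched transform output is rejected
  bad <- rand_bottleneck_params(4, 2)
  bad$w3 <- rand_arr(1, 1, 2, 3)
  bad$b3 <- rnorm(3)
  expect_error(resnet_block_forward(x, bad), "different shapes")
})

test_that("aggregated-transform block sums its 32 paths onto the residual", {
  set.seed(22)
  x <- rand_arr(4, 4, 4)
  zero <- replicate(32, list(w1 = array(0, c(1, 1, 4, 2)),
                             w2 = array(0, c(3, 3, 2, 2)),
                             w3 = array(0, c(1, 1, 2, 4))),
                    simplify = FALSE)
  expect_equal(resnext_block_forward(x, zero), pmax(x, 0))
  expect_error(resnext_block_forward(x, zero[1:8]), "32")
  # identical parameters on every path: 32 x the single-path transform
  p <- rand_bottleneck_params(4, 2)
  shared <- replicate(32, p, simplify = FALSE)
  y <- pmax(naive_conv2d(x, p$w1, p$b1), 0)
  y <- pmax(naive_conv2d(y, p$w2, p$b2, pad = 1L), 0)
  single <- naive_conv2d(y, p$w3, p$b3)
  expect_equal(resnext_block_forward(x, shared), pmax(x + 32 * single, 0),
               tolerance = 1e-10)
  # distinct random paths against direct evaluation
  paths <- replicate(32, rand_bottleneck_params(4, 2), simplify = FALSE)
  acc <- array(0, dim(x))
  for (q in paths) {
    y <- pmax(naive_conv2d(x, q$w1, q$b1), 0)
    y <- pmax(naive_conv2d(y, q$w2, q$b2, pad = 1L), 0)
    acc <- acc + naive_conv2d(y, q$w3, q$b3)
  }
  expect_equal(resnext_block_forward(x, paths), pmax(x + acc, 0),
               tolerance = 1e-10)
})

test_that("dense block concatenation follows the layer recursion", {
  set.seed(23)
  g <- 3L  # growth
  x <- rand_arr(4, 4, 2)
  mk_layer <- function(cin) list(w1 = rand_arr(1, 1, cin, 4),
                                 b1 = rnorm(4),
                                 w2 = rand_arr(3, 3, 4, g), b2 = rnorm(g))
  # strict mode: layer i consumes [Z1..Z_{i-1}] only
  p_strict <- list(mk_layer(2), mk_layer(g), mk_layer(2 * g), mk_layer(3 * g))
  f <- function(inp, q) {
    naive_conv2d(pmax(naive_conv2d(pmax(inp, 0), q$w1, q$b1), 0),
                 q$w2, q$b2, pad = 1L)
  }
  cat3 <- function(xs) array(unlist(xs), c(4, 4, sum(sapply(xs, function(a) dim(a)[3]))))
  z1 <- f(x, p_strict[[1]]); z2 <- f(z1, p_strict[[2]])
  z3 <- f(cat3(list(z1, z2)), p_strict[[3]])
  z4 <- f(cat3(list(z1, z2, z3)), p_strict[[4]])
  expect_equal(dense_block_forward(x, p_strict, mode = "strict"),
               cat3(list(z1, z2, z3, z4)), tolerance = 1e-12)
  # standard mode: input included; channel arithmetic c + 4 g
  p_std <- list(mk_layer(2), mk_layer(2 + g), mk_layer(2 + 2 * g),
                mk_layer(2 + 3 * g))
  out <- dense_block_forward(x, p_std, mode = "standard")
  expect_equal(dim(out)[3], 2 + 4 * g)
  expect_equal(out[, , 1:2], x)
  # zero parameters: all appended channels vanish
  p_zero <- lapply(c(2, 2 + g, 2 + 2 * g, 2 + 3 * g), function(cin) {
    list(w1 = array(0, c(1, 1, cin, 4)), w2 = array(0, c(3, 3, 4, g)))
  })
  out0 <- dense_block_forward(x, p_zero, mode = "standard")
  expect_true(all(out0[, , -(1:2)] == 0))
})

test_that("factorized inception block concatenates its four paths", {
  set.seed(24)
  x <- rand_arr(5, 5, 3)
  n <- 3L
  p <- list(w1 = rand_arr(1, 1, 3, 2), b1 = rnorm(2),
            w2 = rand_arr(1, 1, 3, 2), b2 = rnorm(2),
            w3 = rand_arr(1, 1, 3, 2), b3 = rnorm(2),
            w4 = rand_arr(n, 1, 2, 2), b4 = rnorm(2),
            w5 = rand_arr(1, n, 2, 2), b5 = rnorm(2),
            w6 = rand_arr(1, 1, 3, 2), b6 = rnorm(2),
            w7 = rand_arr(n, 1, 2, 2), b7 = rnorm(2),
            w8 = rand_arr(1, n, 2, 2), b8 = rnorm(2),
            w9 = rand_arr(n, 1, 2, 2), b9 = rnorm(2),
            w10 = rand_arr(1, n, 2, 2), b10 = rnorm(2))
  got <- inception_block_forward(x, p)
  expect_equal(dim(got)[3], 8)  # sum of the four path widths
  # direct evaluation
  z1 <- naive_conv2d(x, p$w1, p$b1)
  pool <- liverseg:::pool_fwd(x, 3L, 1L, 1L, "max")$out
  z2 <- naive_conv2d(pool, p$w2, p$b2)
  z3 <- naive_conv2d(naive_conv2d(naive_conv2d(x, p$w3, p$b3),
                                  p$w4, p$b4, pad = c(1L, 0L)),
                     p$w5, p$b5, pad = c(0L, 1L))
  z4 <- naive_conv2d(x, p$w6, p$b6)
  z4 <- naive_conv2d(z4, p$w7, p$b7, pad = c(1L, 0L))
  z4 <- naive_conv2d(z4, p$w8, p$b8, pad = c(0L, 1L))
  z4 <- naive_conv2d(z4, p$w9, p$b9, pad = c(1L, 0L))
  z4 <- naive_conv2d(z4, p$w10, p$b10, pad = c(0L, 1L))
  want <- array(c(z1, z2, z3, z4), c(5, 5, 8))
  expect_equal(got, want, tolerance = 1e-12)
  # zero parameters, zero biases: every path output vanishes
  p0 <- lapply(p, function(a) a * 0)
  expect_true(all(inception_block_forward(x, p0) == 0))
})

test_that("convolution cost identities hold", {
  expect_equal(conv_cost(1, 1), 1)
  expect_equal(conv_cost(5, 5) / conv_cost(3, 3), 25 / 9)
  expect_equal(round(conv_cost(5, 5) / conv_cost(3, 3), 2), 2.78)
  saving <- (conv_cost(3, 3) - (conv_cost(3, 1) + conv_cost(1, 3))) /
    conv_cost(3, 3)
  expect_equal(saving, 1 / 3)
})

test_that("tiny backbones honour the output-stride-8 extent contract", {
  set.seed(25)
  for (fam in c("resnet152", "resnext101", "densenet201", "inceptionv3")) {
    bb <- build_backbone(fam, tiny = TRUE)
    for (side in c(32L, 64L)) {
      f <- backbone_forward(bb, matrix(runif(side * side), side, side))
      expect_equal(dim(f)[1:2], rep(ceiling(side / 8), 2L),
                   info = paste(fam, side))
    }
    expect_equal(dim(f)[3], bb$out_channels)
  }
})

test_that("full-size adapted backbones emit ceiling(side / 8) maps at side 128", {
  set.seed(26)
  img <- matrix(runif(128 * 128), 128, 128)
  for (fam in c("resnet152", "resnext101", "densenet201", "inceptionv3")) {
    bb <- build_backbone(fam, output_stride = 8L)
    f <- backbone_forward(bb, img)
    expect_equal(dim(f)[1:2], c(16L, 16L), info = fam)
    expect_equal(dim(f)[3], bb$out_channels, info = fam)
    rm(bb, f); gc(FALSE)
  }
})
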