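# The four feature-extractor families and their single-channel /
# output-stride adaptations, plus the closed-form block operations used
# to pin each family's defining computation against a direct oracle.
#
# Equation-form block operations below take plain arrays (rows x cols x
# channels) and explicit parameter lists; batch normalization is absent
# here by construction (it enters only the built networks).

raw_conv <- function(x, w, b = NULL, pad = "same", stride = 1L, dilation = 1L,
                     groups = 1L) {
  conv2d_fwd(x, w, b, stride, dilation, pad, groups)$out
}

#' Residual bottleneck block, closed form
#'
#' `Y = ReLU(X + W3 * ReLU(W2 * ReLU(W1 * X + B1) + B2) + B3)` with the
#' 1x1 / 3x3 / 1x1 kernel schema; the identity path is untouched, so the
#' output and input channel counts must agree.
#'
#' @param x input array (rows x cols x channels).
#' @param p list with `w1, w2, w3` kernel arrays and optional `b1, b2, b3`.
#' @return output array of the same extent as `x`.
#' @export
resnet_block_forward <- function(x, p) {
  y <- ag_relu_arr(raw_conv(x, p$w1, p$b1))
  y <- ag_relu_arr(raw_conv(y, p$w2, p$b2))
  y <- raw_conv(y, p$w3, p$b3)
  if (!all(dim(y) == dim(x))) {
    stop("residual path and transform output have different shapes")
  }
  pmax(x + y, 0)
}

ag_relu_arr <- function(x) pmax(x, 0)

#' Aggregated-transform residual block (cardinality 32), closed form
#'
#' `Y = ReLU(X + sum_i T_i(X))` where each of the 32 paths applies the
#' three-layer bottleneck transform with its own parameters.
#'
#' @param x input array.
#' @param paths list of 32 parameter lists shaped as in
#'   [resnet_block_forward()] (without the final ReLU).
#' @param cardinality expected number of paths.
#' @return output array of the same extent as `x`.
#' @export
resnext_block_forward <- function(x, paths, cardinality = 32L) {
  if (length(paths) != cardinality) {
    stop("expected ", cardinality, " paths, got ", length(paths))
  }
  acc <- array(0, dim(x))
  for (p in paths) {
    y <- ag_relu_arr(raw_conv(x, p$w1, p$b1))
    y <- ag_relu_arr(raw_conv(y, p$w2, p$b2))
    acc <- acc + raw_conv(y, p$w3, p$b3)
  }
  pmax(x + acc, 0)
}

#' Four-layer dense block, closed form
#'
#' Each layer computes `F_i(X) = W_i2 * ReLU(W_i1 * ReLU(X) + B_i1) + B_i2`
#' on the concatenation of all earlier layer outputs. In `"standard"` mode
#' the block input is part of the concatenations and of the output (the
#' form whose channel arithmetic yields the documented 1920 channels for
#' the 201-layer network); `"strict"` mode concatenates the layer outputs
#' only.
#'
#' @param x input array.
#' @param p list of 4 layer parameter lists (`w1, b1, w2, b2`).
#' @param mode `"standard"` or `"strict"`.
#' @return concatenated output array.
#' @export
dense_block_forward <- function(x, p, mode = c("standard", "strict")) {
  mode <- match.arg(mode)
  f <- function(inp, q) {
    raw_conv(ag_relu_arr(raw_conv(pmax(inp, 0), q$w1, q$b1)), q$w2, q$b2)
  }
  cat3 <- function(xs) {
    d <- dim(xs[[1L]])
    array(unlist(xs, use.names = FALSE),
          c(d[1L], d[2L], sum(vapply(xs, function(a) dim(a)[3L], numeric(1)))))
  }
  zs <- list()
  for (i in seq_len(4L)) {
    inp <- if (mode == "standard") cat3(c(list(x), zs)) else {
      if (i == 1L) x else cat3(zs)
    }
    zs[[i]] <- f(inp, p[[i]])
  }
  if (mode == "standard") cat3(c(list(x), zs)) else cat3(zs)
}

#' Four-path factorized inception block, closed form
#'
#' Paths: 1x1; 3x3 max-pool then 1x1; 1x1 -> n x 1 -> 1 x n; and
#' 1x1 followed by two n x 1 / 1 x n pairs. Outputs are concatenated
#' channel-wise; all convolutions are zero-padded to preserve extent.
#'
#' @param x input array.
#' @param p list with kernels `w1..w10` and optional biases `b1..b10`
#'   matching the path schema.
#' @return concatenated output array.
#' @export
inception_block_forward <- function(x, p) {
  z1 <- raw_conv(x, p$w1, p$b1)
  pool <- pool_fwd(x, 3L, 1L, 1L, "max")$out
  z2 <- raw_conv(pool, p$w2, p$b2)
  z3 <- raw_conv(raw_conv(raw_conv(x, p$w3, p$b3), p$w4, p$b4), p$w5, p$b5)
  z4 <- x
  for (k in 6:10) z4 <- raw_conv(z4, p[[paste0("w", k)]], p[[paste0("b", k)]])
  zs <- list(z1, z2, z3, z4)
  d <- dim(z1)
  if (!all(vapply(zs, function(z) all(dim(z)[1:2] == d[1:2]), logical(1)))) {
    stop("inception paths produced differing spatial extents")
  }
  array(unlist(zs, use.names = FALSE),
        c(d[1L], d[2L], sum(vapply(zs, function(z) dim(z)[3L], numeric(1)))))
}

#' Relative multiply cost of a convolution kernel
#'
#' Multiplications per output element per input/output channel pair, i.e.
#' simply `kernel_rows * kernel_cols`; the basis for the 5x5-vs-3x3 cost
#' ratio (25/9 = 2.78) and the asymmetric-factorization saving
#' (1 - (3 + 3)/9 = 1/3).
#'
#' @param kernel_rows,kernel_cols positive kernel extents.
#' @return relative multiply count.
#' @export
conv_cost <- function(kernel_rows, kernel_cols) {
  stopifnot(kernel_rows >= 1, kernel_cols >= 1)
  kernel_rows * kernel_cols
}

# ---- builders -----------------------------------------------------------

resnet_stage <- function(cin, planes, nblocks, stride, dilation, groups,
                         width_mult, expansion) {
  width <- planes * width_mult
  cout <- planes * expansion
  blocks <- vector("list", nblocks)
  blocks[[1L]] <- m_bottleneck(cin, width, cout, stride = stride,
                               dilation = dilation, groups = groups)
  for (i in seq_len(nblocks - 1L)) {
    blocks[[i + 1L]] <- m_bottleneck(cout, width, cout, stride = 1L,
                                     dilation = dilation, groups = groups)
  }
  list(mod = m_seq(blocks), cout = cout)
}

build_residual_backbone <- function(counts, planes, groups, width_mult,
                                    expansion, stem_ch, in_channels,
                                    output_stride) {
  if (output_stride == 8L) {
    strides <- c(1L, 2L, 1L, 1L); dils <- c(1L, 1L, 2L, 4L)
  } else {
    strides <- c(1L, 2L, 2L, 2L); dils <- c(1L, 1L, 1L, 1L)
  }
  stem <- m_seq(
    m_conv(in_channels, stem_ch, 7L, stride = 2L, pad = c(3L, 3L), bias = FALSE),
    m_bn(stem_ch), m_relu(), m_maxpool(3L, 2L, 1L))
  mods <- list(stem)
  cin <- stem_ch
  for (s in seq_len(4L)) {
    st <- resnet_stage(cin, planes[s], counts[s], strides[s], dils[s],
                       groups, width_mult, expansion)
    mods[[length(mods) + 1L]] <- st$mod
    cin <- st$cout
  }
  list(net = m_seq(mods), out_channels = cin)
}

build_densenet <- function(counts, growth, init_ch, in_channels,
                           output_stride) {
  stem <- m_seq(
    m_conv(in_channels, init_ch, 7L, stride = 2L, pad = c(3L, 3L), bias = FALSE),
    m_bn(init_ch), m_relu(), m_maxpool(3L, 2L, 1L))
  mods <- list(stem)
  cin <- init_ch
  for (b in seq_along(counts)) {
    blk <- m_denseblock(cin, counts[b], growth)
    mods[[length(mods) + 1L]] <- blk
    cin <- blk$cout
    if (b < length(counts)) {
      pool <- if (output_stride == 8L) (b == 1L) else TRUE
      cout <- cin %/% 2L
      mods[[length(mods) + 1L]] <- m_transition(cin, cout, pool = pool)
      cin <- cout
    }
  }
  mods[[length(mods) + 1L]] <- m_seq(m_bn(cin), m_relu())
  list(net = m_seq(mods), out_channels = cin)
}

#' Build the convolutional stem of the InceptionV3 extractor
#'
#' The canonical variant is the five-convolution sequence with max pooling
#' after the third and fifth convolutions (valid padding); it emits
#' 192-channel features, 35x35 at the architecture's native 299x299 input.
#' The adapted variant drops both max-pool layers and zero-pads all
#' convolutions so only the first (stride-2) convolution reduces extent.
#'
#' @param in_channels stem input channels (1 for CT slices).
#' @param variant `"canonical"` or `"adapted"`.
#' @return a module; forward it with [forward()].
#' @export
build_inception_stem <- function(in_channels = 1L,
                                 variant = c("canonical", "adapted")) {
  variant <- match.arg(variant)
  if (variant == "canonical") {
    m_seq(
      m_cbr(in_channels, 32L, 3L, stride = 2L, pad = c(0L, 0L)),
      m_cbr(32L, 32L, 3L, pad = c(0L, 0L)),
      m_cbr(32L, 64L, 3L, pad = c(1L, 1L)),
      m_maxpool(3L, 2L, 0L),
      m_cbr(64L, 80L, 1L),
      m_cbr(80L, 192L, 3L, pad = c(0L, 0L)),
      m_maxpool(3L, 2L, 0L))
  } else {
    m_seq(
      m_cbr(in_channels, 32L, 3L, stride = 2L, pad = "same"),
      m_cbr(32L, 32L, 3L, pad = "same"),
      m_cbr(32L, 64L, 3L, pad = "same"),
      m_cbr(64L, 80L, 1L),
      m_cbr(80L, 192L, 3L, pad = "same"))
  }
}

build_inception <- function(in_channels, output_stride, tiny = FALSE) {
  adapted <- output_stride == 8L
  pm <- if (adapted) "same" else "valid"
  stem <- build_inception_stem(in_channels,
                               if (adapted) "adapted" else "canonical")
  if (tiny) {
    mods <- list(stem, m_inc_a(192L, 32L), m_inc_b(256L, pm),
                 m_inc_c(736L, 128L), m_inc_d(768L, pm))
    return(list(net = m_seq(mods), out_channels = 1280L))
  }
  mods <- list(
    stem,
    m_inc_a(192L, 32L), m_inc_a(256L, 64L), m_inc_a(288L, 64L),
    m_inc_b(288L, pm),
    m_inc_c(768L, 128L), m_inc_c(768L, 160L), m_inc_c(768L, 160L),
    m_inc_c(768L, 192L),
    m_inc_d(768L, pm),
    m_inc_e(1280L), m_inc_e(2048L))
  list(net = m_seq(mods), out_channels = 2048L)
}

#' Build a feature-extraction backbone
#'
#' Constructs one of the four supported families as a single-channel
#' feature extractor with the classification head absent. At
#' `output_stride = 8` (the system's operating point) the late stage
#' strides of the residual families are converted to dilation, the second
#' and third dense-family transitions drop their average pooling, and the
#' Inception stem loses its max-pool layers, so the in-plane output extent
#' is `ceiling(side / 8)`. `output_stride = 32` builds the canonical
#' (unmodified) geometry.
#'
#' Block counts: ResNet152 (3, 8, 36, 3); ResNeXt101-32x8d (3, 4, 23, 3)
#' with cardinality 32 and path width 8; DenseNet201 (6, 12, 48, 32)
#' dense layers with growth 32; InceptionV3 modules (3, 5, 2) over its
#' three designs. The `tiny` profile keeps each topology but shrinks block
#' counts and channel widths so training behavior is testable on one CPU.
#'
#' @param family one of `"resnet152"`, `"resnext101"`, `"densenet201"`,
#'   `"inceptionv3"`.
#' @param output_stride 8 (adapted) or 32 (canonical).
#' @param in_channels input image channels (default 1, grayscale CT).
#' @param tiny logical; build the reduced profile.
#' @return an object of class `ls_backbone` with elements `net`, `family`,
#'   `out_channels`, `output_stride`; forward it with [backbone_forward()].
#' @export
build_backbone <- function(family = c("resnet152", "resnext101",
                                      "densenet201", "inceptionv3"),
                           output_stride = 8L, in_channels = 1L,
                           tiny = FALSE) {
  family <- match.arg(family)
  stopifnot(output_stride %in% c(8L, 32L))
  built <- switch(family,
    resnet152 = {
      if (tiny) {
        build_residual_backbone(c(1L, 1L, 1L, 1L), c(4L, 8L, 16L, 32L),
                                groups = 1L, width_mult = 1L, expansion = 2L,
                                stem_ch = 8L, in_channels, output_stride)
      } else {
        build_residual_backbone(c(3L, 8L, 36L, 3L), c(64L, 128L, 256L, 512L),
                                groups = 1L, width_mult = 1L, expansion = 4L,
                                stem_ch = 64L, in_channels, output_stride)
      }
    },
    resnext101 = {
      if (tiny) {
        build_residual_backbone(c(1L, 1L, 1L, 1L), c(4L, 8L, 16L, 32L),
                                groups = 4L, width_mult = 2L, expansion = 2L,
                                stem_ch = 8L, in_channels, output_stride)
      } else {
        build_residual_backbone(c(3L, 4L, 23L, 3L), c(64L, 128L, 256L, 512L),
                                groups = 32L, width_mult = 4L, expansion = 4L,
                                stem_ch = 64L, in_channels, output_stride)
      }
    },
    densenet201 = {
      if (tiny) {
        build_densenet(c(2L, 2L, 2L, 2L), growth = 4L, init_ch = 8L,
                       in_channels = in_channels, output_stride = output_stride)
      } else {
        build_densenet(c(6L, 12L, 48L, 32L), growth = 32L, init_ch = 64L,
                       in_channels = in_channels, output_stride = output_stride)
      }
    },
    inceptionv3 = build_inception(in_channels, output_stride, tiny = tiny))
  structure(list(net = built$net, family = family,
                 out_channels = built$out_channels,
                 output_stride = as.integer(output_stride), tiny = tiny),
            class = "ls_backbone")
}

#' Forward an image through a backbone
#'
#' @param bb an `ls_backbone` from [build_backbone()].
#' @param img numeric matrix (single-channel image) or rows x cols x
#'   channels array, or an autograd node.
#' @param training logical, forwarded to the layers.
#' @return feature array (rows x cols x channels) when given a plain
#'   image; an autograd node when given a node.
#' @export
backbone_forward <- function(bb, img, training = FALSE) {
  if (is_ag_node(img)) return(forward(bb$net, img, training))
  x <- as_image_array(img)
  with_no_grad(node_value(forward(bb$net, ag_const(x), training)))
}

as_image_array <- function(img) {
  if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
}
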