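# Network building blocks. A module is a plain list with a class tag; its
# trainable parameters are `ag_param` nodes, so `collect_params()` can walk
# any nested module tree. `forward()` maps an input node to an output node.

#' Kaiming (He) normal initialization for a convolution kernel
#'
#' Draws `N(0, gain^2 / fan_in)` entries with the ReLU gain
#' `gain = sqrt(2)`; `fan_in = kh * kw * cin_per_group`.
#'
#' @param kh,kw kernel extents.
#' @param cin_g input channels per group.
#' @param cout output channels.
#' @return a `kh x kw x cin_g x cout` array.
#' @keywords internal
kaiming_weights <- function(kh, kw, cin_g, cout) {
  sd <- sqrt(2 / (kh * kw * cin_g))
  array(stats::rnorm(kh * kw * cin_g * cout, sd = sd), c(kh, kw, cin_g, cout))
}

new_module <- function(type, ...) {
  structure(list(...), class = c(paste0("ls_", type), "ls_module"))
}

#' @export
forward <- function(m, x, training = FALSE) UseMethod("forward")

m_conv <- function(cin, cout, k, stride = 1L, dilation = 1L, pad = "same",
                   groups = 1L, bias = TRUE) {
  k <- rep(as.integer(k), length.out = 2L)
  w <- ag_param(kaiming_weights(k[1L], k[2L], cin %/% groups, cout))
  b <- if (bias) ag_param(numeric(cout)) else NULL
  new_module("conv", w = w, b = b, stride = stride, dilation = dilation,
             pad = pad, groups = groups)
}

#' @export
forward.ls_conv <- function(m, x, training = FALSE) {
  ag_conv2d(x, m$w, m$b, stride = m$stride, dilation = m$dilation,
            pad = m$pad, groups = m$groups)
}

m_bn <- function(c) {
  new_module("bn", gamma = ag_param(rep(1, c)), beta = ag_param(numeric(c)),
             mean = numeric(c), var = rep(1, c))
}

#' @export
forward.ls_bn <- function(m, x, training = FALSE) {
  ag_bn(x, m$gamma, m$beta, m$mean, m$var)
}

m_relu <- function() new_module("relu")
#' @export
forward.ls_relu <- function(m, x, training = FALSE) ag_relu(x)

m_maxpool <- function(k, stride, pad = 0L) {
  new_module("maxpool", k = k, stride = stride, pad = pad)
}
#' @export
forward.ls_maxpool <- function(m, x, training = FALSE) {
  ag_pool(x, m$k, m$stride, m$pad, type = "max")
}

m_avgpool <- function(k, stride, pad = 0L) {
  new_module("avgpool", k = k, stride = stride, pad = pad)
}
#' @export
forward.ls_avgpool <- function(m, x, training = FALSE) {
  ag_pool(x, m$k, m$stride, m$pad, type = "avg")
}

m_seq <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1L]]) && !inherits(mods[[1L]], "ls_module")) {
    mods <- mods[[1L]]
  }
  new_module("seq", mods = mods)
}
#' @export
forward.ls_seq <- function(m, x, training = FALSE) {
  for (mod in m$mods) x <- forward(mod, x, training)
  x
}

# Conv-BatchNorm-ReLU block, the repeating unit of all four families
m_cbr <- function(cin, cout, k, stride = 1L, dilation = 1L, pad = "same",
                  groups = 1L) {
  m_seq(m_conv(cin, cout, k, stride, dilation, pad, groups, bias = FALSE),
        m_bn(cout), m_relu())
}

# ---- residual bottleneck (ResNet / ResNeXt) -----------------------------

m_bottleneck <- function(cin, width, cout, stride = 1L, dilation = 1L,
                         groups = 1L) {
  project <- (cin != cout) || (stride != 1L)
  new_module("bottleneck",
    conv1 = m_conv(cin, width, 1L, bias = FALSE), bn1 = m_bn(width),
    conv2 = m_conv(width, width, 3L, stride = stride, dilation = dilation,
                   pad = "same", groups = groups, bias = FALSE),
    bn2 = m_bn(width),
    conv3 = m_conv(width, cout, 1L, bias = FALSE), bn3 = m_bn(cout),
    down = if (project) {
      m_seq(m_conv(cin, cout, 1L, stride = stride, bias = FALSE), m_bn(cout))
    },
    stride = stride)
}

#' @export
forward.ls_bottleneck <- function(m, x, training = FALSE) {
  y <- ag_relu(forward(m$bn1, forward(m$conv1, x)))
  y <- ag_relu(forward(m$bn2, forward(m$conv2, y)))
  y <- forward(m$bn3, forward(m$conv3, y))
  res <- if (is.null(m$down)) x else forward(m$down, x, training)
  ag_relu(ag_add(res, y))
}

# ---- dense block (DenseNet) --------------------------------------------

m_denselayer <- function(cin, growth, bn_size = 4L) {
  new_module("denselayer",
    bn1 = m_bn(cin),
    conv1 = m_conv(cin, bn_size * growth, 1L, bias = FALSE),
    bn2 = m_bn(bn_size * growth),
    conv2 = m_conv(bn_size * growth, growth, 3L, pad = "same", bias = FALSE))
}

#' @export
forward.ls_denselayer <- function(m, x, training = FALSE) {
  y <- forward(m$conv1, ag_relu(forward(m$bn1, x)))
  forward(m$conv2, ag_relu(forward(m$bn2, y)))
}

m_denseblock <- function(cin, n, growth, bn_size = 4L) {
  layers <- vector("list", n)
  c_now <- cin
  for (i in seq_len(n)) {
    layers[[i]] <- m_denselayer(c_now, growth, bn_size)
    c_now <- c_now + growth
  }
  new_module("denseblock", layers = layers, cout = c_now)
}

#' @export
forward.ls_denseblock <- function(m, x, training = FALSE) {
  feat <- x
  for (l in m$layers) {
    feat <- ag_concat(list(feat, forward(l, feat, training)))
  }
  feat
}

m_transition <- function(cin, cout, pool = TRUE) {
  new_module("transition",
    bn = m_bn(cin), conv = m_conv(cin, cout, 1L, bias = FALSE), pool = pool)
}

#' @export
forward.ls_transition <- function(m, x, training = FALSE) {
  y <- forward(m$conv, ag_relu(forward(m$bn, x)))
  if (m$pool) ag_pool(y, 2L, 2L, 0L, type = "avg") else y
}

# ---- Inception modules --------------------------------------------------
# Faithful to the canonical V3 layout; `pad_mode` switches the grid
# reduction paths between valid padding (canonical) and 'same' padding
# (the adapted output-stride-8 configuration).

m_inc_a <- function(cin, pool_features) {
  new_module("inc_a",
    b1 = m_cbr(cin, 64L, 1L),
    b5 = m_seq(m_cbr(cin, 48L, 1L), m_cbr(48L, 64L, 5L, pad = c(2L, 2L))),
    b3d = m_seq(m_cbr(cin, 64L, 1L), m_cbr(64L, 96L, 3L, pad = c(1L, 1L)),
                m_cbr(96L, 96L, 3L, pad = c(1L, 1L))),
    bp = m_cbr(cin, pool_features, 1L))
}

#' @export
forward.ls_inc_a <- function(m, x, training = FALSE) {
  pool <- ag_pool(x, 3L, 1L, 1L, type = "avg")
  ag_concat(list(forward(m$b1, x, training), forward(m$b5, x, training),
                 forward(m$b3d, x, training), forward(m$bp, pool, training)))
}

m_inc_b <- function(cin, pad_mode = "valid") {
  p <- if (pad_mode == "same") "same" else 0L
  new_module("inc_b",
    b3 = m_cbr(cin, 384L, 3L, stride = 2L, pad = p),
    b3d = m_seq(m_cbr(cin, 64L, 1L), m_cbr(64L, 96L, 3L, pad = c(1L, 1L)),
                m_cbr(96L, 96L, 3L, stride = 2L, pad = p)),
    pool_pad = if (pad_mode == "same") "same" else 0L)
}

#' @export
forward.ls_inc_b <- function(m, x, training = FALSE) {
  pool <- ag_pool(x, 3L, 2L, m$pool_pad, type = "max")
  ag_concat(list(forward(m$b3, x, training), forward(m$b3d, x, training), pool))
}

m_inc_c <- function(cin, c7) {
  new_module("inc_c",
    b1 = m_cbr(cin, 192L, 1L),
    b7 = m_seq(m_cbr(cin, c7, 1L),
               m_cbr(c7, c7, c(1L, 7L), pad = c(0L, 3L)),
               m_cbr(c7, 192L, c(7L, 1L), pad = c(3L, 0L))),
    b7d = m_seq(m_cbr(cin, c7, 1L),
                m_cbr(c7, c7, c(7L, 1L), pad = c(3L, 0L)),
                m_cbr(c7, c7, c(1L, 7L), pad = c(0L, 3L)),
                m_cbr(c7, c7, c(7L, 1L), pad = c(3L, 0L)),
                m_cbr(c7, 192L, c(1L, 7L), pad = c(0L, 3L))),
    bp = m_cbr(cin, 192L, 1L))
}

#' @export
forward.ls_inc_c <- function(m, x, training = FALSE) {
  pool <- ag_pool(x, 3L, 1L, 1L, type = "avg")
  ag_concat(list(forward(m$b1, x, training), forward(m$b7, x, training),
                 forward(m$b7d, x, training), forward(m$bp, pool, training)))
}

m_inc_d <- function(cin, pad_mode = "valid") {
  p <- if (pad_mode == "same") "same" else 0L
  new_module("inc_d",
    b3 = m_seq(m_cbr(cin, 192L, 1L), m_cbr(192L, 320L, 3L, stride = 2L, pad = p)),
    b7x3 = m_seq(m_cbr(cin, 192L, 1L),
                 m_cbr(192L, 192L, c(1L, 7L), pad = c(0L, 3L)),
                 m_cbr(192L, 192L, c(7L, 1L), pad = c(3L, 0L)),
                 m_cbr(192L, 192L, 3L, stride = 2L, pad = p)),
    pool_pad = if (pad_mode == "same") "same" else 0L)
}

#' @export
forward.ls_inc_d <- function(m, x, training = FALSE) {
  pool <- ag_pool(x, 3L, 2L, m$pool_pad, type = "max")
  ag_concat(list(forward(m$b3, x, training), forward(m$b7x3, x, training), pool))
}

m_inc_e <- function(cin) {
  new_module("inc_e",
    b1 = m_cbr(cin, 320L, 1L),
    b3_stem = m_cbr(cin, 384L, 1L),
    b3_a = m_cbr(384L, 384L, c(1L, 3L), pad = c(0L, 1L)),
    b3_b = m_cbr(384L, 384L, c(3L, 1L), pad = c(1L, 0L)),
    b3d_stem = m_seq(m_cbr(cin, 448L, 1L), m_cbr(448L, 384L, 3L, pad = c(1L, 1L))),
    b3d_a = m_cbr(384L, 384L, c(1L, 3L), pad = c(0L, 1L)),
    b3d_b = m_cbr(384L, 384L, c(3L, 1L), pad = c(1L, 0L)),
    bp = m_cbr(cin, 192L, 1L))
}

#' @export
forward.ls_inc_e <- function(m, x, training = FALSE) {
  s <- forward(m$b3_stem, x, training)
  br3 <- ag_concat(list(forward(m$b3_a, s, training), forward(m$b3_b, s, training)))
  sd <- forward(m$b3d_stem, x, training)
  br3d <- ag_concat(list(forward(m$b3d_a, sd, training), forward(m$b3d_b, sd, training)))
  pool <- ag_pool(x, 3L, 1L, 1L, type = "avg")
  ag_concat(list(forward(m$b1, x, training), br3, br3d, forward(m$bp, pool, training)))
}
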