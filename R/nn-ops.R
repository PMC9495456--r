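# Differentiable tensor operations. Tensors are dense arrays laid out
# (rows, cols, channels); convolution is evaluated as a sum of per-tap
# GEMMs, which keeps peak memory at one (positions x channels) slab and
# lets BLAS carry the arithmetic.

# ---- geometry helpers ---------------------------------------------------

# Resolve padding/extent bookkeeping for one spatial axis.
conv_axis_geom <- function(n, k, stride, dilation, pad) {
  eff <- dilation * (k - 1L) + 1L
  if (identical(pad, "same")) {
    out <- ceiling(n / stride)
    total <- max(0L, (out - 1L) * stride + eff - n)
    beg <- total %/% 2L
    end <- total - beg
  } else {
    beg <- end <- as.integer(pad)
    out <- (n + beg + end - eff) %/% stride + 1L
    if (out < 1L) stop("convolution kernel larger than padded input (", n, " vs ", eff, ")")
  }
  list(out = as.integer(out), beg = as.integer(beg), end = as.integer(end))
}

conv_geom <- function(H, W, kh, kw, stride, dilation, pad) {
  pad_h <- if (length(pad) == 2L && is.numeric(pad)) pad[1L] else pad
  pad_w <- if (length(pad) == 2L && is.numeric(pad)) pad[2L] else pad
  if (identical(pad, "valid")) pad_h <- pad_w <- 0L
  gh <- conv_axis_geom(H, kh, stride, dilation, pad_h)
  gw <- conv_axis_geom(W, kw, stride, dilation, pad_w)
  list(OH = gh$out, OW = gw$out, top = gh$beg, bottom = gh$end,
       left = gw$beg, right = gw$end)
}

pad_hw <- function(x, top, bottom, left, right, value = 0) {
  if (top == 0L && bottom == 0L && left == 0L && right == 0L) return(x)
  d <- dim(x)
  out <- array(value, c(d[1L] + top + bottom, d[2L] + left + right, d[3L]))
  out[top + seq_len(d[1L]), left + seq_len(d[2L]), ] <- x
  out
}

# ---- convolution --------------------------------------------------------

conv2d_fwd <- function(x, w, b, stride, dilation, pad, groups) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  dw <- dim(w); kh <- dw[1L]; kw <- dw[2L]; cing <- dw[3L]; cout <- dw[4L]
  if (C != cing * groups) {
    stop("conv2d: input has ", C, " channels, kernel expects ", cing * groups)
  }
  g <- conv_geom(H, W, kh, kw, stride, dilation, pad)
  xp <- pad_hw(x, g$top, g$bottom, g$left, g$right)
  OH <- g$OH; OW <- g$OW
  rows0 <- seq.int(1L, by = stride, length.out = OH)
  cols0 <- seq.int(1L, by = stride, length.out = OW)
  coutg <- cout %/% groups
  out <- matrix(0, OH * OW, cout)
  for (i in seq_len(kh)) {
    rs <- rows0 + (i - 1L) * dilation
    for (j in seq_len(kw)) {
      cs <- cols0 + (j - 1L) * dilation
      patch <- xp[rs, cs, , drop = FALSE]
      dim(patch) <- c(OH * OW, C)
      if (groups == 1L) {
        out <- out + patch %*% matrix(w[i, j, , ], cing, cout)
      } else {
        for (gr in seq_len(groups)) {
          ci <- ((gr - 1L) * cing + 1L):(gr * cing)
          co <- ((gr - 1L) * coutg + 1L):(gr * coutg)
          out[, co] <- out[, co] +
            patch[, ci, drop = FALSE] %*% matrix(w[i, j, , co], cing, coutg)
        }
      }
    }
  }
  if (!is.null(b)) out <- sweep(out, 2L, b, "+")
  dim(out) <- c(OH, OW, cout)
  list(out = out, xp = xp, geom = g)
}

ag_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                      pad = "same", groups = 1L) {
  x <- as_ag_node(x); w <- as_ag_node(w)
  bias <- if (is.null(b)) NULL else as_ag_node(b)
  fw <- conv2d_fwd(x$v, w$v, if (is.null(bias)) NULL else bias$v,
                   stride, dilation, pad, groups)
  parents <- c(list(x, w), if (!is.null(bias)) list(bias))
  xp <- fw$xp; g <- fw$geom
  wv <- w$v
  bw <- function(node) {
    dy <- node$grad
    d <- dim(dy); OH <- d[1L]; OW <- d[2L]; cout <- d[3L]
    dyM <- dy; dim(dyM) <- c(OH * OW, cout)
    dw4 <- dim(wv); kh <- dw4[1L]; kw <- dw4[2L]; cing <- dw4[3L]
    coutg <- cout %/% groups
    C <- dim(xp)[3L]
    rows0 <- seq.int(1L, by = stride, length.out = OH)
    cols0 <- seq.int(1L, by = stride, length.out = OW)
    need_dx <- node_tracked(x)
    dxp <- if (need_dx) array(0, dim(xp)) else NULL
    dW <- array(0, dw4)
    for (i in seq_len(kh)) {
      rs <- rows0 + (i - 1L) * dilation
      for (j in seq_len(kw)) {
        cs <- cols0 + (j - 1L) * dilation
        patch <- xp[rs, cs, , drop = FALSE]
        dim(patch) <- c(OH * OW, C)
        if (groups == 1L) {
          Wij <- matrix(wv[i, j, , ], cing, cout)
          dW[i, j, , ] <- dW[i, j, , ] + crossprod(patch, dyM)
          if (need_dx) {
            dpatch <- tcrossprod(dyM, Wij)
            dim(dpatch) <- c(OH, OW, C)
            dxp[rs, cs, ] <- dxp[rs, cs, , drop = FALSE] + dpatch
          }
        } else {
          dpatch <- if (need_dx) matrix(0, OH * OW, C) else NULL
          for (gr in seq_len(groups)) {
            ci <- ((gr - 1L) * cing + 1L):(gr * cing)
            co <- ((gr - 1L) * coutg + 1L):(gr * coutg)
            Wg <- matrix(wv[i, j, , co], cing, coutg)
            dW[i, j, , co] <- dW[i, j, , co] +
              crossprod(patch[, ci, drop = FALSE], dyM[, co, drop = FALSE])
            if (need_dx) {
              dpatch[, ci] <- tcrossprod(dyM[, co, drop = FALSE], Wg)
            }
          }
          if (need_dx) {
            dim(dpatch) <- c(OH, OW, C)
            dxp[rs, cs, ] <- dxp[rs, cs, , drop = FALSE] + dpatch
          }
        }
      }
    }
    acc_grad(w, dW)
    if (!is.null(bias)) acc_grad(bias, colSums(dyM))
    if (need_dx) {
      dp <- dim(xp)
      dx <- dxp[g$top + seq_len(dp[1L] - g$top - g$bottom),
                g$left + seq_len(dp[2L] - g$left - g$right), , drop = FALSE]
      acc_grad(x, dx)
    }
  }
  ag_op(fw$out, parents, bw)
}

# ---- pointwise / structural ops ----------------------------------------

ag_relu <- function(x) {
  x <- as_ag_node(x)
  v <- x$v
  out <- pmax(v, 0)
  ag_op(out, list(x), function(node) acc_grad(x, node$grad * (v > 0)))
}

ag_add <- function(a, b) {
  a <- as_ag_node(a); b <- as_ag_node(b)
  ag_op(a$v + b$v, list(a, b), function(node) {
    acc_grad(a, node$grad); acc_grad(b, node$grad)
  })
}

# channel concatenation (axis 3); column-major layout makes this c()
ag_concat <- function(xs) {
  xs <- lapply(xs, as_ag_node)
  dims <- lapply(xs, function(x) dim(x$v))
  H <- dims[[1L]][1L]; W <- dims[[1L]][2L]
  cs <- vapply(dims, function(d) d[3L], numeric(1))
  out <- array(unlist(lapply(xs, function(x) x$v), use.names = FALSE),
               c(H, W, sum(cs)))
  offsets <- cumsum(c(0, cs))
  ag_op(out, xs, function(node) {
    for (k in seq_along(xs)) {
      idx <- (offsets[k] + 1L):offsets[k + 1L]
      acc_grad(xs[[k]], node$grad[, , idx, drop = FALSE])
    }
  })
}

# per-channel affine batch-norm transform with fixed statistics
ag_bn <- function(x, gamma, beta, mean, var, eps = 1e-5) {
  x <- as_ag_node(x); gamma <- as_ag_node(gamma); beta <- as_ag_node(beta)
  d <- dim(x$v); HW <- d[1L] * d[2L]; C <- d[3L]
  inv <- 1 / sqrt(var + eps)
  xm <- x$v; dim(xm) <- c(HW, C)
  xhat <- sweep(sweep(xm, 2L, mean, "-"), 2L, inv, "*")
  out <- sweep(sweep(xhat, 2L, gamma$v, "*"), 2L, beta$v, "+")
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(node) {
    dy <- node$grad; dim(dy) <- c(HW, C)
    acc_grad(gamma, colSums(dy * xhat))
    acc_grad(beta, colSums(dy))
    if (node_tracked(x)) {
      dx <- sweep(dy, 2L, gamma$v * inv, "*")
      dim(dx) <- d
      acc_grad(x, dx)
    }
  })
}

pool_fwd <- function(x, k, stride, pad, type) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  g <- conv_geom(H, W, k, k, stride, 1L, pad)
  fill <- if (type == "max") -Inf else 0
  xp <- pad_hw(x, g$top, g$bottom, g$left, g$right, value = fill)
  OH <- g$OH; OW <- g$OW
  rows0 <- seq.int(1L, by = stride, length.out = OH)
  cols0 <- seq.int(1L, by = stride, length.out = OW)
  acc <- if (type == "max") array(-Inf, c(OH, OW, C)) else array(0, c(OH, OW, C))
  arg <- if (type == "max") array(0L, c(OH, OW, C)) else NULL
  t_idx <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    t_idx <- t_idx + 1L
    patch <- xp[rows0 + (i - 1L), cols0 + (j - 1L), , drop = FALSE]
    if (type == "max") {
      upd <- patch > acc
      acc[upd] <- patch[upd]
      arg[upd] <- t_idx
    } else {
      acc <- acc + patch
    }
  }
  if (type == "avg") acc <- acc / (k * k)
  list(out = acc, arg = arg, geom = g, dimxp = dim(xp))
}

ag_pool <- function(x, k, stride, pad = 0L, type = c("max", "avg")) {
  type <- match.arg(type)
  x <- as_ag_node(x)
  fw <- pool_fwd(x$v, k, stride, pad, type)
  g <- fw$geom; arg <- fw$arg; dimxp <- fw$dimxp
  ag_op(fw$out, list(x), function(node) {
    dy <- node$grad
    d <- dim(dy); OH <- d[1L]; OW <- d[2L]
    rows0 <- seq.int(1L, by = stride, length.out = OH)
    cols0 <- seq.int(1L, by = stride, length.out = OW)
    dxp <- array(0, dimxp)
    t_idx <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      t_idx <- t_idx + 1L
      rs <- rows0 + (i - 1L); cs <- cols0 + (j - 1L)
      if (type == "max") {
        sel <- arg == t_idx
        if (any(sel)) {
          add <- array(0, d); add[sel] <- dy[sel]
          dxp[rs, cs, ] <- dxp[rs, cs, , drop = FALSE] + add
        }
      } else {
        dxp[rs, cs, ] <- dxp[rs, cs, , drop = FALSE] + dy / (k * k)
      }
    }
    dx <- dxp[g$top + seq_len(dim(x$v)[1L]),
              g$left + seq_len(dim(x$v)[2L]), , drop = FALSE]
    acc_grad(x, dx)
  })
}

# global average pooling to 1x1xC
ag_gap <- function(x) {
  x <- as_ag_node(x)
  d <- dim(x$v); HW <- d[1L] * d[2L]
  xm <- x$v; dim(xm) <- c(HW, d[3L])
  out <- array(colMeans(xm), c(1L, 1L, d[3L]))
  ag_op(out, list(x), function(node) {
    dy <- node$grad
    dx <- array(rep(as.vector(dy) / HW, each = HW), d)
    acc_grad(x, dx)
  })
}

ag_broadcast_hw <- function(x, H, W) {
  x <- as_ag_node(x)
  C <- dim(x$v)[3L]
  out <- array(rep(as.vector(x$v), each = H * W), c(H, W, C))
  ag_op(out, list(x), function(node) {
    dy <- node$grad; dim(dy) <- c(H * W, C)
    acc_grad(x, array(colSums(dy), c(1L, 1L, C)))
  })
}

# ---- resizing -----------------------------------------------------------

# Bilinear interpolation matrix (half-pixel centers, edge clamped); a
# resize is then two GEMMs per tensor and its adjoint is the transpose.
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  lo <- floor(src)
  f <- src - lo
  i0 <- pmin(pmax(lo, 0), n_in - 1) + 1
  i1 <- pmin(pmax(lo + 1, 0), n_in - 1) + 1
  for (r in seq_len(n_out)) {
    A[r, i0[r]] <- A[r, i0[r]] + (1 - f[r])
    A[r, i1[r]] <- A[r, i1[r]] + f[r]
  }
  A
}

nearest_index <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  pmin(pmax(round(src), 0), n_in - 1) + 1
}

# y[, , c] = A %*% x[, , c] %*% t(B), applied over all channels
mat_resize_fwd <- function(x, A, B) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C <- d[3L]
  OH <- nrow(A); OW <- nrow(B)
  y1 <- A %*% matrix(x, H, W * C)              # OH x (W*C)
  dim(y1) <- c(OH, W, C)
  y1 <- aperm(y1, c(2L, 1L, 3L))               # W x OH x C
  y2 <- B %*% matrix(y1, W, OH * C)            # OW x (OH*C)
  dim(y2) <- c(OW, OH, C)
  aperm(y2, c(2L, 1L, 3L))
}

ag_bilinear <- function(x, out_h, out_w) {
  x <- as_ag_node(x)
  d <- dim(x$v)
  A <- interp_matrix(d[1L], out_h)
  B <- interp_matrix(d[2L], out_w)
  out <- mat_resize_fwd(x$v, A, B)
  ag_op(out, list(x), function(node) {
    acc_grad(x, mat_resize_fwd(node$grad, t(A), t(B)))
  })
}

ag_dropout <- function(x, p, training) {
  x <- as_ag_node(x)
  if (!training || p <= 0) return(x)
  keep <- 1 - p
  mask <- array(stats::rbinom(length(x$v), 1L, keep) / keep, dim(x$v))
  ag_op(x$v * mask, list(x), function(node) acc_grad(x, node$grad * mask))
}

ag_sigmoid <- function(x) {
  x <- as_ag_node(x)
  s <- 1 / (1 + exp(-x$v))
  ag_op(s, list(x), function(node) acc_grad(x, node$grad * s * (1 - s)))
}

# mean binary cross-entropy on logits; numerically stable closed form
ag_bce_with_logits <- function(scores, target) {
  scores <- as_ag_node(scores)
  s <- scores$v
  g <- target
  n <- length(s)
  v <- mean(pmax(s, 0) - s * g + log1p(exp(-abs(s))))
  ag_op(v, list(scores), function(node) {
    acc_grad(scores, node$grad * (1 / (1 + exp(-s)) - g) / n)
  })
}
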