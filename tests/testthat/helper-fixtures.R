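# Shared fixtures and independent oracles used across the suite.

# Direct (nested-loop) convolution oracle, independent of the package's
# GEMM path.
naive_conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                         pad = 0L) {
  d <- dim(x)
  kh <- dim(w)[1L]; kw <- dim(w)[2L]; cin <- dim(w)[3L]; cout <- dim(w)[4L]
  ph <- if (length(pad) == 2L) pad[1L] else pad
  pw <- if (length(pad) == 2L) pad[2L] else pad
  xp <- array(0, c(d[1L] + 2L * ph, d[2L] + 2L * pw, d[3L]))
  xp[ph + seq_len(d[1L]), pw + seq_len(d[2L]), ] <- x
  OH <- (dim(xp)[1L] - dilation * (kh - 1L) - 1L) %/% stride + 1L
  OW <- (dim(xp)[2L] - dilation * (kw - 1L) - 1L) %/% stride + 1L
  out <- array(0, c(OH, OW, cout))
  for (oi in seq_len(OH)) for (oj in seq_len(OW)) for (co in seq_len(cout)) {
    s <- 0
    for (i in seq_len(kh)) for (j in seq_len(kw)) for (ci in seq_len(cin)) {
      s <- s + xp[(oi - 1L) * stride + 1L + (i - 1L) * dilation,
                  (oj - 1L) * stride + 1L + (j - 1L) * dilation, ci] *
        w[i, j, ci, co]
    }
    out[oi, oj, co] <- s + if (is.null(b)) 0 else b[co]
  }
  out
}

rand_arr <- function(...) array(rnorm(prod(c(...))), c(...))

# disc-shaped binary mask
disc_mask <- function(side, ctr, r) {
  rows <- matrix(seq_len(side), side, side)
  cols <- matrix(seq_len(side), side, side, byrow = TRUE)
  ((rows - ctr[1L])^2 + (cols - ctr[2L])^2 <= r^2) + 0
}

# random 1x1/3x3/1x1 bottleneck parameter list mapping c channels -> c
rand_bottleneck_params <- function(c_io, c_mid, bias = TRUE) {
  list(w1 = rand_arr(1, 1, c_io, c_mid),
       b1 = if (bias) rnorm(c_mid),
       w2 = rand_arr(3, 3, c_mid, c_mid),
       b2 = if (bias) rnorm(c_mid),
       w3 = rand_arr(1, 1, c_mid, c_io),
       b3 = if (bias) rnorm(c_io))
}

# label 3D connected components (6-connectivity) of a binary volume;
# returns the component count. Test-local oracle, independent of the
# package's 2D labelling.
count_components_3d <- function(vol) {
  idx <- which(vol != 0)
  if (length(idx) == 0L) return(0L)
  d <- dim(vol)
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  coord <- arrayInd(idx, d)
  edges <- NULL
  for (ax in 1:3) {
    nb <- coord
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    j <- id[nb[ok, , drop = FALSE]]
    keep <- j > 0L
    if (any(keep)) {
      edges <- rbind(edges, cbind(id[idx[ok]][keep], j[keep]))
    }
  }
  if (is.null(edges)) return(length(idx))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  igraph::components(g)$no
}
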