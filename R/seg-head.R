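# Atrous-spatial-pyramid-pooling segmentation head: five parallel
# branches (1x1 conv; three 3x3 atrous convs; a global-pooled image-level
# branch broadcast back), concatenated, projected to mid channels,
# dropout, 1x1 projection to a single score channel, bilinear upsampling
# to the output side.

m_aspp <- function(cin, rates = c(4L, 8L, 12L), mid = 256L,
                   out_channels = 1L, output_side = 256L, dropout_p = 0.5) {
  stopifnot(all(diff(rates) > 0), all(rates >= 1), dropout_p >= 0,
            dropout_p < 1)
  new_module("aspp",
    b0 = m_cbr(cin, mid, 1L),
    atrous = lapply(rates, function(r) {
      m_cbr(cin, mid, 3L, dilation = as.integer(r), pad = "same")
    }),
    img = m_cbr(cin, mid, 1L),
    project = m_cbr(mid * 5L, mid, 1L),
    final = m_conv(mid, out_channels, 1L, bias = TRUE),
    rates = as.integer(rates), mid = mid, dropout_p = dropout_p,
    output_side = as.integer(output_side))
}

#' @export
forward.ls_aspp <- function(m, x, training = FALSE) {
  d <- dim(node_value(x))
  for (r in m$rates) {
    if (atrous_validity(r, min(d[1:2])) == "degenerate") {
      warning("atrous rate ", r, " is degenerate for a ", d[1L], "x", d[2L],
              " feature map (acts as 1x1)")
    }
  }
  branches <- c(list(forward(m$b0, x, training)),
                lapply(m$atrous, function(b) forward(b, x, training)),
                list(ag_broadcast_hw(forward(m$img, ag_gap(x), training),
                                     d[1L], d[2L])))
  y <- forward(m$project, ag_concat(branches), training)
  y <- ag_dropout(y, m$dropout_p, training)
  y <- forward(m$final, y, training)
  ag_bilinear(y, m$output_side, m$output_side)
}

#' Classify an atrous rate as valid or degenerate for a feature map
#'
#' A 3x3 kernel dilated by `rate` degenerates to a 1x1 filter when no
#' off-center tap can fall inside the map, i.e. when
#' `rate >= feature_side`.
#'
#' @param rate dilation rate.
#' @param feature_side in-plane feature map extent.
#' @return `"valid"` or `"degenerate"`.
#' @export
atrous_validity <- function(rate, feature_side) {
  if (rate >= feature_side) "degenerate" else "valid"
}

#' Forward feature maps through a segmentation head
#'
#' @param features feature array (rows x cols x channels) or autograd
#'   node.
#' @param head an ASPP head module.
#' @param training logical; enables dropout.
#' @return score map (matrix `output_side x output_side`) for plain
#'   input; an autograd node for node input.
#' @export
head_forward <- function(features, head, training = FALSE) {
  if (is_ag_node(features)) return(forward(head, features, training))
  out <- with_no_grad(node_value(forward(head, ag_const(features), training)))
  matrix(out, dim(out)[1L], dim(out)[2L])
}

#' Build a full segmentation network (backbone + ASPP head)
#'
#' At full size: the adapted backbone (output stride 8) with head rates
#' 4/8/12 chosen for 32x32 feature maps, 256 mid channels and dropout
#' 0.5. The `tiny` profile shrinks the backbone (see [build_backbone()])
#' and uses rates 1/2/3 with 16 mid channels so the whole network trains
#' in seconds on a CPU.
#'
#' @param family backbone family name.
#' @param side input/output image side.
#' @param tiny logical, reduced profile.
#' @param rates,mid,dropout_p head hyper-parameters (defaulted by
#'   profile).
#' @return object of class `ls_segnet`.
#' @export
build_segnet <- function(family = "resnet152", side = 256L, tiny = FALSE,
                         rates = if (tiny) c(1L, 2L, 3L) else c(4L, 8L, 12L),
                         mid = if (tiny) 16L else 256L, dropout_p = 0.5) {
  bb <- build_backbone(family, output_stride = 8L, in_channels = 1L,
                       tiny = tiny)
  head <- m_aspp(bb$out_channels, rates = rates, mid = mid,
                 out_channels = 1L, output_side = side,
                 dropout_p = dropout_p)
  structure(list(backbone = bb, head = head, side = as.integer(side),
                 family = family, tiny = tiny), class = "ls_segnet")
}

#' Forward an image through a segmentation network
#'
#' @param net an `ls_segnet`.
#' @param img numeric matrix (side x side) in the network's input range,
#'   or an autograd node.
#' @param training logical; enables dropout (and gradient taping when
#'   called under an enabled tape).
#' @return score matrix (logits), or an autograd node for node input.
#' @export
segnet_forward <- function(net, img, training = FALSE) {
  if (is_ag_node(img)) {
    f <- forward(net$backbone$net, img, training)
    return(forward(net$head, f, training))
  }
  x <- as_image_array(img)
  out <- with_no_grad({
    f <- forward(net$backbone$net, ag_const(x), training)
    node_value(forward(net$head, f, training))
  })
  matrix(out, dim(out)[1L], dim(out)[2L])
}

#' Sigmoid probability map of a segmentation network
#'
#' @inheritParams segnet_forward
#' @return matrix of probabilities in (0, 1).
#' @export
segnet_predict <- function(net, img) {
  1 / (1 + exp(-segnet_forward(net, img, training = FALSE)))
}
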