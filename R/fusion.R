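# Decision fusion: weighted combination of the four per-network masks,
# weight training by SGD on binary cross-entropy, and the error-overlap
# diagnostic.

#' Fixed network order of the candidate mask tuple
#' @export
fusion_network_ids <- c("densenet201", "inceptionv3", "resnet152", "resnext101")

#' Fuse four candidate masks into one binary decision
#'
#' The default `"threshold"` rule marks a pixel foreground when the
#' weighted sum `sum(w_i P_i)` reaches 0.5 (ties resolve to foreground, so
#' with equal weights two agreeing networks suffice). The
#' `"sigmoid_round"` rule is the literal round-of-sigmoid form, foreground
#' where the weighted sum is strictly positive; on nonnegative masks with
#' positive weights it fires on any single vote, which is why it is not
#' the default.
#'
#' @param masks list of 4 numeric matrices in `[0, 1]`, ordered as
#'   [fusion_network_ids].
#' @param w numeric weight vector of length 4.
#' @param rule `"threshold"` or `"sigmoid_round"`.
#' @return binary matrix.
#' @export
fuse <- function(masks, w, rule = c("threshold", "sigmoid_round")) {
  rule <- match.arg(rule)
  stopifnot(length(masks) == 4L, length(w) == 4L)
  d <- dim(masks[[1L]])
  for (m in masks) {
    if (!all(dim(m) == d)) stop("candidate mask extents differ")
  }
  s <- w[1L] * masks[[1L]] + w[2L] * masks[[2L]] +
       w[3L] * masks[[3L]] + w[4L] * masks[[4L]]
  if (rule == "threshold") (s >= 0.5) + 0 else (s > 0) + 0
}

#' Train the fusion weights by SGD on binary cross-entropy
#'
#' Minimizes the mean pixel-wise cross-entropy between
#' `sigmoid(sum w_i P_i)` and the ground truth over mini-batches of
#' slices, with momentum and no bias term. Defaults follow the system's
#' schedule: learning rate 10, momentum 0.9, 5 epochs, batch 32 slices,
#' equal initial weights of 0.25. The per-epoch slice order is a
#' deterministic function of `(seed, epoch)`.
#'
#' @param candidates list over slices; each element a list of 4 masks
#'   ordered as [fusion_network_ids].
#' @param gt list of ground-truth binary masks, same length and extents.
#' @param lr,momentum,epochs,batch optimizer settings.
#' @param init initial weight vector.
#' @param seed integer seed controlling the epoch shuffles.
#' @return object of class `fusion_weights`: list with `w`, `scaled`
#'   (`w / sum(w)`), `network_ids` and the epoch-end weight `history`.
#' @export
train_fusion_weights <- function(candidates, gt, lr = 10, momentum = 0.9,
                                 epochs = 5L, batch = 32L,
                                 init = rep(0.25, 4L), seed = 1L) {
  n <- length(candidates)
  stopifnot(n > 0L, length(gt) == n)
  # flatten once: per slice an (npix x 4) matrix and a target vector
  P <- lapply(candidates, function(ms) {
    stopifnot(length(ms) == 4L)
    matrix(unlist(ms, use.names = FALSE), ncol = 4L)
  })
  G <- lapply(gt, function(g) as.numeric(g != 0))
  if (all(vapply(P, function(p) all(p == 0), logical(1))) &&
      all(vapply(G, function(g) all(g == 0), logical(1)))) {
    warning("objective is flat (all candidates and ground truths empty); ",
            "returning initial weights")
    return(new_fusion_weights(init, list()))
  }
  w <- init
  mom <- numeric(4L)
  history <- list()
  for (ep in seq_len(epochs)) {
    ord <- batch_order(n, seed, ep)
    starts <- seq.int(1L, n, by = batch)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n)]
      Pb <- do.call(rbind, P[idx])
      gb <- unlist(G[idx], use.names = FALSE)
      z <- as.vector(Pb %*% w)
      grad <- as.vector(crossprod(Pb, 1 / (1 + exp(-z)) - gb)) / length(gb)
      mom <- momentum * mom + grad
      w <- w - lr * mom
    }
    history[[ep]] <- w
  }
  new_fusion_weights(w, history)
}

new_fusion_weights <- function(w, history) {
  structure(list(w = w, scaled = if (sum(w) != 0) w / sum(w) else rep(NA_real_, 4L),
                 network_ids = fusion_network_ids, history = history),
            class = "fusion_weights")
}

#' @export
print.fusion_weights <- function(x, ...) {
  cat("fusion weights:\n")
  for (i in 1:4) {
    cat(sprintf("  %-12s w = %+.5f  scaled = %s\n", x$network_ids[i], x$w[i],
                if (is.na(x$scaled[i])) "NA" else sprintf("%.3f", x$scaled[i])))
  }
  invisible(x)
}

#' Persist / load fusion weights as a small table
#' @param fw a `fusion_weights` object.
#' @param path file path (tab-delimited).
#' @return `write_fusion_weights`: the path, invisibly;
#'   `read_fusion_weights`: a `fusion_weights` object.
#' @export
write_fusion_weights <- function(fw, path) {
  utils::write.table(
    data.frame(network = fw$network_ids, weight = fw$w, scaled = fw$scaled),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fusion_weights
#' @export
read_fusion_weights <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(identical(tb$network, fusion_network_ids))
  new_fusion_weights(tb$weight, list())
}

#' Pairwise Dice overlap of per-network segmentation errors
#'
#' Each network's error set is `|G - P_i|` binarized at 0.5, pooled over
#' all slices; entry `(i, j)` is the Dice coefficient between the error
#' sets of networks i and j. A pair of empty error sets scores 0 (no
#' overlapping error mass); the diagonal is 1 for any network with at
#' least one error. Low off-diagonal values indicate errors the fusion
#' stage can vote away.
#'
#' @param per_network list of 4 lists of candidate masks (one sequence
#'   per network, ordered as [fusion_network_ids]).
#' @param gt list of ground-truth masks of the same length.
#' @return 4x4 numeric matrix with network ids as dimnames.
#' @export
error_overlap_matrix <- function(per_network, gt) {
  stopifnot(length(per_network) == 4L, length(gt) > 0L)
  nsl <- length(gt)
  errs <- lapply(per_network, function(seqs) {
    stopifnot(length(seqs) == nsl)
    lapply(seq_len(nsl), function(k) abs((gt[[k]] != 0) - seqs[[k]]) > 0.5)
  })
  out <- matrix(0, 4L, 4L, dimnames = list(fusion_network_ids,
                                           fusion_network_ids))
  for (i in 1:4) for (j in 1:4) {
    inter <- 0; tot <- 0
    for (k in seq_len(nsl)) {
      inter <- inter + sum(errs[[i]][[k]] & errs[[j]][[k]])
      tot <- tot + sum(errs[[i]][[k]]) + sum(errs[[j]][[k]])
    }
    out[i, j] <- if (tot == 0) 0 else 2 * inter / tot
  }
  out
}
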