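# Optimization schedules, the segmentation loss, and the batching /
# normalization contract of the data loader.

#' Training schedule for one system stage
#'
#' Liver stage: lr 0.05 for 200 epochs, multiplied by 0.95 at every
#' 10-epoch boundary. Lesion stage: lr 0.1 for 20 epochs, halved after
#' every epoch (last-epoch lr 1.9e-7). Fusion stage: constant lr 10 for
#' 5 epochs. All stages use momentum 0.9 and batches of 32 slices.
#'
#' @param stage `"liver"`, `"lesion"` or `"fusion"`.
#' @param epochs,lr0,batch optional overrides.
#' @return list of class `schedule_spec`.
#' @export
schedule_spec <- function(stage = c("liver", "lesion", "fusion"),
                          epochs = NULL, lr0 = NULL, batch = 32L) {
  stage <- match.arg(stage)
  def <- switch(stage,
    liver = list(lr0 = 0.05, epochs = 200L),
    lesion = list(lr0 = 0.1, epochs = 20L),
    fusion = list(lr0 = 10, epochs = 5L))
  structure(list(stage = stage,
                 lr0 = if (is.null(lr0)) def$lr0 else lr0,
                 epochs = if (is.null(epochs)) def$epochs else as.integer(epochs),
                 momentum = 0.9, batch = as.integer(batch)),
            class = "schedule_spec")
}

#' Learning rate at a given epoch of a schedule
#'
#' Liver: `lr0 * 0.95 ^ floor((epoch - 1) / 10)`; lesion:
#' `lr0 * 0.5 ^ (epoch - 1)`; fusion: constant `lr0`.
#'
#' @param spec a [schedule_spec()].
#' @param epoch epoch index, `1 <= epoch <= spec$epochs`.
#' @return learning rate.
#' @export
scheduled_lr <- function(spec, epoch) {
  if (epoch < 1L || epoch > spec$epochs) {
    stop("epoch ", epoch, " outside schedule range 1..", spec$epochs)
  }
  switch(spec$stage,
    liver = spec$lr0 * 0.95^((epoch - 1L) %/% 10L),
    lesion = spec$lr0 * 0.5^(epoch - 1L),
    fusion = spec$lr0)
}

#' Mean binary cross-entropy segmentation loss on logit scores
#'
#' @param scores numeric score (logit) matrix.
#' @param gt binary ground-truth mask of equal extent.
#' @return nonnegative scalar loss.
#' @export
segmentation_loss <- function(scores, gt) {
  if (!all(dim(scores) == dim(gt))) stop("score/mask extents differ")
  if (!all(gt %in% c(0, 1))) stop("ground truth must be binary")
  mean(pmax(scores, 0) - scores * gt + log1p(exp(-abs(scores))))
}

# deterministic epoch permutation as a function of (seed, epoch)
batch_order <- function(n, seed, epoch) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((as.integer(seed) %% 100000L) * 20011L + as.integer(epoch))
  sample.int(n)
}

#' Mini-batch index plan for one epoch
#'
#' Shuffles the slice indices as a deterministic function of
#' `(seed, epoch)` and partitions them into consecutive blocks of `batch`
#' (the final short block is retained).
#'
#' @param n number of slices.
#' @param batch batch size.
#' @param seed integer seed.
#' @param epoch epoch index.
#' @return list of integer index vectors.
#' @export
make_batches <- function(n, batch = 32L, seed = 1L, epoch = 1L) {
  if (n < 1L) stop("empty dataset")
  ord <- batch_order(n, seed, epoch)
  split(ord, (seq_len(n) - 1L) %/% batch)
}

#' Normalize a `[0, 1]` slice to the network input range `[-1, 1]`
#'
#' `v -> (v - 0.5) / 0.5`, the loader's fixed normalization.
#'
#' @param v numeric vector/matrix in `[0, 1]`.
#' @return normalized values.
#' @export
normalize_slice <- function(v) (v - 0.5) / 0.5

#' Train a segmentation network by SGD with momentum
#'
#' Runs the given schedule over a set of slices: per epoch a deterministic
#' shuffle, per mini-batch an averaged backward pass through the network
#' and one momentum-SGD update at the scheduled learning rate. Meant for
#' the tiny network profile at desk scale; the full-size profile uses the
#' same code path.
#'
#' @param net an `ls_segnet` (modified in place; parameter nodes are
#'   reference objects).
#' @param images list of `[0, 1]` slice matrices at the network side.
#' @param masks list of binary masks of the same extent.
#' @param spec a [schedule_spec()].
#' @param seed integer seed (epoch shuffles and dropout draws).
#' @return numeric vector of mean epoch losses.
#' @export
train_segnet <- function(net, images, masks, spec, seed = 1L) {
  stopifnot(length(images) == length(masks), length(images) > 0L)
  params <- collect_params(list(net$backbone, net$head))
  losses <- numeric(spec$epochs)
  set.seed((as.integer(seed) %% 100000L) * 7639L + 17L)
  for (ep in seq_len(spec$epochs)) {
    lr <- scheduled_lr(spec, ep)
    batches <- make_batches(length(images), spec$batch, seed, ep)
    tot <- 0
    for (b in batches) {
      zero_grads(params)
      bl <- 0
      for (i in b) {
        x <- ag_const(as_image_array(normalize_slice(images[[i]])))
        scores <- segnet_forward(net, x, training = TRUE)
        loss <- ag_bce_with_logits(scores, as_image_array(masks[[i]] + 0))
        backprop(loss, seed_grad = 1 / length(b))
        bl <- bl + loss$v / length(b)
      }
      sgd_step(params, lr, spec$momentum)
      tot <- tot + bl * length(b)
    }
    losses[ep] <- tot / length(images)
  }
  losses
}
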