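# Dice similarity in global (pooled-voxel) and per-case (per-volume
# averaged) form.

#' Dice similarity coefficient of two binary grids
#'
#' `DSC(A, B) = 2 |A intersect B| / (|A| + |B|)`. Two empty masks agree
#' perfectly (1); exactly one empty mask scores 0.
#'
#' @param a,b binary arrays of equal extent.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("dice: extents differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Evaluate predicted mask volumes against ground truth
#'
#' Predictions are resized slice-wise (nearest neighbour) to the ground
#' truth in-plane extent when needed, then scored two ways: a global Dice
#' pooling all voxels of all volumes, and a per-case Dice computed per
#' volume and averaged.
#'
#' @param pred named list of 3D binary arrays (slice, row, col).
#' @param gt named list of 3D binary arrays with matching names.
#' @return object of class `dice_report`: list with `global_dice`,
#'   `per_case` (data.frame of volume_id, dice), `per_case_mean`.
#' @export
evaluate_volumes <- function(pred, gt) {
  if (length(pred) == 0L) stop("no predictions supplied")
  ids <- names(pred)
  if (is.null(ids) || !setequal(ids, names(gt))) {
    stop("prediction and ground-truth volume ids do not match")
  }
  inter <- 0; tot <- 0
  per <- numeric(length(ids))
  for (k in seq_along(ids)) {
    p <- pred[[ids[k]]]; g <- gt[[ids[k]]]
    if (dim(p)[1L] != dim(g)[1L]) stop("slice counts differ for ", ids[k])
    if (any(dim(p)[2:3] != dim(g)[2:3])) {
      up <- array(0, dim(g))
      for (s in seq_len(dim(p)[1L])) {
        up[s, , ] <- resize_rect(p[s, , , drop = TRUE],
                                 dim(g)[2L], dim(g)[3L], mode = "mask")
      }
      p <- up
    }
    inter <- inter + sum(p != 0 & g != 0)
    tot <- tot + sum(p != 0) + sum(g != 0)
    per[k] <- dice(p, g)
  }
  structure(list(
    global_dice = if (tot == 0) 1 else 2 * inter / tot,
    per_case = data.frame(volume_id = ids, dice = per,
                          stringsAsFactors = FALSE),
    per_case_mean = mean(per)), class = "dice_report")
}

#' @export
print.dice_report <- function(x, ...) {
  cat(sprintf("Dice report (%d volumes)\n", nrow(x$per_case)))
  cat(sprintf("  global dice:   %.4f\n", x$global_dice))
  cat(sprintf("  per-case mean: %.4f\n", x$per_case_mean))
  invisible(x)
}

#' Write a Dice report to disk
#'
#' Emits a tab-delimited per-case table and a JSON summary.
#'
#' @param report a `dice_report` from [evaluate_volumes()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_dice_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- file.path(dir, "dice_per_case.tsv")
  js <- file.path(dir, "dice_summary.json")
  utils::write.table(report$per_case, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(list(global_dice = report$global_dice,
                            per_case_mean = report$per_case_mean),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
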