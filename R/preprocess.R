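# CT image conditioning: HU windowing, resizing, liver masking, VOI
# extraction, background mean-fill and CLAHE.

#' Window and normalize a Hounsfield-unit slice
#'
#' Clamps values to the `[lo_hu, hi_hu]` window (default -250..250 HU, the
#' soft-tissue window used throughout the pipeline) and rescales linearly
#' to `[0, 1]`: `out = (clamp(v) - lo) / (hi - lo)`. Monotone
#' non-decreasing in HU; total (no error cases).
#'
#' @param slice numeric matrix (or array) of HU values.
#' @param lo_hu,hi_hu window bounds, `lo_hu < hi_hu`.
#' @return same shape, values in `[0, 1]`.
#' @export
window_and_normalize <- function(slice, lo_hu = -250, hi_hu = 250) {
  stopifnot(lo_hu < hi_hu)
  (pmin(pmax(slice, lo_hu), hi_hu) - lo_hu) / (hi_hu - lo_hu)
}

#' Resize a square slice image
#'
#' Continuous mode interpolates bilinearly (half-pixel centers); mask mode
#' uses nearest-neighbour sampling so a binary alphabet is preserved.
#'
#' @param img numeric matrix, square.
#' @param side target side length in pixels (>= 8 for continuous use).
#' @param mode `"continuous"` or `"mask"`.
#' @return `side x side` matrix.
#' @export
resize_image <- function(img, side, mode = c("continuous", "mask")) {
  mode <- match.arg(mode)
  if (nrow(img) != ncol(img)) stop("resize_image expects a square input")
  resize_rect(img, side, side, mode)
}

# non-square-capable internal resize used for VOI crops and reassembly
resize_rect <- function(img, out_r, out_c, mode = "continuous") {
  d <- dim(img)
  if (d[1L] == out_r && d[2L] == out_c) return(img)
  if (mode == "mask") {
    img[nearest_index(d[1L], out_r), nearest_index(d[2L], out_c), drop = FALSE]
  } else {
    A <- interp_matrix(d[1L], out_r)
    B <- interp_matrix(d[2L], out_c)
    A %*% img %*% t(B)
  }
}

#' Apply a binary liver mask to a slice image
#'
#' Pixel-wise product: intensities survive inside the mask, everything
#' else becomes 0.
#'
#' @param img numeric matrix.
#' @param mask binary matrix of equal extent.
#' @return masked image.
#' @export
apply_liver_mask <- function(img, mask) {
  if (!all(dim(img) == dim(mask))) stop("image and mask extents differ")
  img * mask
}

#' Bounding volume of interest of a binary volume
#'
#' Scans each of the three axes and keeps the first and last index with
#' any nonzero value. Coordinates are 0-based with half-open upper bounds.
#'
#' @param maskvol 3D array (slice, row, col) with at least one nonzero
#'   voxel.
#' @return list with integer vectors `lo` (inclusive) and `hi`
#'   (exclusive), one entry per axis.
#' @export
find_voi <- function(maskvol) {
  if (!any(maskvol != 0)) stop("find_voi: volume has no nonzero voxels")
  axis_range <- function(a) {
    nz <- which(apply(maskvol != 0, a, any))
    c(nz[1L] - 1L, nz[length(nz)])
  }
  r <- vapply(1:3, axis_range, integer(2L))
  list(lo = r[1L, ], hi = r[2L, ])
}

#' Crop a volume to a VOI and resize each retained slice
#'
#' Slices outside the VOI are dropped; each remaining slice is cropped
#' in-plane to the VOI bounds and resized to `side x side`.
#'
#' @param vol 3D array (slice, row, col).
#' @param voi a VOI from [find_voi()].
#' @param side output side length.
#' @param mode passed to the resize (`"continuous"` or `"mask"`).
#' @return list of `side x side` matrices, one per retained slice.
#' @export
crop_voi_and_resize <- function(vol, voi, side, mode = "continuous") {
  d <- dim(vol)
  if (any(voi$lo < 0L) || any(voi$hi > d) || any(voi$lo >= voi$hi)) {
    stop("VOI inconsistent with volume extents")
  }
  slices <- (voi$lo[1L] + 1L):voi$hi[1L]
  rows <- (voi$lo[2L] + 1L):voi$hi[2L]
  cols <- (voi$lo[3L] + 1L):voi$hi[3L]
  lapply(slices, function(k) {
    resize_rect(vol[k, rows, cols, drop = TRUE], side, side, mode)
  })
}

#' Replace zero-valued background with the mean of nonzero pixels
#'
#' Limits dynamic range and removes the strong liver/background edge
#' before contrast enhancement. Nonzero pixels are untouched; an all-zero
#' slice is returned unchanged (such slices are dropped by the VOI crop).
#'
#' @param img numeric matrix.
#' @return matrix with zeros replaced by the nonzero mean.
#' @export
fill_background_with_mean <- function(img) {
  nz <- img != 0
  if (!any(nz)) return(img)
  img[!nz] <- mean(img[nz])
  img
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise clipped histogram equalization on a `grid x grid` tiling
#' (default 8x8, i.e. 64 tiles) with bilinear interpolation between tile
#' mappings. The clip limit is expressed as a fraction of the tile pixel
#' count; 0.01 is a conventional default. Backed by `EBImage::clahe()`
#' (Zuiderveld's algorithm), whose relative limit equals
#' `clip_limit * bins`.
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @param grid number of tiles per axis.
#' @param clip_limit clip limit as a fraction of tile pixels.
#' @param bins histogram bins per tile.
#' @return equalized matrix, values in `[0, 1]`.
#' @export
clahe_enhance <- function(img, grid = 8L, clip_limit = 0.01, bins = 256L) {
  if (min(img) < -1e-9 || max(img) > 1 + 1e-9) {
    stop("clahe_enhance expects values in [0, 1]")
  }
  if (any(dim(img) < grid)) stop("image smaller than the tile grid")
  if (diff(range(img)) < 1e-12) return(img)  # degenerate single-level image
  out <- EBImage::clahe(img, nx = grid, ny = grid, bins = bins,
                        limit = max(clip_limit * bins, 1e-6))
  pmin(pmax(out, 0), 1)
}
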