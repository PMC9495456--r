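# Rule-based cleanup of predicted binary masks: distractor-region removal
# for liver masks, minimum-area filtering for lesion masks.
#
# Connected components are computed on a pixel-adjacency graph
# (igraph::components); default connectivity is 8 so diagonal bridges do
# not split a region.

#' Label connected components of a binary mask
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background), with an
#'   attribute `n` giving the number of components.
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  d <- dim(mask)
  fg <- which(mask != 0)
  lab <- matrix(0L, d[1L], d[2L])
  if (length(fg) == 0L) {
    attr(lab, "n") <- 0L
    return(lab)
  }
  id <- matrix(0L, d[1L], d[2L])
  id[fg] <- seq_along(fg)
  shifts <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8L) shifts <- c(shifts, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (s in shifts) {
    dr <- s[1L]; dc <- s[2L]
    r1 <- seq_len(d[1L] - dr)
    c1 <- if (dc >= 0L) seq_len(d[2L] - dc) else (1L - dc):d[2L]
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + dr, c1 + dc, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges[[length(edges) + 1L]] <- cbind(a[keep], b[keep])
  }
  if (length(edges) > 0L) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(fg)
  }
  # relabel in first-appearance order for determinism
  memb <- match(memb, unique(memb))
  lab[fg] <- memb
  attr(lab, "n") <- max(memb)
  lab
}

#' Area and centroid of each labelled region
#'
#' @param lab label matrix from [label_components()].
#' @return data.frame with columns `label`, `area`, `centroid_row`,
#'   `centroid_col` (1-based pixel coordinates).
#' @export
region_stats <- function(lab) {
  n <- attr(lab, "n")
  if (is.null(n)) n <- max(lab)
  if (n == 0L) {
    return(data.frame(label = integer(), area = numeric(),
                      centroid_row = numeric(), centroid_col = numeric()))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(l, n)
  data.frame(label = seq_len(n), area = area,
             centroid_row = rowsum(rows, l)[, 1L] / area,
             centroid_col = rowsum(cols, l)[, 1L] / area)
}

#' Remove distractor regions from a liver mask
#'
#' Labels connected regions; with fewer than 2 regions the mask is left
#' unchanged. The largest region is the main liver area and is always
#' kept; every other region is removed when its centroid lies more than
#' `dist_px` pixels from the main centroid or its area is smaller than
#' `main_area / area_ratio` (strict). Anti-extensive and idempotent.
#'
#' @param mask binary matrix.
#' @param dist_px centroid-distance threshold in pixels.
#' @param area_ratio main-to-secondary area ratio threshold.
#' @param connectivity component connectivity (4 or 8).
#' @return filtered binary matrix.
#' @export
filter_liver_regions <- function(mask, dist_px = 200, area_ratio = 8,
                                 connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n")
  if (n < 2L) return(mask)
  st <- region_stats(lab)
  main <- st[which.max(st$area), ]
  keep <- logical(n)
  keep[main$label] <- TRUE
  for (i in seq_len(n)) {
    if (i == main$label) next
    d <- sqrt((st$centroid_row[i] - main$centroid_row)^2 +
              (st$centroid_col[i] - main$centroid_col)^2)
    keep[i] <- (d <= dist_px) && (st$area[i] >= main$area / area_ratio)
  }
  out <- mask
  out[!(lab > 0L & keep[pmax(lab, 1L)])] <- 0
  out
}

#' Remove small lesion regions
#'
#' Connected regions with area strictly below `min_area` pixels are
#' deleted; all others are untouched.
#'
#' @param mask binary matrix.
#' @param min_area minimum pixel count for a lesion to be registered.
#' @param connectivity component connectivity (4 or 8).
#' @return filtered binary matrix.
#' @export
filter_lesion_regions <- function(mask, min_area = 10, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  n <- attr(lab, "n")
  if (n == 0L) return(mask)
  area <- tabulate(lab[lab > 0L], n)
  keep <- area >= min_area
  out <- mask
  out[!(lab > 0L & keep[pmax(lab, 1L)])] <- 0
  out
}
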