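# Two-stage orchestration: liver segmentation over windowed slices, then
# lesion segmentation inside the liver volume of interest, then
# reassembly into examination geometry.
#
# A "model" here is anything with a predict(img) -> probability-mask
# closure: a trained segmentation network, or an intensity oracle used to
# validate the pipeline plumbing independently of learning.

#' Default pipeline configuration
#'
#' @param side working slice side (training resolution).
#' @param window HU display/processing window.
#' @param rule fusion decision rule (see [fuse()]).
#' @param postprocess apply the region filters.
#' @param liver_dist_px,liver_area_ratio,lesion_min_area post-processing
#'   thresholds.
#' @param clahe_grid,clahe_clip CLAHE parameters for the lesion stage.
#' @return named list of settings.
#' @export
pipeline_config <- function(side = 256L, window = c(-250, 250),
                            rule = "threshold", postprocess = TRUE,
                            liver_dist_px = 200, liver_area_ratio = 8,
                            lesion_min_area = 10, clahe_grid = 8L,
                            clahe_clip = 0.01) {
  list(side = as.integer(side), window = window, rule = rule,
       postprocess = isTRUE(postprocess), liver_dist_px = liver_dist_px,
       liver_area_ratio = liver_area_ratio,
       lesion_min_area = lesion_min_area, clahe_grid = clahe_grid,
       clahe_clip = clahe_clip)
}

#' Wrap a segmentation network as a pipeline model
#'
#' The liver-stage input convention is the loader's: `[0, 1]` slices are
#' normalized to `[-1, 1]` before the network.
#'
#' @param net an `ls_segnet`.
#' @param id model identifier.
#' @return pipeline model (list with `predict` and `id`).
#' @export
make_network_model <- function(net, id = net$family) {
  list(predict = function(img) segnet_predict(net, normalize_slice(img)),
       id = id)
}

#' Intensity-band oracle model
#'
#' Marks pixels whose box-smoothed windowed intensity falls in a fixed
#' band and whose local standard deviation stays below `max_sd_hu`
#' (parenchyma is homogeneous; the homogeneity condition rejects
#' partial-volume edge rings around bright structures such as bone, whose
#' blurred boundary otherwise sweeps through any soft-tissue band). Used
#' to validate the pipeline plumbing (windowing, VOI, fusion, filters,
#' reassembly) independently of network training. The default band
#' 50..75 HU brackets liver parenchyma in the phantom's intensity regime.
#'
#' @param lo_hu,hi_hu band bounds in HU.
#' @param window the HU window the input slices were normalized with.
#' @param smooth box-filter half-width in pixels (0 disables).
#' @param max_sd_hu local standard-deviation ceiling in HU.
#' @param fill_holes fill enclosed holes in the detected region (the
#'   liver is simply connected; hypodense lesions fall outside any
#'   parenchyma band but belong to the liver mask).
#' @param id model identifier.
#' @return pipeline model.
#' @export
make_oracle_model <- function(lo_hu = 50, hi_hu = 75, window = c(-250, 250),
                              smooth = 2L, max_sd_hu = 25,
                              fill_holes = TRUE, id = "oracle") {
  lo <- (lo_hu - window[1L]) / diff(window)
  hi <- (hi_hu - window[1L]) / diff(window)
  max_sd <- max_sd_hu / diff(window)
  list(predict = function(img) {
    if (smooth > 0L) {
      m1 <- box_smooth(img, smooth)
      v <- pmax(box_smooth(img^2, smooth) - m1^2, 0)
      ok_sd <- sqrt(v) <= max_sd
      img <- m1
    } else {
      ok_sd <- TRUE
    }
    out <- (img >= lo & img <= hi & ok_sd) + 0
    if (fill_holes && any(out != 0)) {
      out <- as.matrix(EBImage::fillHull(out))
    }
    out
  }, id = id)
}

box_smooth <- function(img, half = 1L) {
  k <- 2L * half + 1L
  w <- array(1 / (k * k), c(k, k, 1L, 1L))
  out <- conv2d_fwd(array(img, c(dim(img), 1L)), w, NULL, 1L, 1L, "same",
                    1L)$out
  matrix(out, nrow(img), ncol(img))
}

#' Dark-blob oracle model for hypodense lesions
#'
#' Lesion-stage stand-in for trained networks in pipeline validation. The
#' lesion-stage input is mean-filled and CLAHE-enhanced, so absolute HU
#' bands no longer apply, but equalization standardizes the levels: the
#' oracle thresholds the lightly smoothed slice below a fixed dark level,
#' then applies a morphological opening (removing the thin dark halo the
#' bilinear crop-resize leaves along the liver boundary) and discards
#' components touching the crop border (the liver is tangent to its VOI,
#' so true lesions are always interior).
#'
#' @param dark_thr dark threshold in `[0, 1]` post-equalization units.
#' @param smooth box-filter half-width.
#' @param opening_radius disc radius for the opening.
#' @param id model identifier.
#' @return pipeline model.
#' @export
make_lesion_oracle_model <- function(dark_thr = 0.55, smooth = 1L,
                                     opening_radius = 4L,
                                     id = "lesion-oracle") {
  list(predict = function(img) {
    if (smooth > 0L) img <- box_smooth(img, smooth)
    cand <- (img < dark_thr) + 0
    if (opening_radius > 0L) {
      cand <- as.matrix(EBImage::opening(
        cand, EBImage::makeBrush(2L * opening_radius + 1L, "disc")))
    }
    lab <- label_components(cand)
    n <- attr(lab, "n")
    if (n == 0L) return(cand * 0)
    border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                       lab[, ncol(lab)]))
    keep <- setdiff(seq_len(n), border[border > 0L])
    out <- cand * 0
    out[matrix(lab %in% keep, nrow(lab))] <- 1
    out
  }, id = id)
}

new_stage_result <- function(masks, stage, postprocessed, voi = NULL) {
  structure(list(masks = masks, stage = stage,
                 postprocessed = postprocessed, voi = voi),
            class = "stage_result")
}

#' Run the liver segmentation stage
#'
#' Per slice: HU window and normalize, resize to the working side, four
#' model probability maps, binarize at 0.5, per-model region filtering,
#' weighted fusion, and a final region filtering pass on the fused mask.
#'
#' @param volume an `hu_volume`.
#' @param models list of 4 pipeline models ordered as
#'   [fusion_network_ids].
#' @param w fusion weight vector (or `fusion_weights`).
#' @param cfg a [pipeline_config()].
#' @return `stage_result` with one working-side binary mask per slice.
#' @export
run_liver_stage <- function(volume, models, w, cfg = pipeline_config()) {
  stopifnot(length(models) == 4L)
  if (inherits(w, "fusion_weights")) w <- w$w
  masks <- vector("list", volume$n_slices)
  for (k in seq_len(volume$n_slices)) {
    img <- window_and_normalize(volume$voxels[k, , ], cfg$window[1L],
                                cfg$window[2L])
    img <- resize_image(img, cfg$side, "continuous")
    cand <- lapply(models, function(m) (m$predict(img) >= 0.5) + 0)
    if (cfg$postprocess) {
      cand <- lapply(cand, filter_liver_regions, dist_px = cfg$liver_dist_px,
                     area_ratio = cfg$liver_area_ratio)
    }
    fused <- fuse(cand, w, rule = cfg$rule)
    if (cfg$postprocess) {
      fused <- filter_liver_regions(fused, dist_px = cfg$liver_dist_px,
                                    area_ratio = cfg$liver_area_ratio)
    }
    masks[[k]] <- fused
  }
  new_stage_result(masks, "liver", cfg$postprocess)
}

#' Run the lesion segmentation stage inside the liver VOI
#'
#' The liver mask is applied to the windowed volume, the liver volume of
#' interest is extracted and cropped slice-wise to the working side, each
#' slice is background-mean-filled and CLAHE-enhanced, the four models
#' are fused, and the minimum-area lesion filter is applied.
#'
#' @param volume the `hu_volume` examination.
#' @param liver a liver-stage `stage_result`, or a 3D binary array (e.g.
#'   reference masks when evaluating with ground-truth liver).
#' @param models list of 4 pipeline models.
#' @param w fusion weights.
#' @param cfg a [pipeline_config()].
#' @return `stage_result` with VOI recorded; empty masks and a warning
#'   when the liver mask is empty.
#' @export
run_lesion_stage <- function(volume, liver, models, w,
                             cfg = pipeline_config()) {
  stopifnot(length(models) == 4L)
  if (inherits(w, "fusion_weights")) w <- w$w
  mvol <- if (inherits(liver, "stage_result")) {
    reassemble_liver_mask(liver, dim(volume$voxels))
  } else liver
  if (!any(mvol != 0)) {
    warning("liver mask is empty; lesion stage returns no masks")
    return(new_stage_result(list(), "lesion", cfg$postprocess, voi = NULL))
  }
  win <- array(0, dim(volume$voxels))
  for (k in seq_len(volume$n_slices)) {
    win[k, , ] <- window_and_normalize(volume$voxels[k, , ],
                                       cfg$window[1L], cfg$window[2L])
  }
  masked <- win * (mvol != 0)
  voi <- find_voi(mvol)
  crops <- crop_voi_and_resize(masked, voi, cfg$side, "continuous")
  masks <- lapply(crops, function(img) {
    img <- clahe_enhance(fill_background_with_mean(img),
                         grid = cfg$clahe_grid,
                         clip_limit = cfg$clahe_clip)
    cand <- lapply(models, function(m) (m$predict(img) >= 0.5) + 0)
    fused <- fuse(cand, w, rule = cfg$rule)
    if (cfg$postprocess) {
      fused <- filter_lesion_regions(fused, min_area = cfg$lesion_min_area)
    }
    fused
  })
  new_stage_result(masks, "lesion", cfg$postprocess, voi = voi)
}

#' Reassemble liver-stage masks to examination geometry
#'
#' @param stage liver `stage_result`.
#' @param extents target (slice, row, col) extents.
#' @return 3D binary array.
#' @export
reassemble_liver_mask <- function(stage, extents) {
  stopifnot(length(stage$masks) == extents[1L])
  out <- array(0, extents)
  for (k in seq_along(stage$masks)) {
    out[k, , ] <- resize_rect(stage$masks[[k]], extents[2L], extents[3L],
                              "mask")
  }
  out
}

#' Reassemble lesion-stage masks to examination geometry
#'
#' Each working-side mask is resized (nearest neighbour) to the VOI
#' in-plane extents, placed at the VOI offset and zero-padded to the
#' original in-plane extents; all-zero slices are inserted before and
#' after the VOI slice range.
#'
#' @param stage lesion `stage_result` with a recorded VOI.
#' @param extents original (slice, row, col) extents.
#' @return 3D binary array with the original extents.
#' @export
reassemble_lesion_mask <- function(stage, extents) {
  out <- array(0, extents)
  voi <- stage$voi
  if (is.null(voi)) return(out)
  if (any(voi$hi > extents) || any(voi$lo < 0L)) {
    stop("VOI inconsistent with the requested extents")
  }
  rows <- (voi$lo[2L] + 1L):voi$hi[2L]
  cols <- (voi$lo[3L] + 1L):voi$hi[3L]
  slices <- (voi$lo[1L] + 1L):voi$hi[1L]
  stopifnot(length(slices) == length(stage$masks))
  for (i in seq_along(slices)) {
    out[slices[i], rows, cols] <- resize_rect(stage$masks[[i]],
                                              length(rows), length(cols),
                                              "mask")
  }
  out
}

#' Mask volume in millilitres
#'
#' @param mask 3D binary array.
#' @param spacing voxel spacing in mm.
#' @return volume in ml (`count * prod(spacing) / 1000`).
#' @export
volume_ml <- function(mask, spacing) {
  sum(mask != 0) * prod(spacing) / 1000
}

#' Segment an examination end to end
#'
#' Reads a NIfTI file or DICOM series directory, runs the liver and
#' lesion stages, reassembles both masks to examination geometry, writes
#' an RGB-overlay DICOM series plus NIfTI masks, and reports liver and
#' lesion (tumor burden) volumes in ml.
#'
#' @param input NIfTI path or DICOM directory.
#' @param bundle model bundle: list with `liver_models`, `lesion_models`
#'   (4 pipeline models each), `w_liver`, `w_lesion`.
#' @param out_dir output directory (created).
#' @param cfg a [pipeline_config()].
#' @return invisibly, list with `liver` and `lesion` 3D masks, the two
#'   volumes in ml and the output paths.
#' @export
segment_examination <- function(input, bundle, out_dir,
                                cfg = pipeline_config()) {
  need <- c("liver_models", "lesion_models", "w_liver", "w_lesion")
  if (!all(need %in% names(bundle))) {
    stop("incomplete model bundle; needs ", paste(need, collapse = ", "))
  }
  volume <- if (dir.exists(input)) {
    read_dicom_series(input)
  } else {
    read_nifti_volume(input)$volume
  }
  liver_stage <- run_liver_stage(volume, bundle$liver_models,
                                 bundle$w_liver, cfg)
  liver3d <- reassemble_liver_mask(liver_stage, dim(volume$voxels))
  lesion_stage <- run_lesion_stage(volume, liver_stage,
                                   bundle$lesion_models, bundle$w_lesion,
                                   cfg)
  lesion3d <- reassemble_lesion_mask(lesion_stage, dim(volume$voxels))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  overlay <- write_dicom_overlay(volume, liver3d, lesion3d,
                                 file.path(out_dir, "overlay"),
                                 window = cfg$window)
  write_nifti_volume(hu_volume(liver3d, volume$spacing),
                     file.path(out_dir, "liver_mask.nii.gz"))
  write_nifti_volume(hu_volume(lesion3d, volume$spacing),
                     file.path(out_dir, "lesion_mask.nii.gz"))
  res <- list(liver = liver3d, lesion = lesion3d,
              liver_ml = volume_ml(liver3d, volume$spacing),
              lesion_ml = volume_ml(lesion3d, volume$spacing),
              overlay_files = overlay, out_dir = out_dir)
  message(sprintf("liver volume %.1f ml, tumor burden %.1f ml",
                  res$liver_ml, res$lesion_ml))
  invisible(res)
}

#' Oracle model bundle for pipeline validation
#'
#' Four intensity-band oracles for the liver stage and four dark-blob
#' oracles for the lesion stage, with equal fusion weights. The four
#' members of each stage use slightly different bands/thresholds so their
#' errors do not coincide and the 2-of-4 fusion vote has something to
#' cancel. Validates windowing, VOI handling, fusion and post-processing
#' independently of trained networks.
#'
#' @return a model bundle for [segment_examination()].
#' @export
oracle_bundle <- function() {
  lo <- c(50, 51, 52, 50)
  hi <- c(75, 73, 77, 76)
  dk <- c(0.55, 0.53, 0.57, 0.55)
  op <- c(4L, 4L, 3L, 4L)
  list(liver_models = lapply(1:4, function(i) {
         make_oracle_model(lo[i], hi[i], id = fusion_network_ids[i])
       }),
       lesion_models = lapply(1:4, function(i) {
         make_lesion_oracle_model(dark_thr = dk[i], opening_radius = op[i],
                                  id = fusion_network_ids[i])
       }),
       w_liver = rep(0.25, 4L), w_lesion = rep(0.25, 4L))
}
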