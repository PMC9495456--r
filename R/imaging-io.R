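# Examination I/O: NIfTI volumes and DICOM series into HU volumes,
# per-slice raw storage, and RGB-overlay DICOM output.

#' Construct an HU volume
#'
#' A 3D grid of Hounsfield-unit values indexed (slice, row, col) with
#' voxel spacing in mm and a pass-through metadata store.
#'
#' @param voxels 3D numeric array (slice, row, col).
#' @param spacing length-3 positive numeric (mm per voxel along slice,
#'   row, col).
#' @param meta named list of header fields carried through to output.
#' @return object of class `hu_volume`.
#' @export
hu_volume <- function(voxels, spacing = c(1, 1, 1), meta = list()) {
  stopifnot(length(dim(voxels)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 n_slices = dim(voxels)[1L], n_rows = dim(voxels)[2L],
                 n_cols = dim(voxels)[3L], meta = meta),
            class = "hu_volume")
}

#' @export
print.hu_volume <- function(x, ...) {
  cat(sprintf("HU volume: %d slices of %dx%d, spacing %.2fx%.2fx%.2f mm, HU range [%.0f, %.0f]\n",
              x$n_slices, x$n_rows, x$n_cols, x$spacing[1L], x$spacing[2L],
              x$spacing[3L], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct a label volume aligned with an HU volume
#'
#' Labels follow the LiTS convention: 0 background, 1 liver, 2 lesion.
#' The liver-stage ground truth is `labels >= 1`; the lesion-stage ground
#' truth is `labels == 2`.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param volume optional `hu_volume` to validate extents against.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, volume = NULL) {
  stopifnot(length(dim(labels)) == 3L)
  if (!all(labels %in% c(0, 1, 2))) stop("labels must be in {0, 1, 2}")
  if (!is.null(volume) && !all(dim(labels) == dim(volume$voxels))) {
    stop("label extents do not match the HU volume")
  }
  structure(list(labels = labels), class = "label_volume")
}

# slice axis choice: from the affine when available, else the axis with
# the largest spacing
nifti_slice_axis <- function(img) {
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && is.matrix(xf) && !all(xf[1:3, 1:3] == 0)) {
    return(which.max(abs(xf[3L, 1:3])))
  }
  which.max(RNifti::pixdim(img)[1:3])
}

#' Read a NIfTI examination (and optional label volume)
#'
#' The voxel grid is re-oriented so axis 1 is the axial slice axis (taken
#' from the affine when present, else the axis with the largest spacing).
#'
#' @param path NIfTI file (.nii / .nii.gz).
#' @param label_path optional companion segmentation NIfTI.
#' @return list with `volume` (an `hu_volume`) and `labels` (a
#'   `label_volume` or NULL).
#' @export
read_nifti_volume <- function(path, label_path = NULL) {
  img <- RNifti::readNifti(path)
  ax <- nifti_slice_axis(img)
  perm <- c(ax, setdiff(1:3, ax))
  vox <- aperm(array(as.numeric(img), dim(img)[1:3]), perm)
  sp <- RNifti::pixdim(img)[1:3][perm]
  vol <- hu_volume(vox, sp, meta = list(source = path))
  labs <- NULL
  if (!is.null(label_path)) {
    limg <- RNifti::readNifti(label_path)
    if (!all(dim(limg)[1:3] == dim(img)[1:3])) {
      stop("label volume extents differ from the image volume")
    }
    labs <- label_volume(aperm(array(as.numeric(limg), dim(limg)[1:3]), perm),
                         vol)
  }
  list(volume = vol, labels = labs)
}

#' Write an HU volume (and optional labels) as NIfTI
#'
#' @param volume an `hu_volume`.
#' @param path output image path (.nii or .nii.gz).
#' @param labels optional `label_volume`.
#' @param label_path output label path (required with `labels`).
#' @return invisibly, the image path.
#' @export
write_nifti_volume <- function(volume, path, labels = NULL,
                               label_path = NULL) {
  # store as (row, col, slice) so the slice axis is the NIfTI z axis
  arr <- aperm(volume$voxels, c(2L, 3L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- volume$spacing[c(2L, 3L, 1L)]
  RNifti::writeNifti(img, path)
  if (!is.null(labels)) {
    stopifnot(!is.null(label_path))
    limg <- RNifti::asNifti(aperm(labels$labels, c(2L, 3L, 1L)))
    RNifti::pixdim(limg) <- volume$spacing[c(2L, 3L, 1L)]
    RNifti::writeNifti(limg, label_path)
  }
  invisible(path)
}

#' Read a DICOM series directory into an HU volume
#'
#' Files are ordered alphabetically (the series order convention); the
#' modality LUT (rescale slope/intercept) is applied so voxels are in HU.
#'
#' @param dir directory containing one series of single-slice DICOM
#'   files.
#' @return an `hu_volume` with spacing from PixelSpacing /
#'   SliceThickness.
#' @export
read_dicom_series <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE,
                           pattern = "\\.dcm$", ignore.case = TRUE))
  if (length(files) == 0L) {
    files <- sort(list.files(dir, full.names = TRUE))
  }
  if (length(files) == 0L) stop("no DICOM files in ", dir)
  slices <- vector("list", length(files))
  rows <- cols <- NULL
  spacing <- c(1, 1, 1)
  series_number <- 1L
  for (k in seq_along(files)) {
    el <- read_dicom_file(files[k])
    r <- dcm_u16v(el[["0028,0010"]])
    c_ <- dcm_u16v(el[["0028,0011"]])
    if (is.null(rows)) { rows <- r; cols <- c_ }
    if (r != rows || c_ != cols) {
      stop("inconsistent slice extents in series: ", files[k])
    }
    slope <- dcm_numbers(el[["0028,1053"]]); if (is.null(slope)) slope <- 1
    inter <- dcm_numbers(el[["0028,1052"]]); if (is.null(inter)) inter <- 0
    ps <- dcm_numbers(el[["0028,0030"]])
    if (!is.null(ps)) spacing[2:3] <- ps
    st <- dcm_numbers(el[["0018,0050"]])
    if (!is.null(st)) spacing[1L] <- st
    sn <- dcm_string(el[["0020,0011"]])
    if (!is.null(sn)) series_number <- as.integer(sn)
    pix <- el[["7FE0,0010"]]
    if (is.null(pix)) stop("no pixel data in ", files[k])
    v <- readBin(pix$raw, "integer", n = rows * cols, size = 2L,
                 signed = TRUE, endian = "little")
    # pixel data is row-major; fill a matrix by row
    slices[[k]] <- matrix(v * slope + inter, rows, cols, byrow = TRUE)
  }
  vox <- array(0, c(length(files), rows, cols))
  for (k in seq_along(slices)) vox[k, , ] <- slices[[k]]
  hu_volume(vox, spacing,
            meta = list(source = dir, series_number = series_number))
}

#' Write an HU volume as a grayscale CT DICOM series
#'
#' One Explicit-VR-Little-Endian file per slice, int16 stored values with
#' rescale intercept -1024 / slope 1, filenames sorting in slice order.
#'
#' @param volume an `hu_volume`.
#' @param dir output directory (created).
#' @param series_number series number tag value.
#' @return invisibly, the file paths.
#' @export
write_dicom_series <- function(volume, dir, series_number = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(volume$n_slices)
  for (k in seq_len(volume$n_slices)) {
    stored <- round(t(volume$voxels[k, , ])) + 1024  # row-major packing
    stored <- pmin(pmax(stored, -32768), 32767)
    sop <- dcm_uid(sprintf("%d.%d", series_number, k))
    els <- ct_slice_elements(as.vector(stored), volume$n_rows,
                             volume$n_cols, slope = 1, intercept = -1024,
                             pixel_spacing = volume$spacing[2:3],
                             slice_thickness = volume$spacing[1L],
                             series_number = series_number,
                             instance_number = k, sop_instance = sop)
    paths[k] <- file.path(dir, sprintf("slice_%04d.dcm", k))
    write_dicom_file(paths[k], els, sop_class = DCM_CT_SOP,
                     sop_instance = sop)
  }
  invisible(paths)
}

#' Write an RGB-overlay DICOM series of segmentation results
#'
#' Each slice is windowed for display, replicated to three channels, and
#' alpha-composited with the masks: liver green, lesion red, both at
#' alpha 0.3 (`out = 0.7 * gray + 0.3 * color` on mask pixels; the lesion
#' blend is applied after the liver blend). Tags are set for RGB viewing:
#' PhotometricInterpretation RGB, SamplesPerPixel 3, 8-bit samples with
#' HighBit 7, and a SeriesNumber incremented relative to the source.
#'
#' @param source the source `hu_volume`.
#' @param liver binary 3D array aligned with the source.
#' @param lesion binary 3D array aligned with the source.
#' @param dir output directory.
#' @param window display window in HU (lo, hi).
#' @return invisibly, the file paths.
#' @export
write_dicom_overlay <- function(source, liver, lesion, dir,
                                window = c(-250, 250)) {
  if (!all(dim(liver) == dim(source$voxels)) ||
      !all(dim(lesion) == dim(source$voxels))) {
    stop("mask extents differ from the source volume")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sn <- source$meta$series_number
  if (is.null(sn)) sn <- 1L
  out_sn <- as.integer(sn) + 1L
  alpha <- 0.3
  paths <- character(source$n_slices)
  for (k in seq_len(source$n_slices)) {
    g <- window_and_normalize(source$voxels[k, , ], window[1L], window[2L])
    rch <- g; gch <- g; bch <- g
    lv <- liver[k, , ] != 0
    rch[lv] <- (1 - alpha) * rch[lv]
    gch[lv] <- (1 - alpha) * gch[lv] + alpha
    bch[lv] <- (1 - alpha) * bch[lv]
    ls <- lesion[k, , ] != 0
    rch[ls] <- (1 - alpha) * rch[ls] + alpha
    gch[ls] <- (1 - alpha) * gch[ls]
    bch[ls] <- (1 - alpha) * bch[ls]
    # interleave R,G,B per pixel in row-major order
    px <- rbind(as.vector(t(rch)), as.vector(t(gch)), as.vector(t(bch)))
    pix_raw <- as.raw(pmin(pmax(round(px * 255), 0), 255))
    sop <- dcm_uid(sprintf("%d.%d", out_sn, k))
    els <- list(
      list(group = 0x0008L, elem = 0x0016L, vr = "UI", value = DCM_SC_SOP),
      list(group = 0x0008L, elem = 0x0018L, vr = "UI", value = sop),
      list(group = 0x0008L, elem = 0x0060L, vr = "CS", value = "OT"),
      list(group = 0x0018L, elem = 0x0050L, vr = "DS",
           value = format(source$spacing[1L])),
      list(group = 0x0020L, elem = 0x0011L, vr = "IS",
           value = format(out_sn)),
      list(group = 0x0020L, elem = 0x0013L, vr = "IS", value = format(k)),
      list(group = 0x0028L, elem = 0x0002L, vr = "US", value = 3L),
      list(group = 0x0028L, elem = 0x0004L, vr = "CS", value = "RGB"),
      list(group = 0x0028L, elem = 0x0006L, vr = "US", value = 0L),
      list(group = 0x0028L, elem = 0x0010L, vr = "US",
           value = source$n_rows),
      list(group = 0x0028L, elem = 0x0011L, vr = "US",
           value = source$n_cols),
      list(group = 0x0028L, elem = 0x0030L, vr = "DS",
           value = paste(format(source$spacing[2:3]), collapse = "\\")),
      list(group = 0x0028L, elem = 0x0100L, vr = "US", value = 8L),
      list(group = 0x0028L, elem = 0x0101L, vr = "US", value = 8L),
      list(group = 0x0028L, elem = 0x0102L, vr = "US", value = 7L),
      list(group = 0x0028L, elem = 0x0103L, vr = "US", value = 0L),
      list(group = 0x7FE0L, elem = 0x0010L, vr = "OB", value = pix_raw))
    paths[k] <- file.path(dir, sprintf("overlay_%04d.dcm", k))
    write_dicom_file(paths[k], els, sop_class = DCM_SC_SOP,
                     sop_instance = sop)
  }
  invisible(paths)
}

# ---- per-slice raw storage ---------------------------------------------

#' Write pre-processed slices and masks as a per-slice raw store
#'
#' One little-endian float32 file per image slice under `images/` and one
#' per mask slice under `masks/`, named `<volume_id>_<0000k>.raw` so
#' alphabetical order is slice order, plus a JSON manifest with the
#' extents. Slices are individually loadable without the volume.
#'
#' @param images 3D array (slice, side, side) of `[0, 1]` values, or list
#'   of matrices.
#' @param masks matching binary slices.
#' @param out_dir store root directory.
#' @param volume_id identifier used in file names.
#' @return number of slices written.
#' @export
write_slice_store <- function(images, masks, out_dir, volume_id = "vol") {
  if (is.array(images) && length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[1L]), function(k) images[k, , ])
  }
  if (is.array(masks) && length(dim(masks)) == 3L) {
    masks <- lapply(seq_len(dim(masks)[1L]), function(k) masks[k, , ])
  }
  stopifnot(length(images) == length(masks), length(images) > 0L)
  side <- nrow(images[[1L]])
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (k in seq_along(images)) {
    nm <- sprintf("%s_%05d.raw", volume_id, k)
    writeBin(as.numeric(images[[k]]), file.path(out_dir, "images", nm),
             size = 4L, endian = "little")
    writeBin(as.numeric(masks[[k]] != 0), file.path(out_dir, "masks", nm),
             size = 4L, endian = "little")
  }
  manifest <- list(side = side, dtype = "float32le",
                   volumes = list(list(id = volume_id,
                                       n_slices = length(images))))
  mf <- file.path(out_dir, "manifest.json")
  if (file.exists(mf)) {
    old <- jsonlite::read_json(mf)
    stopifnot(old$side == side)
    manifest$volumes <- c(old$volumes, manifest$volumes)
  }
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  length(images)
}

#' Open a slice store for reading
#'
#' @param dir store root containing `images/`, `masks/` and
#'   `manifest.json`.
#' @return list with `side`, sorted `image_files` and `mask_files`, and
#'   slice count `n`.
#' @export
open_slice_store <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  imgs <- sort(list.files(file.path(dir, "images"), full.names = TRUE))
  msks <- sort(list.files(file.path(dir, "masks"), full.names = TRUE))
  stopifnot(length(imgs) == length(msks), length(imgs) > 0L)
  list(side = manifest$side, image_files = imgs, mask_files = msks,
       n = length(imgs))
}

#' Load one slice (image and mask) from a store
#'
#' @param store handle from [open_slice_store()].
#' @param k slice index in alphabetical file order.
#' @return list with `image` and `mask` matrices.
#' @export
read_slice <- function(store, k) {
  side <- store$side
  rd <- function(path) {
    n <- file.info(path)$size / 4L
    if (n != side * side) {
      stop("slice file ", path, " has ", n, " values, expected ",
           side * side)
    }
    matrix(readBin(path, "numeric", n = n, size = 4L, endian = "little"),
           side, side)
  }
  list(image = rd(store$image_files[[k]]), mask = rd(store$mask_files[[k]]))
}
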