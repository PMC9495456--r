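# Minimal DICOM codec: uncompressed, single-frame, Explicit VR Little
# Endian (reading also tolerates Implicit VR LE). Covers exactly what the
# pipeline needs — CT slice series in and RGB overlay series out — not
# the general standard (no sequences-of-interest, no compressed transfer
# syntaxes, no multi-frame objects).

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
DCM_IMPLICIT_LE <- "1.2.840.10008.1.2"
DCM_CT_SOP <- "1.2.840.10008.5.1.4.1.1.2"
DCM_SC_SOP <- "1.2.840.10008.5.1.4.1.1.7"
LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- function(suffix) {
  # private test root; uniqueness within a run is all that is required
  paste0("1.2.826.0.1.3680043.9.7435.", suffix)
}

pad_even <- function(r, pad = as.raw(0L)) {
  if (length(r) %% 2L == 1L) c(r, pad) else r
}

enc_value <- function(vr, value) {
  if (vr %in% c("US")) {
    writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr %in% c("UL")) {
    writeBin(as.integer(value), raw(), size = 4L, endian = "little")
  } else if (vr %in% c("SS")) {
    writeBin(as.integer(value), raw(), size = 2L, endian = "little")
  } else if (vr %in% c("OB", "OW")) {
    value  # already raw
  } else if (vr == "UI") {
    pad_even(charToRaw(paste(value, collapse = "\\")))
  } else {
    pad_even(charToRaw(paste(value, collapse = "\\")), charToRaw(" "))
  }
}

enc_element <- function(group, elem, vr, value) {
  val <- enc_value(vr, value)
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2L,
                  endian = "little")
  if (vr %in% LONG_VRS) {
    c(hdr, charToRaw(vr), raw(2L),
      writeBin(length(val), raw(), size = 4L, endian = "little"), val)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(val), raw(), size = 2L, endian = "little"), val)
  }
}

# elements: list of list(group, elem, vr, value); must be presorted
write_dicom_file <- function(path, elements, sop_class = DCM_CT_SOP,
                             sop_instance = dcm_uid("0.0")) {
  meta <- c(
    enc_element(0x0002L, 0x0002L, "UI", sop_class),
    enc_element(0x0002L, 0x0003L, "UI", sop_instance),
    enc_element(0x0002L, 0x0010L, "UI", DCM_EXPLICIT_LE))
  meta <- c(enc_element(0x0002L, 0x0000L, "UL", length(meta)), meta)
  body <- unlist(lapply(elements, function(e) {
    enc_element(e$group, e$elem, e$vr, e$value)
  }), use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

dec_u16 <- function(r, off) {
  readBin(r[(off + 1L):(off + 2L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
dec_u32 <- function(r, off) {
  readBin(r[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "little")
}

# Parse a single-frame DICOM file into a tag-keyed list. Values of string
# VRs are returned as character, US/UL/SS as integers, pixel data as raw.
read_dicom_file <- function(path) {
  r <- readBin(path, "raw", n = file.info(path)$size)
  off <- 0L
  explicit <- TRUE
  if (length(r) > 132L && rawToChar(r[129:132]) == "DICM") {
    off <- 132L
    # walk group-0002 meta (always explicit VR) and note transfer syntax
    ts <- DCM_EXPLICIT_LE
    while (off + 8L <= length(r) && dec_u16(r, off) == 0x0002L) {
      elem <- dec_u16(r, off + 2L)
      vr <- rawToChar(r[(off + 5L):(off + 6L)])
      if (vr %in% LONG_VRS) {
        len <- dec_u32(r, off + 8L); voff <- off + 12L
      } else {
        len <- dec_u16(r, off + 6L); voff <- off + 8L
      }
      if (elem == 0x0010L) {
        ts <- raw_to_string(r[(voff + 1L):(voff + len)])
      }
      off <- voff + len
    }
    explicit <- !identical(ts, DCM_IMPLICIT_LE)
  }
  out <- list()
  while (off + 8L <= length(r)) {
    group <- dec_u16(r, off)
    elem <- dec_u16(r, off + 2L)
    if (explicit) {
      vr <- rawToChar(r[(off + 5L):(off + 6L)])
      if (vr %in% LONG_VRS) {
        len <- dec_u32(r, off + 8L); voff <- off + 12L
      } else {
        len <- dec_u16(r, off + 6L); voff <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- dec_u32(r, off + 4L); voff <- off + 8L
    }
    if (len < 0L || voff + len > length(r)) {
      stop("corrupt DICOM element at offset ", off, " in ", path)
    }
    val <- r[seq.int(voff + 1L, length.out = len)]
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- list(vr = vr, raw = val)
    off <- voff + len
  }
  out
}

# decode a string value, dropping NUL/space padding
raw_to_string <- function(r) {
  r <- r[r != as.raw(0L)]
  sub("[ ]+$", "", rawToChar(r))
}

dcm_string <- function(el) {
  if (is.null(el)) return(NULL)
  raw_to_string(el$raw)
}
dcm_numbers <- function(el) {
  if (is.null(el)) return(NULL)
  as.numeric(strsplit(dcm_string(el), "\\\\")[[1L]])
}
dcm_u16v <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

# standard CT slice element list (grayscale int16 + modality LUT)
ct_slice_elements <- function(pixels_int16, rows, cols, slope, intercept,
                              pixel_spacing, slice_thickness, series_number,
                              instance_number, sop_instance) {
  pix <- writeBin(as.integer(pixels_int16), raw(), size = 2L,
                  endian = "little")
  list(
    list(group = 0x0008L, elem = 0x0016L, vr = "UI", value = DCM_CT_SOP),
    list(group = 0x0008L, elem = 0x0018L, vr = "UI", value = sop_instance),
    list(group = 0x0008L, elem = 0x0060L, vr = "CS", value = "CT"),
    list(group = 0x0018L, elem = 0x0050L, vr = "DS",
         value = format(slice_thickness)),
    list(group = 0x0020L, elem = 0x0011L, vr = "IS",
         value = format(series_number)),
    list(group = 0x0020L, elem = 0x0013L, vr = "IS",
         value = format(instance_number)),
    list(group = 0x0028L, elem = 0x0002L, vr = "US", value = 1L),
    list(group = 0x0028L, elem = 0x0004L, vr = "CS", value = "MONOCHROME2"),
    list(group = 0x0028L, elem = 0x0010L, vr = "US", value = rows),
    list(group = 0x0028L, elem = 0x0011L, vr = "US", value = cols),
    list(group = 0x0028L, elem = 0x0030L, vr = "DS",
         value = paste(format(pixel_spacing), collapse = "\\")),
    list(group = 0x0028L, elem = 0x0100L, vr = "US", value = 16L),
    list(group = 0x0028L, elem = 0x0101L, vr = "US", value = 16L),
    list(group = 0x0028L, elem = 0x0102L, vr = "US", value = 15L),
    list(group = 0x0028L, elem = 0x0103L, vr = "US", value = 1L),
    list(group = 0x0028L, elem = 0x1052L, vr = "DS",
         value = format(intercept)),
    list(group = 0x0028L, elem = 0x1053L, vr = "DS", value = format(slope)),
    list(group = 0x7FE0L, elem = 0x0010L, vr = "OW", value = pix))
}
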