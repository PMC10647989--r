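## Minimal DICOM RTDOSE reader: implicit and explicit VR little endian,
## uncompressed pixel data, axis-aligned orientation. Only the data elements
## an RTDOSE grid needs are decoded; everything else (including sequences)
## is skipped structurally.

.u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

.u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

.EXPLICIT_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UT", "UN", "UC", "UR")

## Parse one element header at pos; returns list(group, element, vr, len,
## data_pos, next_pos). len of -1 marks undefined length.
.dcm_header <- function(raw, pos, explicit) {
  group <- .u16(raw, pos)
  element <- .u16(raw, pos + 2L)
  if (group == 0xFFFEL) {  # item / delimiter tags: always implicit format
    len <- .u32(raw, pos + 4L)
    if (len == 4294967295) len <- -1
    return(list(group = group, element = element, vr = "", len = len,
                data_pos = pos + 8L))
  }
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% .EXPLICIT_LONG_VRS) {
      len <- .u32(raw, pos + 8L)
      data_pos <- pos + 12L
    } else {
      len <- .u16(raw, pos + 6L)
      data_pos <- pos + 8L
    }
  } else {
    vr <- ""
    len <- .u32(raw, pos + 4L)
    data_pos <- pos + 8L
  }
  if (len == 4294967295) len <- -1
  list(group = group, element = element, vr = vr, len = len,
       data_pos = data_pos)
}

## Skip over an undefined-length sequence/item body; returns position after
## the matching delimiter.
.dcm_skip_undefined <- function(raw, pos, explicit) {
  repeat {
    if (pos + 7L > length(raw)) stop("truncated DICOM sequence")
    h <- .dcm_header(raw, pos, explicit)
    if (h$group == 0xFFFEL && h$element %in% c(0xE00DL, 0xE0DDL))
      return(h$data_pos)  # item/sequence delimitation item (zero length)
    if (h$len < 0) pos <- .dcm_skip_undefined(raw, h$data_pos, explicit)
    else pos <- h$data_pos + h$len
  }
}

.dcm_str <- function(raw, h) {
  if (h$len <= 0) return("")
  b <- raw[h$data_pos:(h$data_pos + h$len - 1L)]
  b <- b[b != as.raw(0L)]  # UI values are NUL-padded
  trimws(rawToChar(b))
}

.dcm_ds <- function(raw, h) {
  s <- .dcm_str(raw, h)
  if (!nzchar(s)) return(numeric())
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us <- function(raw, h) .u16(raw, h$data_pos)

#' Read a DICOM RTDOSE file
#'
#' Supports implicit and explicit VR little endian transfer syntaxes with
#' uncompressed 16- or 32-bit pixel data and identity (axis-aligned)
#' ImageOrientationPatient. Stored values are scaled by DoseGridScaling; the
#' returned grid is in Gy with spacing (column, row, slice) in mm and origin
#' at ImagePositionPatient offset by the first GridFrameOffsetVector entry.
#' The isocenter defaults to the grid center (RTDOSE stores none); use
#' [loadDoseGrid()] with \code{isocenterOverride} to set it.
#'
#' @param path file path.
#' @return a [DoseGrid-class].
#' @export
readDicomDose <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)

  ## file meta group (0002,xxxx): always explicit little endian
  pos <- 133L
  transfer_syntax <- "1.2.840.10008.1.2.1"
  while (pos + 7L <= length(raw)) {
    h <- .dcm_header(raw, pos, explicit = TRUE)
    if (h$group != 2L) break
    if (h$element == 0x0010L) transfer_syntax <- .dcm_str(raw, h)
    pos <- h$data_pos + h$len
  }
  explicit <- switch(transfer_syntax,
    "1.2.840.10008.1.2" = FALSE,
    "1.2.840.10008.1.2.1" = TRUE,
    stop("unsupported DICOM transfer syntax: ", transfer_syntax))

  tags <- new.env(parent = emptyenv())
  pixel <- NULL
  while (pos + 7L <= length(raw)) {
    h <- .dcm_header(raw, pos, explicit)
    key <- sprintf("%04X%04X", h$group, h$element)
    if (h$len < 0) {
      pos <- .dcm_skip_undefined(raw, h$data_pos, explicit)
      next
    }
    if (key %in% c("00080060", "30040002")) assign(key, .dcm_str(raw, h), tags)
    else if (key %in% c("00280030", "00200032", "00200037",
                        "3004000C", "3004000E"))
      assign(key, .dcm_ds(raw, h), tags)
    else if (key %in% c("00280010", "00280011", "00280100", "00280103"))
      assign(key, .dcm_us(raw, h), tags)
    else if (key == "00280008")  # NumberOfFrames is IS (string)
      assign(key, as.integer(.dcm_str(raw, h)), tags)
    else if (key == "7FE00010")
      pixel <- raw[h$data_pos:(h$data_pos + h$len - 1L)]
    pos <- h$data_pos + h$len
  }

  get_tag <- function(key, what) {
    if (!exists(key, tags)) stop("DICOM RTDOSE missing required element: ", what)
    get(key, tags)
  }

  modality <- get_tag("00080060", "Modality")
  if (!identical(modality, "DOSE"))
    stop("not an RTDOSE object (Modality is '", modality, "')")
  if (exists("30040002", tags) && !identical(get("30040002", tags), "GY"))
    warning("DoseUnits is not GY; values passed through unscaled to Gy",
            call. = FALSE)

  rows <- get_tag("00280010", "Rows")
  cols <- get_tag("00280011", "Columns")
  frames <- if (exists("00280008", tags)) get("00280008", tags) else 1L
  bits <- get_tag("00280100", "BitsAllocated")
  ps <- get_tag("00280030", "PixelSpacing")          # (row, col) spacing
  ipp <- get_tag("00200032", "ImagePositionPatient")
  gfov <- get_tag("3004000C", "GridFrameOffsetVector")
  scaling <- get_tag("3004000E", "DoseGridScaling")
  if (length(ps) != 2L || length(ipp) != 3L)
    stop("DICOM RTDOSE has malformed spatial metadata")
  iop <- if (exists("00200037", tags)) get("00200037", tags) else c(1, 0, 0, 0, 1, 0)
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
    stop("unsupported ImageOrientationPatient (only axis-aligned identity)")

  if (length(gfov) != frames)
    stop("GridFrameOffsetVector length does not match NumberOfFrames")
  dz <- if (frames > 1L) diff(gfov) else 1
  if (frames > 2L && (max(dz) - min(dz)) > 1e-3)
    stop("non-uniform slice spacing beyond 1e-3 mm in GridFrameOffsetVector")
  slice_spacing <- if (frames > 1L) mean(dz) else 1

  if (is.null(pixel)) stop("DICOM RTDOSE missing PixelData")
  n_vox <- as.numeric(rows) * cols * frames
  if (bits == 16L) {
    stored <- readBin(pixel, "integer", n = n_vox, size = 2L,
                      signed = FALSE, endian = "little")
  } else if (bits == 32L) {
    stored <- readBin(pixel, "integer", n = n_vox, size = 4L,
                      signed = TRUE, endian = "little")
    stored <- as.numeric(stored)
    stored[stored < 0] <- stored[stored < 0] + 4294967296
  } else stop("unsupported BitsAllocated: ", bits)
  if (length(stored) < n_vox) stop("PixelData shorter than Rows*Columns*Frames")

  ## stored order: column fastest, then row, then frame -> dim (x, y, z)
  values <- array(stored * scaling, dim = c(cols, rows, frames))
  DoseGrid(values,
           spacing = c(ps[2], ps[1], slice_spacing),
           origin = c(ipp[1], ipp[2], ipp[3] + gfov[1]))
}
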