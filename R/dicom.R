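# Minimal DICOM reader for the RTDOSE / RTSTRUCT subset this package maps
# onto its internal types. Explicit-VR little-endian only; read-only.
#
# DICOM patient axes are LPS (x to the patient's left, y posterior, z
# superior); the package's axes are x = left-right, y = inferior-superior,
# z = anterior-posterior (anterior positive). The conversion, applied and
# logged at this boundary, is: internal (x, y, z) = patient (x, z, -y).

.u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
.u32 <- function(raw, off) {
  b <- as.numeric(raw[off + (1:4)])
  b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
}

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one element starting at offset `off` (0-based). Returns list(tag,
# value, next_off). Sequences recurse into lists of item datasets.
.parse_element <- function(raw, off) {
  group <- .u16(raw, off); elem <- .u16(raw, off + 2)
  tag <- sprintf("%04X,%04X", group, elem)
  if (group == 0xFFFE) {             # item / delimiter: implicit structure
    len <- .u32(raw, off + 4)
    return(list(tag = tag, len = len, next_off = off + 8))
  }
  vr <- rawToChar(raw[off + (5:6)])
  if (vr %in% .LONG_VRS) {
    len <- .u32(raw, off + 8)
    hdr <- 12L
  } else {
    len <- .u16(raw, off + 6)
    hdr <- 8L
  }
  body_off <- off + hdr
  if (vr == "SQ") {
    items <- list()
    if (len == 4294967295) {         # undefined length
      pos <- body_off
      repeat {
        it <- .parse_element(raw, pos)
        if (it$tag == "FFFE,E0DD") { pos <- it$next_off; break }
        if (it$tag != "FFFE,E000") stop("malformed sequence item")
        parsed <- .parse_item(raw, it$next_off, it$len)
        items[[length(items) + 1L]] <- parsed$dataset
        pos <- parsed$next_off
      }
      return(list(tag = tag, value = items, vr = vr, next_off = pos))
    }
    pos <- body_off
    end <- body_off + len
    while (pos < end) {
      it <- .parse_element(raw, pos)
      if (it$tag != "FFFE,E000") stop("malformed sequence item")
      parsed <- .parse_item(raw, it$next_off, it$len)
      items[[length(items) + 1L]] <- parsed$dataset
      pos <- parsed$next_off
    }
    return(list(tag = tag, value = items, vr = vr, next_off = end))
  }
  body <- raw[body_off + seq_len(len)]
  value <- switch(vr,
    US = vapply(seq_len(len / 2) - 1L, function(i) .u16(body, 2L * i),
                integer(1)),
    UL = vapply(seq_len(len / 4) - 1L, function(i) .u32(body, 4L * i),
                numeric(1)),
    OB = , OW = , UN = body,
    {                                # string VRs (DS, IS, LO, CS, UI, SH, PN...)
      s <- rawToChar(body)
      trimws(strsplit(s, "\\", fixed = TRUE)[[1]])
    })
  list(tag = tag, value = value, vr = vr, next_off = body_off + len)
}

.parse_item <- function(raw, off, len) {
  if (len == 4294967295) {           # undefined item length
    ds <- list(); pos <- off
    repeat {
      el <- .parse_element(raw, pos)
      if (el$tag == "FFFE,E00D") { pos <- el$next_off; break }
      ds[[el$tag]] <- el$value
      pos <- el$next_off
    }
    list(dataset = ds, next_off = pos)
  } else {
    list(dataset = .parse_dataset(raw, off, off + len), next_off = off + len)
  }
}

.parse_dataset <- function(raw, off, end) {
  ds <- list(); pos <- off
  while (pos < end) {
    el <- .parse_element(raw, pos)
    ds[[el$tag]] <- el$value
    pos <- el$next_off
  }
  ds
}

# Read a DICOM file into a flat named list keyed "GGGG,EEEE".
.read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  off <- 0L
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") off <- 132L
  ds <- .parse_dataset(raw, off, length(raw))
  ts <- ds[["0002,0010"]]
  if (!is.null(ts) && !identical(ts, "1.2.840.10008.1.2.1"))
    stop(sprintf("unsupported transfer syntax '%s' (explicit VR little endian only)",
                 ts))
  ds
}

.ds_num <- function(ds, tag, what = tag) {
  v <- ds[[tag]]
  if (is.null(v)) stop(sprintf("DICOM element %s (%s) is missing", tag, what))
  as.numeric(v)
}

.decode_pixels <- function(raw, bits, signed) {
  size <- bits / 8
  n <- length(raw) / size
  v <- readBin(raw, integer(), n = n, size = size, endian = "little",
               signed = if (size == 2) signed else TRUE)
  if (!signed && size == 2 && any(v < 0)) v <- v + 65536  # paranoia; readBin handles
  v
}

#' Read DICOM RTDOSE and RTSTRUCT files
#'
#' Maps a standard RTDOSE grid (after DoseGridScaling, in Gy) and the RTSTRUCT
#' contour sequences onto the package's [dose_grid()] and [rt_structure()]
#' types, converting DICOM patient axes (LPS) to the internal left-right /
#' inferior-superior / anterior-posterior convention. Explicit-VR little
#' endian, identity image orientation and uniform frame spacing only.
#' Mismatched frame-of-reference UIDs between the two files produce a warning,
#' not an error.
#'
#' @param rtdose_path path to an RTDOSE file (optional, `NULL` to skip).
#' @param rtstruct_path path to an RTSTRUCT file (optional, `NULL` to skip).
#' @return list with `dose` (a [dose_grid()] in Gy or `NULL`) and
#'   `structures` (named list of [rt_structure()]).
#' @export
read_dicom_rt <- function(rtdose_path = NULL, rtstruct_path = NULL) {
  dose <- NULL
  dose_for <- NULL
  if (!is.null(rtdose_path)) {
    ds <- .read_dicom(rtdose_path)
    rows <- as.integer(.ds_num(ds, "0028,0010", "Rows"))
    cols <- as.integer(.ds_num(ds, "0028,0011", "Columns"))
    nfrm <- if (!is.null(ds[["0028,0008"]]))
      as.integer(.ds_num(ds, "0028,0008")) else 1L
    ps <- .ds_num(ds, "0028,0030", "PixelSpacing")       # row, col spacing
    ipp <- .ds_num(ds, "0020,0032", "ImagePositionPatient")
    iop <- if (!is.null(ds[["0020,0037"]]))
      .ds_num(ds, "0020,0037") else c(1, 0, 0, 0, 1, 0)
    if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-6)
      stop("unsupported ImageOrientationPatient (identity orientation only)")
    offs <- if (nfrm > 1) .ds_num(ds, "3004,000C", "GridFrameOffsetVector")
      else 0
    if (nfrm > 1) {
      dz <- diff(offs)
      if (max(abs(dz - dz[1])) > 1e-6)
        stop("unsupported non-uniform GridFrameOffsetVector")
    }
    if (is.null(ds[["3004,000E"]]))
      stop("RTDOSE is missing DoseGridScaling (3004,000E)")
    scaling <- .ds_num(ds, "3004,000E")
    bits <- as.integer(.ds_num(ds, "0028,0100", "BitsAllocated"))
    signed <- !is.null(ds[["0028,0103"]]) && .ds_num(ds, "0028,0103") == 1
    px <- ds[["7FE0,0010"]]
    if (is.null(px)) stop("RTDOSE is missing PixelData")
    v <- .decode_pixels(px, bits, signed) * scaling
    # stored order: within a frame, rows sequentially (row-major); frames last
    arr_pat <- array(v, c(cols, rows, nfrm))             # x, y(P), z(S)
    # internal axes: x = patient x, y = patient z, z = -patient y
    vals <- aperm(arr_pat, c(1, 3, 2))[, , rows:1, drop = FALSE]
    frame_sp <- if (nfrm > 1) abs(offs[2] - offs[1]) else ps[1]
    dose <- dose_grid(vals,
                      origin = c(ipp[1], ipp[3] + offs[1],
                                 -(ipp[2] + (rows - 1) * ps[1])),
                      spacing = c(ps[2], frame_sp, ps[1]))
    dose_for <- ds[["0020,0052"]]
    message("RTDOSE axis mapping: internal (x,y,z) = patient (x, z, -y); ",
            "doses scaled to Gy by DoseGridScaling = ", scaling)
  }
  structures <- list()
  if (!is.null(rtstruct_path)) {
    ds <- .read_dicom(rtstruct_path)
    rois <- ds[["3006,0020"]]
    if (is.null(rois)) stop("RTSTRUCT is missing StructureSetROISequence")
    names_by_num <- list()
    struct_for <- NULL
    for (item in rois) {
      num <- as.character(as.integer(item[["3006,0022"]][1]))
      names_by_num[[num]] <- item[["3006,0026"]][1]
      if (is.null(struct_for) && !is.null(item[["3006,0024"]]))
        struct_for <- item[["3006,0024"]]
    }
    if (!is.null(dose_for) && !is.null(struct_for) &&
        !identical(dose_for, struct_for))
      warning("frame-of-reference UIDs of RTDOSE and RTSTRUCT differ; ",
              "loading anyway")
    rcs <- ds[["3006,0039"]]
    if (is.null(rcs)) stop("RTSTRUCT is missing ROIContourSequence")
    for (item in rcs) {
      num <- as.character(as.integer(item[["3006,0084"]][1]))
      nm <- names_by_num[[num]]
      if (is.null(nm)) nm <- paste0("ROI_", num)
      cs <- item[["3006,0040"]]
      if (is.null(cs)) next
      contours <- lapply(cs, function(ci) {
        xyz <- matrix(as.numeric(ci[["3006,0050"]]), ncol = 3, byrow = TRUE)
        contour(y_slice = xyz[1, 3],
                points = cbind(xyz[, 1], -xyz[, 2]), check = FALSE)
      })
      role <- if (grepl("cord", nm, ignore.case = TRUE)) "spinal_cord"
        else if (grepl("external|body", nm, ignore.case = TRUE)) "external"
        else "other"
      structures[[nm]] <- rt_structure(nm, contours, role = role)
    }
    message("RTSTRUCT axis mapping: internal (x,y,z) = patient (x, z, -y)")
  }
  list(dose = dose, structures = structures)
}
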