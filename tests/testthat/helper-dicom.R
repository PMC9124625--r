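# Test-only writer of minimal explicit-VR little-endian DICOM byte streams
# (the package itself never writes DICOM).

.raw_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                 endian = "little")
.raw_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                 endian = "little")

.pad_even <- function(body, pad = as.raw(0x20)) {
  if (length(body) %% 2 == 1) c(body, pad) else body
}

dcm_elem <- function(group, elem, vr, value) {
  body <- switch(vr,
    US = .raw_u16(value),
    UL = .raw_u32(value),
    OW = value,                                    # raw already
    SQ = value,                                    # raw item stream
    UI = .pad_even(charToRaw(paste(value, collapse = "\\")), as.raw(0)),
    .pad_even(charToRaw(paste(value, collapse = "\\"))))
  hdr <- c(.raw_u16(group), .raw_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(hdr, as.raw(c(0, 0)), .raw_u32(length(body)), body)
  else
    c(hdr, .raw_u16(length(body)), body)
}

dcm_item <- function(dataset_raw)
  c(.raw_u16(0xFFFE), .raw_u16(0xE000), .raw_u32(length(dataset_raw)),
    dataset_raw)

dcm_file <- function(path, dataset_raw) {
  meta <- dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  writeBin(c(raw(128), charToRaw("DICM"), meta, dataset_raw), path)
  path
}

# RTDOSE: `values` is an integer array [cols, rows, frames] in patient pixel
# order (x fastest). Doses are values * scaling Gy.
write_rtdose <- function(path, values, scaling, ipp = c(0, 0, 0),
                         pixel_spacing = c(1, 1), frame_offsets = NULL,
                         frame_of_reference = "1.2.3.4") {
  d <- dim(values)
  if (is.null(frame_offsets)) frame_offsets <- seq_len(d[3]) - 1
  # stored row-major within frame: rows sequentially, x fastest within a row
  px <- .raw_u16(as.vector(values))
  ds <- c(
    dcm_elem(0x0020, 0x0032, "DS", sprintf("%g", ipp)),
    dcm_elem(0x0020, 0x0037, "DS", sprintf("%g", c(1, 0, 0, 0, 1, 0))),
    dcm_elem(0x0020, 0x0052, "UI", frame_of_reference),
    dcm_elem(0x0028, 0x0008, "IS", sprintf("%d", d[3])),
    dcm_elem(0x0028, 0x0010, "US", d[2]),          # Rows
    dcm_elem(0x0028, 0x0011, "US", d[1]),          # Columns
    dcm_elem(0x0028, 0x0030, "DS", sprintf("%g", pixel_spacing)),
    dcm_elem(0x0028, 0x0100, "US", 16),
    dcm_elem(0x0028, 0x0103, "US", 0),
    dcm_elem(0x3004, 0x000C, "DS", sprintf("%g", frame_offsets)),
    dcm_elem(0x3004, 0x000E, "DS", sprintf("%g", scaling)),
    dcm_elem(0x7FE0, 0x0010, "OW", px))
  dcm_file(path, ds)
}

# RTSTRUCT with one ROI: `contours` is a list of n x 3 matrices of patient
# (x, y, z) mm.
write_rtstruct <- function(path, roi_name, contours,
                           frame_of_reference = "1.2.3.4") {
  roi_item <- dcm_item(c(
    dcm_elem(0x3006, 0x0022, "IS", "1"),
    dcm_elem(0x3006, 0x0024, "UI", frame_of_reference),
    dcm_elem(0x3006, 0x0026, "LO", roi_name)))
  contour_items <- do.call(c, lapply(contours, function(m)
    dcm_item(dcm_elem(0x3006, 0x0050, "DS",
                      sprintf("%g", as.vector(t(m)))))))
  rc_item <- dcm_item(c(
    dcm_elem(0x3006, 0x0040, "SQ", contour_items),
    dcm_elem(0x3006, 0x0084, "IS", "1")))
  ds <- c(
    dcm_elem(0x3006, 0x0020, "SQ", roi_item),
    dcm_elem(0x3006, 0x0039, "SQ", rc_item))
  dcm_file(path, ds)
}
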