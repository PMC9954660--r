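# Craft minimal DICOM byte streams in the test code (laid out directly from
# the standard's element encoding) so the reader is checked against the
# format, not against itself.

dcm_bytes_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_bytes_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element_explicit <- function(group, elem, vr, data) {
  head <- c(dcm_bytes_u16(group), dcm_bytes_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)), dcm_bytes_u32(length(data)), data)
  } else {
    c(head, dcm_bytes_u16(length(data)), data)
  }
}

dcm_element_implicit <- function(group, elem, data) {
  c(dcm_bytes_u16(group), dcm_bytes_u16(elem), dcm_bytes_u32(length(data)), data)
}

dcm_str <- function(s) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(" "))  # even-length padding
  r
}

# Build a single-frame CT DICOM file. `stored` is an integer matrix of raw
# pixel values (row-major in the file); rescale maps stored -> HU.
write_test_dicom <- function(path, stored, slope = 1, intercept = -1024,
                             explicit = TRUE, photometric = "MONOCHROME2",
                             signed = FALSE) {
  px <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  el <- if (explicit) {
    c(dcm_element_explicit(0x0028, 0x0004, "CS", dcm_str(photometric)),
      dcm_element_explicit(0x0028, 0x0010, "US", dcm_bytes_u16(nrow(stored))),
      dcm_element_explicit(0x0028, 0x0011, "US", dcm_bytes_u16(ncol(stored))),
      dcm_element_explicit(0x0028, 0x0100, "US", dcm_bytes_u16(16)),
      dcm_element_explicit(0x0028, 0x0103, "US", dcm_bytes_u16(as.integer(signed))),
      dcm_element_explicit(0x0028, 0x1052, "DS", dcm_str(format(intercept))),
      dcm_element_explicit(0x0028, 0x1053, "DS", dcm_str(format(slope))),
      dcm_element_explicit(0x7fe0, 0x0010, "OW", px))
  } else {
    c(dcm_element_implicit(0x0028, 0x0004, dcm_str(photometric)),
      dcm_element_implicit(0x0028, 0x0010, dcm_bytes_u16(nrow(stored))),
      dcm_element_implicit(0x0028, 0x0011, dcm_bytes_u16(ncol(stored))),
      dcm_element_implicit(0x0028, 0x0100, dcm_bytes_u16(16)),
      dcm_element_implicit(0x0028, 0x0103, dcm_bytes_u16(as.integer(signed))),
      dcm_element_implicit(0x0028, 0x1052, dcm_str(format(intercept))),
      dcm_element_implicit(0x0028, 0x1053, dcm_str(format(slope))),
      dcm_element_implicit(0x7fe0, 0x0010, px))
  }
  writeBin(c(raw(128), charToRaw("DICM"), el), path)
  invisible(path)
}
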