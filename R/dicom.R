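# Minimal single-frame CT DICOM reader: uncompressed little-endian transfer
# syntaxes (explicit or implicit VR), MONOCHROME photometric interpretation,
# 16- or 8-bit pixel data. Rescale slope/intercept are applied to yield HU.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

#' Read a single-frame CT DICOM file
#'
#' Supports uncompressed little-endian encodings (explicit and implicit VR)
#' with grayscale pixel data — sufficient for exported CT slices. Pixel data
#' is mapped to Hounsfield units via RescaleSlope and RescaleIntercept.
#'
#' @param path DICOM file path.
#' @param slice_id Identifier; defaults to the file name.
#' @return A [ct_slice()].
#' @export
read_dicom_slice <- function(path, slice_id = sub("\\.[^.]*$", "", basename(path))) {
  n <- file.size(path)
  if (is.na(n) || n < 140) stop("format error: not a DICOM file (too short)", call. = FALSE)
  raw <- readBin(path, "raw", n = n)
  pos <- if (n > 132 && rawToChar(raw[129:132]) == "DICM") 133L else 1L

  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 7L <= n) {
    group <- dcm_u16(raw, pos); elem <- dcm_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% long_vrs) {
      len <- dcm_u32(raw, pos + 8L); dstart <- pos + 12L
    } else if (explicit) {
      len <- dcm_u16(raw, pos + 6L); dstart <- pos + 8L
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, pos + 4L); dstart <- pos + 8L
    }
    if (len >= 4294967295) {
      stop("format error: undefined-length element not supported", call. = FALSE)
    }
    dend <- dstart + len - 1L
    if (dend > n) stop("format error: truncated DICOM element", call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    if (key %in% c("0028,0010", "0028,0011", "0028,0100", "0028,0103")) {
      tags[[key]] <- dcm_u16(raw, dstart)
    } else if (key %in% c("0028,1052", "0028,1053")) {
      tags[[key]] <- as.numeric(trimws(rawToChar(raw[dstart:dend])))
    } else if (key == "0028,0004") {
      tags[[key]] <- trimws(rawToChar(raw[dstart:dend]))
    } else if (key == "7fe0,0010") {
      tags[[key]] <- raw[dstart:dend]
      break
    }
    pos <- dend + 1L
  }
  need <- c("0028,0010", "0028,0011", "7fe0,0010")
  if (!all(need %in% names(tags))) {
    stop("format error: missing Rows/Columns/PixelData", call. = FALSE)
  }
  phot <- tags[["0028,0004"]]
  if (!is.null(phot) && !grepl("^MONOCHROME", phot)) {
    stop("content error: non-grayscale DICOM (", phot, ")", call. = FALSE)
  }
  rows <- tags[["0028,0010"]]; cols <- tags[["0028,0011"]]
  bits <- tags[["0028,0100"]] %||% 16L
  signed <- (tags[["0028,0103"]] %||% 0L) == 1L
  px <- tags[["7fe0,0010"]]
  if (bits == 16) {
    if (length(px) < 2 * rows * cols) stop("format error: short pixel data", call. = FALSE)
    v <- readBin(px, "integer", n = rows * cols, size = 2,
                 signed = signed, endian = "little")
  } else if (bits == 8) {
    if (length(px) < rows * cols) stop("format error: short pixel data", call. = FALSE)
    v <- as.integer(px[seq_len(rows * cols)])
  } else {
    stop("format error: unsupported bits allocated: ", bits, call. = FALSE)
  }
  slope <- tags[["0028,1053"]] %||% 1
  inter <- tags[["0028,1052"]] %||% 0
  hu <- round(slope * v + inter)
  ct_slice(matrix(hu, nrow = rows, ncol = cols, byrow = TRUE), slice_id = slice_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
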