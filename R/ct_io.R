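# CT slice / mask containers, Hounsfield windowing, resizing, QC and splits.

#' CT slice container
#'
#' Holds one 2D slice of signed Hounsfield-unit pixels.
#'
#' @param pixels Integer-valued matrix of HU values (rows = image rows).
#' @param slice_id Identifier string.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, slice_id = "slice") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  stopifnot(nrow(pixels) > 0, ncol(pixels) > 0)
  if (any(pixels < -2048 | pixels > 4096, na.rm = TRUE)) {
    stop("HU values must lie in [-2048, 4096]", call. = FALSE)
  }
  structure(list(pixels = pixels, slice_id = as.character(slice_id),
                 height = nrow(pixels), width = ncol(pixels)),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat("<ct_slice>", x$slice_id, ":", x$height, "x", x$width,
      "px, HU range", paste(range(x$pixels), collapse = ".."), "\n")
  invisible(x)
}

#' Hounsfield display window
#'
#' The default (-160, 240) is the usual abdominal soft-tissue window
#' (level 40, width 400).
#'
#' @param hu_low,hu_high Window bounds in HU; `hu_low < hu_high`.
#' @return An object of class `hu_window`.
#' @export
hu_window <- function(hu_low = -160, hu_high = 240) {
  if (!(hu_low < hu_high)) stop("degenerate window: hu_low must be < hu_high", call. = FALSE)
  structure(list(hu_low = hu_low, hu_high = hu_high), class = "hu_window")
}

#' Apply a Hounsfield window
#'
#' Maps HU values affinely onto `[0, 1]`, clamping outside the window:
#' `clamp((hu - hu_low) / (hu_high - hu_low), 0, 1)`.
#'
#' @param x A `ct_slice` or a numeric matrix of HU values.
#' @param window A [hu_window()].
#' @return Numeric matrix in `[0, 1]` with the input's dimensions.
#' @export
#' @examples
#' apply_hu_window(matrix(c(-160, 40, 240, 740), 2), hu_window(-160, 240))
apply_hu_window <- function(x, window = hu_window()) {
  stopifnot(inherits(window, "hu_window"))
  m <- if (inherits(x, "ct_slice")) x$pixels else as.matrix(x)
  out <- (m - window$hu_low) / (window$hu_high - window$hu_low)
  out[out < 0] <- 0
  out[out > 1] <- 1
  storage.mode(out) <- "double"
  out
}

#' Image/mask sample pair
#'
#' A windowed image in `[0, 1]` aligned with a binary ground-truth mask of
#' identical geometry.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary (0/1) matrix of the same dimensions.
#' @param slice_id Identifier string.
#' @return An object of class `sample_pair`.
#' @export
sample_pair <- function(image, mask, slice_id = "slice") {
  image <- as.matrix(image); mask <- as.matrix(mask)
  if (!identical(dim(image), dim(mask))) {
    stop("pairing error: image and mask dimensions differ", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)", call. = FALSE)
  storage.mode(mask) <- "double"
  structure(list(image = image, mask = mask, slice_id = as.character(slice_id)),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat("<sample_pair>", x$slice_id, ":", nrow(x$image), "x", ncol(x$image),
      "px,", sum(x$mask), "foreground px\n")
  invisible(x)
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation; the mask with
#' nearest-neighbour so it stays binary. The default target reproduces the
#' pipeline's 512 to 224 reduction.
#'
#' @param pair A [sample_pair()].
#' @param side Target square side in pixels. Default 224.
#' @return A resized `sample_pair`.
#' @export
resize_pair <- function(pair, side = 224L) {
  stopifnot(inherits(pair, "sample_pair"), side > 0)
  side <- as.integer(side)
  sample_pair(
    image = .resize2d_cpp(pair$image, side, side, TRUE),
    mask = .resize2d_cpp(pair$mask, side, side, FALSE),
    slice_id = pair$slice_id
  )
}

#' Overlay quality check of an image/mask pair
#'
#' Superimposes the mask outline on the windowed image and reports the
#' fraction of mask-foreground pixels whose windowed intensity exceeds
#' `threshold` — a quick check that image and marker belong to the same
#' acquisition. An empty mask yields `NA` coverage with a warning.
#'
#' @param pair A [sample_pair()].
#' @param threshold Windowed-intensity threshold used for the coverage
#'   fraction. Default 0.5.
#' @return An object of class `overlay_check`: list with `coverage`,
#'   `n_foreground`, `threshold` and the pair, plottable via [autoplot()].
#' @export
overlay_check <- function(pair, threshold = 0.5) {
  if (!inherits(pair, "sample_pair")) {
    stop("pairing error: overlay_check needs a sample_pair", call. = FALSE)
  }
  fg <- pair$mask == 1
  nfg <- sum(fg)
  coverage <- if (nfg == 0) {
    warning("empty mask foreground: coverage undefined", call. = FALSE)
    NA_real_
  } else {
    mean(pair$image[fg] > threshold)
  }
  structure(list(coverage = coverage, n_foreground = nfg,
                 threshold = threshold, pair = pair),
            class = "overlay_check")
}

#' @export
print.overlay_check <- function(x, ...) {
  cat("<overlay_check>", x$pair$slice_id, ": coverage",
      format(x$coverage, digits = 4), "over", x$n_foreground,
      "foreground px (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Split sample pairs into training and validation sets
#'
#' Pairs are shuffled with a seeded RNG and the first `floor(ratio * n)` go to
#' the training set, mirroring the 8:2 protocol. With `group`, whole groups
#' (e.g. patients) are kept on one side of the split to avoid leakage.
#'
#' @param pairs List of [sample_pair()] objects.
#' @param ratio Training fraction in (0, 1). Default 0.8.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param group Optional vector (length of `pairs`) of group labels.
#' @return An object of class `dataset_split`: list with `train`, `val`,
#'   `ratio`, `seed`.
#' @export
#' @examples
#' prs <- lapply(1:10, function(i)
#'   sample_pair(matrix(runif(16), 4), matrix(0, 4, 4), paste0("s", i)))
#' sp <- split_dataset(prs, ratio = 0.8, seed = 1)
#' lengths(sp[c("train", "val")])
split_dataset <- function(pairs, ratio = 0.8, seed = 1L, group = NULL) {
  stopifnot(length(pairs) >= 2)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)", call. = FALSE)
  n <- length(pairs)
  if (is.null(group)) {
    idx <- withr::with_seed(seed, sample.int(n))
    ntr <- floor(ratio * n)
    tr <- idx[seq_len(ntr)]
    va <- idx[setdiff(seq_len(n), seq_len(ntr))]
  } else {
    stopifnot(length(group) == n)
    gs <- unique(group)
    gs <- withr::with_seed(seed, sample(gs))
    ntr <- floor(ratio * n)
    tr <- integer(0)
    for (g in gs) {
      members <- which(group == g)
      if (length(tr) + length(members) <= ntr || length(tr) == 0) {
        tr <- c(tr, members)
      }
      if (length(tr) >= ntr) break
    }
    va <- setdiff(seq_len(n), tr)
  }
  structure(list(train = pairs[tr], val = pairs[va],
                 ratio = ratio, seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split>", length(x$train), "train /", length(x$val),
      "val (ratio", x$ratio, ", seed", x$seed, ")\n")
  invisible(x)
}

## ---- 16-bit PNG and manifest I/O ------------------------------------------

u32_be <- function(x) {
  as.raw(c(x %/% 16777216 %% 256, x %/% 65536 %% 256, x %/% 256 %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(.crc32_cpp(body)))
}

# Write a non-negative integer matrix (<= 65535) as 16-bit grayscale PNG.
write_png16_raw <- function(m, path) {
  stopifnot(all(m >= 0), all(m <= 65535))
  H <- nrow(m); W <- ncol(m)
  v <- t(m)                              # scanline order: row by row
  hi <- matrix(as.integer(v %/% 256L), W, H)
  lo <- matrix(as.integer(v %% 256L), W, H)
  sc <- matrix(0L, 2L * W + 1L, H)       # leading filter byte per scanline
  sc[2 * seq_len(W), ] <- hi
  sc[2 * seq_len(W) + 1L, ] <- lo
  idat <- memCompress(as.raw(sc), "gzip")
  ihdr <- c(u32_be(W), u32_be(H),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # bit depth 16, grayscale
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Write a CT slice as 16-bit PNG
#'
#' Stored value = HU + `offset` (default 1024), the package's lossless
#' unsigned encoding of signed HU.
#'
#' @param slice A [ct_slice()].
#' @param path Output file path.
#' @param offset Stored-value offset. Default 1024.
#' @export
write_slice_png16 <- function(slice, path, offset = 1024L) {
  stopifnot(inherits(slice, "ct_slice"))
  write_png16_raw(slice$pixels + as.integer(offset), path)
}

#' Write a binary mask as 8-bit PNG
#'
#' Foreground stored as 255, background as 0.
#'
#' @param mask Binary 0/1 matrix.
#' @param path Output file path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(all(mask %in% c(0, 1)))
  storage.mode(mask) <- "double"
  png::writePNG(mask, path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG file with `{0, 255}` (or `{0, 1}`) grayscale values.
#' @return Binary 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m >= 0.5) + 0
}

#' Load a CT slice from disk
#'
#' Reads a single-frame DICOM (rescale slope/intercept applied to yield HU)
#' or a 16-bit grayscale PNG using the stored = HU + `offset` convention.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"dicom"`, or `"png16"`.
#' @param offset PNG stored-value offset. Default 1024.
#' @param slice_id Identifier; defaults to the file name.
#' @return A [ct_slice()].
#' @export
load_slice <- function(path, format = c("auto", "dicom", "png16"),
                       offset = 1024L,
                       slice_id = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom" else "png16"
  }
  if (format == "dicom") return(read_dicom_slice(path, slice_id = slice_id))
  m <- tryCatch(png::readPNG(path), error = function(e) {
    stop("format error: cannot parse PNG: ", conditionMessage(e), call. = FALSE)
  })
  if (length(dim(m)) == 3) {
    if (dim(m)[3] > 2) stop("content error: PNG is not grayscale", call. = FALSE)
    m <- m[, , 1]
  }
  ct_slice(round(m * 65535) - as.integer(offset), slice_id = slice_id)
}

#' Write sample pairs and a manifest
#'
#' Writes each pair as a 16-bit image PNG (the `[0, 1]` image is stored as
#' `round(image * 65535)`) and an 8-bit mask PNG, plus a CSV manifest with
#' columns `slice_id`, `image_path`, `mask_path`, `split`.
#'
#' @param pairs List of [sample_pair()]s.
#' @param dir Output directory (created if needed).
#' @param split Optional character vector (`"train"`/`"val"`) per pair.
#' @return The manifest tibble, invisibly written to `dir/manifest.csv`.
#' @export
write_pairs <- function(pairs, dir, split = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(split)) split <- rep(NA_character_, length(pairs))
  rows <- purrr::map2(pairs, split, function(p, s) {
    ip <- file.path(dir, paste0(p$slice_id, "_img.png"))
    mp <- file.path(dir, paste0(p$slice_id, "_mask.png"))
    write_png16_raw(round(p$image * 65535), ip)
    write_mask_png(p$mask, mp)
    tibble::tibble(slice_id = p$slice_id, image_path = ip, mask_path = mp, split = s)
  })
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read sample pairs from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_pairs()].
#' @return A list of [sample_pair()]s; the manifest tibble is attached as the
#'   `"manifest"` attribute.
#' @export
read_pairs <- function(manifest_path) {
  man <- tibble::as_tibble(utils::read.csv(manifest_path, stringsAsFactors = FALSE))
  pairs <- purrr::pmap(man[c("slice_id", "image_path", "mask_path")],
                       function(slice_id, image_path, mask_path) {
    img <- png::readPNG(image_path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    sample_pair(img, read_mask_png(mask_path), slice_id)
  })
  attr(pairs, "manifest") <- man
  pairs
}
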