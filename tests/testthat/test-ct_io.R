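# Windowing, resizing, QC overlay, splits and file round-trips.

test_that("HU windowing is the clamped affine map", {
  w <- hu_window(-160, 240)
  expect_equal(apply_hu_window(matrix(-160), w)[1, 1], 0)
  expect_equal(apply_hu_window(matrix(240), w)[1, 1], 1)
  expect_equal(apply_hu_window(matrix(40), w)[1, 1], 0.5)
  expect_equal(apply_hu_window(matrix(740), w)[1, 1], 1)    # clamped above
  expect_equal(apply_hu_window(matrix(-2000), w)[1, 1], 0)  # clamped below
  expect_error(hu_window(100, 100), "degenerate")
})

test_that("windowing is monotone and stable under re-windowing with (0, 1)", {
  hu <- matrix(seq(-500, 500, length.out = 64), 8)
  y <- apply_hu_window(hu, hu_window(-160, 240))
  expect_true(all(diff(as.vector(y)) >= 0))
  y2 <- apply_hu_window(y, hu_window(0, 1))
  expect_equal(y2, y)
})

test_that("ct_slice enforces the HU range invariant", {
  expect_error(ct_slice(matrix(5000, 2, 2)), "HU")
  s <- ct_slice(matrix(0L, 3, 4), "a")
  expect_equal(s$height, 3)
  expect_equal(s$width, 4)
})

test_that("resize_pair uses bilinear images and nearest binary masks", {
  set.seed(9)
  img <- matrix(runif(64 * 64), 64)
  msk <- matrix(0, 64, 64); msk[20:40, 25:45] <- 1
  p <- sample_pair(img, msk, "s")
  q <- resize_pair(p, 28)
  expect_equal(dim(q$image), c(28L, 28L))
  expect_true(all(q$mask %in% c(0, 1)))
  # identity resize leaves pixels unchanged
  expect_equal(resize_pair(p, 64)$image, img, tolerance = 1e-12)
  # constant mask is preserved at any size
  ones <- sample_pair(img, matrix(1, 64, 64), "o")
  expect_true(all(resize_pair(ones, 17)$mask == 1))
  # shrink then restore: mask stays binary
  back <- resize_pair(resize_pair(p, 28), 64)
  expect_true(all(back$mask %in% c(0, 1)))
})

test_that("overlay_check reports foreground coverage and flags empty masks", {
  ph <- generate_phantom(phantom_spec(side = 48, noise_sigma = 0,
                                      lesion_pattern = "single_large"), seed = 2)
  img <- apply_hu_window(ph$slice)
  # lesion HU 60 windows to 0.55 > 0.5 everywhere -> full coverage
  oc <- overlay_check(sample_pair(img, ph$lesion_mask, "p"), threshold = 0.5)
  expect_equal(oc$coverage, 1)
  expect_warning(oc0 <- overlay_check(sample_pair(img, matrix(0, 48, 48), "z")),
                 "empty")
  expect_true(is.na(oc0$coverage))
  # mismatched geometry cannot even form a pair
  expect_error(sample_pair(matrix(0.5, 4, 4), matrix(0, 8, 8)), "pairing")
})

test_that("split_dataset honours the ratio and is deterministic", {
  prs <- lapply(1:10, function(i) tiny_pair(paste0("s", i)))
  sp <- split_dataset(prs, 0.8, seed = 7)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$val), 2)
  sp2 <- split_dataset(prs, 0.8, seed = 7)
  expect_identical(vapply(sp$train, `[[`, "", "slice_id"),
                   vapply(sp2$train, `[[`, "", "slice_id"))
  # disjoint and exhaustive
  ids <- c(vapply(sp$train, `[[`, "", "slice_id"),
           vapply(sp$val, `[[`, "", "slice_id"))
  expect_setequal(ids, paste0("s", 1:10))
  expect_equal(anyDuplicated(ids), 0)
  expect_error(split_dataset(prs, 1.2), "ratio")
})

test_that("split proportions hold at corpus scale and for grouped splits", {
  prs <- lapply(1:2136, function(i) tiny_pair(paste0("s", i)))
  sp <- split_dataset(prs, 0.8, seed = 1)
  expect_equal(length(sp$train), 1708)
  expect_equal(length(sp$val), 428)
  # groups stay on one side
  grp <- rep(1:20, length.out = 100)
  sp2 <- split_dataset(prs[1:100], 0.8, seed = 2, group = grp)
  tr_ids <- vapply(sp2$train, `[[`, "", "slice_id")
  tr_grp <- grp[match(tr_ids, paste0("s", 1:100))]
  va_ids <- vapply(sp2$val, `[[`, "", "slice_id")
  va_grp <- grp[match(va_ids, paste0("s", 1:100))]
  expect_length(intersect(unique(tr_grp), unique(va_grp)), 0)
})

test_that("16-bit PNG round-trips HU pixels exactly", {
  set.seed(15)
  hu <- matrix(sample(-1024:3000, 32 * 20, replace = TRUE), 32, 20)
  s <- ct_slice(hu, "rt")
  f <- withr::local_tempfile(fileext = ".png")
  write_slice_png16(s, f)
  s2 <- load_slice(f, format = "png16")
  expect_identical(s2$pixels, s$pixels)
})

test_that("mask PNG round-trips the {0,255} convention", {
  set.seed(16)
  m <- random_mask(15, 11, 0.4)
  f <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, f)
  expect_equal(read_mask_png(f), m)
})

test_that("write_pairs/read_pairs round-trip a manifest", {
  set.seed(17)
  prs <- lapply(1:3, function(i)
    sample_pair(matrix(runif(64), 8), random_mask(8, 8, 0.3), paste0("p", i)))
  d <- withr::local_tempdir()
  man <- write_pairs(prs, d, split = c("train", "train", "val"))
  expect_true(file.exists(file.path(d, "manifest.csv")))
  back <- read_pairs(file.path(d, "manifest.csv"))
  expect_equal(length(back), 3)
  expect_equal(back[[2]]$mask, prs[[2]]$mask)
  expect_equal(back[[1]]$image, prs[[1]]$image, tolerance = 1 / 65535)
  expect_equal(attr(back, "manifest")$split, c("train", "train", "val"))
})

test_that("DICOM reader applies rescale and handles both VR encodings", {
  stored <- matrix(sample(0:2500, 12), 4, 3)
  f <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(f, stored, slope = 1, intercept = -1024)
  s <- read_dicom_slice(f)
  expect_identical(s$pixels, matrix(as.integer(stored - 1024), 4, 3))
  # stored 1024 with intercept -1024 -> HU 0
  stored[1, 1] <- 1024
  write_test_dicom(f, stored)
  expect_equal(read_dicom_slice(f)$pixels[1, 1], 0L)
  # implicit VR little endian
  write_test_dicom(f, stored, explicit = FALSE)
  expect_identical(read_dicom_slice(f)$pixels, matrix(as.integer(stored - 1024), 4, 3))
  # fractional slope
  write_test_dicom(f, stored, slope = 2, intercept = -2048)
  expect_equal(read_dicom_slice(f)$pixels[2, 2], as.integer(2 * stored[2, 2] - 2048))
})

test_that("DICOM reader rejects degenerate inputs", {
  f <- withr::local_tempfile(fileext = ".dcm")
  writeBin(raw(60), f)
  expect_error(read_dicom_slice(f), "format error")
  # truncated pixel data
  stored <- matrix(1:20, 4, 5)
  write_test_dicom(f, stored)
  raw_all <- readBin(f, "raw", file.size(f))
  writeBin(raw_all[1:(length(raw_all) - 10)], f)
  expect_error(read_dicom_slice(f), "format error")
  # non-grayscale content
  write_test_dicom(f, stored, photometric = "RGB")
  expect_error(read_dicom_slice(f), "content error")
})

test_that("load_slice dispatches by format and errors on unreadable files", {
  f <- withr::local_tempfile(fileext = ".png")
  writeBin(as.raw(1:10), f)
  expect_error(load_slice(f), "format error")
  expect_error(load_slice("no/such/file.png"), "format error")
})
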