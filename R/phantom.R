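# Synthetic abdominal-CT-like phantoms with exact organ and lesion masks.
# The taxonomy mirrors the case variety seen in clinical bladder series:
# round, elongated and irregular organ outlines, organs abutting bone or the
# abdominal wall, and lesions ranging from single large masses to multiple
# small or irregular blobs.

#' Phantom specification
#'
#' Tissue mean HU values are chosen so each tissue is separated from its
#' surroundings by more than twice the noise standard deviation, which makes
#' the segmentation task solvable by thresholding at zero noise — training
#' failures on phantoms therefore indicate pipeline bugs, not data
#' impossibility.
#'
#' @param side Image side in pixels. Default 224.
#' @param body_hu,urine_hu,lesion_hu,bone_hu Mean HU per tissue role.
#'   Defaults 40 / 10 / 60 / 700.
#' @param noise_sigma Additive Gaussian HU noise. Default 10.
#' @param organ_shape One of `"round"`, `"elongated"`, `"irregular"`,
#'   `"near_bone"`, `"near_top"`.
#' @param lesion_pattern One of `"none"`, `"single_large"`, `"multi_large"`,
#'   `"small"`, `"irregular"`.
#' @param organ_area_range Organ area as a fraction of the image, within
#'   (0, 0.5). Default `c(0.04, 0.12)`.
#' @param lesion_count_range Blob count range for multi-blob patterns.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 224L, body_hu = 40, urine_hu = 10,
                         lesion_hu = 60, bone_hu = 700, noise_sigma = 10,
                         organ_shape = c("round", "elongated", "irregular",
                                         "near_bone", "near_top"),
                         lesion_pattern = c("none", "single_large",
                                            "multi_large", "small", "irregular"),
                         organ_area_range = c(0.04, 0.12),
                         lesion_count_range = c(1L, 3L)) {
  organ_shape <- match.arg(organ_shape)
  lesion_pattern <- match.arg(lesion_pattern)
  stopifnot(side >= 16, noise_sigma >= 0,
            organ_area_range[1] > 0, organ_area_range[2] < 0.5,
            organ_area_range[1] <= organ_area_range[2],
            lesion_count_range[1] >= 1,
            lesion_count_range[1] <= lesion_count_range[2])
  # adjacent-tissue contrasts must beat the noise for the task to be learnable
  seps <- c(abs(urine_hu - body_hu), abs(lesion_hu - urine_hu),
            abs(bone_hu - body_hu))
  if (any(seps <= 2 * noise_sigma)) {
    stop("tissue HU contrasts must exceed 2 * noise_sigma", call. = FALSE)
  }
  structure(list(side = as.integer(side), body_hu = body_hu,
                 urine_hu = urine_hu, lesion_hu = lesion_hu, bone_hu = bone_hu,
                 noise_sigma = noise_sigma, organ_shape = organ_shape,
                 lesion_pattern = lesion_pattern,
                 organ_area_range = organ_area_range,
                 lesion_count_range = as.integer(lesion_count_range)),
            class = "phantom_spec")
}

# Radially perturbed ellipse mask. amp = 0 gives an exact ellipse.
blob_mask <- function(side, cx, cy, rx, ry, amp = 0, harmonics = NULL,
                      phases = NULL) {
  x <- matrix(rep(0:(side - 1), each = side), side)   # column index
  y <- matrix(rep(0:(side - 1), times = side), side)  # row index
  u <- (x - cx) / rx; v <- (y - cy) / ry
  r <- sqrt(u^2 + v^2)
  if (amp > 0) {
    th <- atan2(v, u)
    pert <- rep(0, length(th))
    for (i in seq_along(harmonics)) {
      pert <- pert + sin(harmonics[i] * th + phases[i])
    }
    lim <- 1 + amp * pert / max(1, length(harmonics) - 1)
  } else {
    lim <- 1
  }
  (r <= lim) + 0
}

#' Generate one phantom slice with organ and lesion masks
#'
#' Draws a soft-tissue background with mild low-frequency texture, one
#' urine-filled organ region shaped per `organ_shape`, optional lesion blobs
#' inside the organ per `lesion_pattern`, a bone-like high-HU crescent for
#' the `near_bone` shape, and additive Gaussian noise. Masks record the
#' exact pre-noise geometry; the lesion mask is always contained in the
#' organ mask.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed; the same spec and seed reproduce the
#'   phantom bit-identically.
#' @return List with `slice` (a [ct_slice()]), `organ_mask` and
#'   `lesion_mask` (binary matrices).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(side = 64), seed = 1)
#' sum(ph$lesion_mask & !ph$organ_mask)  # containment: always 0
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  run <- function() {
    s <- spec$side
    # organ geometry
    afrac <- stats::runif(1, spec$organ_area_range[1], spec$organ_area_range[2])
    aspect <- switch(spec$organ_shape,
                     round = 1,
                     elongated = stats::runif(1, 1.9, 2.8),
                     irregular = stats::runif(1, 1, 1.5),
                     near_bone = stats::runif(1, 1, 1.6),
                     near_top = stats::runif(1, 1, 1.6))
    r0 <- sqrt(afrac * s^2 / (pi * aspect))
    rx <- r0 * aspect; ry <- r0
    if (stats::runif(1) < 0.5) { tmp <- rx; rx <- ry; ry <- tmp }
    cy <- switch(spec$organ_shape,
                 near_top = s * stats::runif(1, 0.18, 0.28),
                 s * stats::runif(1, 0.45, 0.62))
    cx <- s * stats::runif(1, 0.42, 0.58)
    amp <- if (spec$organ_shape == "irregular") stats::runif(1, 0.15, 0.3) else 0
    nh <- sample(3:5, 1)
    organ <- blob_mask(s, cx, cy, rx, ry, amp,
                       harmonics = sample(2:6, nh), phases = stats::runif(nh, 0, 2 * pi))
    # bone crescent for near_bone: annulus segment adjacent to the organ
    bone <- matrix(0, s, s)
    if (spec$organ_shape == "near_bone") {
      bc_x <- cx + rx * stats::runif(1, 0.9, 1.1)
      bc_y <- cy + ry * stats::runif(1, 0.3, 0.7)
      rr <- r0 * stats::runif(1, 0.9, 1.3)
      outer_m <- blob_mask(s, bc_x, bc_y, rr * 1.25, rr * 1.25)
      inner_m <- blob_mask(s, bc_x, bc_y, rr * 0.8, rr * 0.8)
      bone <- (outer_m == 1 & inner_m == 0) + 0
      organ[bone == 1] <- 0
    }
    # lesions inside the organ
    lesion <- matrix(0, s, s)
    if (spec$lesion_pattern != "none" && sum(organ) > 0) {
      fg <- which(organ == 1)
      les_r <- switch(spec$lesion_pattern,
                      single_large = r0 * stats::runif(1, 0.45, 0.6),
                      multi_large = r0 * stats::runif(1, 0.3, 0.42),
                      small = r0 * stats::runif(1, 0.1, 0.18),
                      irregular = r0 * stats::runif(1, 0.35, 0.55))
      les_r <- max(les_r, 1.5)
      count <- switch(spec$lesion_pattern,
                      single_large = 1L,
                      irregular = 1L,
                      sample(spec$lesion_count_range[1]:spec$lesion_count_range[2], 1))
      for (b in seq_len(count)) {
        at <- fg[sample(length(fg), 1)]
        by <- (at - 1) %% s          # row, 0-based
        bx <- (at - 1) %/% s         # column, 0-based
        la <- if (spec$lesion_pattern == "irregular") stats::runif(1, 0.25, 0.4) else 0
        lh <- sample(2:5, 3)
        lesion <- pmax(lesion,
                       blob_mask(s, bx, by, les_r, les_r, la,
                                 harmonics = lh, phases = stats::runif(3, 0, 2 * pi)))
      }
      lesion <- (lesion == 1 & organ == 1) + 0
    }
    # compose HU image: body texture, organ, lesion, bone, noise
    x <- matrix(rep(0:(s - 1), each = s), s) / s
    y <- matrix(rep(0:(s - 1), times = s), s) / s
    tex <- 0
    for (j in 1:3) {
      tex <- tex + stats::runif(1, 2, 6) *
        cos(2 * pi * (stats::runif(1, 0.5, 2) * x + stats::runif(1, 0.5, 2) * y) +
              stats::runif(1, 0, 2 * pi))
    }
    img <- matrix(spec$body_hu, s, s) + tex
    img[organ == 1] <- spec$urine_hu
    img[lesion == 1] <- spec$lesion_hu
    img[bone == 1] <- spec$bone_hu
    if (spec$noise_sigma > 0) {
      img <- img + stats::rnorm(s * s, sd = spec$noise_sigma)
    }
    list(slice = ct_slice(pmin(pmax(round(img), -2048), 4096),
                          slice_id = paste0("phantom_", spec$organ_shape, "_",
                                            spec$lesion_pattern)),
         organ_mask = organ, lesion_mask = lesion)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate a phantom dataset of organ and lesion sample pairs
#'
#' Draws `n` phantoms with organ shapes and lesion patterns sampled from
#' mixture weights, windows each slice with `window`, and returns aligned
#' organ-task and lesion-task sample pairs.
#'
#' @param n Number of phantoms (> 0).
#' @param spec Template [phantom_spec()]; its shape/pattern fields are
#'   overridden by the sampled taxonomy.
#' @param seed Integer seed for the whole dataset.
#' @param shape_weights Named mixture weights over organ shapes.
#' @param lesion_weights Named mixture weights over lesion patterns.
#' @param window The [hu_window()] applied to images.
#' @return List with `organ` and `lesion` (lists of [sample_pair()]s) and
#'   `meta` (tibble: slice_id, organ_shape, lesion_pattern).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), seed = 1L,
                             shape_weights = c(round = 0.3, elongated = 0.2,
                                               irregular = 0.2, near_bone = 0.15,
                                               near_top = 0.15),
                             lesion_weights = c(none = 0.2, single_large = 0.2,
                                                multi_large = 0.2, small = 0.2,
                                                irregular = 0.2),
                             window = hu_window()) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  withr::with_seed(seed, {
    shapes <- sample(names(shape_weights), n, replace = TRUE, prob = shape_weights)
    patterns <- sample(names(lesion_weights), n, replace = TRUE, prob = lesion_weights)
    organ <- vector("list", n); lesion <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- spec
      sp$organ_shape <- shapes[i]
      sp$lesion_pattern <- patterns[i]
      ph <- generate_phantom(sp)
      id <- sprintf("ph%05d", i)
      img <- apply_hu_window(ph$slice, window)
      organ[[i]] <- sample_pair(img, ph$organ_mask, id)
      lesion[[i]] <- sample_pair(img, ph$lesion_mask, id)
    }
    list(organ = organ, lesion = lesion,
         meta = tibble::tibble(slice_id = sprintf("ph%05d", seq_len(n)),
                               organ_shape = shapes, lesion_pattern = patterns))
  })
}
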