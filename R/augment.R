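# Joint image/mask affine augmentation: scale, rotation, shift, shear,
# horizontal flip, applied identically to both members of a pair.

#' Augmentation policy
#'
#' The five transform families with their sampling ranges, and the dataset
#' expansion multiplier. Defaults follow the training recipe: magnification
#' chosen from the original size or 120%, rotation within +/-15 degrees,
#' shifts within +/-10 pixels on each axis, shear within +/-5 degrees, and a
#' 50% chance of horizontal flip; each original contributes `multiplier`
#' output pairs (itself plus `multiplier - 1` augmented copies), expanding
#' 712 originals to 2136.
#'
#' @param scale_choices Discrete magnification factors. Default `c(1, 1.2)`.
#' @param rotation_deg Rotation half-range in degrees. Default 15.
#' @param shift_px Shift half-range in pixels per axis. Default 10.
#' @param shear_deg Shear half-range in degrees. Default 5.
#' @param hflip_prob Horizontal flip probability. Default 0.5.
#' @param multiplier Output pairs per original (>= 1, includes the original).
#'   Default 3.
#' @return An object of class `augment_policy`.
#' @export
augment_policy <- function(scale_choices = c(1, 1.2), rotation_deg = 15,
                           shift_px = 10, shear_deg = 5, hflip_prob = 0.5,
                           multiplier = 3L) {
  stopifnot(multiplier >= 1, hflip_prob >= 0, hflip_prob <= 1,
            rotation_deg >= 0, shift_px >= 0, shear_deg >= 0,
            all(scale_choices > 0))
  structure(list(scale_choices = scale_choices, rotation_deg = rotation_deg,
                 shift_px = shift_px, shear_deg = shear_deg,
                 hflip_prob = hflip_prob, multiplier = as.integer(multiplier)),
            class = "augment_policy")
}

#' Draw one random transform from a policy
#'
#' Each component is drawn independently: scale uniformly from the choice
#' set, rotation/shift/shear uniformly from their symmetric ranges, flip as
#' a Bernoulli draw. Uses the session RNG; seed with `set.seed()` for
#' reproducibility.
#'
#' @param policy An [augment_policy()].
#' @return A list of class `transform_spec` with fields `scale`, `angle`,
#'   `dx`, `dy`, `shear`, `flip`.
#' @export
sample_transform <- function(policy = augment_policy()) {
  stopifnot(inherits(policy, "augment_policy"))
  structure(list(
    scale = if (length(policy$scale_choices) == 1) policy$scale_choices
            else sample(policy$scale_choices, 1),
    angle = stats::runif(1, -policy$rotation_deg, policy$rotation_deg),
    dx = stats::runif(1, -policy$shift_px, policy$shift_px),
    dy = stats::runif(1, -policy$shift_px, policy$shift_px),
    shear = stats::runif(1, -policy$shear_deg, policy$shear_deg),
    flip = stats::runif(1) < policy$hflip_prob
  ), class = "transform_spec")
}

#' The identity transform
#' @return A `transform_spec` that leaves a pair unchanged.
#' @export
identity_transform <- function() {
  structure(list(scale = 1, angle = 0, dx = 0, dy = 0, shear = 0, flip = FALSE),
            class = "transform_spec")
}

# Inverse 2x3 affine matrix mapping output pixel coordinates to input
# coordinates, for the composition scale -> rotate -> shear -> shift -> flip
# about the image center. Coordinates: x = column, y = row, 0-based.
transform_inverse_matrix <- function(t, H, W) {
  th <- t$angle * pi / 180
  sh <- t$shear * pi / 180
  S <- diag(c(t$scale, t$scale))
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Sh <- matrix(c(1, 0, tan(sh), 1), 2, 2)
  F_ <- if (t$flip) diag(c(-1, 1)) else diag(2)
  A <- Sh %*% R %*% S
  Ainv <- solve(A)
  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  c_ <- c(cx, cy)
  L <- Ainv %*% F_
  off <- c_ - L %*% c_ - Ainv %*% c(t$dx, t$dy)
  cbind(L, off)
}

#' Apply a transform jointly to an image/mask pair
#'
#' A single affine map (scale, rotation, shear, shift, optional horizontal
#' flip, composed in that order about the image center) is applied
#' identically to both members: bilinear interpolation with zero fill for
#' the image, nearest-neighbour with zero fill for the mask, so the mask
#' stays binary. Output shape is unchanged; positive `dx`/`dy` move content
#' rightwards/downwards.
#'
#' @param pair A [sample_pair()].
#' @param t A `transform_spec` from [sample_transform()].
#' @return The transformed `sample_pair`.
#' @export
apply_transform <- function(pair, t = identity_transform()) {
  stopifnot(inherits(pair, "sample_pair"), inherits(t, "transform_spec"))
  H <- nrow(pair$image); W <- ncol(pair$image)
  minv <- transform_inverse_matrix(t, H, W)
  sample_pair(
    image = .warp_affine_cpp(pair$image, minv, TRUE, 0),
    mask = .warp_affine_cpp(pair$mask, minv, FALSE, 0),
    slice_id = pair$slice_id
  )
}

#' Expand a dataset by joint augmentation
#'
#' Emits, for each input pair, the original followed by `multiplier - 1`
#' independently sampled augmented copies, so the output holds exactly
#' `multiplier * n` pairs (712 originals become 2136 at the default
#' multiplier of 3). Augmented copies get derived slice ids
#' (`<id>_aug1`, ...). Fixing `seed` makes the expansion bit-reproducible.
#'
#' @param pairs List of [sample_pair()]s.
#' @param policy An [augment_policy()].
#' @param seed Integer seed for the transform draws.
#' @return List of `multiplier * length(pairs)` sample pairs.
#' @export
expand_dataset <- function(pairs, policy = augment_policy(), seed = 1L) {
  if (length(pairs) == 0) {
    warning("empty input: nothing to expand", call. = FALSE)
    return(list())
  }
  withr::with_seed(seed, {
    out <- vector("list", policy$multiplier * length(pairs))
    k <- 0L
    for (p in pairs) {
      k <- k + 1L
      out[[k]] <- p
      for (j in seq_len(policy$multiplier - 1L)) {
        k <- k + 1L
        q <- apply_transform(p, sample_transform(policy))
        q$slice_id <- paste0(p$slice_id, "_aug", j)
        out[[k]] <- q
      }
    }
    out
  })
}
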