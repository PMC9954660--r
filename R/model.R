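# Architecture: residual/dense encoder with attention-gated decoder.

#' Network configuration for the residual-dense attention U-Net
#'
#' Builds the hyperparameter set describing the five-level encoder-decoder.
#' The encoder runs two residual stages followed by three dense stages; the
#' first four stages are each followed by 2x2 max-pooling and the fifth acts
#' as the bottleneck. Each of the four skip connections passes through an
#' additive attention gate before being concatenated with the upsampled
#' decoder features.
#'
#' The default configuration is the package's frozen reference architecture:
#' channel widths `base_width * c(1, 2, 4, 8, 8)`, two residual blocks per
#' residual stage, dense stages with (4, 2, 2) layers at growth rate 14,
#' 1x1 dense transitions, and attention-gate inner width equal to 0.75 times
#' the skip width. At `base_width = 64` this instantiates with exactly
#' 13,053,861 trainable parameters (see [count_parameters()]).
#'
#' @param input_side Expected square input side in pixels (metadata only; the
#'   network is fully convolutional). Default 224.
#' @param input_channels Number of input channels. Default 1 (windowed CT).
#' @param base_width Channels of the first stage; deeper stages use
#'   `base_width * c(1, 2, 4, 8, 8)` unless `width_per_level` is given.
#' @param width_per_level Optional explicit channel widths (length 5).
#' @param stage_kinds Encoder stage kinds, `"res"` or `"dense"` (length 5).
#' @param res_blocks_per_stage Number of residual blocks stacked in each
#'   residual stage. Default 2.
#' @param dense_layers_per_block Number of 3x3 layers in each dense stage
#'   (recycled across dense stages). Default `c(4, 2, 2)`.
#' @param growth_rate Channels added by each dense layer. Default scales with
#'   `base_width` as `max(1, round(14 * base_width / 64))`.
#' @param ag_inner_width_ratio Attention-gate inner width as a fraction of the
#'   skip channel count. Default 0.75.
#' @param output_channels Number of output probability maps. Default 1.
#' @return An object of class `rda_net_config`.
#' @seealso [build_rda_unet()], [count_parameters()]
#' @export
#' @examples
#' cfg <- rda_net_config(base_width = 8)
#' cfg$width_per_level
rda_net_config <- function(input_side = 224L, input_channels = 1L,
                           base_width = 64L, width_per_level = NULL,
                           stage_kinds = c("res", "res", "dense", "dense", "dense"),
                           res_blocks_per_stage = 2L,
                           dense_layers_per_block = c(4L, 2L, 2L),
                           growth_rate = NULL,
                           ag_inner_width_ratio = 0.75,
                           output_channels = 1L) {
  if (is.null(width_per_level)) {
    width_per_level <- as.integer(base_width * c(1, 2, 4, 8, 8))
  }
  if (is.null(growth_rate)) growth_rate <- max(1L, as.integer(round(14 * base_width / 64)))
  depth <- length(stage_kinds)
  stopifnot(
    depth == length(width_per_level),
    all(width_per_level > 0),
    all(stage_kinds %in% c("res", "dense")),
    res_blocks_per_stage >= 1,
    growth_rate >= 1,
    ag_inner_width_ratio > 0,
    input_side > 0, input_channels >= 1, output_channels >= 1
  )
  n_dense <- sum(stage_kinds == "dense")
  dense_layers <- rep_len(as.integer(dense_layers_per_block), max(n_dense, 1L))
  structure(list(
    input_side = as.integer(input_side),
    input_channels = as.integer(input_channels),
    base_width = as.integer(base_width),
    depth = as.integer(depth),
    stage_kinds = stage_kinds,
    width_per_level = as.integer(width_per_level),
    res_blocks_per_stage = as.integer(res_blocks_per_stage),
    dense_layers_per_block = dense_layers,
    growth_rate = as.integer(growth_rate),
    ag_inner_width_ratio = ag_inner_width_ratio,
    output_channels = as.integer(output_channels)
  ), class = "rda_net_config")
}

#' @export
print.rda_net_config <- function(x, ...) {
  cat("<rda_net_config>\n")
  cat("  input:", x$input_side, "x", x$input_side, "x", x$input_channels, "\n")
  cat("  stages:", paste(x$stage_kinds, collapse = ", "), "\n")
  cat("  widths:", paste(x$width_per_level, collapse = ", "), "\n")
  cat("  res blocks/stage:", x$res_blocks_per_stage,
      "| dense layers:", paste(x$dense_layers_per_block, collapse = ","),
      "| growth:", x$growth_rate, "\n")
  cat("  attention inner ratio:", x$ag_inner_width_ratio, "\n")
  invisible(x)
}

## ---- layer units ----------------------------------------------------------

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

conv_unit <- function(k, cin, cout, bn = TRUE) {
  u <- list(k = k, cin = cin, cout = cout,
            w = nn_param(he_init(k, cin, cout)),
            b = nn_param(numeric(cout)),
            bn = bn)
  if (bn) {
    u$gamma <- nn_param(rep(1, cout))
    u$beta <- nn_param(numeric(cout))
    u$state <- new.env(parent = emptyenv())
    u$state$rm <- numeric(cout)
    u$state$rv <- rep(1, cout)
  }
  u
}

tconv_unit <- function(cin, cout, bn = TRUE) {
  u <- list(k = 2L, cin = cin, cout = cout,
            w = nn_param(array(stats::rnorm(4 * cin * cout, sd = sqrt(2 / (4 * cin))),
                               c(2, 2, cin, cout))),
            b = nn_param(numeric(cout)),
            bn = bn)
  if (bn) {
    u$gamma <- nn_param(rep(1, cout))
    u$beta <- nn_param(numeric(cout))
    u$state <- new.env(parent = emptyenv())
    u$state$rm <- numeric(cout)
    u$state$rv <- rep(1, cout)
  }
  u
}

fw_unit <- function(tape, x, u, training, act = "relu", transposed = FALSE) {
  y <- if (transposed) op_convt2(tape, x, u$w, u$b) else op_conv2d(tape, x, u$w, u$b)
  if (isTRUE(u$bn)) y <- op_batchnorm(tape, y, u$gamma, u$beta, u$state, training)
  if (act == "relu") y <- op_relu(tape, y)
  y
}

#' Assemble the residual-dense attention U-Net
#'
#' Instantiates all trainable weights for the architecture described by a
#' [rda_net_config()]. Residual stages stack blocks of two 3x3
#' convolution-batchnorm layers with an additive identity shortcut (1x1
#' projection when widths change); dense stages chain 3x3 layers whose inputs
#' are the concatenation of all previous outputs, closed by a 1x1 transition;
#' decoder stages upsample with a learnable 2x2 transposed convolution, gate
#' the skip features with additive attention, concatenate, and refine with two
#' 3x3 convolutions. The final 1x1 convolution produces one logit map;
#' probabilities are obtained with a sigmoid at prediction time.
#'
#' Weight initialization draws from the session RNG (He-scaled normal); call
#' `set.seed()` beforehand for reproducible builds.
#'
#' @param config A [rda_net_config()].
#' @return An object of class `rda_unet`.
#' @export
#' @examples
#' set.seed(1)
#' net <- build_rda_unet(rda_net_config(base_width = 4))
#' count_parameters(net)$total
build_rda_unet <- function(config = rda_net_config()) {
  stopifnot(inherits(config, "rda_net_config"))
  W <- config$width_per_level
  depth <- config$depth
  enc <- vector("list", depth)
  cin <- config$input_channels
  dense_i <- 0L
  for (i in seq_len(depth)) {
    w <- W[i]
    if (config$stage_kinds[i] == "res") {
      blocks <- vector("list", config$res_blocks_per_stage)
      for (r in seq_len(config$res_blocks_per_stage)) {
        blocks[[r]] <- list(
          conv1 = conv_unit(3, cin, w),
          conv2 = conv_unit(3, w, w),
          proj = if (cin != w) conv_unit(1, cin, w) else NULL
        )
        cin <- w
      }
      enc[[i]] <- list(kind = "res", blocks = blocks)
    } else {
      dense_i <- dense_i + 1L
      L <- config$dense_layers_per_block[dense_i]
      g <- config$growth_rate
      layers <- vector("list", L)
      c0 <- cin
      for (l in seq_len(L)) layers[[l]] <- conv_unit(3, c0 + (l - 1) * g, g)
      enc[[i]] <- list(kind = "dense", layers = layers,
                       trans = conv_unit(1, c0 + L * g, w))
      cin <- w
    }
  }
  dec <- vector("list", depth - 1L)
  dec_in <- W[depth]
  for (i in seq(depth - 1L, 1L)) {
    w <- W[i]
    f <- max(1L, as.integer(round(w * config$ag_inner_width_ratio)))
    dec[[i]] <- list(
      up = tconv_unit(dec_in, w),
      theta = conv_unit(1, w, f, bn = FALSE),
      phi = conv_unit(1, w, f, bn = FALSE),
      psi = conv_unit(1, f, 1, bn = FALSE),
      conv1 = conv_unit(3, 2 * w, w),
      conv2 = conv_unit(3, w, w)
    )
    dec_in <- w
  }
  net <- structure(list(
    config = config,
    enc = enc,
    dec = dec,
    final = conv_unit(1, W[1], config$output_channels, bn = FALSE)
  ), class = "rda_unet")
  net
}

# Collect named parameter environments of a unit / the whole net.
unit_params <- function(u, prefix) {
  ps <- list()
  ps[[paste0(prefix, ".w")]] <- u$w
  ps[[paste0(prefix, ".b")]] <- u$b
  if (isTRUE(u$bn)) {
    ps[[paste0(prefix, ".gamma")]] <- u$gamma
    ps[[paste0(prefix, ".beta")]] <- u$beta
  }
  ps
}

net_params <- function(net) {
  ps <- list()
  for (i in seq_along(net$enc)) {
    st <- net$enc[[i]]
    pre <- paste0("enc", i)
    if (st$kind == "res") {
      for (r in seq_along(st$blocks)) {
        bl <- st$blocks[[r]]
        ps <- c(ps, unit_params(bl$conv1, paste0(pre, ".block", r, ".conv1")),
                unit_params(bl$conv2, paste0(pre, ".block", r, ".conv2")))
        if (!is.null(bl$proj)) {
          ps <- c(ps, unit_params(bl$proj, paste0(pre, ".block", r, ".proj")))
        }
      }
    } else {
      for (l in seq_along(st$layers)) {
        ps <- c(ps, unit_params(st$layers[[l]], paste0(pre, ".layer", l)))
      }
      ps <- c(ps, unit_params(st$trans, paste0(pre, ".transition")))
    }
  }
  for (i in seq_along(net$dec)) {
    d <- net$dec[[i]]
    pre <- paste0("dec", i)
    ps <- c(ps,
            unit_params(d$up, paste0(pre, ".up")),
            unit_params(d$theta, paste0(pre, ".ag.theta")),
            unit_params(d$phi, paste0(pre, ".ag.phi")),
            unit_params(d$psi, paste0(pre, ".ag.psi")),
            unit_params(d$conv1, paste0(pre, ".conv1")),
            unit_params(d$conv2, paste0(pre, ".conv2")))
  }
  c(ps, unit_params(net$final, "final"))
}

#' Count trainable parameters
#'
#' Sums every trainable weight, bias and batch-normalization scale/shift of a
#' built network, with a per-stage breakdown. The frozen default
#' configuration totals 13,053,861 parameters.
#'
#' @param net An `rda_unet` from [build_rda_unet()].
#' @return A list with `total` (integer count) and `by_stage`, a tibble with
#'   columns `stage` and `parameters`.
#' @export
#' @examples
#' set.seed(1)
#' count_parameters(build_rda_unet(rda_net_config(base_width = 4)))$by_stage
count_parameters <- function(net) {
  stopifnot(inherits(net, "rda_unet"))
  ps <- net_params(net)
  sizes <- vapply(ps, function(p) length(p$v), numeric(1))
  stage <- sub("\\..*$", "", names(sizes))
  tb <- tibble::tibble(stage = stage, parameters = sizes) |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(parameters = sum(.data$parameters), .groups = "drop") |>
    dplyr::arrange(match(.data$stage, unique(stage)))
  list(total = sum(sizes), by_stage = tb)
}

## ---- forward pass ---------------------------------------------------------

fw_res_stage <- function(tape, x, st, training) {
  for (bl in st$blocks) {
    h <- fw_unit(tape, x, bl$conv1, training, act = "relu")
    h <- fw_unit(tape, h, bl$conv2, training, act = "none")
    s <- if (is.null(bl$proj)) x else fw_unit(tape, x, bl$proj, training, act = "none")
    x <- op_relu(tape, op_add(tape, h, s))
  }
  x
}

fw_dense_stage <- function(tape, x, st, training) {
  cur <- x
  for (ly in st$layers) {
    h <- fw_unit(tape, cur, ly, training, act = "relu")
    cur <- op_concat_c(tape, cur, h)
  }
  fw_unit(tape, cur, st$trans, training, act = "relu")
}

fw_attention_gate <- function(tape, d, skip, gate, training) {
  t1 <- fw_unit(tape, skip, d$theta, training, act = "none")
  t2 <- fw_unit(tape, gate, d$phi, training, act = "none")
  r <- op_relu(tape, op_add(tape, t1, t2))
  alpha <- op_sigmoid(tape, fw_unit(tape, r, d$psi, training, act = "none"))
  list(gated = op_mul_bc(tape, skip, alpha), alpha = alpha)
}

# Full forward pass; returns the logit node plus attention coefficient maps.
rda_forward <- function(net, tape, x_node, training = FALSE) {
  depth <- net$config$depth
  skips <- vector("list", depth - 1L)
  cur <- x_node
  for (i in seq_len(depth)) {
    st <- net$enc[[i]]
    cur <- if (st$kind == "res") fw_res_stage(tape, cur, st, training)
           else fw_dense_stage(tape, cur, st, training)
    if (i < depth) {
      skips[[i]] <- cur
      cur <- op_maxpool2(tape, cur)
    }
  }
  attn <- vector("list", depth - 1L)
  for (i in seq(depth - 1L, 1L)) {
    d <- net$dec[[i]]
    up <- fw_unit(tape, cur, d$up, training, act = "relu", transposed = TRUE)
    ag <- fw_attention_gate(tape, d, skips[[i]], up, training)
    attn[[i]] <- ag$alpha$v
    cur <- op_concat_c(tape, ag$gated, up)
    cur <- fw_unit(tape, cur, d$conv1, training, act = "relu")
    cur <- fw_unit(tape, cur, d$conv2, training, act = "relu")
  }
  logits <- fw_unit(tape, cur, net$final, training, act = "none")
  list(logits = logits, attention = attn)
}

# Pad a (H, W, C, N) array with zeros to sides divisible by `mult`, returning
# the padded array and the original dims for cropping back.
pad_to_multiple <- function(x, mult) {
  d <- dim(x)
  H2 <- as.integer(ceiling(d[1] / mult) * mult)
  W2 <- as.integer(ceiling(d[2] / mult) * mult)
  if (H2 == d[1] && W2 == d[2]) return(list(x = x, H = d[1], W = d[2]))
  y <- array(0, c(H2, W2, d[3], d[4]))
  y[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = y, H = d[1], W = d[2])
}

#' Predict probability maps or binary masks
#'
#' Runs the network in evaluation mode (batch-norm uses running statistics).
#' Images whose side is not divisible by the network stride are zero-padded
#' and the output cropped back.
#'
#' @param object An `rda_unet`.
#' @param image A numeric matrix in `[0, 1]`, or a list of such matrices.
#' @param type `"prob"` for the sigmoid probability map, `"mask"` for the
#'   thresholded binary mask.
#' @param threshold Probability threshold for `type = "mask"`. Default 0.5.
#' @param batch_size Images evaluated per forward pass. Default 8.
#' @param ... Unused.
#' @return A matrix (or list of matrices) matching the input geometry.
#' @export
predict.rda_unet <- function(object, image, type = c("prob", "mask"),
                             threshold = 0.5, batch_size = 8L, ...) {
  type <- match.arg(type)
  single <- is.matrix(image)
  imgs <- if (single) list(image) else image
  stopifnot(length(imgs) >= 1, threshold > 0, threshold < 1)
  d1 <- dim(imgs[[1]])
  stopifnot(all(vapply(imgs, function(m) identical(dim(m), d1), logical(1))))
  mult <- 2^(object$config$depth - 1L)
  out <- vector("list", length(imgs))
  for (start in seq(1, length(imgs), by = batch_size)) {
    ii <- start:min(start + batch_size - 1L, length(imgs))
    x <- array(unlist(imgs[ii], use.names = FALSE), c(d1[1], d1[2], 1, length(ii)))
    p <- pad_to_multiple(x, mult)
    tape <- nn_tape()
    res <- rda_forward(object, tape, op_input(tape, p$x), training = FALSE)
    prob <- stats::plogis(res$logits$v)
    for (j in seq_along(ii)) {
      m <- prob[seq_len(p$H), seq_len(p$W), 1, j]
      out[[ii[j]]] <- if (type == "mask") (m > threshold) + 0 else m
    }
  }
  if (single) out[[1]] else out
}

#' @export
print.rda_unet <- function(x, ...) {
  cp <- count_parameters(x)
  cat("<rda_unet> residual-dense attention U-Net\n")
  print(x$config)
  cat("  trainable parameters:", format(cp$total, big.mark = ","), "\n")
  invisible(x)
}
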