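# Seeded minibatch training with ADAM, per-epoch accuracy curves, checkpoints.

#' Training configuration
#'
#' Defaults follow the reference recipe: ADAM, learning rate `1e-3`, batch
#' size 8; 200 epochs were used for the organ task and 100 for the lesion
#' task. The loss is binary cross-entropy on the logits by default, with
#' soft-Dice and the BCE+Dice sum selectable.
#'
#' @param epochs Number of epochs (>= 1). Default 200.
#' @param batch_size Minibatch size. Default 8.
#' @param learning_rate ADAM step size. Default 1e-3.
#' @param loss `"bce"`, `"dice"` or `"bce+dice"`.
#' @param seed Integer seed controlling shuffling (and any other training
#'   randomness).
#' @param prediction_threshold Probability threshold for pixel accuracy and
#'   mask prediction, in (0, 1). Default 0.5.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, learning_rate = 1e-3,
                         loss = c("bce", "dice", "bce+dice"), seed = 1L,
                         prediction_threshold = 0.5) {
  loss <- match.arg(loss)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            prediction_threshold > 0, prediction_threshold < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = "adam", loss = loss,
                 seed = as.integer(seed),
                 prediction_threshold = prediction_threshold),
            class = "train_config")
}

adam_state <- function() {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

adam_step <- function(params, st, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$g)) next
    if (is.null(st$m[[nm]])) {
      st$m[[nm]] <- p$g * 0
      st$v[[nm]] <- p$g * 0
    }
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * p$g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * p$g^2
    p$v <- p$v - lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  invisible(NULL)
}

pairs_to_arrays <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  n <- length(pairs)
  x <- array(0, c(d[1], d[2], 1, n))
  y <- array(0, c(d[1], d[2], 1, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- pairs[[i]]$image
    y[, , 1, i] <- pairs[[i]]$mask
  }
  list(x = x, y = y, n = n)
}

loss_node <- function(tape, logits, target, kind) {
  switch(kind,
         "bce" = op_bce_logits(tape, logits, target),
         "dice" = op_dice_logits(tape, logits, target),
         "bce+dice" = {
           a <- op_bce_logits(tape, logits, target)
           b <- op_dice_logits(tape, logits, target)
           nn_node(tape, a$v + b$v, bw = function(nd) {
             nn_acc(a, nd$g); nn_acc(b, nd$g)
           })
         })
}

eval_set <- function(net, xs, ys, batch_size, threshold, loss_kind) {
  n <- dim(xs)[4]
  tot_loss <- 0; correct <- 0; npix <- 0
  for (start in seq(1, n, by = batch_size)) {
    ii <- start:min(start + batch_size - 1L, n)
    xb <- xs[, , , ii, drop = FALSE]; yb <- ys[, , , ii, drop = FALSE]
    tape <- nn_tape()
    res <- rda_forward(net, tape, op_input(tape, xb), training = FALSE)
    l <- loss_node(tape, res$logits, yb, loss_kind)
    tot_loss <- tot_loss + l$v * length(ii)
    pred <- stats::plogis(res$logits$v) > threshold
    correct <- correct + sum(pred == (yb == 1))
    npix <- npix + length(yb)
  }
  list(loss = tot_loss / n, acc = correct / npix)
}

#' Train a network on a dataset split
#'
#' Standard seeded minibatch loop: per epoch, the training pairs are
#' reshuffled, each batch runs forward/backward through the tape, and ADAM
#' updates all parameters. Training loss and pixel accuracy are accumulated
#' over the training batches (batch-norm in training mode); validation loss
#' and accuracy are computed at the end of each epoch in evaluation mode.
#' The weights of the epoch with the lowest validation loss are restored
#' into the returned network. A non-finite loss aborts with a diagnostic.
#'
#' @param net An `rda_unet` from [build_rda_unet()].
#' @param split A `dataset_split` from [split_dataset()] (or any list with
#'   `train` and `val` lists of [sample_pair()]s).
#' @param config A [train_config()].
#' @param verbose Print a line per epoch. Default `FALSE`.
#' @return An object of class `rda_fit`: list with `net` (best-validation
#'   weights), `history` (tibble: epoch, loss, acc, val_loss, val_acc,
#'   attn_min, attn_max), `best_epoch`, `config`.
#' @export
train_model <- function(net, split, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "rda_unet"), length(split$train) >= 1)
  tr <- pairs_to_arrays(split$train)
  va <- if (length(split$val)) pairs_to_arrays(split$val) else NULL
  params <- net_params(net)
  st <- adam_state()
  hist <- vector("list", config$epochs)
  best <- list(loss = Inf, epoch = NA_integer_, values = NULL, bn = NULL)
  bn_states <- collect_bn_states(net)
  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(tr$n)
      ep_loss <- 0; ep_correct <- 0; ep_pix <- 0
      at_min <- Inf; at_max <- -Inf
      for (start in seq(1, tr$n, by = config$batch_size)) {
        ii <- idx[start:min(start + config$batch_size - 1L, tr$n)]
        xb <- tr$x[, , , ii, drop = FALSE]
        yb <- tr$y[, , , ii, drop = FALSE]
        tape <- nn_tape()
        res <- rda_forward(net, tape, op_input(tape, xb), training = TRUE)
        l <- loss_node(tape, res$logits, yb, config$loss)
        if (!is.finite(l$v)) {
          stop("training diverged: non-finite loss at epoch ", epoch, call. = FALSE)
        }
        nn_zero_grads(params)
        nn_backward(tape, l)
        adam_step(params, st, config$learning_rate)
        ep_loss <- ep_loss + l$v * length(ii)
        pred <- stats::plogis(res$logits$v) > config$prediction_threshold
        ep_correct <- ep_correct + sum(pred == (yb == 1))
        ep_pix <- ep_pix + length(yb)
        rng <- range(unlist(lapply(res$attention, range)))
        at_min <- min(at_min, rng[1]); at_max <- max(at_max, rng[2])
      }
      vl <- if (is.null(va)) list(loss = NA_real_, acc = NA_real_) else
        eval_set(net, va$x, va$y, config$batch_size,
                 config$prediction_threshold, config$loss)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = ep_loss / tr$n, acc = ep_correct / ep_pix,
        val_loss = vl$loss, val_acc = vl$acc,
        attn_min = at_min, attn_max = at_max)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.4f  val_loss %.4f  val_acc %.4f",
                        epoch, ep_loss / tr$n, ep_correct / ep_pix, vl$loss, vl$acc))
      }
      track <- if (is.null(va)) ep_loss / tr$n else vl$loss
      if (is.finite(track) && track < best$loss) {
        best$loss <- track
        best$epoch <- epoch
        best$values <- lapply(params, function(p) p$v)
        best$bn <- lapply(bn_states, function(s) list(rm = s$rm, rv = s$rv))
      }
    }
  })
  if (!is.null(best$values)) {
    for (nm in names(params)) params[[nm]]$v <- best$values[[nm]]
    for (i in seq_along(bn_states)) {
      bn_states[[i]]$rm <- best$bn[[i]]$rm
      bn_states[[i]]$rv <- best$bn[[i]]$rv
    }
  }
  structure(list(net = net, history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, config = config),
            class = "rda_fit")
}

collect_bn_states <- function(net) {
  sts <- list()
  grab <- function(u) if (isTRUE(u$bn)) sts[[length(sts) + 1]] <<- u$state
  for (stg in net$enc) {
    if (stg$kind == "res") {
      for (bl in stg$blocks) {
        grab(bl$conv1); grab(bl$conv2)
        if (!is.null(bl$proj)) grab(bl$proj)
      }
    } else {
      for (ly in stg$layers) grab(ly)
      grab(stg$trans)
    }
  }
  for (d in net$dec) {
    grab(d$up); grab(d$theta); grab(d$phi); grab(d$psi); grab(d$conv1); grab(d$conv2)
  }
  grab(net$final)
  sts
}

#' Predict a binary mask for one image
#'
#' Thin wrapper over [predict.rda_unet()] with `type = "mask"`; thresholding
#' is monotone — raising the threshold never adds foreground pixels.
#'
#' @param net An `rda_unet` or `rda_fit`.
#' @param image Numeric matrix in `[0, 1]`.
#' @param threshold Probability threshold in (0, 1). Default 0.5.
#' @return Binary 0/1 matrix.
#' @export
predict_mask <- function(net, image, threshold = 0.5) {
  if (inherits(net, "rda_fit")) net <- net$net
  predict(net, image, type = "mask", threshold = threshold)
}

#' @export
print.rda_fit <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("<rda_fit>", nrow(x$history), "epochs; best epoch", x$best_epoch, "\n")
  cat(sprintf("  final: loss %.4f acc %.4f val_loss %.4f val_acc %.4f\n",
              h$loss, h$acc, h$val_loss, h$val_acc))
  invisible(x)
}

#' Save a trained network checkpoint
#'
#' Stores the architecture configuration, all parameter values and
#' batch-norm running statistics; [load_checkpoint()] reproduces predictions
#' bit-identically.
#'
#' @param net An `rda_unet` or `rda_fit`.
#' @param path Output file (RDS).
#' @export
save_checkpoint <- function(net, path) {
  if (inherits(net, "rda_fit")) net <- net$net
  stopifnot(inherits(net, "rda_unet"))
  params <- net_params(net)
  bn <- collect_bn_states(net)
  saveRDS(list(config = net$config,
               values = lapply(params, function(p) p$v),
               bn = lapply(bn, function(s) list(rm = s$rm, rv = s$rv))),
          path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return An `rda_unet` with restored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_rda_unet(ck$config)
  params <- net_params(net)
  stopifnot(identical(names(params), names(ck$values)))
  for (nm in names(params)) params[[nm]]$v <- ck$values[[nm]]
  bn <- collect_bn_states(net)
  for (i in seq_along(bn)) {
    bn[[i]]$rm <- ck$bn[[i]]$rm
    bn[[i]]$rv <- ck$bn[[i]]$rv
  }
  net
}

#' Attention coefficient maps for one image
#'
#' Runs the network in evaluation mode and returns the per-level attention
#' gate coefficient maps (values in `[0, 1]`, one map per gated skip).
#'
#' @param net An `rda_unet` or `rda_fit`.
#' @param image Numeric matrix in `[0, 1]`.
#' @return List of matrices, finest level first.
#' @export
attention_maps <- function(net, image) {
  if (inherits(net, "rda_fit")) net <- net$net
  d <- dim(image)
  mult <- 2^(net$config$depth - 1L)
  p <- pad_to_multiple(array(image, c(d[1], d[2], 1, 1)), mult)
  tape <- nn_tape()
  res <- rda_forward(net, tape, op_input(tape, p$x), training = FALSE)
  lapply(res$attention, function(a) a[, , 1, 1])
}
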