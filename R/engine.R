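# Minimal reverse-mode tape for the network engine.
#
# Values are R arrays dim (H, W, C, N). A "node" is an environment holding the
# forward value `v`, the accumulated gradient `g` and a backward closure `bw`
# that pushes `g` into the node's inputs. Trainable parameters are free-standing
# environments (`nn_param`) whose gradients accumulate across a backward pass;
# they are not recorded on the tape.

nn_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

nn_node <- function(tape, v, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$bw <- bw
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

nn_param <- function(v) {
  p <- new.env(parent = emptyenv())
  p$v <- v
  p$g <- NULL
  p
}

nn_acc <- function(target, g) {
  if (is.null(target$g)) target$g <- g else target$g <- target$g + g
  invisible(NULL)
}

# Backward pass from a scalar loss node.
nn_backward <- function(tape, loss) {
  loss$g <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$bw) && !is.null(nd$g)) nd$bw(nd)
  }
  invisible(NULL)
}

nn_zero_grads <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

## ---- ops ------------------------------------------------------------------

op_input <- function(tape, x) nn_node(tape, x)

op_conv2d <- function(tape, x, w, b) {
  y <- .nn_conv2d_fw(x$v, w$v, b$v)
  nn_node(tape, y, bw = function(nd) {
    r <- .nn_conv2d_bw(x$v, w$v, nd$g)
    nn_acc(x, r$gx); nn_acc(w, r$gw); nn_acc(b, r$gb)
  })
}

op_convt2 <- function(tape, x, w, b) {
  y <- .nn_convt2_fw(x$v, w$v, b$v)
  nn_node(tape, y, bw = function(nd) {
    r <- .nn_convt2_bw(x$v, w$v, nd$g)
    nn_acc(x, r$gx); nn_acc(w, r$gw); nn_acc(b, r$gb)
  })
}

op_maxpool2 <- function(tape, x) {
  d <- dim(x$v)
  r <- .nn_maxpool2_fw(x$v)
  idx <- r$idx
  nn_node(tape, r$y, bw = function(nd) {
    nn_acc(x, .nn_maxpool2_bw(nd$g, idx, d[1], d[2]))
  })
}

op_relu <- function(tape, x) {
  nn_node(tape, .nn_relu_fw(x$v), bw = function(nd) {
    nn_acc(x, .nn_relu_bw(x$v, nd$g))
  })
}

op_sigmoid <- function(tape, x) {
  y <- stats::plogis(x$v)
  if (is.null(dim(y))) dim(y) <- dim(x$v)
  nn_node(tape, y, bw = function(nd) nn_acc(x, nd$g * y * (1 - y)))
}

op_add <- function(tape, a, b) {
  nn_node(tape, a$v + b$v, bw = function(nd) {
    nn_acc(a, nd$g); nn_acc(b, nd$g)
  })
}

op_concat_c <- function(tape, a, b) {
  da <- dim(a$v); db <- dim(b$v)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a$v
  y[, , da[3] + seq_len(db[3]), ] <- b$v
  nn_node(tape, y, bw = function(nd) {
    nn_acc(a, nd$g[, , seq_len(da[3]), , drop = FALSE])
    nn_acc(b, nd$g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Multiply each channel of `x` by a single-channel coefficient map `alpha`.
op_mul_bc <- function(tape, x, alpha) {
  d <- dim(x$v)
  al <- x$v
  al[] <- alpha$v[, , rep(1L, d[3]), , drop = FALSE]
  nn_node(tape, x$v * al, bw = function(nd) {
    nn_acc(x, nd$g * al)
    gal <- nd$g * x$v
    arr <- aperm(array(gal, c(d[1] * d[2], d[3], d[4])), c(2, 1, 3))
    ga <- colSums(arr)                      # (H*W, N)
    nn_acc(alpha, array(ga, c(d[1], d[2], 1, d[4])))
  })
}

# Batch normalization over (H, W, N) per channel.
op_batchnorm <- function(tape, x, gamma, beta, state, training,
                         momentum = 0.9, eps = 1e-5) {
  if (training) {
    st <- .nn_bn_stats(x$v)
    mu <- st$mu; va <- st$va
    state$rm <- momentum * state$rm + (1 - momentum) * mu
    state$rv <- momentum * state$rv + (1 - momentum) * va
  } else {
    mu <- state$rm; va <- state$rv
  }
  y <- .nn_bn_fw(x$v, gamma$v, beta$v, mu, va, eps)
  nn_node(tape, y, bw = function(nd) {
    r <- .nn_bn_bw(x$v, gamma$v, mu, va, nd$g, training, eps)
    nn_acc(gamma, r$gg); nn_acc(beta, r$gb); nn_acc(x, r$gx)
  })
}

# Mean binary cross-entropy on logits (numerically stable).
op_bce_logits <- function(tape, z, target) {
  zv <- z$v
  loss <- mean(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv))))
  nn_node(tape, loss, bw = function(nd) {
    nn_acc(z, nd$g * (stats::plogis(zv) - target) / length(zv))
  })
}

# Soft Dice loss on logits: 1 - (2*sum(p*t) + s) / (sum(p) + sum(t) + s).
op_dice_logits <- function(tape, z, target, smooth = 1) {
  p <- stats::plogis(z$v)
  num <- 2 * sum(p * target) + smooth
  den <- sum(p) + sum(target) + smooth
  nn_node(tape, 1 - num / den, bw = function(nd) {
    dp <- (num / den^2) - (2 * target) / den
    nn_acc(z, nd$g * dp * p * (1 - p))
  })
}
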