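# Building blocks, assembly, parameter accounting and gradients.

test_that("unit parameter counts follow the conv/batchnorm arithmetic", {
  u <- rdaunet:::conv_unit(3, 1, 1, bn = FALSE)
  expect_equal(length(u$w$v) + length(u$b$v), 10)  # 3*3*1*1 + 1
  ub <- rdaunet:::conv_unit(3, 4, 8, bn = TRUE)
  expect_equal(length(ub$gamma$v) + length(ub$beta$v), 16)  # 2C
  expect_equal(length(ub$w$v), 3 * 3 * 4 * 8)
})

test_that("the default configuration instantiates the reference parameter total", {
  set.seed(1)
  net <- build_rda_unet(rda_net_config())
  cp <- count_parameters(net)
  expect_identical(cp$total, 13053861)
  expect_true(all(c("enc1", "enc5", "dec1", "dec4", "final") %in% cp$by_stage$stage))
  expect_equal(sum(cp$by_stage$parameters), cp$total)
})

test_that("dense stages concatenate previous layers at the growth rate", {
  set.seed(1)
  net <- build_rda_unet(rda_net_config())  # enc3 input 128, growth 14, 4 layers
  st <- net$enc[[3]]
  expect_equal(st$kind, "dense")
  expect_equal(dim(st$layers[[1]]$w$v), c(3, 3, 128, 14))
  expect_equal(dim(st$layers[[4]]$w$v), c(3, 3, 128 + 3 * 14, 14))
  expect_equal(dim(st$trans$w$v), c(1, 1, 128 + 4 * 14, 256))
})

test_that("halving the channel widths strictly reduces the parameter total", {
  set.seed(1)
  full <- count_parameters(build_rda_unet(rda_net_config()))$total
  half <- count_parameters(build_rda_unet(rda_net_config(base_width = 32)))$total
  expect_lt(half, full)
})

test_that("parameter count is invariant to the declared input size", {
  set.seed(1)
  a <- count_parameters(build_rda_unet(rda_net_config(input_side = 224, base_width = 8)))$total
  b <- count_parameters(build_rda_unet(rda_net_config(input_side = 64, base_width = 8)))$total
  expect_identical(a, b)
})

test_that("forward output matches input shape with sigmoid-bounded values", {
  set.seed(2)
  net <- build_rda_unet(rda_net_config(base_width = 4, growth_rate = 2,
                                       dense_layers_per_block = c(2, 1, 1)))
  img <- matrix(runif(32 * 32), 32)
  p <- predict(net, img, type = "prob")
  expect_equal(dim(p), c(32L, 32L))
  expect_true(all(p > 0 & p < 1))
  # side not divisible by the stride: padding is applied and cropped back
  img2 <- matrix(runif(48 * 48), 48)
  p2 <- predict(net, img2, type = "prob")
  expect_equal(dim(p2), c(48L, 48L))
  # evaluation-mode forward is deterministic
  expect_identical(p, predict(net, img, type = "prob"))
})

test_that("a zeroed residual block is the identity under ReLU", {
  set.seed(3)
  net <- build_rda_unet(rda_net_config(base_width = 4, growth_rate = 2,
                                       dense_layers_per_block = c(1, 1, 1)))
  st <- net$enc[[2]]  # res stage with cin == w for its second block
  bl <- st$blocks[[2]]
  expect_null(bl$proj)  # width unchanged: identity shortcut
  bl$conv1$w$v[] <- 0; bl$conv1$b$v[] <- 0
  bl$conv2$w$v[] <- 0; bl$conv2$b$v[] <- 0
  x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  tape <- rdaunet:::nn_tape()
  one_block <- list(kind = "res", blocks = list(bl))
  y <- rdaunet:::fw_res_stage(tape, rdaunet:::op_input(tape, x), one_block,
                              training = TRUE)
  expect_equal(y$v, pmax(x, 0), tolerance = 1e-12)
})

test_that("attention gates pass through or suppress under forced psi settings", {
  set.seed(4)
  net <- build_rda_unet(rda_net_config(base_width = 4, growth_rate = 2,
                                       dense_layers_per_block = c(1, 1, 1)))
  d <- net$dec[[1]]
  w <- dim(d$theta$w$v)[3]
  skip <- array(rnorm(16 * 16 * w), c(16, 16, w, 1))
  gate <- array(rnorm(16 * 16 * w), c(16, 16, w, 1))
  run_ag <- function() {
    tape <- rdaunet:::nn_tape()
    ag <- rdaunet:::fw_attention_gate(tape, d,
                                      rdaunet:::op_input(tape, skip),
                                      rdaunet:::op_input(tape, gate), FALSE)
    list(alpha = ag$alpha$v, out = ag$gated$v)
  }
  r0 <- run_ag()
  expect_true(all(r0$alpha >= 0 & r0$alpha <= 1))
  d$psi$w$v[] <- 0; d$psi$b$v[] <- 30   # sigmoid ~ 1: output equals skip
  r1 <- run_ag()
  expect_equal(r1$out, skip, tolerance = 1e-8)
  d$psi$b$v[] <- -30                    # sigmoid ~ 0: output suppressed
  r2 <- run_ag()
  expect_lt(max(abs(r2$out)), 1e-8)
})

test_that("gradients flow to the trainable parameters and match finite differences", {
  set.seed(5)
  cfg <- rda_net_config(input_side = 16, base_width = 3, growth_rate = 2,
                        dense_layers_per_block = c(2, 1, 1))
  net <- build_rda_unet(cfg)
  ps <- rdaunet:::net_params(net)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  tgt <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  lossfun <- function() {
    tape <- rdaunet:::nn_tape()
    res <- rdaunet:::rda_forward(net, tape, rdaunet:::op_input(tape, x), TRUE)
    list(tape = tape, loss = rdaunet:::op_bce_logits(tape, res$logits, tgt))
  }
  r <- lossfun()
  rdaunet:::nn_zero_grads(ps)
  rdaunet:::nn_backward(r$tape, r$loss)
  # every parameter receives a defined, finite gradient
  for (p in ps) {
    expect_false(is.null(p$g))
    expect_true(all(is.finite(p$g)))
  }
  # weights, scales and shifts get nonzero gradients (conv biases feeding a
  # batch-norm have identically zero gradient: the normalisation removes any
  # constant shift, so they are excluded from the nonzero check)
  kinds <- sub(".*\\.", "", names(ps))
  for (nm in names(ps)[kinds %in% c("w", "gamma", "beta")]) {
    expect_gt(max(abs(ps[[nm]]$g)), 0)
  }
  # spot-check against central finite differences
  worst <- 0
  for (nm in sample(names(ps), 20)) {
    p <- ps[[nm]]
    i <- sample(length(p$v), 1)
    v0 <- p$v[i]
    p$v[i] <- v0 + 1e-6; lp <- lossfun()$loss$v
    p$v[i] <- v0 - 1e-6; lm <- lossfun()$loss$v
    p$v[i] <- v0
    num <- (lp - lm) / 2e-6
    ana <- p$g[i]
    if (abs(num) + abs(ana) > 1e-8) {
      worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(rda_net_config(width_per_level = c(8, 16)), "length")
  expect_error(rda_net_config(stage_kinds = c("res", "foo", "dense", "dense", "dense")))
  expect_error(rda_net_config(growth_rate = 0))
})
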