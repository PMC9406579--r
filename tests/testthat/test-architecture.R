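test_that("residual block: zeroed residual branch is the identity, shapes and shortcut params are right", {
  set.seed(1)
  blk <- res_block(8, 8)
  # zero the residual branch; the shortcut (identity) must pass x through
  blk$conv1$W[] <- 0; blk$conv1$b[] <- 0
  blk$conv2$W[] <- 0; blk$conv2$b[] <- 0
  x <- array(rnorm(32 * 32 * 8 * 2), c(32, 32, 8, 2))
  out <- segment_forward(blk, x, training = TRUE)
  expect_lt(max(abs(out - x)), 1e-6)
  # shape preservation with random weights
  set.seed(2)
  blk2 <- res_block(8, 8)
  expect_equal(dim(segment_forward(blk2, x, training = TRUE)), c(32, 32, 8, 2))
  # channel change requires a 1x1 projection: 8*16 weights + 16 biases
  blk3 <- res_block(8, 16)
  expect_equal(length(blk3$shortcut$W) + length(blk3$shortcut$b), 8 * 16 + 16)
  expect_null(res_block(8, 8)$shortcut)
})

test_that("dense block: channel arithmetic holds and layers=0 is the identity", {
  set.seed(3)
  cases <- list(c(16, 4, 8, 48), c(8, 2, 4, 16), c(3, 5, 7, 38))
  for (cs in cases) {
    blk <- dense_block(cs[1], cs[2], cs[3])
    x <- array(rnorm(16 * 16 * cs[1] * 2), c(16, 16, cs[1], 2))
    out <- segment_forward(blk, x, training = TRUE)
    expect_equal(dim(out)[3], cs[4])
    expect_equal(dim(out)[3], cs[1] + cs[2] * cs[3])
    # the block input passes through as the first channels
    expect_equal(out[, , seq_len(cs[1]), ], x)
  }
  blk0 <- dense_block(6, 0, 1)
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6, 1))
  expect_identical(segment_forward(blk0, x), x)
})

test_that("dense connectivity: perturbing layer 1 changes the inputs of all later layers", {
  set.seed(4)
  blk <- dense_block(6, 3, 4, norm = "none")
  x <- array(rnorm(8 * 8 * 6), c(8, 8, 6, 1))
  out1 <- segment_forward(blk, x)
  blk2 <- blk
  blk2$stages$layer1$conv$b <- blk2$stages$layer1$conv$b + 5
  out2 <- segment_forward(blk2, x)
  g <- blk$growth_rate
  for (i in 1:3) {
    sl <- 6 + (i - 1) * g + seq_len(g)
    expect_gt(max(abs(out2[, , sl, ] - out1[, , sl, ])), 0)
  }
  # the passthrough input channels are untouched
  expect_equal(out2[, , 1:6, ], out1[, , 1:6, ])
})

test_that("attention gate: coefficients in (0,1); saturated psi bias gives pass-through or suppression", {
  set.seed(5)
  gt <- attention_gate(skip_ch = 6, gate_ch = 10, inter_ch = 3)
  x <- array(runif(16 * 16 * 6 * 2), c(16, 16, 6, 2))
  g <- array(runif(8 * 8 * 10 * 2), c(8, 8, 10, 2))
  out <- segment_forward(gt, list(x = x, g = g))
  alpha <- attr(out, "alpha")
  expect_true(all(alpha > 0 & alpha < 1))
  expect_equal(dim(out), dim(x))
  # alpha -> 1: output equals the skip feature
  gt_open <- gt; gt_open$psi$b[] <- 20
  out_open <- segment_forward(gt_open, list(x = x, g = g))
  expect_lt(max(abs(out_open - x)), 1e-6 * max(abs(x)))
  # alpha -> 0: output suppressed
  gt_shut <- gt; gt_shut$psi$b[] <- -20
  out_shut <- segment_forward(gt_shut, list(x = x, g = g))
  expect_lt(max(abs(out_shut)), 1e-6 * max(abs(x)))
  # spatial precondition: g must be at half resolution
  g_bad <- array(runif(16 * 16 * 10 * 2), c(16, 16, 10, 2))
  expect_error(segment_forward(gt, list(x = x, g = g_bad)),
               "twice the spatial size")
})

test_that("end-to-end shape contract holds across input sizes and depths", {
  cases <- list(c(64, 3), c(128, 4), c(224, 4))
  for (cs in cases) {
    cfg <- arch_config(input_size = cs[1], depth = cs[2], base_filters = 4,
                       dense_layers = 2)
    net <- rda_unet(cfg, seed = 9)
    x <- array(runif(cs[1]^2), c(cs[1], cs[1], 1, 1))
    fw <- net_forward(net, x)
    expect_equal(dim(fw$prob), c(cs[1], cs[1], 1, 1))
    expect_true(all(fw$prob > 0 & fw$prob < 1))
  }
  expect_error(arch_config(input_size = 100, depth = 3), "divisible")
})

test_that("one attention gate per decoder stage; zero and one images produce different outputs", {
  cfg <- arch_config(input_size = 64, depth = 3, base_filters = 4, dense_layers = 1)
  net <- rda_unet(cfg, seed = 11)
  expect_length(net$decoder, 3)
  expect_true(all(vapply(net$decoder, function(s) s$gate$kind == "gate", logical(1))))
  fw0 <- net_forward(net, array(0, c(64, 64, 1, 1)))
  fw1 <- net_forward(net, array(1, c(64, 64, 1, 1)))
  expect_gt(max(abs(fw1$prob - fw0$prob)), 0)
  # per-sample independence: permuting the batch permutes the outputs
  set.seed(12)
  xa <- array(runif(64 * 64), c(64, 64, 1, 1))
  xb <- array(runif(64 * 64), c(64, 64, 1, 1))
  batch_ab <- array(c(xa, xb), c(64, 64, 1, 2))
  batch_ba <- array(c(xb, xa), c(64, 64, 1, 2))
  fa <- net_forward(net, batch_ab)$prob
  fb <- net_forward(net, batch_ba)$prob
  expect_equal(fa[, , , 1], fb[, , , 2])
  expect_equal(fa[, , , 2], fb[, , , 1])
})

test_that("count_parameters equals the analytic spreadsheet oracle", {
  # single 3x3 convolution, 1 -> 8 channels, with bias
  expect_equal(count_parameters(rdaunet:::new_conv(1, 8, 3)), 80)
  configs <- list(c(2, 4, 2), c(3, 8, 4), c(4, 16, 4))
  for (cs in configs) {
    cfg <- arch_config(input_size = 2^cs[1] * 4, depth = cs[1],
                       base_filters = cs[2], dense_layers = cs[3])
    net <- rda_unet(cfg, seed = 1)
    expect_equal(count_parameters(net), oracle_unet_params(cs[1], cs[2], cs[3]),
                 label = paste(cs, collapse = "/"))
  }
  # the manifest's per-node counts sum to the same total
  cfg <- arch_config(input_size = 32, depth = 2, base_filters = 4, dense_layers = 2)
  net <- rda_unet(cfg, seed = 2)
  expect_equal(sum(layer_manifest(net)$params), count_parameters(net))
})

test_that("doubling base_filters roughly quadruples the convolution weight count", {
  conv_weights <- function(net) {
    total <- 0
    walk <- function(obj) {
      if (!is.list(obj)) return(invisible())
      if (!is.null(obj$kind) && obj$kind %in% c("conv", "sconv", "convt")) {
        total <<- total + length(obj$W)
        return(invisible())
      }
      for (nm in names(obj)) if (is.list(obj[[nm]])) walk(obj[[nm]])
    }
    walk(net)
    total
  }
  n1 <- conv_weights(rda_unet(arch_config(input_size = 64, depth = 3,
                                          base_filters = 8), seed = 1))
  n2 <- conv_weights(rda_unet(arch_config(input_size = 64, depth = 3,
                                          base_filters = 16), seed = 1))
  expect_gt(n2 / n1, 3.5)
  expect_lt(n2 / n1, 4.5)
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- arch_config(input_size = 16, depth = 2, base_filters = 4, dense_layers = 2)
  net <- rda_unet(cfg, seed = 42)
  set.seed(1)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
  loss_at <- function(n) {
    f <- net_forward(n, x, training = TRUE)
    rdaunet:::compute_loss("bce", f$prob, y)$loss
  }
  fw <- net_forward(net, x, training = TRUE)
  ls <- rdaunet:::compute_loss("bce", fw$prob, y)
  bw <- rdaunet:::net_backward(net, fw$cache, ls$dlogits)
  paths <- rdaunet:::collect_param_paths(net)
  set.seed(2)
  for (pi in sample(length(paths), 10)) {
    p <- paths[[pi]]
    arr <- net[[p]]
    j <- sample(length(arr), 1)
    h <- 1e-5
    np <- net; np[[p]][j] <- arr[j] + h
    nm <- net; nm[[p]][j] <- arr[j] - h
    gnum <- (loss_at(np) - loss_at(nm)) / (2 * h)
    gana <- bw$grads[[p]][j]
    expect_lt(abs(gnum - gana) / max(1e-8, abs(gnum) + abs(gana)), 1e-4)
  }
})

test_that("the network description lists nodes as TSV", {
  cfg <- arch_config(input_size = 32, depth = 2, base_filters = 4, dense_layers = 1)
  net <- rda_unet(cfg, seed = 3)
  txt <- capture.output(describe_network(net))
  expect_gt(length(txt), 10)
  expect_match(txt[1], "node\ttype\tout_shape\tparams")
})
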