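# The full residual-dense-attention U-Net: configuration, construction,
# forward/backward, and the per-node shape/parameter manifest.

#' Architecture configuration
#'
#' Collects every hyperparameter of the network: the resolution schedule, the
#' channel schedule, the dense-block geometry and the attention-gate widths.
#'
#' Channel widths double per resolution level starting from `base_filters`.
#' Each encoder stage is (by default) a residual block to the level width
#' followed by a dense block; the dense growth rate defaults to half the
#' level width, so the stage (skip) channel count is
#' `w + dense_layers * w/2`. Attention-gate intermediate channels default to
#' half the skip channels.
#'
#' @param input_size Input image side in pixels; must be divisible by
#'   `2^depth` so pooling and up-convolution round-trip exactly.
#' @param input_channels Image channels (1 for CT).
#' @param depth Number of encoder resolution levels (a bottleneck sits below
#'   the deepest level).
#' @param base_filters Channel count at the top level.
#' @param dense_layers Convolutions per dense block.
#' @param growth_rate Channels added per dense layer; `NULL` (default) uses
#'   half the level width (at least 1).
#' @param attention_inter_channels Intermediate channels of each attention
#'   gate; `NULL` (default) uses half the skip channels (at least 1).
#' @param output_channels Output channels (1: binary probability map).
#' @param norm `"batchnorm"` or `"none"`, applied after each convolution.
#' @param blocks Encoder stage composition: `"serial"` (residual block then
#'   dense block, the default), `"res_only"` or `"dense_only"` for ablations.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(input_size = 224, input_channels = 1, depth = 4,
                        base_filters = 16, dense_layers = 4,
                        growth_rate = NULL, attention_inter_channels = NULL,
                        output_channels = 1,
                        norm = c("batchnorm", "none"),
                        blocks = c("serial", "res_only", "dense_only")) {
  norm <- match.arg(norm)
  blocks <- match.arg(blocks)
  if (depth < 2) stop_config("depth", "must be >= 2")
  if (base_filters < 1 || input_channels < 1 || output_channels < 1) {
    stop_config("channels", "must be >= 1")
  }
  if (dense_layers < 0) stop_config("dense_layers", "must be >= 0")
  if (input_size %% 2^depth != 0) {
    stop_config("input_size", sprintf("must be divisible by 2^depth = %d", 2^depth))
  }
  structure(list(input_size = input_size, input_channels = input_channels,
                 depth = depth, base_filters = base_filters,
                 dense_layers = dense_layers, growth_rate = growth_rate,
                 attention_inter_channels = attention_inter_channels,
                 output_channels = output_channels, norm = norm,
                 blocks = blocks),
            class = "arch_config")
}

# Channel schedule implied by a config: per-level widths, growth rates and
# stage (skip) output channels, plus the bottleneck.
channel_plan <- function(config) {
  d <- config$depth
  width <- config$base_filters * 2^(seq_len(d) - 1)
  growth <- if (is.null(config$growth_rate)) pmax(1, width %/% 2) else rep(config$growth_rate, d)
  wb <- config$base_filters * 2^d
  gb <- if (is.null(config$growth_rate)) max(1, wb %/% 2) else config$growth_rate
  stage_in <- numeric(d)
  stage_out <- numeric(d)
  cin <- config$input_channels
  for (l in seq_len(d)) {
    stage_in[l] <- cin
    stage_out[l] <- switch(config$blocks,
      serial = width[l] + config$dense_layers * growth[l],
      res_only = width[l],
      dense_only = cin + config$dense_layers * growth[l])
    cin <- stage_out[l]
  }
  bottleneck_out <- switch(config$blocks,
    serial = wb + config$dense_layers * gb,
    res_only = wb,
    dense_only = cin + config$dense_layers * gb)
  list(width = width, growth = growth, stage_in = stage_in,
       stage_out = stage_out, wb = wb, gb = gb,
       bottleneck_in = cin, bottleneck_out = bottleneck_out)
}

make_stage <- function(config, in_ch, width, growth) {
  st <- list(kind_stage = "enc")
  if (config$blocks %in% c("serial", "res_only")) {
    st$res <- res_block(in_ch, width, norm = config$norm)
    in_ch <- width
  }
  if (config$blocks %in% c("serial", "dense_only")) {
    st$dense <- dense_block(in_ch, config$dense_layers, growth, norm = config$norm)
  }
  st
}

stage_forward <- function(st, x, training) {
  cc <- list()
  if (!is.null(st$res)) {
    f <- res_forward(st$res, x, training); cc$res <- f$cache; x <- f$out
  }
  if (!is.null(st$dense)) {
    f <- dense_forward(st$dense, x, training); cc$dense <- f$cache; x <- f$out
  }
  list(out = x, cache = cc)
}

stage_backward <- function(st, cache, dout) {
  grads <- list()
  if (!is.null(st$dense)) {
    b <- dense_backward(st$dense, cache$dense, dout)
    grads$dense <- b$grads
    dout <- b$dx
  }
  if (!is.null(st$res)) {
    b <- res_backward(st$res, cache$res, dout)
    grads$res <- b$grads
    dout <- b$dx
  }
  list(dx = dout, grads = grads)
}

#' Build the residual-dense-attention U-Net
#'
#' Constructs the full layer graph: an encoder of `depth` stages (residual
#' block, dense block, 2x2 max pooling) with channel widths doubling per
#' level, a residual+dense bottleneck, and a decoder of `depth` stages (2x
#' up-convolution, attention gate on the corresponding encoder skip,
#' concatenation, two 3x3 convolutions), closed by a 1x1 convolution and a
#' sigmoid producing a one-channel probability map at input resolution.
#'
#' @param config An [arch_config()].
#' @param seed Optional integer; seeds the weight initialization (He-normal
#'   for convolutions) so construction is reproducible.
#' @return An object of class `rda_net`.
#' @export
rda_unet <- function(config = arch_config(), seed = NULL) {
  stopifnot(inherits(config, "arch_config"))
  with_seed(seed, {
    plan <- channel_plan(config)
    d <- config$depth
    enc <- list()
    for (l in seq_len(d)) {
      enc[[paste0("stage", l)]] <-
        make_stage(config, plan$stage_in[l], plan$width[l], plan$growth[l])
    }
    bottleneck <- make_stage(config, plan$bottleneck_in, plan$wb, plan$gb)
    dec <- list()
    gate_ch <- plan$bottleneck_out
    for (l in rev(seq_len(d))) {
      skip_ch <- plan$stage_out[l]
      inter <- if (is.null(config$attention_inter_channels)) {
        max(1, skip_ch %/% 2)
      } else config$attention_inter_channels
      dec[[paste0("stage", l)]] <-
        new_decoder_stage(skip_ch, gate_ch, plan$width[l], inter, config$norm)
      gate_ch <- plan$width[l]
    }
    head <- new_conv(plan$width[1], config$output_channels, 1, 0)
    structure(list(config = config, plan = plan, encoder = enc,
                   bottleneck = bottleneck, decoder = dec, head = head),
              class = "rda_net")
  })
}

#' Forward pass of the network
#'
#' @param net An [rda_unet()] network.
#' @param x Input batch, `[H, W, C, N]` array (a single `[H, W]` matrix or
#'   `[H, W, C]` array is promoted to a batch of one).
#' @param training Logical; training mode uses batch statistics in
#'   normalization layers and records them into the running buffers.
#' @return List with `prob` (probability maps `[H, W, 1, N]`, values in
#'   (0, 1)), `logits`, and `cache` (for the backward pass).
#' @export
net_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 2L || is.null(dim(x))) dim(x) <- c(dim(x) %||% length(x), 1, 1)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1)
  d <- dim(x)
  if (d[1] != net$config$input_size || d[2] != net$config$input_size) {
    stop(sprintf("input spatial size %dx%d does not match the configured input_size %d",
                 d[1], d[2], net$config$input_size), call. = FALSE)
  }
  if (d[3] != net$config$input_channels) {
    stop("input channel count does not match the configuration", call. = FALSE)
  }
  cc <- list(encoder = list(), pools = list(), decoder = list())
  skips <- list()
  h <- x
  for (l in seq_len(net$config$depth)) {
    nm <- paste0("stage", l)
    sf <- stage_forward(net$encoder[[nm]], h, training)
    cc$encoder[[nm]] <- sf$cache
    skips[[nm]] <- sf$out
    pf <- maxpool_forward(sf$out)
    cc$pools[[nm]] <- pf$cache
    h <- pf$out
  }
  bf <- stage_forward(net$bottleneck, h, training)
  cc$bottleneck <- bf$cache
  h <- bf$out
  alphas <- list()
  for (l in rev(seq_len(net$config$depth))) {
    nm <- paste0("stage", l)
    df <- dec_forward(net$decoder[[nm]], skips[[nm]], h, training)
    cc$decoder[[nm]] <- df$cache
    alphas[[nm]] <- df$alpha
    h <- df$out
  }
  hf <- conv_forward(net$head, h)
  cc$head <- hf$cache
  sf <- sigmoid_forward(hf$out)
  cc$sig <- sf$cache
  list(prob = sf$out, logits = hf$out, cache = cc, alphas = alphas)
}

# Backward pass from a gradient w.r.t. the head logits (pre-sigmoid). Returns
# the gradient tree matching the network structure.
net_backward <- function(net, cache, dlogits) {
  grads <- list(encoder = list(), decoder = list())
  hb <- conv_backward(net$head, cache$head, dlogits)
  grads$head <- hb$grads
  dh <- hb$dx
  dskips <- list()
  for (l in seq_len(net$config$depth)) {
    nm <- paste0("stage", l)
    db <- dec_backward(net$decoder[[nm]], cache$decoder[[nm]], dh)
    grads$decoder[[nm]] <- db$grads
    dskips[[nm]] <- db$dskip
    dh <- db$dg
  }
  bb <- stage_backward(net$bottleneck, cache$bottleneck, dh)
  grads$bottleneck <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(net$config$depth))) {
    nm <- paste0("stage", l)
    dpool <- maxpool_backward(cache$pools[[nm]], dh)
    sb <- stage_backward(net$encoder[[nm]], cache$encoder[[nm]],
                         dpool + dskips[[nm]])
    grads$encoder[[nm]] <- sb$grads
    dh <- sb$dx
  }
  list(grads = grads, dx = dh)
}

#' Per-node shape and parameter manifest
#'
#' Walks the network structure, propagating spatial sizes and channel counts,
#' and reports one row per parameterized node (convolutions, up-convolutions,
#' normalizations) with its output shape and trainable-parameter count. The
#' `params` column sums to [count_parameters()].
#'
#' @param net An [rda_unet()] network.
#' @return A tibble with columns `node`, `type`, `out_shape`, `params`.
#' @export
layer_manifest <- function(net) {
  rows <- list()
  add <- function(node, type, h, w, c, params) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node = node, type = type,
      out_shape = sprintf("%dx%dx%d", h, w, c), params = params)
  }
  n_conv <- function(l) length(l$W) + length(l$b)
  n_bn <- function(l) length(l$gamma) + length(l$beta)
  emit_stage <- function(st, prefix, h, w) {
    if (!is.null(st$res)) {
      r <- st$res
      oc <- r$conv1$out_ch
      add(paste0(prefix, ".res.conv1"), "conv3x3", h, w, oc, n_conv(r$conv1))
      if (!is.null(r$bn1)) add(paste0(prefix, ".res.bn1"), "batchnorm", h, w, oc, n_bn(r$bn1))
      add(paste0(prefix, ".res.conv2"), "conv3x3", h, w, oc, n_conv(r$conv2))
      if (!is.null(r$bn2)) add(paste0(prefix, ".res.bn2"), "batchnorm", h, w, oc, n_bn(r$bn2))
      if (!is.null(r$shortcut)) {
        add(paste0(prefix, ".res.shortcut"), "conv1x1", h, w, oc, n_conv(r$shortcut))
      }
    }
    if (!is.null(st$dense)) {
      dn <- st$dense
      for (i in seq_len(dn$layers)) {
        l <- dn$stages[[paste0("layer", i)]]
        add(sprintf("%s.dense.layer%d.conv", prefix, i), "conv3x3", h, w,
            dn$growth_rate, n_conv(l$conv))
        if (!is.null(l$bn)) {
          add(sprintf("%s.dense.layer%d.bn", prefix, i), "batchnorm", h, w,
              dn$growth_rate, n_bn(l$bn))
        }
      }
      add(paste0(prefix, ".dense.concat"), "concat", h, w, dn$out_ch, 0)
    }
  }
  s <- net$config$input_size
  h <- s
  for (l in seq_len(net$config$depth)) {
    nm <- paste0("stage", l)
    emit_stage(net$encoder[[nm]], paste0("encoder.", nm), h, h)
    add(paste0("encoder.", nm, ".pool"), "maxpool2x2", h / 2, h / 2,
        net$plan$stage_out[l], 0)
    h <- h / 2
  }
  emit_stage(net$bottleneck, "bottleneck", h, h)
  for (l in rev(seq_len(net$config$depth))) {
    nm <- paste0("stage", l)
    st <- net$decoder[[nm]]
    g <- st$gate
    add(paste0("decoder.", nm, ".gate.theta_x"), "conv1x1s2", h, h,
        g$inter_ch, n_conv(g$theta_x))
    add(paste0("decoder.", nm, ".gate.phi_g"), "conv1x1", h, h,
        g$inter_ch, n_conv(g$phi_g))
    add(paste0("decoder.", nm, ".gate.psi"), "conv1x1", h, h, 1, n_conv(g$psi))
    h <- h * 2
    add(paste0("decoder.", nm, ".up"), "convT2x2", h, h, st$up$out_ch, n_conv(st$up))
    add(paste0("decoder.", nm, ".conv1"), "conv3x3", h, h,
        st$conv1$out_ch, n_conv(st$conv1))
    if (!is.null(st$bn1)) add(paste0("decoder.", nm, ".bn1"), "batchnorm", h, h,
                              st$conv1$out_ch, n_bn(st$bn1))
    add(paste0("decoder.", nm, ".conv2"), "conv3x3", h, h,
        st$conv2$out_ch, n_conv(st$conv2))
    if (!is.null(st$bn2)) add(paste0("decoder.", nm, ".bn2"), "batchnorm", h, h,
                              st$conv2$out_ch, n_bn(st$bn2))
  }
  add("head", "conv1x1+sigmoid", s, s, net$config$output_channels, n_conv(net$head))
  dplyr::bind_rows(rows)
}

#' Print the layer manifest as TSV
#'
#' @param net An [rda_unet()] network.
#' @param file Connection or path; default prints to stdout.
#' @export
describe_network <- function(net, file = stdout()) {
  m <- layer_manifest(net)
  write.table(m, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @export
print.rda_net <- function(x, ...) {
  cat(sprintf("<rda_net> input %dx%dx%d, depth %d, base filters %d, %s blocks, %s\n",
              x$config$input_size, x$config$input_size, x$config$input_channels,
              x$config$depth, x$config$base_filters, x$config$blocks,
              x$config$norm))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}
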