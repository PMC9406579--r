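# Composite network blocks: residual block, dense block, attention gate and
# the decoder stage. Each has a constructor, a forward and a backward; the
# backward returns a gradient tree with the same names as the block so the
# optimizer can walk both in parallel.

#' Residual convolution block
#'
#' Computes `H(x) = F(x) + shortcut(x)`, where the residual branch `F` is two
#' 3x3 convolution -> normalization -> ReLU stages mapping `in_ch` to
#' `out_ch` channels, and the shortcut is the identity when channels match or
#' a 1x1 convolution otherwise. The residual formulation lets a stage fall
#' back to an (approximate) identity mapping, which mitigates vanishing
#' gradients in deep encoders. Spatial size is preserved.
#'
#' @param in_ch,out_ch Input and output channel counts (>= 1).
#' @param norm `"batchnorm"` (default) or `"none"`.
#' @return A block object usable with [segment_forward()] and inside
#'   [rda_unet()].
#' @export
res_block <- function(in_ch, out_ch, norm = c("batchnorm", "none")) {
  norm <- match.arg(norm)
  if (in_ch < 1 || out_ch < 1) stop_config("channels", "must be >= 1")
  blk <- list(kind = "res", norm = norm,
              conv1 = new_conv(in_ch, out_ch, 3),
              conv2 = new_conv(out_ch, out_ch, 3))
  if (norm == "batchnorm") {
    blk$bn1 <- new_bn(out_ch)
    blk$bn2 <- new_bn(out_ch)
  }
  if (in_ch != out_ch) blk$shortcut <- new_conv(in_ch, out_ch, 1, 0)
  blk
}

res_forward <- function(blk, x, training) {
  cc <- list()
  f1 <- conv_forward(blk$conv1, x); cc$conv1 <- f1$cache
  h <- f1$out
  if (blk$norm == "batchnorm") {
    b1 <- bn_forward(blk$bn1, h, training); cc$bn1 <- b1$cache; h <- b1$out
  }
  r1 <- relu_forward(h); cc$relu1 <- r1$cache; h <- r1$out
  f2 <- conv_forward(blk$conv2, h); cc$conv2 <- f2$cache
  h <- f2$out
  if (blk$norm == "batchnorm") {
    b2 <- bn_forward(blk$bn2, h, training); cc$bn2 <- b2$cache; h <- b2$out
  }
  r2 <- relu_forward(h); cc$relu2 <- r2$cache; fx <- r2$out
  if (!is.null(blk$shortcut)) {
    sc <- conv_forward(blk$shortcut, x); cc$shortcut <- sc$cache
    s <- sc$out
  } else {
    s <- x
  }
  list(out = fx + s, cache = cc)
}

res_backward <- function(blk, cache, dout) {
  grads <- list()
  # shortcut branch
  if (!is.null(blk$shortcut)) {
    bs <- conv_backward(blk$shortcut, cache$shortcut, dout)
    grads$shortcut <- bs$grads
    dx_short <- bs$dx
  } else {
    dx_short <- dout
  }
  # residual branch
  dh <- relu_backward(cache$relu2, dout)
  if (blk$norm == "batchnorm") {
    b2 <- bn_backward(blk$bn2, cache$bn2, dh)
    grads$bn2 <- b2$grads
    dh <- b2$dx
  }
  c2 <- conv_backward(blk$conv2, cache$conv2, dh)
  grads$conv2 <- c2$grads
  dh <- relu_backward(cache$relu1, c2$dx)
  if (blk$norm == "batchnorm") {
    b1 <- bn_backward(blk$bn1, cache$bn1, dh)
    grads$bn1 <- b1$grads
    dh <- b1$dx
  }
  c1 <- conv_backward(blk$conv1, cache$conv1, dh)
  grads$conv1 <- c1$grads
  list(dx = c1$dx + dx_short, grads = grads)
}

#' Densely connected convolution block
#'
#' Each layer consumes the channel-wise concatenation of the block input and
#' all previous layers' outputs and emits `growth_rate` new channels
#' (3x3 convolution -> normalization -> ReLU). The block output is the
#' concatenation of the input with every layer's output, so its channel count
#' is `in_ch + layers * growth_rate`. Feature reuse through concatenation
#' keeps the per-layer width small while giving later layers direct access to
#' earlier features.
#'
#' @param in_ch Input channel count.
#' @param layers Number of convolution layers (>= 0; 0 gives the identity).
#' @param growth_rate Channels added per layer (>= 1).
#' @inheritParams res_block
#' @return A block object.
#' @export
dense_block <- function(in_ch, layers, growth_rate, norm = c("batchnorm", "none")) {
  norm <- match.arg(norm)
  if (layers < 0) stop_config("layers", "must be >= 0")
  if (layers > 0 && growth_rate < 1) stop_config("growth_rate", "must be >= 1")
  lyrs <- list()
  cin <- in_ch
  for (i in seq_len(layers)) {
    l <- list(conv = new_conv(cin, growth_rate, 3))
    if (norm == "batchnorm") l$bn <- new_bn(growth_rate)
    lyrs[[paste0("layer", i)]] <- l
    cin <- cin + growth_rate
  }
  list(kind = "dense", norm = norm, in_ch = in_ch, layers = layers,
       growth_rate = growth_rate, out_ch = in_ch + layers * growth_rate,
       stages = lyrs)
}

dense_forward <- function(blk, x, training) {
  if (blk$layers == 0) return(list(out = x, cache = list()))
  cc <- list()
  feat <- x
  for (i in seq_len(blk$layers)) {
    nm <- paste0("layer", i)
    l <- blk$stages[[nm]]
    f <- conv_forward(l$conv, feat)
    lc <- list(conv = f$cache)
    h <- f$out
    if (blk$norm == "batchnorm") {
      b <- bn_forward(l$bn, h, training); lc$bn <- b$cache; h <- b$out
    }
    r <- relu_forward(h); lc$relu <- r$cache
    cc[[nm]] <- lc
    feat <- cat_channels(feat, r$out)
  }
  list(out = feat, cache = cc)
}

dense_backward <- function(blk, cache, dout) {
  if (blk$layers == 0) return(list(dx = dout, grads = list()))
  g <- blk$growth_rate
  # Channel layout of the output: [input (in_ch) | y1 | y2 | ... | yL]
  dfeat <- dout  # gradient wrt the running concatenation
  grads <- list(stages = list())
  for (i in rev(seq_len(blk$layers))) {
    nm <- paste0("layer", i)
    l <- blk$stages[[nm]]
    lc <- cache[[nm]]
    nin <- blk$in_ch + (i - 1) * g
    dyi <- dfeat[, , nin + seq_len(g), , drop = FALSE]
    dprev <- dfeat[, , seq_len(nin), , drop = FALSE]
    dh <- relu_backward(lc$relu, dyi)
    lg <- list()
    if (blk$norm == "batchnorm") {
      b <- bn_backward(l$bn, lc$bn, dh)
      lg$bn <- b$grads
      dh <- b$dx
    }
    cb <- conv_backward(l$conv, lc$conv, dh)
    lg$conv <- cb$grads
    grads$stages[[nm]] <- lg
    dfeat <- dprev + cb$dx
  }
  list(dx = dfeat, grads = grads)
}

#' Additive attention gate
#'
#' Gates an encoder skip feature `x` with a coarser gating signal `g` coming
#' from one resolution level below (half the spatial size). `x` is
#' downsampled to `g`'s grid by a strided 1x1 convolution, both inputs are
#' projected to `inter_ch` channels (`Wx`, `Wg`), summed, passed through ReLU,
#' projected to a single channel (`psi`) and squashed with a sigmoid to give
#' attention coefficients in (0, 1). The coefficients are upsampled back to
#' `x`'s grid and multiplied into every channel of `x`, suppressing regions
#' the decoder considers irrelevant.
#'
#' @param skip_ch Channels of the skip feature `x`.
#' @param gate_ch Channels of the gating signal `g`.
#' @param inter_ch Channels of the intermediate attention space.
#' @return A gate object; forward it with [segment_forward()] giving
#'   `list(x = ..., g = ...)`.
#' @export
attention_gate <- function(skip_ch, gate_ch, inter_ch) {
  if (min(skip_ch, gate_ch, inter_ch) < 1) stop_config("channels", "must be >= 1")
  list(kind = "gate", skip_ch = skip_ch, gate_ch = gate_ch, inter_ch = inter_ch,
       theta_x = new_sconv(skip_ch, inter_ch),
       phi_g = new_conv(gate_ch, inter_ch, 1, 0),
       psi = new_conv(inter_ch, 1, 1, 0))
}

gate_forward <- function(gt, x, g) {
  dx_ <- dim(x); dg <- dim(g)
  if (dx_[1] != 2 * dg[1] || dx_[2] != 2 * dg[2]) {
    stop("attention gate: skip feature must have twice the spatial size of the gating signal",
         call. = FALSE)
  }
  cc <- list()
  tx <- sconv_forward(gt$theta_x, x); cc$theta_x <- tx$cache
  pg <- conv_forward(gt$phi_g, g); cc$phi_g <- pg$cache
  r <- relu_forward(tx$out + pg$out); cc$relu <- r$cache
  ps <- conv_forward(gt$psi, r$out); cc$psi <- ps$cache
  sg <- sigmoid_forward(ps$out); cc$sig <- sg$cache
  up <- upsample_nn_forward(sg$out); cc$up <- up$cache
  alpha_full <- up$out[, , rep(1L, dx_[3]), , drop = FALSE]
  cc$x <- x
  cc$alpha <- up$out
  list(out = x * alpha_full, cache = cc, alpha = sg$out)
}

gate_backward <- function(gt, cache, dout) {
  d <- dim(cache$x)
  alpha_full <- cache$alpha[, , rep(1L, d[3]), , drop = FALSE]
  dx1 <- dout * alpha_full
  # gradient wrt the (broadcast) attention map: sum over channels
  da_full <- dout * cache$x
  m <- act_to_mat(da_full)
  dalpha <- array(rowSums(m), c(d[1], d[2], 1, d[4]))
  da_small <- upsample_nn_backward(cache$up, dalpha)
  sg <- sigmoid_backward(cache$sig, da_small)
  ps <- conv_backward(gt$psi, cache$psi, sg)
  ds <- relu_backward(cache$relu, ps$dx)
  tx <- sconv_backward(gt$theta_x, cache$theta_x, ds)
  pg <- conv_backward(gt$phi_g, cache$phi_g, ds)
  list(dx = dx1 + tx$dx, dg = pg$dx,
       grads = list(theta_x = tx$grads, phi_g = pg$grads, psi = ps$grads))
}

# ---- decoder stage ----------------------------------------------------------

new_decoder_stage <- function(skip_ch, gate_ch, out_ch, inter_ch, norm) {
  st <- list(kind = "dec", norm = norm,
             gate = attention_gate(skip_ch, gate_ch, inter_ch),
             up = new_convt(gate_ch, out_ch),
             conv1 = new_conv(out_ch + skip_ch, out_ch, 3),
             conv2 = new_conv(out_ch, out_ch, 3))
  if (norm == "batchnorm") {
    st$bn1 <- new_bn(out_ch)
    st$bn2 <- new_bn(out_ch)
  }
  st
}

dec_forward <- function(st, skip, g, training) {
  cc <- list()
  gf <- gate_forward(st$gate, skip, g); cc$gate <- gf$cache
  uf <- convt_forward(st$up, g); cc$up <- uf$cache
  cc$n_up <- dim(uf$out)[3]
  h <- cat_channels(uf$out, gf$out)
  f1 <- conv_forward(st$conv1, h); cc$conv1 <- f1$cache; h <- f1$out
  if (st$norm == "batchnorm") {
    b1 <- bn_forward(st$bn1, h, training); cc$bn1 <- b1$cache; h <- b1$out
  }
  r1 <- relu_forward(h); cc$relu1 <- r1$cache; h <- r1$out
  f2 <- conv_forward(st$conv2, h); cc$conv2 <- f2$cache; h <- f2$out
  if (st$norm == "batchnorm") {
    b2 <- bn_forward(st$bn2, h, training); cc$bn2 <- b2$cache; h <- b2$out
  }
  r2 <- relu_forward(h); cc$relu2 <- r2$cache
  list(out = r2$out, cache = cc, alpha = gf$alpha)
}

dec_backward <- function(st, cache, dout) {
  grads <- list()
  dh <- relu_backward(cache$relu2, dout)
  if (st$norm == "batchnorm") {
    b2 <- bn_backward(st$bn2, cache$bn2, dh); grads$bn2 <- b2$grads; dh <- b2$dx
  }
  c2 <- conv_backward(st$conv2, cache$conv2, dh); grads$conv2 <- c2$grads
  dh <- relu_backward(cache$relu1, c2$dx)
  if (st$norm == "batchnorm") {
    b1 <- bn_backward(st$bn1, cache$bn1, dh); grads$bn1 <- b1$grads; dh <- b1$dx
  }
  c1 <- conv_backward(st$conv1, cache$conv1, dh); grads$conv1 <- c1$grads
  n_up <- cache$n_up
  dup <- c1$dx[, , seq_len(n_up), , drop = FALSE]
  dgated <- c1$dx[, , n_up + seq_len(dim(c1$dx)[3] - n_up), , drop = FALSE]
  ub <- convt_backward(st$up, cache$up, dup); grads$up <- ub$grads
  gb <- gate_backward(st$gate, cache$gate, dgated); grads$gate <- gb$grads
  list(dskip = gb$dx, dg = ub$dx + gb$dg, grads = grads)
}

#' Run a standalone block segment forward
#'
#' Convenience forward pass for individual blocks ([res_block()],
#' [dense_block()], [attention_gate()]), mainly for inspection and testing.
#' Inputs are `[H, W, C, N]` arrays; attention gates take
#' `list(x = skip, g = gating)`.
#'
#' @param segment A block object.
#' @param input Input activation array, or a list for gates.
#' @param training Logical; use batch statistics (TRUE) or running statistics
#'   (FALSE) in normalization layers.
#' @return The output activation array. For attention gates the attention
#'   coefficients are attached as attribute `"alpha"`.
#' @export
segment_forward <- function(segment, input, training = FALSE) {
  switch(segment$kind,
    res = res_forward(segment, input, training)$out,
    dense = dense_forward(segment, input, training)$out,
    gate = {
      f <- gate_forward(segment, input$x, input$g)
      out <- f$out
      attr(out, "alpha") <- f$alpha
      out
    },
    stop("unknown segment kind: ", segment$kind)
  )
}
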