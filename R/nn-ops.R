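# Low-level neural-network primitives with explicit backward passes.
#
# Activations are 4-D arrays [H, W, C, N] (rows, columns, channels, batch).
# Every layer is a plain list carrying its parameter arrays; forward functions
# return list(out, cache) and backward functions return list(dx, grads) where
# grads mirrors the layer's parameter names. Convolutions are im2col + GEMM;
# the patch gather/scatter lives in compiled code (src/im2col.cpp).

# ---- reshape helpers --------------------------------------------------------

# [H,W,C,N] -> (H*W*N) x C matrix, row index ordered (i, j, n).
act_to_mat <- function(x) {
  d <- dim(x)
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

# inverse of act_to_mat
mat_to_act <- function(m, H, W, N) {
  C <- ncol(m)
  aperm(array(m, c(H, W, N, C)), c(1, 2, 4, 3))
}

cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- convolution (k x k, stride 1, zero padding) ----------------------------

new_conv <- function(in_ch, out_ch, k = 3, pad = (k - 1) %/% 2) {
  sd <- sqrt(2 / (k * k * in_ch))
  list(kind = "conv", k = k, pad = pad, in_ch = in_ch, out_ch = out_ch,
       W = array(rnorm(k * k * in_ch * out_ch, sd = sd), c(k, k, in_ch, out_ch)),
       b = numeric(out_ch))
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  if (layer$k == 1L && layer$pad == 0L) {
    xm <- act_to_mat(x)
    Wm <- matrix(layer$W, layer$in_ch, layer$out_ch)
    Z <- xm %*% Wm
    Z <- sweep(Z, 2, layer$b, "+")
    list(out = mat_to_act(Z, d[1], d[2], d[4]), cache = list(x = x, d = d))
  } else {
    P <- im2col_cpp(x, d[1], d[2], d[3], d[4], layer$k, layer$pad)
    Wm <- matrix(layer$W, layer$k^2 * layer$in_ch, layer$out_ch)
    Z <- P %*% Wm
    Z <- sweep(Z, 2, layer$b, "+")
    oh <- d[1] + 2 * layer$pad - layer$k + 1
    ow <- d[2] + 2 * layer$pad - layer$k + 1
    list(out = mat_to_act(Z, oh, ow, d[4]), cache = list(P = P, d = d))
  }
}

conv_backward <- function(layer, cache, dout) {
  d <- cache$d
  dZ <- act_to_mat(dout)
  if (layer$k == 1L && layer$pad == 0L) {
    xm <- act_to_mat(cache$x)
    Wm <- matrix(layer$W, layer$in_ch, layer$out_ch)
    dW <- array(crossprod(xm, dZ), dim(layer$W))
    db <- colSums(dZ)
    dx <- mat_to_act(tcrossprod(dZ, Wm), d[1], d[2], d[4])
  } else {
    P <- cache$P
    Wm <- matrix(layer$W, layer$k^2 * layer$in_ch, layer$out_ch)
    dW <- array(crossprod(P, dZ), dim(layer$W))
    db <- colSums(dZ)
    dP <- tcrossprod(dZ, Wm)
    dx <- col2im_cpp(dP, d[1], d[2], d[3], d[4], layer$k, layer$pad)
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- 1x1 convolution with stride 2 (attention-gate downsampling) ------------

new_sconv <- function(in_ch, out_ch) {
  sd <- sqrt(2 / in_ch)
  list(kind = "sconv", in_ch = in_ch, out_ch = out_ch,
       W = array(rnorm(in_ch * out_ch, sd = sd), c(1, 1, in_ch, out_ch)),
       b = numeric(out_ch))
}

sconv_forward <- function(layer, x) {
  d <- dim(x)
  ri <- seq(1, d[1], by = 2); ci <- seq(1, d[2], by = 2)
  xs <- x[ri, ci, , , drop = FALSE]
  xm <- act_to_mat(xs)
  Wm <- matrix(layer$W, layer$in_ch, layer$out_ch)
  Z <- sweep(xm %*% Wm, 2, layer$b, "+")
  list(out = mat_to_act(Z, length(ri), length(ci), d[4]),
       cache = list(xm = xm, d = d, ri = ri, ci = ci))
}

sconv_backward <- function(layer, cache, dout) {
  d <- cache$d
  dZ <- act_to_mat(dout)
  Wm <- matrix(layer$W, layer$in_ch, layer$out_ch)
  dW <- array(crossprod(cache$xm, dZ), dim(layer$W))
  db <- colSums(dZ)
  dxs <- mat_to_act(tcrossprod(dZ, Wm), length(cache$ri), length(cache$ci), d[4])
  dx <- array(0, d)
  dx[cache$ri, cache$ci, , ] <- dxs
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- transposed convolution 2x2, stride 2 (up-convolution) ------------------
# Kernel 2 with stride 2 tiles the output exactly: output pixels receive a
# contribution from a single input pixel, so the op is a GEMM plus a scatter.

new_convt <- function(in_ch, out_ch) {
  sd <- sqrt(2 / in_ch)
  list(kind = "convt", in_ch = in_ch, out_ch = out_ch,
       W = array(rnorm(4 * in_ch * out_ch, sd = sd), c(2, 2, in_ch, out_ch)),
       b = numeric(out_ch))
}

convt_wmat <- function(layer) {
  # Cin x (4 * Cout), column = a + 2*(b-1) + 4*(co-1)
  matrix(aperm(layer$W, c(3, 1, 2, 4)), layer$in_ch, 4 * layer$out_ch)
}

convt_forward <- function(layer, x) {
  d <- dim(x)
  xm <- act_to_mat(x)
  Z <- xm %*% convt_wmat(layer)
  H2 <- 2 * d[1]; W2 <- 2 * d[2]
  out <- array(0, c(H2, W2, layer$out_ch, d[4]))
  for (a in 1:2) for (b in 1:2) {
    cols <- (a + 2 * (b - 1)) + 4 * (seq_len(layer$out_ch) - 1)
    out[seq(a, H2, 2), seq(b, W2, 2), , ] <-
      mat_to_act(Z[, cols, drop = FALSE], d[1], d[2], d[4])
  }
  out <- sweep(out, 3, layer$b, "+")
  list(out = out, cache = list(xm = xm, d = d))
}

convt_backward <- function(layer, cache, dout) {
  d <- cache$d
  H2 <- 2 * d[1]; W2 <- 2 * d[2]
  dZ <- matrix(0, nrow(cache$xm), 4 * layer$out_ch)
  for (a in 1:2) for (b in 1:2) {
    cols <- (a + 2 * (b - 1)) + 4 * (seq_len(layer$out_ch) - 1)
    dZ[, cols] <- act_to_mat(dout[seq(a, H2, 2), seq(b, W2, 2), , , drop = FALSE])
  }
  Wm <- convt_wmat(layer)
  dWm <- crossprod(cache$xm, dZ)
  dW <- aperm(array(dWm, c(layer$in_ch, 2, 2, layer$out_ch)), c(2, 3, 1, 4))
  db <- as.numeric(apply(dout, 3, sum))
  dx <- mat_to_act(tcrossprod(dZ, Wm), d[1], d[2], d[4])
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- batch normalization ----------------------------------------------------
# Running statistics live in an environment so they update in place during
# training without threading modified layers back through every caller.

new_bn <- function(C, momentum = 0.1, eps = 1e-5) {
  stats <- new.env(parent = emptyenv())
  stats$mean <- numeric(C)
  stats$var <- rep(1, C)
  list(kind = "bn", C = C, momentum = momentum, eps = eps,
       gamma = rep(1, C), beta = numeric(C), stats = stats)
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  xm <- act_to_mat(x)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc * xc)
    layer$stats$mean <- (1 - layer$momentum) * layer$stats$mean + layer$momentum * mu
    layer$stats$var <- (1 - layer$momentum) * layer$stats$var + layer$momentum * v
  } else {
    mu <- layer$stats$mean
    v <- layer$stats$var
    xc <- sweep(xm, 2, mu)
  }
  inv_std <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2, inv_std, "*")
  ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(out = mat_to_act(ym, d[1], d[2], d[4]),
       cache = list(xhat = xhat, inv_std = inv_std, d = d, training = training))
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$d
  dym <- act_to_mat(dout)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  M <- nrow(dym)
  dxhat <- sweep(dym, 2, layer$gamma, "*")
  if (cache$training) {
    # dX = (1/M) inv_std * (M*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
    t1 <- M * dxhat
    t2 <- matrix(colSums(dxhat), M, ncol(dym), byrow = TRUE)
    t3 <- cache$xhat * matrix(colSums(dxhat * cache$xhat), M, ncol(dym), byrow = TRUE)
    dxm <- sweep(t1 - t2 - t3, 2, cache$inv_std / M, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$inv_std, "*")
  }
  list(dx = mat_to_act(dxm, d[1], d[2], d[4]),
       grads = list(gamma = dgamma, beta = dbeta))
}

# ---- activations ------------------------------------------------------------

relu_forward <- function(x) {
  out <- x * (x > 0)
  list(out = out, cache = x > 0)
}
relu_backward <- function(cache, dout) dout * cache

sigmoid_forward <- function(x) {
  out <- 1 / (1 + exp(-x))
  list(out = out, cache = out)
}
sigmoid_backward <- function(cache, dout) dout * cache * (1 - cache)

# ---- 2x2 max pooling, stride 2 ----------------------------------------------

maxpool_forward <- function(x) {
  d <- dim(x)
  r1 <- seq(1, d[1], 2); r2 <- seq(2, d[1], 2)
  c1 <- seq(1, d[2], 2); c2 <- seq(2, d[2], 2)
  s <- list(x[r1, c1, , , drop = FALSE], x[r2, c1, , , drop = FALSE],
            x[r1, c2, , , drop = FALSE], x[r2, c2, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  # first-window-position tie break
  m1 <- s[[1]] == out
  m2 <- (s[[2]] == out) & !m1
  m3 <- (s[[3]] == out) & !m1 & !m2
  m4 <- (s[[4]] == out) & !m1 & !m2 & !m3
  list(out = out, cache = list(masks = list(m1, m2, m3, m4), d = d))
}

maxpool_backward <- function(cache, dout) {
  d <- cache$d
  dx <- array(0, d)
  r1 <- seq(1, d[1], 2); r2 <- seq(2, d[1], 2)
  c1 <- seq(1, d[2], 2); c2 <- seq(2, d[2], 2)
  m <- cache$masks
  dx[r1, c1, , ] <- dout * m[[1]]
  dx[r2, c1, , ] <- dx[r2, c1, , , drop = FALSE] + dout * m[[2]]
  dx[r1, c2, , ] <- dx[r1, c2, , , drop = FALSE] + dout * m[[3]]
  dx[r2, c2, , ] <- dx[r2, c2, , , drop = FALSE] + dout * m[[4]]
  dx
}

# ---- nearest-neighbour 2x upsampling (attention coefficients) ---------------

upsample_nn_forward <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  r1 <- seq(1, 2 * d[1], 2); r2 <- seq(2, 2 * d[1], 2)
  c1 <- seq(1, 2 * d[2], 2); c2 <- seq(2, 2 * d[2], 2)
  out[r1, c1, , ] <- x; out[r2, c1, , ] <- x
  out[r1, c2, , ] <- x; out[r2, c2, , ] <- x
  list(out = out, cache = d)
}

upsample_nn_backward <- function(cache, dout) {
  d <- cache
  r1 <- seq(1, 2 * d[1], 2); r2 <- seq(2, 2 * d[1], 2)
  c1 <- seq(1, 2 * d[2], 2); c2 <- seq(2, 2 * d[2], 2)
  dout[r1, c1, , , drop = FALSE] + dout[r2, c1, , , drop = FALSE] +
    dout[r1, c2, , , drop = FALSE] + dout[r2, c2, , , drop = FALSE]
}

# ---- parameter tree walking and Adam ----------------------------------------

param_names_for_kind <- c("W", "b", "gamma", "beta")

# All parameter paths of a (possibly nested) layer structure, as character
# vectors usable with `[[`.
collect_param_paths <- function(obj, path = character()) {
  if (!is.list(obj)) return(list())
  out <- list()
  if (!is.null(obj$kind) && obj$kind %in% c("conv", "sconv", "convt", "bn")) {
    for (nm in intersect(param_names_for_kind, names(obj))) {
      out[[length(out) + 1]] <- c(path, nm)
    }
    return(out)
  }
  for (nm in names(obj)) {
    child <- obj[[nm]]
    if (is.list(child)) {
      out <- c(out, collect_param_paths(child, c(path, nm)))
    }
  }
  out
}

get_by_path <- function(obj, path) obj[[path]]
set_by_path <- function(obj, path, value) {
  obj[[path]] <- value
  obj
}

#' Count trainable parameters of a network or layer segment
#'
#' Sums the sizes of all weight, bias and normalization (gamma/beta) arrays in
#' the structure. Running batch-norm statistics are buffers, not trainable
#' parameters, and are excluded.
#'
#' @param graph A network built by [rda_unet()] or any block segment built by
#'   [res_block()], [dense_block()] or [attention_gate()].
#' @return Integer total of trainable parameters.
#' @export
count_parameters <- function(graph) {
  paths <- collect_param_paths(graph)
  sum(vapply(paths, function(p) length(get_by_path(graph, p)), numeric(1)))
}

adam_init <- function(net) {
  paths <- collect_param_paths(net)
  state <- new.env(parent = emptyenv())
  state$t <- 0
  state$m <- lapply(paths, function(p) array(0, dim = dim(get_by_path(net, p)) %||% length(get_by_path(net, p))))
  state$v <- state$m
  state$paths <- paths
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(state$paths)) {
    p <- state$paths[[i]]
    g <- get_by_path(grads, p)
    if (is.null(g)) next
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g * g
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    val <- get_by_path(net, p) - lr * mhat / (sqrt(vhat) + eps)
    net[[p]] <- val
  }
  net
}

# Snapshot / restore of all parameters and batch-norm running statistics,
# used for best-validation checkpointing and model serialization.
snapshot_params <- function(net) {
  paths <- collect_param_paths(net)
  vals <- lapply(paths, function(p) get_by_path(net, p))
  bn <- snapshot_bn(net)
  list(paths = paths, values = vals, bn = bn)
}

restore_params <- function(net, snap) {
  for (i in seq_along(snap$paths)) net[[snap$paths[[i]]]] <- snap$values[[i]]
  restore_bn(net, snap$bn)
  net
}

walk_bn <- function(obj, path, fn) {
  if (!is.list(obj)) return(invisible(NULL))
  if (!is.null(obj$kind) && obj$kind == "bn") {
    fn(obj, path)
    return(invisible(NULL))
  }
  for (nm in names(obj)) {
    if (is.list(obj[[nm]])) walk_bn(obj[[nm]], c(path, nm), fn)
  }
  invisible(NULL)
}

snapshot_bn <- function(net) {
  out <- list()
  walk_bn(net, character(), function(layer, path) {
    out[[paste(path, collapse = ".")]] <<- list(mean = layer$stats$mean,
                                                var = layer$stats$var)
  })
  out
}

restore_bn <- function(net, snap) {
  walk_bn(net, character(), function(layer, path) {
    key <- paste(path, collapse = ".")
    if (!is.null(snap[[key]])) {
      layer$stats$mean <- snap[[key]]$mean
      layer$stats$var <- snap[[key]]$var
    }
  })
  invisible(net)
}

# Fresh batch-norm stats environments (used when deserializing a model so
# two loaded copies never share state).
rebuild_bn_envs <- function(obj) {
  if (!is.list(obj)) return(obj)
  if (!is.null(obj$kind) && obj$kind == "bn") {
    stats <- new.env(parent = emptyenv())
    stats$mean <- obj$stats$mean
    stats$var <- obj$stats$var
    obj$stats <- stats
    return(obj)
  }
  for (nm in names(obj)) {
    if (is.list(obj[[nm]])) obj[[nm]] <- rebuild_bn_envs(obj[[nm]])
  }
  obj
}
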