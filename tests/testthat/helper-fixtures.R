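# Shared fixtures: random masks, small phantom configs, a tiny trained model
# (memoized across tests), and brute-force metric oracles.

# Random non-empty binary mask: one disc plus salt noise. Always contains at
# least one foreground pixel, so boundary-based metrics are defined.
random_mask <- function(size = 32, seed = 1) {
  set.seed(seed)
  m <- matrix(0, size, size)
  cx <- runif(1, size * 0.25, size * 0.75)
  cy <- runif(1, size * 0.25, size * 0.75)
  r <- runif(1, 2, size * 0.25)
  X <- matrix(rep(seq_len(size), each = size), size, size)
  Y <- matrix(rep(seq_len(size), times = size), size, size)
  m[(Y - cy)^2 + (X - cx)^2 <= r^2] <- 1
  noise <- matrix(rbinom(size * size, 1, 0.05), size, size)
  m <- pmax(m, noise)
  m
}

# --- brute-force oracles (independent of the package implementation) ---------

# 4-connectivity erosion by explicit neighbour checks.
bf_erode4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (m[i, j] == 1 &&
        (i > 1 && m[i - 1, j] == 1) && (i < h && m[i + 1, j] == 1) &&
        (j > 1 && m[i, j - 1] == 1) && (j < w && m[i, j + 1] == 1)) {
      out[i, j] <- 1
    }
  }
  out
}

bf_boundary_points <- function(m) {
  which(m - bf_erode4(m) == 1, arr.ind = TRUE)
}

# All-pairs average Hausdorff distance between boundary sets.
bf_average_hausdorff <- function(gt, pred) {
  G <- bf_boundary_points(gt)
  S <- bf_boundary_points(pred)
  d2 <- outer(G[, 1], S[, 1], "-")^2 + outer(G[, 2], S[, 2], "-")^2
  g_to_s <- mean(sqrt(apply(d2, 1, min)))
  s_to_g <- mean(sqrt(apply(d2, 2, min)))
  (g_to_s + s_to_g) / 2
}

# Exhaustive pairwise rank-statistic AUC (ties half credit).
bf_auc <- function(prob, gt) {
  pos <- prob[gt == 1]; neg <- prob[gt == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# --- analytic parameter-count oracle -----------------------------------------
# Hand summation over the documented architecture, from the convolution
# parameter formula k*k*Cin*Cout + Cout and 2C per normalization.

oracle_conv <- function(k, cin, cout) k * k * cin * cout + cout
oracle_bn <- function(c) 2 * c

oracle_res <- function(cin, cout, bn = TRUE) {
  n <- oracle_conv(3, cin, cout) + oracle_conv(3, cout, cout)
  if (bn) n <- n + 2 * oracle_bn(cout)
  if (cin != cout) n <- n + oracle_conv(1, cin, cout)
  n
}

oracle_dense <- function(cin, layers, growth, bn = TRUE) {
  n <- 0
  for (i in seq_len(layers)) {
    n <- n + oracle_conv(3, cin + (i - 1) * growth, growth)
    if (bn) n <- n + oracle_bn(growth)
  }
  n
}

oracle_gate <- function(skip, gate, inter) {
  oracle_conv(1, skip, inter) + oracle_conv(1, gate, inter) + oracle_conv(1, inter, 1)
}

oracle_unet_params <- function(depth, base, dense_layers, input_channels = 1,
                               bn = TRUE) {
  width <- base * 2^(seq_len(depth) - 1)
  growth <- pmax(1, width %/% 2)
  total <- 0
  cin <- input_channels
  stage_out <- numeric(depth)
  for (l in seq_len(depth)) {
    total <- total + oracle_res(cin, width[l], bn) +
      oracle_dense(width[l], dense_layers, growth[l], bn)
    stage_out[l] <- width[l] + dense_layers * growth[l]
    cin <- stage_out[l]
  }
  wb <- base * 2^depth
  gb <- max(1, wb %/% 2)
  total <- total + oracle_res(cin, wb, bn) + oracle_dense(wb, dense_layers, gb, bn)
  cg <- wb + dense_layers * gb
  for (l in rev(seq_len(depth))) {
    skip <- stage_out[l]
    inter <- max(1, skip %/% 2)
    total <- total + oracle_gate(skip, cg, inter)
    total <- total + 4 * cg * width[l] + width[l]           # 2x2 up-convolution
    total <- total + oracle_conv(3, width[l] + skip, width[l]) +
      oracle_conv(3, width[l], width[l])
    if (bn) total <- total + 2 * oracle_bn(width[l])
    cg <- width[l]
  }
  total + oracle_conv(1, width[1], 1)
}

# --- small phantom dataset + trained model, memoized per test session --------

tiny_manifest <- function(n = 10, seed = 500, size = 64) {
  dir <- file.path(tempdir(), sprintf("phantoms_%d_%d_%d", n, seed, size))
  if (!file.exists(file.path(dir, "manifest.json"))) {
    cfg <- phantom_config(image_size = size, lesion_count_range = c(0L, 2L))
    generate_dataset(cfg, n = n, seed = seed, out_dir = dir)
  }
  read_manifest(dir)
}

.tiny_model_env <- new.env()

tiny_trained_model <- function() {
  if (is.null(.tiny_model_env$model)) {
    man <- tiny_manifest()
    arch <- arch_config(input_size = 32, depth = 2, base_filters = 4,
                        dense_layers = 2)
    cfg <- train_config_demo(epochs = 2, seed = 7, target = "liver")
    .tiny_model_env$model <- train(arch, cfg, man)
    .tiny_model_env$manifest <- man
  }
  list(model = .tiny_model_env$model, manifest = .tiny_model_env$manifest)
}
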