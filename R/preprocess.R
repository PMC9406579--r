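# CT image conditioning: Hounsfield-unit windowing, resizing to the network
# grid, dataset splitting, histogram equalization (optional) and contour
# overlay rendering.

#' Hounsfield window specification
#'
#' A diagnostic HU window: values are clamped to `[hu_min, hu_max]` and
#' rescaled to `[0, 1]`. The default `[-100, 400]` is a wide soft-tissue
#' window under which liver parenchyma sits mid-grey and hypervascular
#' lesions turn bright.
#'
#' @param hu_min,hu_max Window bounds in HU, `hu_min < hu_max`.
#' @export
window_spec <- function(hu_min = -100, hu_max = 400) {
  if (!is.numeric(hu_min) || !is.numeric(hu_max) || !is.finite(hu_min) ||
      !is.finite(hu_max) || hu_min >= hu_max) {
    stop_config("window", "requires finite hu_min < hu_max")
  }
  structure(list(hu_min = hu_min, hu_max = hu_max), class = "window_spec")
}

#' Apply a Hounsfield window
#'
#' Clamps the image to the window and linearly rescales it so `hu_min` maps
#' to 0 and `hu_max` to 1. Idempotent on already-windowed data only in the
#' sense that re-windowing a `[0, 1]` image with a `[0, 1]` window is the
#' identity; the usual invariant is that the output always lies in `[0, 1]`.
#'
#' @param image Numeric matrix/array of HU values (finite).
#' @param window A [window_spec()].
#' @return Array of the same shape with values in `[0, 1]`.
#' @export
window_hu <- function(image, window = window_spec()) {
  stopifnot(inherits(window, "window_spec"))
  if (any(!is.finite(image))) stop("image contains non-finite values", call. = FALSE)
  out <- pmin(pmax(image, window$hu_min), window$hu_max)
  (out - window$hu_min) / (window$hu_max - window$hu_min)
}

#' Resize a square image or mask to the network grid
#'
#' Images are resampled with bilinear interpolation; masks with
#' nearest-neighbour so they remain strictly binary.
#'
#' @param image Square numeric matrix.
#' @param target Output side length in pixels.
#' @param is_mask Logical; use nearest-neighbour and preserve `{0, 1}`.
#' @return `target x target` matrix.
#' @export
resize_to_grid <- function(image, target, is_mask = FALSE) {
  if (nrow(image) != ncol(image)) {
    stop("input must be square; pad to square before resizing", call. = FALSE)
  }
  if (is_mask) check_mask(image)
  if (nrow(image) == target) return(image)
  out <- EBImage::resize(image, w = target, h = target,
                         filter = if (is_mask) "none" else "bilinear")
  matrix(as.numeric(out), target, target)
}

#' Histogram equalization (optional conditioning step)
#'
#' Equalizes a `[0, 1]` image over 256 grey levels. Off by default in the
#' pipeline; exposed because contrast equalization is a common companion to
#' HU windowing for non-contrast CT.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @export
equalize_image <- function(image) {
  as.matrix(EBImage::equalize(image, range = c(0, 1), levels = 256))
}

#' Split sample identifiers into training and validation sets
#'
#' Uniformly random permutation under `seed`, then a prefix/suffix split with
#' `round(ratio * n)` training ids. Deterministic in `(ids, ratio, seed)`.
#'
#' @param ids Character or integer vector of sample identifiers (non-empty).
#' @param ratio Training fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return A `split_result`: list with `train_ids`, `val_ids`, `ratio`,
#'   `seed`. The two id sets are disjoint and exhaust `ids`.
#' @export
split_dataset <- function(ids, ratio = 0.8, seed = 1L) {
  if (length(ids) == 0) stop("'ids' must be non-empty", call. = FALSE)
  if (anyDuplicated(ids)) stop("'ids' must be unique", call. = FALSE)
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop_config("ratio", "must lie strictly between 0 and 1")
  }
  n <- length(ids)
  n_train <- round(ratio * n)
  if (n_train < 1 || n_train > n - 1) {
    stop_config("ratio", "leaves an empty training or validation partition")
  }
  perm <- with_seed(seed, sample(ids, n))
  structure(list(train_ids = perm[seq_len(n_train)],
                 val_ids = perm[seq(n_train + 1, n)],
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_result")
}

#' Render a contour overlay
#'
#' Replicates a `[0, 1]` grayscale image to three channels and paints the
#' mask's boundary pixels (mask minus its one-pixel 4-connectivity erosion)
#' with `color`. All non-boundary pixels are left unchanged, which makes the
#' number of modified pixels equal to the boundary-set size.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param mask Binary mask on the same grid.
#' @param color RGB triple in `[0, 1]` (default red).
#' @return `[H, W, 3]` array.
#' @export
overlay_contour <- function(image, mask, color = c(1, 0, 0)) {
  check_same_grid(image, mask)
  check_mask(mask)
  stopifnot(length(color) == 3)
  boundary <- boundary_mask(mask) == 1
  out <- array(rep(image, 3), c(dim(image), 3))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[boundary] <- color[ch]
    out[, , ch] <- plane
  }
  out
}

#' Write an overlay (or any `[0,1]` image) as PNG
#'
#' @param x Matrix or `[H, W, 3]` array with values in `[0, 1]`.
#' @param path Output file path.
#' @export
write_png <- function(x, path) {
  img <- if (length(dim(x)) == 3) {
    EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(x))
  }
  EBImage::writeImage(img, path, type = "png")
  invisible(path)
}

# ---- augmentation -----------------------------------------------------------

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

apply_spatial_op <- function(m, op) {
  switch(op,
         hflip = flip_h(m),
         vflip = flip_v(m),
         rot90 = rot90cw(m),
         rot180 = rot90cw(rot90cw(m)),
         rot270 = rot90cw(rot90cw(rot90cw(m))),
         stop_config("ops", sprintf("contains unknown operation '%s'", op)))
}

#' Spatially augment an image with its masks
#'
#' Applies the listed operations in order, identically to the image and every
#' mask, so mask/image alignment and mask nesting are preserved and masks
#' stay binary. Supported operations: `"hflip"`, `"vflip"` (horizontal and
#' vertical flips) and `"rot90"`, `"rot180"`, `"rot270"` (clockwise
#' rotations). With a `seed`, each listed operation is instead applied
#' independently with probability 1/2, which is the stochastic form used for
#' training-time data enhancement.
#'
#' @param sample A list with an `image` matrix; every other matrix element
#'   whose name ends in `"mask"` is transformed alongside it (a
#'   `phantom_sample` works directly).
#' @param ops Character vector of operation names.
#' @param seed Optional integer; switches to random application.
#' @return The augmented sample (same structure).
#' @export
augment <- function(sample, ops, seed = NULL) {
  bad <- setdiff(ops, c("hflip", "vflip", "rot90", "rot180", "rot270"))
  if (length(bad) > 0) {
    stop_config("ops", sprintf("contains unknown operation '%s'", bad[1]))
  }
  if (!is.null(seed)) {
    keep <- with_seed(seed, rbinom(length(ops), 1, 0.5) == 1)
    ops <- ops[keep]
  }
  fields <- c("image", grep("mask$", names(sample), value = TRUE))
  for (op in ops) {
    for (f in fields) sample[[f]] <- apply_spatial_op(sample[[f]], op)
  }
  sample
}
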