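# Synthetic CT-like phantom slices with liver and lesion ground truth.
# The phantom emulates a single-channel HU-valued abdominal slice: an air
# background, a soft-tissue "body" ellipse, one connected liver region whose
# boundary is a low-frequency radial deformation of an ellipse, and 0-5
# disc-shaped lesions nested strictly inside the liver. Each tissue class
# receives a constant HU value drawn from its configured interval, then
# additive Gaussian noise is applied.

#' Phantom generator configuration
#'
#' @param image_size Pixels per side of the square slice.
#' @param liver_axes_range Min/max of the liver ellipse semi-axes, as a
#'   fraction of `image_size`.
#' @param lesion_count_range Integer interval of lesions per slice.
#' @param lesion_radius_range Min/max lesion radius in pixels; defaults scale
#'   with `image_size`. Must stay below the smallest liver semi-axis.
#' @param hu_background,hu_soft_tissue,hu_liver,hu_lesion HU intervals the
#'   per-class (pre-noise) intensities are drawn from. Defaults follow
#'   typical CT ranges: air around -1000 HU, soft tissue 0-60 HU, liver
#'   parenchyma 40-70 HU, hyperintense (post-windowing bright) lesions
#'   80-140 HU.
#' @param noise_sd Standard deviation of the additive Gaussian noise, in HU.
#' @param seed Default seed used by the generator when none is supplied.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 512,
                           liver_axes_range = c(0.22, 0.32),
                           lesion_count_range = c(0L, 5L),
                           lesion_radius_range = NULL,
                           hu_background = c(-1000, -800),
                           hu_soft_tissue = c(0, 60),
                           hu_liver = c(40, 70),
                           hu_lesion = c(80, 140),
                           noise_sd = 5,
                           seed = 1L) {
  if (!is.numeric(image_size) || length(image_size) != 1 || image_size <= 0) {
    stop_config("image_size", "must be a positive number")
  }
  image_size <- as.integer(image_size)
  check_interval(liver_axes_range, "liver_axes_range")
  if (liver_axes_range[1] <= 0 || liver_axes_range[2] >= 0.5) {
    stop_config("liver_axes_range", "must lie in (0, 0.5) as a fraction of image_size")
  }
  check_interval(lesion_count_range, "lesion_count_range")
  if (any(lesion_count_range < 0) || any(lesion_count_range != round(lesion_count_range))) {
    stop_config("lesion_count_range", "must be non-negative integers")
  }
  if (is.null(lesion_radius_range)) {
    lesion_radius_range <- pmax(2, round(c(0.02, 0.055) * image_size))
  }
  check_interval(lesion_radius_range, "lesion_radius_range")
  if (lesion_radius_range[2] >= liver_axes_range[1] * image_size) {
    stop_config("lesion_radius_range",
                "maximum radius must be smaller than the smallest liver semi-axis")
  }
  check_interval(hu_background, "hu_background")
  check_interval(hu_soft_tissue, "hu_soft_tissue")
  check_interval(hu_liver, "hu_liver")
  check_interval(hu_lesion, "hu_lesion")
  if (hu_lesion[1] <= hu_background[2] && hu_background[1] <= hu_lesion[2]) {
    stop_config("hu_lesion", "interval must be disjoint from hu_background")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop_config("noise_sd", "must be >= 0")
  structure(list(image_size = image_size,
                 liver_axes_range = liver_axes_range,
                 lesion_count_range = as.integer(lesion_count_range),
                 lesion_radius_range = lesion_radius_range,
                 hu_background = hu_background,
                 hu_soft_tissue = hu_soft_tissue,
                 hu_liver = hu_liver,
                 hu_lesion = hu_lesion,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Star-convex region: radius of the (perturbed) ellipse boundary along angle
# theta from the centre. Low-frequency cosine modes keep the boundary smooth
# and the region connected.
region_mask <- function(size, cx, cy, a, b, pert_amp = NULL, pert_phase = NULL) {
  X <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  Y <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- X - cx
  dy <- Y - cy
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  r_e <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  if (!is.null(pert_amp)) {
    mod <- rep(1, length(theta))
    for (k in seq_along(pert_amp)) {
      mod <- mod + pert_amp[k] * cos((k + 1) * theta + pert_phase[k])
    }
    r_e <- r_e * mod
  }
  (rho <= r_e) * 1
}

#' Generate one synthetic CT-like phantom slice
#'
#' Draws a soft-tissue body ellipse on an air background, a connected liver
#' region (radially perturbed ellipse) and `lesion_count_range` disc lesions
#' placed strictly inside the liver (the placement region is the liver
#' interior at distance greater than the lesion radius from the boundary, so
#' lesions may approach but never cross it). Lesions are kept mutually
#' separated so the lesion mask has exactly as many connected components as
#' lesions. Class intensities are constants drawn from the configured HU
#' intervals; Gaussian noise (`noise_sd`) is added last.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed; identical `(config, seed)` pairs reproduce
#'   bit-identical output. Defaults to `config$seed`.
#' @return A `phantom_sample`: list with `image` (HU matrix), `liver_mask`,
#'   `lesion_mask` (0/1 matrices on the same grid), and `meta` (class HU
#'   values, lesion geometry, seed).
#' @export
generate_phantom <- function(config = phantom_config(), seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(seed, {
    s <- config$image_size
    # body (soft tissue) ellipse
    bcx <- s * (0.5 + runif(1, -0.02, 0.02))
    bcy <- s * (0.5 + runif(1, -0.02, 0.02))
    body <- region_mask(s, bcx, bcy, s * runif(1, 0.42, 0.46), s * runif(1, 0.38, 0.42))
    # liver: perturbed ellipse inside the body
    lcx <- s * (0.5 + runif(1, -0.08, 0.08))
    lcy <- s * (0.5 + runif(1, -0.08, 0.08))
    a <- s * runif(1, config$liver_axes_range[1], config$liver_axes_range[2])
    b <- s * runif(1, config$liver_axes_range[1], config$liver_axes_range[2])
    amp <- runif(3, 0, 0.06)
    phase <- runif(3, 0, 2 * pi)
    liver <- region_mask(s, lcx, lcy, a, b, amp, phase)
    # lesions: discs whose centres keep distance > radius from the liver
    # boundary and stay clear of each other
    n_lesion <- if (config$lesion_count_range[1] == config$lesion_count_range[2]) {
      config$lesion_count_range[1]
    } else {
      sample(seq(config$lesion_count_range[1], config$lesion_count_range[2]), 1)
    }
    dmap <- as.matrix(EBImage::distmap(liver, metric = "euclidean"))
    X <- matrix(rep(seq_len(s), each = s), s, s)
    Y <- matrix(rep(seq_len(s), times = s), s, s)
    lesion <- matrix(0, s, s)
    centres <- matrix(numeric(0), 0, 3) # row, col, radius
    placed <- 0
    attempts <- 0
    while (placed < n_lesion && attempts < 500) {
      attempts <- attempts + 1
      r <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
      ok <- which(dmap > r + 1, arr.ind = TRUE)
      if (nrow(ok) == 0) next
      pick <- ok[sample.int(nrow(ok), 1), ]
      if (nrow(centres) > 0) {
        gap <- sqrt((centres[, 1] - pick[1])^2 + (centres[, 2] - pick[2])^2)
        if (any(gap < centres[, 3] + r + 3)) next
      }
      lesion[(Y - pick[1])^2 + (X - pick[2])^2 <= r^2] <- 1
      centres <- rbind(centres, c(pick[1], pick[2], r))
      placed <- placed + 1
    }
    if (placed < n_lesion) {
      stop("could not place the requested number of lesions; ",
           "check lesion_radius_range against the liver size", call. = FALSE)
    }
    hu <- c(bg = runif(1, config$hu_background[1], config$hu_background[2]),
            soft = runif(1, config$hu_soft_tissue[1], config$hu_soft_tissue[2]),
            liver = runif(1, config$hu_liver[1], config$hu_liver[2]),
            lesion = runif(1, config$hu_lesion[1], config$hu_lesion[2]))
    img <- matrix(hu["bg"], s, s)
    img[body == 1] <- hu["soft"]
    img[liver == 1] <- hu["liver"]
    img[lesion == 1] <- hu["lesion"]
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(s * s, sd = config$noise_sd), s, s)
    }
    structure(list(image = img, liver_mask = liver, lesion_mask = lesion,
                   meta = list(hu = hu, n_lesion = placed, centres = centres,
                               seed = seed)),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom samples as NIfTI pairs (image, liver mask, lesion mask)
#' plus a JSON manifest listing file paths (relative to `out_dir`) and the
#' per-sample seeds (`seed + i - 1`). Re-running with identical arguments
#' reproduces identical files.
#'
#' @param config A [phantom_config()].
#' @param n Number of samples (>= 1).
#' @param seed Base seed.
#' @param out_dir Output directory (created if missing).
#' @param spacing_mm Isotropic in-plane voxel size recorded in the NIfTI
#'   headers; the default models a 360 mm abdominal field of view.
#' @return The manifest as a tibble (invisibly written to
#'   `out_dir/manifest.json`): columns `sample_id`, `image_path`,
#'   `liver_mask_path`, `lesion_mask_path`, `seed`.
#' @export
generate_dataset <- function(config = phantom_config(), n, seed = config$seed,
                             out_dir, spacing_mm = 360 / config$image_size) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.numeric(n) || n < 1) stop("'n' must be >= 1", call. = FALSE)
  n <- as.integer(n)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir) || file.access(out_dir, 2) != 0) {
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("phantom_%04d", i)
    s_seed <- as.integer(seed + i - 1)
    sm <- generate_phantom(config, seed = s_seed)
    paths <- c(image = paste0(sid, "_image.nii.gz"),
               liver = paste0(sid, "_liver_mask.nii.gz"),
               lesion = paste0(sid, "_lesion_mask.nii.gz"))
    write_nifti_2d(sm$image, file.path(out_dir, paths["image"]), spacing_mm)
    write_nifti_2d(sm$liver_mask, file.path(out_dir, paths["liver"]), spacing_mm)
    write_nifti_2d(sm$lesion_mask, file.path(out_dir, paths["lesion"]), spacing_mm)
    rows[[i]] <- tibble::tibble(sample_id = sid,
                                image_path = unname(paths["image"]),
                                liver_mask_path = unname(paths["liver"]),
                                lesion_mask_path = unname(paths["lesion"]),
                                seed = s_seed)
  }
  manifest <- dplyr::bind_rows(rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

write_nifti_2d <- function(mat, path, spacing_mm) {
  im <- RNifti::asNifti(array(mat, c(dim(mat), 1)))
  RNifti::pixdim(im) <- c(spacing_mm, spacing_mm, 1)
  RNifti::writeNifti(im, path)
  invisible(path)
}

read_nifti_2d <- function(path) {
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 3 && dim(a)[3] == 1) dim(a) <- dim(a)[1:2]
  a
}

#' Read a dataset manifest
#'
#' @param path Path to a `manifest.json` written by [generate_dataset()], or
#'   the directory containing it.
#' @return Tibble with the manifest columns plus a `dir` attribute used to
#'   resolve the relative paths.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  df <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  attr(df, "dir") <- dirname(normalizePath(path))
  df
}

manifest_dir <- function(manifest) {
  d <- attr(manifest, "dir")
  if (is.null(d)) stop("manifest has no 'dir' attribute; use read_manifest()",
                       call. = FALSE)
  d
}

# Load one manifest row as in-memory arrays.
load_manifest_sample <- function(manifest, i) {
  d <- manifest_dir(manifest)
  list(sample_id = manifest$sample_id[i],
       image = read_nifti_2d(file.path(d, manifest$image_path[i])),
       liver_mask = read_nifti_2d(file.path(d, manifest$liver_mask_path[i])),
       lesion_mask = read_nifti_2d(file.path(d, manifest$lesion_mask_path[i])))
}
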