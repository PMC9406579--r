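test_that("phantom generation is a pure function of (config, seed)", {
  cfg <- phantom_config(image_size = 64, lesion_count_range = c(0L, 2L))
  a <- generate_phantom(cfg, seed = 42)
  b <- generate_phantom(cfg, seed = 42)
  expect_identical(a$image, b$image)
  expect_identical(a$liver_mask, b$liver_mask)
  expect_identical(a$lesion_mask, b$lesion_mask)
  d <- generate_phantom(cfg, seed = 43)
  expect_false(identical(a$image, d$image))
})

test_that("lesions nest strictly inside the liver for many seeds", {
  cfg <- phantom_config(image_size = 64, lesion_count_range = c(0L, 2L))
  for (seed in 1:100) {
    s <- generate_phantom(cfg, seed = seed)
    expect_true(all(s$lesion_mask * (1 - s$liver_mask) == 0),
                label = sprintf("lesion within liver, seed %d", seed))
    expect_true(all(s$liver_mask %in% c(0, 1)))
    expect_true(all(s$lesion_mask %in% c(0, 1)))
  }
})

test_that("liver region is a single connected component", {
  cfg <- phantom_config(image_size = 96)
  for (seed in c(1, 7, 19, 101)) {
    s <- generate_phantom(cfg, seed = seed)
    labels <- EBImage::bwlabel(s$liver_mask)
    expect_equal(max(labels), 1)
  }
})

test_that("degenerate HU interval with zero noise pins lesion pixels exactly", {
  cfg <- phantom_config(image_size = 64, noise_sd = 0,
                        lesion_count_range = c(1L, 2L),
                        hu_lesion = c(100, 100))
  s <- generate_phantom(cfg, seed = 5)
  expect_gt(sum(s$lesion_mask), 0)
  expect_true(all(s$image[s$lesion_mask == 1] == 100))
})

test_that("per-class mean intensities fall inside their HU intervals before noise", {
  cfg <- phantom_config(image_size = 64, noise_sd = 0,
                        lesion_count_range = c(1L, 2L))
  for (seed in c(2, 9, 33)) {
    s <- generate_phantom(cfg, seed = seed)
    liver_only <- s$liver_mask == 1 & s$lesion_mask == 0
    m_liver <- mean(s$image[liver_only])
    m_lesion <- mean(s$image[s$lesion_mask == 1])
    expect_gte(m_liver, cfg$hu_liver[1]); expect_lte(m_liver, cfg$hu_liver[2])
    expect_gte(m_lesion, cfg$hu_lesion[1]); expect_lte(m_lesion, cfg$hu_lesion[2])
  }
})

test_that("lesion count is exact: connected-component oracle over 50 seeds", {
  cfg <- phantom_config(image_size = 96, lesion_count_range = c(3L, 3L))
  for (seed in 1:50) {
    s <- generate_phantom(cfg, seed = seed)
    n_cc <- max(EBImage::bwlabel(s$lesion_mask))
    expect_equal(n_cc, 3, label = sprintf("components at seed %d", seed))
  }
})

test_that("lesion pixels stay brighter than liver parenchyma under mild noise", {
  cfg <- phantom_config(image_size = 64, noise_sd = 5,
                        lesion_count_range = c(1L, 3L))
  for (seed in 1:30) {
    s <- generate_phantom(cfg, seed = seed)
    liver_only <- s$liver_mask == 1 & s$lesion_mask == 0
    expect_gt(mean(s$image[s$lesion_mask == 1]) - mean(s$image[liver_only]), 0)
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(phantom_config(image_size = -1), "image_size")
  expect_error(phantom_config(hu_liver = c(70, 40)), "hu_liver")
  expect_error(phantom_config(lesion_radius_range = c(5, 400)), "lesion_radius_range")
  expect_error(phantom_config(hu_lesion = c(-900, -850)), "hu_lesion")
  expect_error(phantom_config(lesion_count_range = c(-1, 2)), "lesion_count_range")
})

test_that("dataset generation writes NIfTI pairs, a manifest, and round-trips", {
  cfg <- phantom_config(image_size = 64, lesion_count_range = c(0L, 2L))
  dir <- withr::local_tempdir()
  man <- generate_dataset(cfg, n = 4, seed = 10, out_dir = dir)
  expect_equal(nrow(man), 4)
  niis <- list.files(dir, pattern = "\\.nii\\.gz$")
  expect_length(niis, 12)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man2 <- read_manifest(dir)
  expect_equal(man2$sample_id, man$sample_id)
  # round-trip: written image equals the in-memory sample for its seed
  s <- generate_phantom(cfg, seed = man2$seed[2])
  img <- as.array(RNifti::readNifti(file.path(dir, man2$image_path[2])))
  expect_equal(matrix(img, 64, 64), s$image, tolerance = 1e-6)
})

test_that("dataset generation reproduces identical files and manifest bytes", {
  cfg <- phantom_config(image_size = 64, lesion_count_range = c(0L, 2L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, n = 64, seed = 77, out_dir = d1)
  generate_dataset(cfg, n = 64, seed = 77, out_dir = d2)
  m1 <- file.path(d1, "manifest.json"); m2 <- file.path(d2, "manifest.json")
  expect_identical(readBin(m1, "raw", file.size(m1)),
                   readBin(m2, "raw", file.size(m2)))
  for (f in list.files(d1, pattern = "nii.gz$")[c(1, 30, 100, 192)]) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})
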