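# NIfTI round-trips, isotropic resampling, stride extraction, preprocessing
# and joint augmentation.

test_that("volumes round-trip bit-exactly through NIfTI", {
  set.seed(20)
  vol <- mri_volume(array(rnorm(16^3), c(16, 16, 16)), spacing = c(1, 1, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  rt <- read_volume(f)
  expect_identical(rt$grid, vol$grid)
  expect_equal(rt$spacing, c(1, 1, 3))
})

test_that("unreadable files raise informative I/O errors", {
  expect_error(read_volume(tempfile()), "not found")
  bad <- tempfile(fileext = ".nii")
  writeLines("this is not a nifti", bad)
  suppressWarnings(expect_error(read_volume(bad), "NIfTI"))
})

test_that("isotropic resampling scales axis lengths by the spacing ratio", {
  set.seed(21)
  iso <- mri_volume(array(rnorm(10^3), c(10, 10, 10)))
  expect_identical(resample_isotropic(iso)$grid, iso$grid)
  aniso <- mri_volume(array(rnorm(20 * 20 * 100), c(20, 20, 100)),
                      spacing = c(1, 1, 2))
  rs <- resample_isotropic(aniso)
  expect_equal(dim(rs$grid), c(20L, 20L, 200L))  # 100 voxels at 2mm -> 200 at 1mm
  expect_equal(rs$spacing, c(1, 1, 1))
})

test_that("nearest-neighbour resampling never invents labels", {
  lab <- array(sample(0:4, 12 * 12 * 30, replace = TRUE), c(12, 12, 30))
  vol <- mri_volume(lab, spacing = c(1, 1, 2.5))
  rs <- resample_isotropic(vol, method = "nearest")
  expect_true(all(rs$grid %in% 0:4))
  expect_setequal(unique(as.vector(rs$grid)), unique(as.vector(lab)))
})

test_that("stride slice counts match exhaustive enumeration", {
  for (len in c(1L, 7L, 24L, 50L)) for (k in 1:10) for (off in 0:(k - 1L)) {
    if (off >= len) next
    expect_identical(slice_count(len, k, off),
                     length(seq.int(off, len - 1L, by = k)))
  }
})

test_that("stride 5 doubles the slices of stride 10 on even-length axes", {
  vol <- mri_volume(array(0, c(8, 8, 100)))
  n5 <- length(extract_slices(vol, stride_plan(5)))
  n10 <- length(extract_slices(vol, stride_plan(10)))
  expect_identical(n5, 2L * n10)
})

test_that("stride 1 returns every slice in order with provenance", {
  g <- array(seq_len(4 * 4 * 6), c(4, 4, 6))
  vol <- mri_volume(g, source_path = "v1")
  sl <- extract_slices(vol, stride_plan(1))
  expect_length(sl, 6L)
  expect_identical(sl[[3L]]$image, g[, , 3L])
  expect_identical(sl[[3L]]$provenance$index, 2L)  # 0-based
  expect_identical(sl[[1L]]$provenance$volume, "v1")
  expect_error(extract_slices(vol, stride_plan(2, axes = 4L)), "axes")
})

test_that("preprocessing clamps, normalizes to [0,1] and resizes", {
  m <- matrix(0:999, 25, 40)
  s <- preprocess_slice(m, preprocess_config(target_size = c(32L, 32L)))
  expect_equal(dim(s$image), c(32L, 32L))
  expect_gte(min(s$image), 0); expect_lte(max(s$image), 1)
  # without resize distortion the extremes are exactly 0 and 1
  s2 <- preprocess_slice(m, preprocess_config(target_size = c(25L, 40L)))
  expect_equal(min(s2$image), 0); expect_equal(max(s2$image), 1)
})

test_that("constant slices map to zeros and are flagged", {
  s <- preprocess_slice(matrix(3.7, 10, 10),
                        preprocess_config(target_size = c(10L, 10L)))
  expect_true(all(s$image == 0))
  expect_true(s$provenance$constant)
})

test_that("percentile clamping defuses extreme outliers", {
  set.seed(23)
  m <- matrix(runif(40 * 40), 40, 40)
  m[5, 5] <- 1e6
  s <- preprocess_slice(m, preprocess_config(target_size = c(40L, 40L)))
  # direct percentile computation on the same slice is the oracle
  q <- quantile(m, c(0.001, 0.999), names = FALSE)
  expect_equal(median(s$image), (median(pmin(pmax(m, q[1]), q[2])) - q[1]) / (q[2] - q[1]))
  expect_gt(median(s$image), 0)
})

test_that("preprocess is idempotent on an already-normalized slice", {
  set.seed(24)
  m <- matrix(runif(32 * 32), 32, 32)
  cfg <- preprocess_config(clamp_low = 0, clamp_high = 100,
                           target_size = c(32L, 32L))
  s1 <- preprocess_slice(m, cfg)
  s2 <- preprocess_slice(s1$image, cfg)
  expect_equal(s2$image, s1$image, tolerance = 1e-12)
})

test_that("masks and labels ride along through preprocessing", {
  m <- matrix(runif(20 * 20), 20, 20)
  mask <- matrix(rep(c(0, 1), each = 200), 20, 20)
  s <- preprocess_slice(m, preprocess_config(target_size = c(40L, 40L)), mask = mask)
  expect_equal(dim(s$brain_mask), c(40L, 40L))
  expect_true(all(s$brain_mask %in% c(0, 1)))  # nearest-neighbour keeps it binary
})

test_that("augmentation is a joint transform, seeded, with identity fallback", {
  s <- disc_sample(32L)
  none <- augment_config(rotation = FALSE, flip = FALSE, crop = FALSE)
  expect_identical(augment_slice(s, none, 1L), s)
  cfg <- augment_config(flip_probability = 1, rotation = FALSE, crop = FALSE)
  a <- augment_slice(s, cfg, seed = 2L)
  expect_identical(a$brain_mask, s$brain_mask[rev(seq_len(32L)), ])
  expect_identical(a$image, s$image[rev(seq_len(32L)), ])
  full <- augment_config()
  a1 <- augment_slice(s, full, seed = 9L)
  a2 <- augment_slice(s, full, seed = 9L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$label_grid, a2$label_grid)
  # geometric transform commutes with mask binarization
  expect_true(all(a1$brain_mask %in% c(0, 1)))
  expect_identical(a1$brain_mask > 0.5, a1$brain_mask == 1)
})
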