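test_that("local contrast normalisation matches a sliding-window reference", {
  set.seed(21)
  x <- matrix(sample(0:255, 81, TRUE), 9, 9)
  r <- 2; sdevs <- 3
  got <- normalize_local_contrast(x, r, sdevs, c(0, 255))
  # direct reference with symmetric reflection indexing
  refl <- function(j, n) { j <- (j - 1) %% (2 * n); ifelse(j >= n, 2 * n - 1 - j, j) + 1 }
  for (i in 1:9) for (j in 1:9) {
    vals <- c()
    for (di in -r:r) for (dj in -r:r) {
      vals <- c(vals, x[refl(i + di, 9), refl(j + dj, 9)])
    }
    mu <- mean(vals); s <- sqrt(mean(vals^2) - mu^2)
    z <- if (s == 0) 0 else min(max((x[i, j] - mu) / s, -sdevs), sdevs)
    expect_equal(got[i, j], (z + sdevs) / (2 * sdevs) * 255, tolerance = 1e-8)
  }
})

test_that("local contrast normalisation handles flat images and clamps to range", {
  flat <- matrix(7, 20, 20)
  out <- normalize_local_contrast(flat, 3, 3, c(0, 255))
  expect_true(all(out == 127.5))
  set.seed(22)
  x <- matrix(runif(400, 0, 255), 20, 20)
  out <- normalize_local_contrast(x, 3, 3, c(0, 255))
  expect_true(all(out >= 0 & out <= 255))
})

test_that("gaussian smoothing conserves flats, normalises impulses, matches direct convolution", {
  flat <- matrix(3.5, 15, 15)
  expect_equal(gaussian_smooth(flat, 1), flat, tolerance = 1e-12)

  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  sm <- gaussian_smooth(imp, 1)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # interior impulse: response equals the separable kernel itself
  r <- 4
  k <- exp(-((-r:r)^2) / 2); k <- k / sum(k)
  expect_equal(sm[(8 - r):(8 + r), (8 - r):(8 + r)], outer(k, k), tolerance = 1e-12)
})

test_that("Li threshold separates a two-level image and is scale-equivariant", {
  x <- matrix(c(rep(10, 900), rep(200, 100)), 100, 10)
  t1 <- li_threshold(x)
  expect_gt(t1, 10); expect_lt(t1, 200)
  expect_equal(sum(x > t1), 100)
  expect_equal(li_threshold(3 * x), 3 * t1, tolerance = 1e-6)
  expect_error(li_threshold(matrix(5, 4, 4)), "constant")
})

test_that("Li threshold agrees with the exhaustive cross-entropy scan", {
  for (i in 1:12) {
    set.seed(100 + i)
    x <- matrix(sample(0:255, 64 * 64, TRUE), 64)
    expect_lt(abs(li_threshold(x) - li_exhaustive_oracle(x)), 1)
  }
})

test_that("connected-component labelling distinguishes 4- and 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal contact
  expect_equal(max(label_components(m, 8L)), 1L)
  expect_equal(max(label_components(m, 4L)), 2L)
  m[1, 5] <- TRUE
  lab <- label_components(m, 8L)
  expect_equal(max(lab), 2L)
  expect_equal(sum(lab > 0), 3)
})

test_that("segmentation recovers generated clusters and masks raw intensities", {
  cfg <- aggregate_field_config(n_clusters = 3, seed = 101, mode = "mixed")
  fld <- generate_aggregate_field(cfg)
  rois <- segment_aggregates(fld$image)
  expect_length(rois, 3)
  matched <- match_rois_to_truth(rois, fld$truth)
  expect_false(any(is.na(matched)))
  expect_equal(sort(matched), 1:3)
  # masked intensity conservation: ROI intensities are raw values inside the mask
  roi <- rois[[1]]
  b <- roi$bbox
  raw <- fld$image$data[1, (b[1] + 1):b[3], (b[2] + 1):b[4]]
  expect_identical(sum(roi$intensities$red), sum(raw[roi$mask]))
  expect_true(all(roi$intensities$red[!roi$mask] == 0))
})

test_that("a field with only sub-threshold-size debris yields no ROIs", {
  # constant background with scattered small speckles: everything the
  # chain detects stays far below the 1000 px size filter
  set.seed(9)
  arr <- array(10, dim = c(2, 256, 256))
  for (k in 1:30) {
    r <- sample(5:250, 1); c <- sample(5:250, 1)
    arr[sample(1:2, 1), r:(r + 2), c:(c + 2)] <- 200
  }
  img <- mc_image(arr, dtype_range = c(0, 255))
  expect_length(segment_aggregates(img), 0)
})

test_that("lowering the size filter never decreases the ROI count", {
  cfg <- aggregate_field_config(n_clusters = 3, seed = 55)
  fld <- generate_aggregate_field(cfg)
  counts <- vapply(c(5000L, 2000L, 1000L, 200L, 50L), function(a) {
    length(segment_aggregates(fld$image, segmentation_params(min_object_area_px = a)))
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("segmentation is stable under field translation", {
  cfg <- aggregate_field_config(image_height_px = 320, image_width_px = 320,
                                n_clusters = 1, cluster_radius_px = c(40, 45),
                                seed = 77)
  fld <- generate_aggregate_field(cfg)
  arr <- fld$image$data
  sh <- array(arr[, c(316:320, 1:315), c(314:320, 1:313)], dim = dim(arr))
  img_sh <- mc_image(sh, dtype_range = fld$image$dtype_range)
  p <- segmentation_params(contrast_block_radius_px = 63L)
  r1 <- segment_aggregates(fld$image, p)
  r2 <- segment_aggregates(img_sh, p)
  expect_length(r1, 1); expect_length(r2, 1)
  expect_equal(r2[[1]]$bbox[1] - r1[[1]]$bbox[1], 5)
  expect_equal(r2[[1]]$bbox[2] - r1[[1]]$bbox[2], 7)
  # overlap of the two masks laid over their common extent
  n1 <- pmin(dim(r1[[1]]$mask), dim(r2[[1]]$mask))
  m1 <- r1[[1]]$mask[seq_len(n1[1]), seq_len(n1[2])]
  m2 <- r2[[1]]$mask[seq_len(n1[1]), seq_len(n1[2])]
  expect_gt(sum(m1 & m2) / max(r1[[1]]$area_px, r2[[1]]$area_px), 0.98)
})
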