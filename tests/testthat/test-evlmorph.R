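test_that("boundary binarisation respects fixed thresholds and rejects flat images", {
  set.seed(41)
  x <- matrix(runif(100, 10, 50), 10, 10)
  expect_true(all(binarize_boundaries(x, "fixed", fixed_value = 5)))
  expect_false(any(binarize_boundaries(x, "fixed", fixed_value = 60)))
  expect_error(binarize_boundaries(matrix(1, 5, 5), "li"), "constant")
})

test_that("binarisation recovers most ground-truth boundary pixels", {
  cfg <- tessellation_config(n_cells = 50, domain_size_px = 256, seed = 14)
  ts <- generate_tessellation(cfg)
  mask <- binarize_boundaries(get_channel(ts$image, "phalloidin"), "li")
  truth_boundary <- ts$truth$label_map == 0
  expect_gt(sum(mask & truth_boundary) / sum(truth_boundary), 0.95)
})

test_that("despeckle removes isolated speckles, keeps solid structure, equals a loop median", {
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_true(all(despeckle(m) == 0))
  # a solid block keeps its majority interior (a 3x3 median erodes the
  # four corner pixels of any solid square, which see only 4/9 ones)
  blk <- matrix(0, 9, 9); blk[3:7, 3:7] <- 1
  ds <- despeckle(blk)
  expect_true(all(ds[4:6, 4:6] == 1))
  expect_true(all(ds[blk == 0] == 0))
  expect_equal(sum(blk) - sum(ds), 4)

  set.seed(42)
  x <- matrix(sample(0:1, 144, TRUE), 12, 12)
  got <- despeckle(x)
  pad <- x[c(1, 1:12, 12), c(1, 1:12, 12)]
  for (i in 1:12) for (j in 1:12) {
    expect_equal(got[i, j], median(pad[i:(i + 2), j:(j + 2)]))
  }
})

test_that("watershed separates enclosed regions and labels boundaries zero", {
  b <- matrix(TRUE, 40, 60)
  b[5:18, 5:25] <- FALSE
  b[25:36, 30:55] <- FALSE
  lab <- watershed_cells(b, merge_min_area = 10)
  expect_equal(max(lab), 2L)
  expect_true(all(lab[b] == 0L))
  expect_warning(watershed_cells(matrix(TRUE, 10, 10)), "no enclosed region")
})

test_that("watershed recovers a synthetic tessellation's cells and areas", {
  cfg <- tessellation_config(n_cells = 100, domain_size_px = 512, seed = 3)
  ts <- generate_tessellation(cfg)
  lab <- watershed_cells(despeckle(binarize_boundaries(
    get_channel(ts$image, "phalloidin"), "li")))
  n <- max(lab)
  expect_gte(n, 95); expect_lte(n, 105)
  cm <- cell_metrics(lab)
  tr <- ts$truth$cells
  matched <- lab[cbind(round(tr$centroid_row) + 1, round(tr$centroid_col) + 1)]
  ok <- matched > 0
  expect_gt(mean(ok), 0.95)
  r <- cor(tr$area_px[ok], cm$area_px[match(matched[ok], cm$label)])
  expect_gte(r, 0.95)
})

test_that("cell metrics match analytic geometry for squares and disks", {
  sq <- matrix(0L, 60, 60); sq[6:55, 6:55] <- 1L
  cm <- cell_metrics(sq)
  expect_equal(cm$area_px, 2500)
  expect_gte(cm$circularity, 0.75); expect_lte(cm$circularity, 0.89)

  n <- 121; rows <- matrix(0:(n - 1), n, n); cols <- t(rows)
  dk <- matrix(0L, n, n); dk[(rows - 60)^2 + (cols - 60)^2 <= 50^2] <- 1L
  cmd <- cell_metrics(dk)
  expect_gte(cmd$circularity, 0.95); expect_lte(cmd$circularity, 1)
})

test_that("region areas add up to the non-boundary pixel count", {
  cfg <- tessellation_config(n_cells = 40, domain_size_px = 256, seed = 12)
  ts <- generate_tessellation(cfg)
  cm <- cell_metrics(ts$truth$label_map)
  expect_equal(sum(cm$area_px), sum(ts$truth$label_map > 0))
  expect_true(all(cm$circularity > 0 & cm$circularity <= 1))
})

test_that("morphometry summaries are invariant under label permutation", {
  cfg <- tessellation_config(n_cells = 30, domain_size_px = 200, seed = 19)
  ts <- generate_tessellation(cfg)
  lab <- ts$truth$label_map
  perm <- sample(30)
  lab2 <- lab; lab2[lab > 0] <- perm[lab[lab > 0]]
  s1 <- morphometry_summary(lab)
  s2 <- morphometry_summary(lab2)
  expect_equal(s1$n_cells, s2$n_cells)
  expect_equal(s1$mean_area, s2$mean_area)
  expect_equal(s1$mean_circularity, s2$mean_circularity)
  expect_equal(s1$junction_arity_counts, s2$junction_arity_counts)
})

test_that("junction detection finds injected rosettes at their positions", {
  cfg <- tessellation_config(n_cells = 100, domain_size_px = 512, seed = 3,
                             rosette_injections = c(5, 6, 7))
  ts <- generate_tessellation(cfg)
  jx <- detect_junctions(ts$truth$label_map)
  for (a in 5:7) {
    gt <- ts$truth$junctions[ts$truth$junctions$arity == a, ]
    det <- jx[jx$arity == a, ]
    expect_equal(nrow(det), 1)
    expect_lt(sqrt((det$row - gt$row)^2 + (det$col - gt$col)^2), 3)
  }
  # no spurious high-arity junctions on an uninjected control
  cfg0 <- tessellation_config(n_cells = 100, domain_size_px = 512, seed = 28)
  jx0 <- detect_junctions(generate_tessellation(cfg0)$truth$label_map)
  expect_equal(sum(jx0$is_rosette), 0)
  expect_gt(mean(jx0$arity == 3), 0.8)
})

test_that("two-cell contacts are reportable but never junction points", {
  cfg <- tessellation_config(n_cells = 30, domain_size_px = 200, seed = 33)
  ts <- generate_tessellation(cfg)
  j3 <- detect_junctions(ts$truth$label_map)
  j2 <- detect_junctions(ts$truth$label_map, include_two_cell = TRUE)
  expect_true(all(j3$arity >= 3))
  expect_true(any(j2$arity == 2))
  expect_gt(nrow(j2), nrow(j3))
})

test_that("mitotic percentages count nucleus-bearing cells", {
  lab <- matrix(0L, 40, 40)
  for (i in 0:3) for (j in 0:3) lab[(i * 10 + 2):(i * 10 + 9), (j * 10 + 2):(j * 10 + 9)] <- i * 4 + j + 1L
  ph <- matrix(0, 40, 40)
  ph[4:6, 4:6] <- 200   # nucleus in cell 1
  ph[24:26, 14:16] <- 200  # nucleus in cell 10
  expect_equal(mitotic_fraction(lab, ph, nucleus_min_area_px = 4), 100 * 2 / 16)
  expect_equal(mitotic_fraction(lab, matrix(0, 40, 40)), 0)
})

test_that("generated mitotic fractions are recovered exactly from the truth labels", {
  cfg <- tessellation_config(n_cells = 100, domain_size_px = 512, seed = 3,
                             mitotic_fraction = 0.1)
  ts <- generate_tessellation(cfg)
  got <- mitotic_fraction(ts$truth$label_map, get_channel(ts$image, "phh3"))
  expect_equal(got, 100 * sum(ts$truth$cells$is_mitotic) / 100)
})
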