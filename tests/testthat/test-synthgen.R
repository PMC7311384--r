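test_that("aggregate fields are byte-identical under a repeated seed", {
  cfg <- aggregate_field_config(n_clusters = 2, seed = 123, mode = "sorted",
                                mixing_m = 0.3)
  a <- generate_aggregate_field(cfg)
  b <- generate_aggregate_field(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$clusters, b$truth$clusters)
})

test_that("sorted mode at m = 0 separates the channel centroids along the sorting axis", {
  cfg <- aggregate_field_config(n_clusters = 1, seed = 17, mode = "sorted",
                                mixing_m = 0)
  fld <- generate_aggregate_field(cfg)
  cl <- fld$truth$clusters[[1]]
  cen_red <- colMeans(cl$cells[cl$cells$channel == "red", c("row", "col")])
  cen_grn <- colMeans(cl$cells[cl$cells$channel == "green", c("row", "col")])
  # red occupies the negative side of the sorting axis
  expect_lt(sum((cen_red - cl$center) * cl$sorting_axis), 0)
  expect_gt(sum((cen_grn - cl$center) * cl$sorting_axis), 0)
  expect_gt(cl$true_centroid_separation, 0.5 * cl$radius_px)
})

test_that("manifest centroid separation is non-increasing in the mixing parameter", {
  ms <- c(0, 0.25, 0.5, 0.75, 1)
  sep <- vapply(ms, function(m) {
    mean(vapply(1:30, function(i) {
      cfg <- aggregate_field_config(image_height_px = 64, image_width_px = 64,
        n_clusters = 1, cluster_radius_px = c(18, 22), cells_per_cluster = 50,
        cell_sigma_px = 3, mode = "sorted", mixing_m = m, seed = 4600 + i)
      fld <- generate_aggregate_field(cfg)
      fld$truth$clusters[[1]]$true_centroid_separation
    }, 0))
  }, 0)
  expect_true(all(diff(sep) < 0))
})

test_that("channel counts follow red_fraction and rendered mass matches the blob integral", {
  cfg <- aggregate_field_config(n_clusters = 2, cells_per_cluster = 40,
                                red_fraction = 0.4, seed = 3,
                                background_level = 0, gaussian_noise_sd = 0,
                                cell_amplitude = 20, bit_depth = 16)
  fld <- generate_aggregate_field(cfg)
  cells <- do.call(rbind, lapply(fld$truth$clusters, `[[`, "cells"))
  expect_equal(sum(cells$channel == "red"), 2 * round(0.4 * 40))
  # noise-free, zero-background: total intensity ~ n_cells * 2 pi sigma^2 A
  blob_integral <- 2 * pi * cfg$cell_sigma_px^2 * cfg$cell_amplitude
  for (ch in 1:2) {
    n_ch <- sum(cells$channel == c("red", "green")[ch])
    expect_equal(sum(fld$image$data[ch, , ]), n_ch * blob_integral,
                 tolerance = 0.01)
  }
})

test_that("infeasible aggregate geometry is rejected", {
  expect_error(
    aggregate_field_config(image_height_px = 100, image_width_px = 100,
                           cluster_radius_px = c(45, 60)) |>
      generate_aggregate_field(),
    "geometry infeasible")
  expect_error(
    generate_aggregate_field(aggregate_field_config(
      image_height_px = 150, image_width_px = 150, n_clusters = 20,
      cluster_radius_px = c(30, 40))),
    "geometry infeasible")
})

test_that("tessellations are reproducible and cover the domain with n_cells labels", {
  cfg <- tessellation_config(n_cells = 60, domain_size_px = 256, seed = 8)
  a <- generate_tessellation(cfg)
  b <- generate_tessellation(cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$label_map, b$truth$label_map)
  expect_equal(sort(unique(a$truth$label_map[a$truth$label_map > 0])), 1:60)
  # area conservation: cells + boundary/background = full domain
  expect_equal(sum(a$truth$cells$area_px) + sum(a$truth$label_map == 0), 256^2)
})

test_that("generic tessellation junctions are three-way; injections hit their arity exactly", {
  cfg <- tessellation_config(n_cells = 80, domain_size_px = 400, seed = 21)
  ts <- generate_tessellation(cfg)
  expect_true(all(ts$truth$junctions$arity >= 3))
  expect_gt(mean(ts$truth$junctions$arity == 3), 0.9)
  # every listed junction has arity = number of distinct incident labels
  expect_true(all(ts$truth$junctions$arity ==
                    vapply(ts$truth$junctions$labels, length, 0L)))

  cfg6 <- tessellation_config(n_cells = 80, domain_size_px = 400, seed = 21,
                              rosette_injections = 6L)
  ts6 <- generate_tessellation(cfg6)
  expect_equal(sum(ts6$truth$junctions$arity == 6), 1)
  expect_equal(ts6$truth$junctions$arity[ts6$truth$junctions$injected], 6L)
})

test_that("infeasible rosette injections fail naming the injection index", {
  expect_error(
    generate_tessellation(tessellation_config(n_cells = 5, domain_size_px = 64,
                                              rosette_injections = c(5, 8),
                                              seed = 2)),
    "injection")
})

test_that("mitotic flags follow the round-half-up counting rule", {
  cfg <- tessellation_config(n_cells = 40, domain_size_px = 256,
                             mitotic_fraction = 0.05, seed = 5)
  ts <- generate_tessellation(cfg)
  expect_equal(sum(ts$truth$cells$is_mitotic), 2)  # 0.05 * 40
  cfg2 <- tessellation_config(n_cells = 30, domain_size_px = 256,
                              mitotic_fraction = 0.05, seed = 5)
  # 1.5 rounds up
  expect_equal(sum(generate_tessellation(cfg2)$truth$cells$is_mitotic), 2)
})

test_that("epiboly tables are reproducible and carry the injected delay", {
  a <- generate_epiboly_table(3, seed = 6)
  b <- generate_epiboly_table(3, seed = 6)
  expect_identical(a, b)

  clean <- generate_epiboly_table(2, genotype_delay_h = 0, noise_sd_h = 0, seed = 1)
  wt <- clean[clean$genotype == "wt", ]
  mut <- clean[clean$genotype == "mut", ]
  expect_equal(wt$time_h, mut$time_h)

  del <- generate_epiboly_table(2, genotype_delay_h = 25 / 60, noise_sd_h = 0, seed = 1)
  dd <- del$time_h[del$genotype == "mut"] - del$time_h[del$genotype == "wt"]
  expect_equal(dd[del$stage[del$genotype == "mut"] == "dome"], c(0, 0))
  expect_equal(unique(round(dd[del$stage[del$genotype == "mut"] != "dome"], 9)),
               round(25 / 60, 9))
  # times non-decreasing within each series
  for (g in c("wt", "mut")) for (r in 1:2) {
    tt <- del$time_h[del$genotype == g & del$repeat_id == r]
    expect_true(all(diff(tt) >= 0))
  }
})

test_that("qPCR tables encode fold changes as CT shifts under perfect efficiency", {
  q <- generate_qpcr_table(c("actb1", "appb"), c(actb1 = 0, appb = 2),
                           ct_sd = 0, n_samples = 2, seed = 9)
  wt <- q[q$gene == "appb" & q$genotype == "wt", ]
  mut <- q[q$gene == "appb" & q$genotype == "mut", ]
  expect_equal(unique(wt$ct1 - mut$ct1), 2)
  expect_identical(q, generate_qpcr_table(c("actb1", "appb"),
                                          c(actb1 = 0, appb = 2),
                                          ct_sd = 0, n_samples = 2, seed = 9))
})
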