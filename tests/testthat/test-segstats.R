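test_that("identical channels give coincident centroids, S = 1 and P = 0", {
  roi <- make_disk_roi(60, "identical")
  m <- channel_moments(roi)
  expect_equal(m$centroid_red, m$centroid_green)
  expect_equal(m$g_red, m$g_green)
  expect_identical(scattering(roi, "ratio"), 1)
  expect_identical(scattering(roi, "bounded"), 1)
  expect_identical(dipole_moment(roi), 0)
})

test_that("uniform disk gyration radius approaches R/sqrt(2)", {
  for (R in c(40, 80)) {
    roi <- make_disk_roi(R, "identical")
    m <- channel_moments(roi)
    expect_equal(m$g_red, R / sqrt(2), tolerance = 0.01)
  }
})

test_that("moments are invariant to per-channel brightness scaling", {
  roi <- make_disk_roi(50, "bisected")
  roi7 <- roi
  roi7$intensities$red <- roi$intensities$red * 7
  m1 <- channel_moments(roi); m7 <- channel_moments(roi7)
  expect_equal(m1, m7, tolerance = 1e-12)
})

test_that("vectorized moments equal an explicit per-pixel loop oracle", {
  set.seed(31)
  mask <- matrix(TRUE, 12, 14)
  red <- matrix(runif(12 * 14), 12, 14)
  grn <- matrix(runif(12 * 14), 12, 14)
  roi <- aggregate_roi(1L, mask, c(3L, 5L, 15L, 19L), list(red = red, green = grn))
  got <- channel_moments(roi)
  exp_ <- moments_loop_oracle(roi)
  expect_equal(got$centroid_red, exp_$centroid_red, tolerance = 1e-9)
  expect_equal(got$centroid_green, exp_$centroid_green, tolerance = 1e-9)
  expect_equal(got$g_red, exp_$g_red, tolerance = 1e-9)
  expect_equal(got$g_green, exp_$g_green, tolerance = 1e-9)
})

test_that("zero-mass channels are rejected with the channel named", {
  roi <- make_disk_roi(30, "identical")
  roi$intensities$green[] <- 0
  expect_error(channel_moments(roi), "green")
})

test_that("channel swap fixes P, reflects S_bounded and inverts S_ratio", {
  roi <- make_disk_roi(60, "engulfed")
  sw <- roi
  sw$intensities <- list(red = roi$intensities$green, green = roi$intensities$red)
  expect_equal(dipole_moment(sw), dipole_moment(roi), tolerance = 1e-9)
  expect_equal(scattering(sw, "bounded"), 2 - scattering(roi, "bounded"), tolerance = 1e-9)
  expect_equal(scattering(sw, "ratio"), 1 / scattering(roi, "ratio"), tolerance = 1e-9)
})

test_that("S and P are invariant under translation and 90-degree rotation", {
  roi <- make_disk_roi(50, "bisected")
  s0 <- scattering(roi); p0 <- dipole_moment(roi)
  tr <- roi; tr$bbox <- roi$bbox + c(12L, 7L, 12L, 7L)
  expect_equal(scattering(tr), s0, tolerance = 1e-9)
  expect_equal(dipole_moment(tr), p0, tolerance = 1e-9)
  rot <- aggregate_roi(1L, t(roi$mask)[rev(seq_len(ncol(roi$mask))), ],
                       roi$bbox[c(2, 1, 4, 3)],
                       lapply(roi$intensities, function(m) t(m)[rev(seq_len(ncol(m))), ]))
  expect_equal(scattering(rot), s0, tolerance = 0.01)
  expect_equal(dipole_moment(rot), p0, tolerance = 0.01)
})

test_that("intermixed classification uses an open window", {
  expect_true(classify_intermixed(1.0))
  expect_false(classify_intermixed(0.9))
  expect_false(classify_intermixed(1.1))
  expect_false(classify_intermixed(1.25))
  expect_equal(classify_intermixed(c(0.95, 1.3)), c(TRUE, FALSE))
})

test_that("population summaries count intermixed clusters and conserve histogram mass", {
  res <- tibble::tibble(S_bounded = c(0.5, 1.0, 1.05, 1.3),
                        P = c(1.2, 0.1, 0.2, 1.9))
  s <- summarize_population(res, repeat_ids = c(1, 1, 2, 2))
  expect_equal(s$intermixed_fraction, 0.5)
  expect_equal(s$per_repeat_fractions, c(0.5, 0.5))
  expect_equal(sum(s$S_histogram$counts), 4)
  expect_equal(sum(s$P_histogram$counts), 4)  # P = 1.9 clipped into the last bin
  expect_error(summarize_population(res[0, ]), "empty")
})

test_that("group comparison is symmetric and degenerate-safe", {
  a <- summarize_population(tibble::tibble(S_bounded = rep(1, 6), P = rep(0, 6)),
                            repeat_ids = rep(1:3, each = 2))
  b <- a
  cmp <- compare_groups(a, b)
  expect_identical(cmp$t_statistic, 0)
  expect_identical(cmp$p_value, 1)

  resa <- tibble::tibble(S_bounded = c(1, 1, 1, 1.5, 1, 1), P = 0)
  resb <- tibble::tibble(S_bounded = c(1, 1.5, 1, 1.5, 1, 1.5), P = 0)
  sa <- summarize_population(resa, repeat_ids = rep(1:3, each = 2))
  sb <- summarize_population(resb, repeat_ids = rep(1:3, each = 2))
  ab <- compare_groups(sa, sb)
  ba <- compare_groups(sb, sa)
  expect_equal(ab$t_statistic, -ba$t_statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("engulfment shows in S but not P; sorting shows in P but not S", {
  eng <- simulate_cluster_population("engulfed", 0, n_clusters = 20, seed = 900)
  srt <- simulate_cluster_population("sorted", 0, n_clusters = 20, seed = 900)
  # engulfed: coincident centroids (P at its sampling floor), compact core
  expect_lt(mean(eng$P), 0.25)
  expect_lt(mean(eng$S_bounded), 0.85)
  # sorted: separated centroids (P deflated ~25% by the padded truth
  # mask inflating R_eq), equal gyration radii
  expect_gt(mean(srt$P), 0.6)
  expect_gt(mean(srt$P), 3 * mean(eng$P))
  expect_true(all(abs(srt$S_bounded - 1) < 0.1))
})
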