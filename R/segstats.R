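#' Intensity moments of a two-channel ROI
#'
#' Treats each channel's masked intensities as a mass distribution: each
#' channel is normalised to unit total mass; centroids are the first
#' moments; the combined centroid is that of the average of the two
#' normalised channels (equivalently the midpoint of the two centroids,
#' robust to unequal labelling brightness); `g_red` / `g_green` are the
#' intensity-weighted RMS radii (radii of gyration) of each channel about
#' the combined centroid. Coordinates are 0-based `(row, col)`.
#'
#' @param roi an [aggregate_roi()] with two channels.
#' @return list with `centroid_red`, `centroid_green`, `combined_centroid`
#'   (each `(row, col)`), and `g_red`, `g_green` in pixels.
#' @export
channel_moments <- function(roi) {
  stopifnot(inherits(roi, "aggregate_roi"), length(roi$intensities) == 2L)
  w <- roi$intensities
  for (ch in names(w)) {
    if (sum(w[[ch]]) <= 0) stop(sprintf("channel '%s' has zero total intensity in ROI %d", ch, roi$id))
  }
  nr <- nrow(roi$mask)
  rows <- matrix(seq_len(nr) - 1L, nr, ncol(roi$mask))          # 0-based, local
  cols <- matrix(seq_len(ncol(roi$mask)) - 1L, nr, ncol(roi$mask), byrow = TRUE)
  moments1 <- function(m) {
    m <- m / sum(m)
    c(sum(m * rows), sum(m * cols))
  }
  c_red <- moments1(w[[1]])
  c_grn <- moments1(w[[2]])
  c_all <- (c_red + c_grn) / 2
  gyr <- function(m) {
    m <- m / sum(m)
    sqrt(sum(m * ((rows - c_all[1])^2 + (cols - c_all[2])^2)))
  }
  off <- roi$bbox[1:2]
  list(centroid_red = c_red + off, centroid_green = c_grn + off,
       combined_centroid = c_all + off,
       g_red = gyr(w[[1]]), g_green = gyr(w[[2]]))
}

#' Dipole moment P of a two-channel ROI
#'
#' The distance between the red and green intensity centroids, normalised
#' by the centroid separation of the two half-disks of the cluster's
#' equivalent circle, `8 R_eq / (3 pi)` with `R_eq = sqrt(area / pi)`.
#' An ideally bisected uniform disk therefore scores P = 1; a fully mixed
#' or concentrically engulfed cluster scores P ~ 0.
#'
#' @param roi an [aggregate_roi()].
#' @param moments optional precomputed [channel_moments()] result.
#' @return non-negative scalar.
#' @export
dipole_moment <- function(roi, moments = NULL) {
  if (is.null(moments)) moments <- channel_moments(roi)
  r_eq <- sqrt(roi$area_px / pi)
  d <- sqrt(sum((moments$centroid_red - moments$centroid_green)^2))
  d / (8 * r_eq / (3 * pi))
}

#' Scattering statistic S of a two-channel ROI
#'
#' Compares the two populations' radii of gyration about the combined
#' centroid. `convention = "ratio"` returns `g_red / g_green`, with range
#' `[0, Inf)`; `"bounded"` (default) returns `2 g_red / (g_red + g_green)`,
#' a symmetric form bounded in `[0, 2]`. Both equal 1 for statistically
#' identical (intermixed) channels and move towards 0 or 2 as one
#' population concentrates relative to the other.
#'
#' @param roi an [aggregate_roi()].
#' @param convention `"bounded"` (default) or `"ratio"`.
#' @param moments optional precomputed [channel_moments()] result.
#' @return scalar S.
#' @export
scattering <- function(roi, convention = c("bounded", "ratio"), moments = NULL) {
  convention <- match.arg(convention)
  if (is.null(moments)) moments <- channel_moments(roi)
  if (convention == "ratio") {
    if (moments$g_green == 0) stop("g_green is zero; S ratio undefined")
    moments$g_red / moments$g_green
  } else {
    2 * moments$g_red / (moments$g_red + moments$g_green)
  }
}

#' Full segregation statistics for one ROI
#'
#' @param roi an [aggregate_roi()].
#' @return one-row tibble: roi_id, centroids, gyration radii, S under both
#'   conventions, P, area and equivalent radius.
#' @export
segregation_result <- function(roi) {
  m <- channel_moments(roi)
  tibble::tibble(
    roi_id = roi$id,
    centroid_red_row = m$centroid_red[1], centroid_red_col = m$centroid_red[2],
    centroid_green_row = m$centroid_green[1], centroid_green_col = m$centroid_green[2],
    g_red = m$g_red, g_green = m$g_green,
    S_ratio = scattering(roi, "ratio", m),
    S_bounded = scattering(roi, "bounded", m),
    P = dipole_moment(roi, m),
    area_px = roi$area_px,
    R_eq = sqrt(roi$area_px / pi)
  )
}

#' Segregation statistics for a list of ROIs
#'
#' @param rois list of [aggregate_roi()] objects.
#' @return tibble, one row per ROI (see [segregation_result()]).
#' @export
segregation_stats <- function(rois) {
  dplyr::bind_rows(lapply(rois, segregation_result))
}

#' Classify a cluster as intermixed
#'
#' TRUE iff S falls strictly inside the window (open interval).
#'
#' @param S scattering value(s).
#' @param window `(lo, hi)`, default `c(0.9, 1.1)`.
#' @return logical.
#' @export
classify_intermixed <- function(S, window = c(0.9, 1.1)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  S > window[1] & S < window[2]
}

#' Population summary of segregation statistics
#'
#' Computes the intermixed fraction (overall and per experimental repeat)
#' and frequency histograms of S and P. Values outside the histogram span
#' are counted in the extreme bins so counts always sum to the number of
#' clusters.
#'
#' @param results tibble from [segregation_stats()] (needs the column named
#'   by `s_column`, and `P`).
#' @param repeat_ids optional vector assigning each cluster to a repeat.
#' @param window intermixed window, default `c(0.9, 1.1)` (open).
#' @param s_column which S convention to classify on (`"S_bounded"` default).
#' @param s_breaks,p_breaks histogram bin edges.
#' @param group_label free-text label for the group.
#' @return a `population_summary` list.
#' @export
summarize_population <- function(results, repeat_ids = NULL,
                                 window = c(0.9, 1.1),
                                 s_column = "S_bounded",
                                 s_breaks = seq(0, 2, by = 0.1),
                                 p_breaks = seq(0, 1.5, by = 0.05),
                                 group_label = "") {
  if (NROW(results) == 0L) stop("summarize_population: empty results")
  S <- results[[s_column]]
  P <- results[["P"]]
  inter <- classify_intermixed(S, window)
  per_repeat <- NULL
  if (!is.null(repeat_ids)) {
    stopifnot(length(repeat_ids) == length(S))
    per_repeat <- as.numeric(tapply(inter, repeat_ids, mean))
  }
  hist_of <- function(x, breaks) {
    x <- pmin(pmax(x, breaks[1]), breaks[length(breaks)])
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    list(bin_edges = breaks, counts = h$counts)
  }
  structure(list(
    group_label = group_label,
    n_clusters = length(S),
    intermixed_fraction = mean(inter),
    intermixed_window = window,
    s_convention = s_column,
    S_histogram = hist_of(S, s_breaks),
    P_histogram = hist_of(P, p_breaks),
    per_repeat_fractions = per_repeat
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("<population_summary '%s'> n = %d clusters; intermixed (%g, %g): %.1f%%\n",
              x$group_label, x$n_clusters, x$intermixed_window[1],
              x$intermixed_window[2], 100 * x$intermixed_fraction))
  invisible(x)
}

#' Compare intermixed fractions between two groups
#'
#' Unpaired two-sided Student's t-test (equal-variance by default; Welch
#' via `welch = TRUE`) on the per-repeat intermixed fractions of two
#' population summaries. The experimental repeat, not the cluster, is the
#' statistical unit.
#'
#' @param a,b `population_summary` objects with `per_repeat_fractions`
#'   (>= 2 repeats each).
#' @param welch use the Welch (unequal-variance) form.
#' @return a `group_comparison` list: means, t statistic, p value, group sizes.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  fa <- a$per_repeat_fractions; fb <- b$per_repeat_fractions
  if (is.null(fa) || is.null(fb) || length(fa) < 2L || length(fb) < 2L) {
    stop("compare_groups needs >= 2 repeats per group")
  }
  out <- compare_means(fa, fb, welch = welch)
  out$label_a <- a$group_label
  out$label_b <- b$group_label
  out
}
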