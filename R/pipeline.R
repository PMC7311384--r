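#' Mixing-parameter response of the segregation statistics
#'
#' Runs the full detection-and-scoring chain over synthetic fields at a
#' series of mixing levels: generate multi-cluster fields, segment them,
#' match ROIs to the manifest, score S and P, and summarise per level.
#' Used to verify that the statistics recover the generator's mixing
#' parameter monotonically.
#'
#' @param mode `"sorted"` or `"engulfed"` arrangements.
#' @param m_levels mixing levels to sweep.
#' @param fields_per_level fields generated at each level (default 8
#'   fields of 4 clusters = 32 clusters per level).
#' @param seed base seed.
#' @param window intermixed window for the fraction.
#' @return tibble: `mixing_m`, `n_clusters`, `mean_P`, `mean_S_bounded`,
#'   `intermixed_fraction`.
#' @export
segregation_mixing_sweep <- function(mode = "sorted",
                                     m_levels = c(0, 0.25, 0.5, 0.75, 1),
                                     fields_per_level = 8L,
                                     seed = 1L,
                                     window = c(0.9, 1.1)) {
  rows <- lapply(seq_along(m_levels), function(li) {
    stats_all <- list()
    for (f in seq_len(fields_per_level)) {
      cfg <- aggregate_field_config(mode = mode, mixing_m = m_levels[li],
                                    seed = seed + li * 1000L + f)
      fld <- generate_aggregate_field(cfg)
      rois <- segment_aggregates(fld$image)
      matched <- unique(stats::na.omit(match_rois_to_truth(rois, fld$truth)))
      keep <- rois[matched]
      if (length(keep) > 0) stats_all[[f]] <- segregation_stats(keep)
    }
    st <- dplyr::bind_rows(stats_all)
    tibble::tibble(
      mixing_m = m_levels[li],
      n_clusters = nrow(st),
      mean_P = mean(st$P),
      mean_S_bounded = mean(st$S_bounded),
      intermixed_fraction = mean(classify_intermixed(st$S_bounded, window))
    )
  })
  dplyr::bind_rows(rows)
}

#' Two-group intermixed-fraction study
#'
#' Emulates the two-group cluster comparison: for each group, simulates
#' `n_repeats` experimental repeats of `clusters_per_repeat` single-cluster
#' aggregates under the frozen arrangement conditions
#' ([segregation_study_conditions()]), summarises each group's intermixed
#' fraction per repeat, and compares the groups with an unpaired t-test on
#' the per-repeat fractions.
#'
#' @param seed base seed.
#' @param n_repeats repeats per group (default 3).
#' @param clusters_per_repeat clusters per repeat (default 300).
#' @return list: `summary_a` (higher-mixing group), `summary_b`,
#'   `comparison` ([compare_groups()] result).
#' @export
segregation_group_study <- function(seed = 1L, n_repeats = 3L,
                                    clusters_per_repeat = 300L) {
  cond <- segregation_study_conditions()
  run_group <- function(m, label, off) {
    per_rep <- lapply(seq_len(n_repeats), function(k) {
      st <- simulate_cluster_population(cond$mode, m, clusters_per_repeat,
                                        seed = seed + off + k * 1000L)
      st$repeat_id <- k
      st
    })
    st <- dplyr::bind_rows(per_rep)
    summarize_population(st, repeat_ids = st$repeat_id, group_label = label)
  }
  a <- run_group(cond$mixing_high, "wt/wt-like (higher mixing)", 0L)
  b <- run_group(cond$mixing_low, "wt/mut-like (lower mixing)", 500000L)
  list(summary_a = a, summary_b = b, comparison = compare_groups(a, b))
}
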