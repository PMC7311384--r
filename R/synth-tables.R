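#' Standard epiboly stage reference times
#'
#' Hours post fertilisation at which a wild-type embryo reaches each stage
#' under standard staging (dome at 4.33 h). These are configuration data,
#' not measurements.
#'
#' @return named numeric vector over [epiboly_stages()].
#' @export
default_stage_offsets <- function() {
  stats::setNames(c(4.33, 4.67, 5.25, 5.67, 6.0, 8.0, 9.0, 10.0),
                  epiboly_stages())
}

#' Generate a synthetic epiboly staging table
#'
#' Emulates repeated staging sessions of wild-type and mutant plates:
#' wild-type times are the stage reference plus an optional per-repeat
#' technical shift (shared by both genotypes, as both plates run in the
#' same session — this is what [normalize_epiboly()] removes) plus
#' independent per-record measurement jitter; mutants are additionally
#' delayed by `genotype_delay_h` at every post-dome stage. Within each
#' genotype-repeat series times are made non-decreasing (a later stage is
#' never recorded before an earlier one).
#'
#' @param n_repeats number of repeats (sessions).
#' @param stage_offsets_h named stage reference times, default
#'   [default_stage_offsets()].
#' @param genotype_delay_h mutant delay (h) at post-dome stages
#'   (25 min = 0.4167 h is a realistic effect size).
#' @param noise_sd_h SD (h) of the per-record measurement jitter.
#' @param tech_shift_sd_h SD (h) of the per-repeat technical shift
#'   (default 0).
#' @param seed RNG seed.
#' @return tibble: `genotype`, `stage`, `repeat_id`, `time_h`.
#' @export
generate_epiboly_table <- function(n_repeats = 3L,
                                   stage_offsets_h = default_stage_offsets(),
                                   genotype_delay_h = 25 / 60,
                                   noise_sd_h = 5 / 60,
                                   tech_shift_sd_h = 0,
                                   seed = 1L) {
  stopifnot(n_repeats >= 1, all(names(stage_offsets_h) == epiboly_stages()))
  set.seed(seed)
  stages <- names(stage_offsets_h)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    tech <- if (tech_shift_sd_h > 0) stats::rnorm(1, 0, tech_shift_sd_h) else 0
    for (gt in c("wt", "mut")) {
      delay <- ifelse(stages == "dome", 0, ifelse(gt == "mut", genotype_delay_h, 0))
      t <- stage_offsets_h + tech + delay + stats::rnorm(length(stages), 0, noise_sd_h)
      t <- cummax(t)  # staging is ordinal: enforce non-decreasing times
      rows[[length(rows) + 1L]] <- tibble::tibble(
        genotype = gt, stage = stages, repeat_id = rep_i, time_h = unname(t))
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a synthetic qPCR CT table
#'
#' Draws CT triplicates under the perfect-efficiency model (one cycle per
#' doubling): a gene with true log2 fold change `f` in mutants has its
#' mutant CT lowered by `f` cycles relative to wild type. A per-sample
#' offset (pipetting/input variation) shifts all genes of a sample
#' equally, including the housekeeping gene, and therefore cancels in the
#' delta-delta-Ct analysis. The housekeeping gene must be included with
#' fold 0.
#'
#' @param genes character vector of gene names (housekeeping included).
#' @param true_log2_fold named vector, per-gene true log2 fold (mut vs wt);
#'   the housekeeping gene must be 0.
#' @param ct_sd technical SD of a single CT replicate (0 gives exact CTs).
#' @param n_samples samples per genotype.
#' @param housekeeping_gene which gene is the housekeeping reference.
#' @param base_ct named baseline CTs per gene (defaults: 20 for the
#'   housekeeping gene, 26 for targets).
#' @param sample_offset_sd SD of the per-sample global CT offset (only
#'   applied when `ct_sd > 0`).
#' @param seed RNG seed.
#' @return tibble: `sample_id`, `genotype`, `gene`, `ct1`..`ct3`.
#' @export
generate_qpcr_table <- function(genes, true_log2_fold, ct_sd = 0.15,
                                n_samples = 4L,
                                housekeeping_gene = genes[1],
                                base_ct = NULL, sample_offset_sd = 0.3,
                                seed = 1L) {
  stopifnot(housekeeping_gene %in% genes,
            all(genes %in% names(true_log2_fold)),
            true_log2_fold[[housekeeping_gene]] == 0,
            n_samples >= 1, ct_sd >= 0)
  set.seed(seed)
  if (is.null(base_ct)) {
    base_ct <- stats::setNames(ifelse(genes == housekeeping_gene, 20, 26), genes)
  }
  rows <- list()
  for (gt in c("wt", "mut")) {
    for (s in seq_len(n_samples)) {
      sid <- sprintf("%s_%d", gt, s)
      offset <- if (ct_sd > 0) stats::rnorm(1, 0, sample_offset_sd) else 0
      for (g in genes) {
        fold <- if (gt == "mut") true_log2_fold[[g]] else 0
        mu <- base_ct[[g]] - fold + offset
        cts <- mu + stats::rnorm(3, 0, ct_sd)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sid, genotype = gt, gene = g,
          ct1 = cts[1], ct2 = cts[2], ct3 = cts[3])
      }
    }
  }
  dplyr::bind_rows(rows)
}
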