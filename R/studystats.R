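#' Unpaired two-sample comparison of means
#'
#' Two-sided unpaired t-test (Student's equal-variance form by default,
#' Welch optionally). Degenerate inputs where both groups have zero
#' variance are handled explicitly: equal means give t = 0, p = 1;
#' unequal means give an infinite statistic and p = 0.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @param welch use the Welch form.
#' @return a `group_comparison` list: `mean_a`, `mean_b`, `t_statistic`,
#'   `p_value`, `n_a`, `n_b`.
#' @export
compare_means <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p = if (eq) 1 else 0)
  } else {
    tt <- stats::t.test(a, b, var.equal = !welch)
    res <- list(t = unname(tt$statistic), p = tt$p.value)
  }
  structure(list(mean_a = mean(a), mean_b = mean(b),
                 t_statistic = res$t, p_value = res$p,
                 n_a = length(a), n_b = length(b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> mean_a = %.4g (n=%d), mean_b = %.4g (n=%d); t = %.4g, p = %.4g\n",
              x$mean_a, x$n_a, x$mean_b, x$n_b, x$t_statistic, x$p_value))
  invisible(x)
}

#' The ordered epiboly stages used throughout the package
#' @export
epiboly_stages <- function() {
  c("dome", "30pct", "50pct", "germ_ring", "shield", "75pct", "90pct", "100pct")
}

#' Normalise epiboly stage times to the dome reference
#'
#' Within each repeat, the deviation of the observed wild-type dome time
#' from the reference (4.33 h in standard staging) is subtracted from every
#' record of that repeat, both genotypes — correcting for technical shifts
#' between repeats. Wild-type dome time becomes exactly the reference; the
#' operation is idempotent.
#'
#' @param records tibble with columns `genotype` ("wt"/"mut"), `stage`,
#'   `repeat_id`, `time_h`.
#' @param dome_reference_h reference dome time, default 4.33 h.
#' @return records with normalised `time_h`.
#' @export
normalize_epiboly <- function(records, dome_reference_h = 4.33) {
  stopifnot(all(c("genotype", "stage", "repeat_id", "time_h") %in% names(records)))
  for (rep_id in unique(records$repeat_id)) {
    sel <- records$repeat_id == rep_id
    dome <- records$time_h[sel & records$genotype == "wt" & records$stage == "dome"]
    if (length(dome) != 1L) {
      stop(sprintf("normalize_epiboly: repeat %s has no (unique) wt dome record", rep_id))
    }
    records$time_h[sel] <- records$time_h[sel] - (dome - dome_reference_h)
  }
  records
}

#' Two-way ANOVA of epiboly progress with per-stage post-hoc tests
#'
#' Fixed-effects two-way ANOVA (genotype, stage, interaction) on a balanced
#' genotype x stage x repeat table, with Bonferroni-corrected per-stage
#' wild-type-vs-mutant comparisons at every post-dome stage. The post-hoc
#' t statistics use the pooled ANOVA residual mean square (the standard
#' post-hoc construction after a two-way ANOVA); p values are multiplied
#' by the number of post-dome stages and capped at 1.
#'
#' A fully degenerate table (zero residual and genotype variance) is
#' reported as F = 0, p = 1.
#'
#' @param records tibble with `genotype`, `stage`, `repeat_id`, `time_h`;
#'   the design must be balanced (equal repeats in every genotype x stage cell).
#' @return list: `genotype_F`, `genotype_p`, `per_stage` (named Bonferroni
#'   p values for post-dome stages), `ss` (named sums of squares).
#' @export
epiboly_anova <- function(records) {
  stopifnot(all(c("genotype", "stage", "repeat_id", "time_h") %in% names(records)))
  stages <- intersect(epiboly_stages(), unique(as.character(records$stage)))
  d <- data.frame(
    genotype = factor(records$genotype, levels = c("wt", "mut")),
    stage = factor(as.character(records$stage), levels = stages),
    y = records$time_h
  )
  cell_n <- table(d$genotype, d$stage)
  if (length(unique(as.vector(cell_n))) != 1L || any(cell_n < 2)) {
    stop("epiboly_anova: design must be balanced with >= 2 repeats per cell")
  }
  n_rep <- unname(cell_n[1, 1])
  fit <- stats::aov(y ~ genotype * stage, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  ss <- stats::setNames(tab[["Sum Sq"]], rownames(tab))
  ms_res <- tab["Residuals", "Mean Sq"]
  df_res <- tab["Residuals", "Df"]
  if (!is.finite(ms_res) || ms_res <= .Machine$double.eps * max(1, mean(d$y)^2)) {
    ms_res <- 0
    if (ss[["genotype"]] <= .Machine$double.eps * max(1, mean(d$y)^2)) {
      g_F <- 0; g_p <- 1
    } else {
      g_F <- Inf; g_p <- 0
    }
  } else {
    g_F <- tab["genotype", "F value"]
    g_p <- tab["genotype", "Pr(>F)"]
  }
  post_stages <- setdiff(stages, "dome")
  k <- length(post_stages)
  per_stage <- stats::setNames(rep(NA_real_, k), post_stages)
  for (s in post_stages) {
    ywt <- d$y[d$genotype == "wt" & d$stage == s]
    ymut <- d$y[d$genotype == "mut" & d$stage == s]
    if (ms_res == 0) {
      per_stage[s] <- if (isTRUE(all.equal(mean(ywt), mean(ymut)))) 1 else 0
    } else {
      tstat <- (mean(ymut) - mean(ywt)) / sqrt(ms_res * 2 / n_rep)
      per_stage[s] <- min(1, 2 * stats::pt(-abs(tstat), df_res) * k)
    }
  }
  list(genotype_F = g_F, genotype_p = g_p, per_stage = per_stage, ss = ss)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per sample and gene: `dCT = mean CT(gene) - mean CT(housekeeping)`;
#' `ddCT = dCT(sample) - dCT(calibrator sample)`; `RQ = 2^(-ddCT)`,
#' assuming perfect amplification efficiency (one cycle per doubling;
#' override via `efficiency`, the fold amplification per cycle).
#'
#' @param measurements tibble with columns `sample_id`, `genotype`, `gene`,
#'   `ct1`, `ct2`, `ct3`.
#' @param housekeeping_gene name of the housekeeping gene (must be present
#'   in every sample).
#' @param calibrator_sample `sample_id` of the calibrator.
#' @param efficiency fold amplification per cycle, default 2.
#' @return tibble with one row per sample x target gene: `dct`, `ddct`,
#'   `rq`, `log2_rq`.
#' @export
ddct <- function(measurements, housekeeping_gene, calibrator_sample,
                 efficiency = 2) {
  need <- c("sample_id", "genotype", "gene", "ct1", "ct2", "ct3")
  stopifnot(all(need %in% names(measurements)))
  m <- dplyr::mutate(measurements, ct_mean = (ct1 + ct2 + ct3) / 3)
  hk <- dplyr::filter(m, gene == housekeeping_gene)
  if (!all(unique(m$sample_id) %in% hk$sample_id)) {
    stop(sprintf("housekeeping gene '%s' missing for some samples", housekeeping_gene))
  }
  if (!calibrator_sample %in% m$sample_id) {
    stop(sprintf("calibrator sample '%s' not found", calibrator_sample))
  }
  hk_ct <- stats::setNames(hk$ct_mean, hk$sample_id)
  targets <- dplyr::filter(m, gene != housekeeping_gene)
  targets <- dplyr::mutate(targets, dct = ct_mean - unname(hk_ct[sample_id]))
  cal <- dplyr::filter(targets, sample_id == calibrator_sample)
  cal_dct <- stats::setNames(cal$dct, cal$gene)
  if (!all(unique(targets$gene) %in% names(cal_dct))) {
    stop("calibrator sample lacks some target genes")
  }
  targets <- dplyr::mutate(targets,
    ddct = dct - unname(cal_dct[gene]),
    rq = efficiency^(-ddct),
    log2_rq = log2(rq))
  dplyr::select(targets, sample_id, genotype, gene, dct, ddct, rq, log2_rq)
}

#' Group-level summary of relative quantities
#'
#' Aggregates per-sample RQs from [ddct()] as mean with standard error,
#' per gene and genotype.
#'
#' @param rq_table output of [ddct()].
#' @return tibble: `gene`, `genotype`, `rq` (mean), `log2_rq`, `sem`, `n`.
#' @export
ddct_summary <- function(rq_table) {
  dplyr::summarise(
    dplyr::group_by(rq_table, gene, genotype),
    sem = stats::sd(rq) / sqrt(dplyr::n()),
    rq = mean(rq),
    log2_rq = log2(rq),
    n = dplyr::n(),
    .groups = "drop"
  )[, c("gene", "genotype", "rq", "log2_rq", "sem", "n")]
}
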