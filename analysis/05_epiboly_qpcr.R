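#!/usr/bin/env Rscript
# Tabular study statistics: epiboly staging normalisation + two-way ANOVA
# with Bonferroni post-hoc tests on the simulated staging table, and
# delta-delta-Ct relative quantification of the simulated qPCR CTs.

suppressPackageStartupMessages({
  library(segmix)
  library(jsonlite)
})
data_dir <- "results/data"
out <- "results/tables"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## epiboly: normalise to the 4.33 h dome reference, then test the genotype effect
ep <- read.csv(file.path(data_dir, "epiboly_times.csv"))
norm <- normalize_epiboly(ep)
write.csv(norm, file.path(out, "epiboly_normalized.csv"), row.names = FALSE)
an <- epiboly_anova(norm)
cat(sprintf("two-way ANOVA genotype effect: F = %.1f, p = %.2g\n",
            an$genotype_F, an$genotype_p))
cat("Bonferroni post-hoc p (post-dome stages):\n")
print(round(an$per_stage, 5))
write_json(list(genotype_F = an$genotype_F, genotype_p = an$genotype_p,
                per_stage_bonferroni_p = as.list(an$per_stage)),
           file.path(out, "epiboly_anova.json"), auto_unbox = TRUE, digits = NA)

delay_min <- 60 * mean(norm$time_h[norm$genotype == "mut" & norm$stage != "dome"] -
                         norm$time_h[norm$genotype == "wt" & norm$stage != "dome"])
cat(sprintf("mean post-dome mutant delay: %.1f min\n", delay_min))

## qPCR: delta-delta-Ct against actb1, first wild-type sample as calibrator
qp <- read.csv(file.path(data_dir, "qpcr_ct.csv"))
rq <- ddct(qp, housekeeping_gene = "actb1", calibrator_sample = "wt_1")
write.csv(rq, file.path(out, "qpcr_rq_per_sample.csv"), row.names = FALSE)
summ <- ddct_summary(rq)
write.csv(summ, file.path(out, "qpcr_rq_summary.csv"), row.names = FALSE)
cat("\nrelative quantities (mean +/- SEM by gene and genotype):\n")
print(as.data.frame(summ), digits = 3)

# per-gene wt vs mut comparison of per-sample RQs
for (g in unique(rq$gene)) {
  cmp <- compare_means(rq$rq[rq$gene == g & rq$genotype == "wt"],
                       rq$rq[rq$gene == g & rq$genotype == "mut"])
  cat(sprintf("%s: wt %.2f vs mut %.2f, t = %+.2f, p = %.3g\n",
              g, cmp$mean_a, cmp$mean_b, cmp$t_statistic, cmp$p_value))
}
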