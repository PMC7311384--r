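#!/usr/bin/env Rscript
# Generate the synthetic study datasets: a two-channel aggregate field
# with its ground-truth manifest, a boundary-stained EVL tessellation with
# rosettes and a pHH3 channel, an epiboly staging table, and a qPCR CT
# table. Everything downstream (02-05) runs off these files.

suppressPackageStartupMessages({
  library(segmix)
  library(jsonlite)
})
seed <- 20260101L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## two-channel aggregate field (sorted arrangement, partial mixing)
cfg <- aggregate_field_config(n_clusters = 4, mode = "sorted", mixing_m = 0.5,
                              seed = seed)
fld <- generate_aggregate_field(cfg)
write_field_tiff(fld$image, file.path(out, "aggregate_field.tif"))
manifest <- list(
  seed = cfg$seed, mode = cfg$mode, mixing_m = cfg$mixing_m,
  clusters = lapply(fld$truth$clusters, function(cl) {
    list(id = cl$id, center = cl$center, radius_px = cl$radius_px,
         n_cells = nrow(cl$cells),
         true_centroid_separation = cl$true_centroid_separation)
  }))
write_json(manifest, file.path(out, "aggregate_field_manifest.json"),
           auto_unbox = TRUE, digits = NA)
cat(sprintf("aggregate field: %d clusters, %s mode, m = %.2f -> %s\n",
            cfg$n_clusters, cfg$mode, cfg$mixing_m,
            file.path(out, "aggregate_field.tif")))

## EVL tessellation with injected rosettes and 10% mitotic cells
tcfg <- tessellation_config(n_cells = 100, domain_size_px = 512,
                            rosette_injections = c(5, 6, 7),
                            mitotic_fraction = 0.1, seed = seed + 1L)
ts <- generate_tessellation(tcfg)
write_field_tiff(ts$image, file.path(out, "evl_tessellation.tif"))
write.csv(ts$truth$cells, file.path(out, "evl_truth_cells.csv"), row.names = FALSE)
jx <- ts$truth$junctions
jx$labels <- vapply(jx$labels, paste, "", collapse = ";")
write.csv(jx, file.path(out, "evl_truth_junctions.csv"), row.names = FALSE)
cat(sprintf("EVL tessellation: %d cells, rosettes of arity %s, %d mitotic\n",
            tcfg$n_cells, paste(tcfg$rosette_injections, collapse = "/"),
            sum(ts$truth$cells$is_mitotic)))

## epiboly staging table (25 min mutant delay, 5 min jitter, technical shift)
ep <- generate_epiboly_table(n_repeats = 3, genotype_delay_h = 25 / 60,
                             noise_sd_h = 5 / 60, tech_shift_sd_h = 10 / 60,
                             seed = seed + 2L)
write.csv(ep, file.path(out, "epiboly_times.csv"), row.names = FALSE)
cat(sprintf("epiboly table: %d records, injected delay 25 min\n", nrow(ep)))

## qPCR CT triplicates (appb knocked down 2-fold in mutants)
qp <- generate_qpcr_table(c("actb1", "appb", "appa", "aplp1", "aplp2"),
                          c(actb1 = 0, appb = -1, appa = 0.3, aplp1 = 0, aplp2 = 0.2),
                          ct_sd = 0.15, n_samples = 4, seed = seed + 3L)
write.csv(qp, file.path(out, "qpcr_ct.csv"), row.names = FALSE)
cat(sprintf("qPCR table: %d gene x sample rows in triplicate\n", nrow(qp)))
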