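#!/usr/bin/env Rscript
# Generate the synthetic study inputs: two patient cohorts (miRNA
# expression + clinical outcomes), gene expression with planted targets,
# gene sets, a DWI phantom, a histology scene, and xenograft growth
# curves. Everything derives from one seed; re-running reproduces the
# files byte for byte.

library(radiomir)

seed <- 1L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)

for (cohort in names(cfg$n_patients)) {
  co <- gen_cohort(cfg, cohort)
  write_expression_tsv(co$mirna,
                       file.path(outdir, paste0("mirna_", cohort, ".tsv")))
  write.csv(co$clinical,
            file.path(outdir, paste0("clinical_", cohort, ".csv")),
            row.names = FALSE)
  g <- gen_gene_expression(cfg, co$mirna, cohort)
  write_expression_tsv(g$genes,
                       file.path(outdir, paste0("genes_", cohort, ".tsv")))
  if (cohort == names(cfg$n_patients)[1]) {
    write.csv(g$truth, file.path(outdir, "true_targets.csv"),
              row.names = FALSE)
    sets <- gen_gene_sets(rownames(g$genes), true_targets = g$truth$gene,
                          seed = seed)
    write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  }
  cat(sprintf("cohort %-12s: %3d patients, %d/%d recurrences\n", cohort,
              ncol(co$mirna), sum(!is.na(co$clinical$recurrence_site)),
              ncol(co$mirna)))
}

dwi <- gen_dwi(cfg)
write_dwi(dwi$series, file.path(outdir, "dwi_phantom.tiff"))
cat(sprintf("DWI phantom: %d ROI voxels, true necrotic fraction %.3f\n",
            sum(dwi$series$roi), dwi$truth$necrotic_fraction))

gr <- gen_growth(cfg)
write.csv(gr$curves, file.path(outdir, "growth_curves.csv"),
          row.names = FALSE)
cat(sprintf("growth curves: %d tumors, planted delays %s days\n",
            length(unique(gr$curves$tumor)),
            paste(cfg$delay_days, collapse = "/")))
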