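#!/usr/bin/env Rscript
# Dual-cohort miRNA-target anticorrelation filtering, regulatory-network
# construction, and over-representation enrichment under both background
# modes (global gene universe and the candidate-target list).

library(radiomir)

seed <- 1L
outdir <- "results"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- sim_config(seed = seed)

cn <- names(cfg$n_patients)
c1 <- gen_cohort(cfg, cn[1]); c2 <- gen_cohort(cfg, cn[2])
g1 <- gen_gene_expression(cfg, c1$mirna, cn[1])
g2 <- gen_gene_expression(cfg, c2$mirna, cn[2])

t1 <- correlate_targets(c1$mirna, g1$genes, g1$candidate_map, cn[1])
t2 <- correlate_targets(c2$mirna, g2$genes, g2$candidate_map, cn[2])
filt <- filter_targets(t1, t2)
net <- build_network(filt)
st <- network_stats(net)

cat(sprintf("potential targets: %d of %d candidates (%d planted; recall %.0f%%)\n",
            length(filt$potential_targets), cfg$n_genes,
            nrow(g1$truth),
            100 * mean(g1$truth$gene %in% filt$potential_targets)))
cat(sprintf("network: %d genes, %d edges; %d (%d%%) genes interact with >1 miRNA\n",
            st$n_genes, nrow(net$edges), st$n_multi,
            round(100 * st$multi_fraction)))
cat("targets per miRNA:", paste(names(st$per_mirna), st$per_mirna,
                                sep = "=", collapse = ", "), "\n")

write.csv(filt$pairs, file.path(outdir, "correlation_pairs.csv"),
          row.names = FALSE)
write.csv(data.frame(gene = filt$potential_targets),
          file.path(outdir, "potential_targets.csv"), row.names = FALSE)
write.csv(net$edges, file.path(outdir, "network_edges.csv"),
          row.names = FALSE)
write_sif(net, file.path(outdir, "network.sif"))

sets <- gen_gene_sets(rownames(g1$genes), true_targets = g1$truth$gene,
                      seed = seed)
for (mode in c("global_universe", "candidate_list")) {
  enr <- enrich_all(filt$potential_targets, sets,
                    background = rownames(g1$genes),
                    background_mode = mode,
                    candidate_list = unique(unlist(g1$candidate_map)))
  top <- enr[1, ]
  cat(sprintf("enrichment (%s): top set %s, q = %.3g, fold = %.1f\n",
              mode, top$set, top$q, top$fold_enrichment))
  write.csv(enr, file.path(outdir, paste0("enrichment_", mode, ".csv")),
            row.names = FALSE)
}
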