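#' Read and write expression matrices as TSV
#'
#' Features in rows, samples in columns, with a header row of sample ids
#' and the feature id in the first column.
#'
#' @param path file path.
#' @return `read_expression_tsv`: numeric matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  d <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(d)
}

#' @rdname read_expression_tsv
#' @param m numeric matrix with dimnames.
#' @export
write_expression_tsv <- function(m, path) {
  d <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Format a Cox result table for reporting
#'
#' Renders P, HR and 95% CI columns in the conventional clinical-table
#' layout.
#'
#' @param cox data frame from [cox_fit()].
#' @return data frame with columns `covariate`, `P`, `HR`, `CI95`.
#' @export
format_cox_table <- function(cox) {
  if (is.null(cox) || !nrow(cox)) {
    return(data.frame(covariate = character(), P = character(),
                      HR = character(), CI95 = character()))
  }
  data.frame(covariate = cox$covariate,
             P = formatC(cox$p, format = "g", digits = 2),
             HR = formatC(cox$HR, format = "f", digits = 2),
             CI95 = sprintf("%.2f-%.2f", cox$ci_low, cox$ci_high),
             stringsAsFactors = FALSE)
}

#' Run the full synthetic analysis pipeline
#'
#' Generates the two synthetic cohorts and every auxiliary data set, then
#' runs the complete analysis: per-cohort miRNA scores, site-specific and
#' progression-free survival endpoints with univariate Cox and
#' optimal-cutoff stratification, dual-cohort target anticorrelation
#' filtering with network statistics, over-representation enrichment
#' under both background modes, ADC fitting with necrosis classification,
#' histology quantification, and xenograft growth-delay metrics. All
#' randomness derives from `config$seed`; equal configs give identical
#' results and identical output files.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, result tables are
#'   written as CSV/TSV/GMT/SIF files.
#' @param n_perm permutations for the cutoff-scan correction.
#' @return Nested list of results per stage (see names of the return
#'   value).
#' @export
run_synthetic_pipeline <- function(config = sim_config(), outdir = NULL,
                                   n_perm = 200L) {
  cohorts <- names(config$n_patients)
  coh <- lapply(cohorts, function(cn) gen_cohort(config, cn))
  names(coh) <- cohorts
  scores <- lapply(coh, function(x) {
    compute_score(x$mirna, members = rownames(x$mirna))
  })
  # merged cohort: scores centered within cohort, then pooled
  clinical <- do.call(rbind, lapply(coh, `[[`, "clinical"))
  score_all <- unlist(scores, use.names = FALSE)
  endpoints <- c("pfs", "central_control", "lateral_control",
                 "distal_control")
  surv_res <- lapply(endpoints, function(ep) {
    e <- build_endpoint(clinical, ep, horizon = config$censor_months)
    cox <- cox_fit(e, data.frame(score = score_all))
    scan <- optimal_cutoff_scan(score_all, e, correction = "permutation",
                                n_perm = n_perm,
                                seed = stage_seed(config, "cohort", 99L))
    km <- km_estimate(e, score_all <= scan$cutoff)
    list(endpoint = ep, table = e, cox = cox, scan = scan, km = km,
         lml = log_minus_log(km))
  })
  names(surv_res) <- endpoints
  gene1 <- gen_gene_expression(config, coh[[1L]]$mirna, cohorts[1L])
  gene2 <- gen_gene_expression(config, coh[[2L]]$mirna, cohorts[2L])
  c1 <- correlate_targets(coh[[1L]]$mirna, gene1$genes,
                          gene1$candidate_map, cohorts[1L])
  c2 <- correlate_targets(coh[[2L]]$mirna, gene2$genes,
                          gene2$candidate_map, cohorts[2L])
  filt <- filter_targets(c1, c2)
  net <- build_network(filt)
  stats_net <- network_stats(net)
  sets <- gen_gene_sets(rownames(gene1$genes),
                        true_targets = gene1$truth$gene,
                        seed = stage_seed(config, "sets"))
  enr <- list(
    global = enrich_all(filt$potential_targets, sets,
                        background = rownames(gene1$genes),
                        background_mode = "global_universe"),
    candidates = enrich_all(filt$potential_targets, sets,
                            background = rownames(gene1$genes),
                            background_mode = "candidate_list",
                            candidate_list = unique(unlist(
                              gene1$candidate_map))))
  dwi <- gen_dwi(config)
  adc_map <- fit_adc(dwi$series)
  necro <- classify_necrosis(adc_map)
  adc <- list(map = adc_map, necrosis = necro,
              median_adc = median_adc(adc_map), truth = dwi$truth)
  hist_scene <- gen_histology(config)
  dec <- color_deconvolve(hist_scene$images$ki67)
  metrics <- histo_metrics(hist_scene$masks$roi,
                           hist_scene$masks$necrosis,
                           hist_scene$masks$hypoxia,
                           hist_scene$masks$gfp,
                           dec$dab, dab_threshold = 0.5)
  histo <- list(metrics = metrics, truth = hist_scene$truth)
  gr <- gen_growth(config)
  t15 <- do.call(rbind, lapply(split(gr$curves, gr$curves$tumor),
                               function(d) {
    tt <- time_to_factor(d$day, d$volume_mm3)
    data.frame(tumor = d$tumor[1L], line = d$line[1L],
               irradiated = d$irradiated[1L], t_days = tt$t_days,
               censored = tt$censored, stringsAsFactors = FALSE)
  }))
  rownames(t15) <- NULL
  td <- vapply(split(gr$curves[!gr$curves$irradiated, ],
                     gr$curves$tumor[!gr$curves$irradiated]),
               function(d) doubling_time(d$day, d$volume_mm3)$td_days,
               numeric(1L))
  delay <- growth_delay(t15)
  response <- list(t15 = t15, td_days = td, delay = delay,
                   truth = gr$truth)
  res <- list(config = config, cohorts = coh, scores = scores,
              survival = surv_res,
              network = list(correlations = list(c1 = c1, c2 = c2),
                             filtered = filt, net = net,
                             stats = stats_net,
                             truth = gene1$truth),
              enrichment = enr, adc = adc, histology = histo,
              response = response)
  if (!is.null(outdir)) export_pipeline(res, outdir, sets = sets)
  res
}

#' Export pipeline results to disk
#'
#' Writes the main result tables as plain-text files: per-cohort scores
#' and miRNA matrices (TSV), clinical and endpoint tables, Cox and cutoff
#' tables, the filtered pair table, network edges (CSV + SIF + GraphML),
#' enrichment tables, ADC/histology/response summaries, and the gene-set
#' collection (GMT).
#'
#' @param res result of [run_synthetic_pipeline()].
#' @param outdir output directory (created if needed).
#' @param sets optional gene-set collection to write as GMT.
#' @return `outdir`, invisibly.
#' @export
export_pipeline <- function(res, outdir, sets = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) {
    utils::write.csv(d, file.path(outdir, name), row.names = FALSE)
  }
  for (cn in names(res$cohorts)) {
    write_expression_tsv(res$cohorts[[cn]]$mirna,
                         file.path(outdir, paste0("mirna_", cn, ".tsv")))
    wcsv(res$cohorts[[cn]]$clinical, paste0("clinical_", cn, ".csv"))
    wcsv(data.frame(patient_id = names(res$scores[[cn]]),
                    score = unname(res$scores[[cn]])),
         paste0("score_", cn, ".csv"))
  }
  cox_rows <- do.call(rbind, lapply(res$survival, function(s) {
    cbind(endpoint = s$endpoint, s$cox)
  }))
  wcsv(cox_rows, "cox_univariate_score.csv")
  scan_rows <- do.call(rbind, lapply(res$survival, function(s) {
    data.frame(endpoint = s$endpoint, cutoff = s$scan$cutoff,
               fraction_low = s$scan$fraction_low, chi2 = s$scan$chi2,
               p_uncorrected = s$scan$p_uncorrected,
               p_corrected = s$scan$p_corrected)
  }))
  wcsv(scan_rows, "cutoff_scan.csv")
  wcsv(res$network$filtered$pairs, "correlation_pairs.csv")
  wcsv(data.frame(gene = res$network$filtered$potential_targets),
       "potential_targets.csv")
  wcsv(res$network$net$edges, "network_edges.csv")
  write_sif(res$network$net, file.path(outdir, "network.sif"))
  if (igraph::gorder(res$network$net$graph) > 0L) {
    igraph::write_graph(res$network$net$graph,
                        file.path(outdir, "network.graphml"),
                        format = "graphml")
  }
  wcsv(res$enrichment$global, "enrichment_global_background.csv")
  wcsv(res$enrichment$candidates, "enrichment_candidate_background.csv")
  if (!is.null(sets)) write_gmt(sets, file.path(outdir, "gene_sets.gmt"))
  wcsv(data.frame(median_adc = res$adc$median_adc,
                  necrotic_fraction = res$adc$necrosis$necrotic_fraction,
                  true_necrotic_fraction = res$adc$truth$necrotic_fraction),
       "adc_summary.csv")
  wcsv(res$histology$metrics, "histology_metrics.csv")
  wcsv(res$response$t15, "t15x.csv")
  wcsv(data.frame(line = names(res$response$delay$tgd),
                  tgd_days = unname(res$response$delay$tgd)),
       "growth_delay.csv")
  wcsv(data.frame(ef = res$response$delay$ef,
                  t_test_p = res$response$delay$t_test_p),
       "enhancement_factor.csv")
  invisible(outdir)
}
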