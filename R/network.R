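#' Spearman correlation of candidate targets with miRNA expression
#'
#' For every (miRNA, candidate gene) pair in the candidate map, computes
#' the Spearman rank correlation between the gene's and the miRNA's
#' expression across the samples of one cohort, with a two-sided p-value
#' from the t approximation. FDR q-values (Benjamini-Hochberg) are computed
#' per miRNA within the cohort, i.e. the adjustment family is that miRNA's
#' candidate list — matching per-miRNA candidate sets from target
#' databases. Pairs with a constant gene or miRNA vector have undefined
#' correlation; they are flagged (`rho = NA`) and excluded from the FDR
#' family rather than assigned p = 1.
#'
#' @param mirna expression matrix, miRNAs x samples.
#' @param genes expression matrix, genes x samples (same samples, same
#'   order).
#' @param candidates named list: miRNA id -> character vector of candidate
#'   gene ids. Candidate genes absent from `genes` are dropped and
#'   reported in the `unmatched` attribute.
#' @param cohort label stored in the output's `cohort` column.
#' @param fdr_family "per_mirna" (default) or "global".
#' @return data frame with columns `mirna`, `gene`, `cohort`, `rho`, `p`,
#'   `q`.
#' @export
correlate_targets <- function(mirna, genes, candidates, cohort,
                              fdr_family = c("per_mirna", "global")) {
  fdr_family <- match.arg(fdr_family)
  mirna <- as.matrix(mirna); genes <- as.matrix(genes)
  if (ncol(mirna) != ncol(genes) ||
      !identical(colnames(mirna), colnames(genes))) {
    stop("sample ids of the two matrices must be identical")
  }
  n <- ncol(mirna)
  if (n < 10L) stop("need at least 10 samples")
  unmatched <- lapply(candidates, setdiff, y = rownames(genes))
  candidates <- lapply(candidates, intersect, y = rownames(genes))
  # rank rows once; Pearson on average ranks = Spearman with ties handled
  rk_m <- t(apply(mirna, 1L, rank))
  rk_g <- t(apply(genes, 1L, rank))
  const_m <- apply(mirna, 1L, function(v) length(unique(v)) < 2L)
  const_g <- apply(genes, 1L, function(v) length(unique(v)) < 2L)
  tabs <- lapply(names(candidates), function(mi) {
    gs <- candidates[[mi]]
    if (!length(gs)) return(NULL)
    if (!mi %in% rownames(mirna)) stop("miRNA not in matrix: ", mi)
    rho <- suppressWarnings(
      drop(stats::cor(rk_m[mi, ], t(rk_g[gs, , drop = FALSE]))))
    rho[const_m[mi] | const_g[gs]] <- NA_real_
    tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p[abs(rho) >= 1 & !is.na(rho)] <- 0
    data.frame(mirna = mi, gene = gs, cohort = cohort, rho = rho, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out$q <- NA_real_
  if (fdr_family == "per_mirna") {
    for (mi in unique(out$mirna)) {
      idx <- which(out$mirna == mi & !is.na(out$p))
      out$q[idx] <- bh_adjust(out$p[idx])
    }
  } else {
    idx <- which(!is.na(out$p))
    out$q[idx] <- bh_adjust(out$p[idx])
  }
  attr(out, "unmatched") <- unmatched[vapply(unmatched, length,
                                             integer(1L)) > 0L]
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' q for the i-th ordered p is min over j >= i of p_(j) * m / j, capped at
#' one. Thin wrapper around [stats::p.adjust()] so the whole pipeline uses
#' a single FDR implementation.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Dual-cohort anticorrelation filter for potential targets
#'
#' A candidate (miRNA, gene) pair is a potential regulatory interaction
#' when the Spearman correlation is negative in both cohorts, nominally
#' significant (p < 0.05) in both, and FDR-significant (q < 0.1) in at
#' least one. A gene is a potential target when at least one of its miRNA
#' pairs passes. Pairs present in only one cohort are excluded and
#' reported.
#'
#' @param c1,c2 correlation tables from [correlate_targets()] for the two
#'   cohorts.
#' @param p_threshold nominal per-cohort threshold (default 0.05).
#' @param q_threshold FDR threshold required in at least one cohort
#'   (default 0.1).
#' @param q_rule "any" (default: q < threshold in at least one cohort) or
#'   "both".
#' @return List with `pairs` (merged table with per-cohort rho/p/q and a
#'   `pass` flag), `potential_targets` (character vector of gene ids), and
#'   `unpaired` (rows present in a single cohort only).
#' @export
filter_targets <- function(c1, c2, p_threshold = 0.05, q_threshold = 0.1,
                           q_rule = c("any", "both")) {
  q_rule <- match.arg(q_rule)
  m <- merge(c1, c2, by = c("mirna", "gene"), suffixes = c("_1", "_2"))
  key <- function(d) paste(d$mirna, d$gene)
  unpaired <- rbind(c1[!(key(c1) %in% key(m)), c("mirna", "gene")],
                    c2[!(key(c2) %in% key(m)), c("mirna", "gene")])
  ok_q <- if (q_rule == "any") {
    (!is.na(m$q_1) & m$q_1 < q_threshold) |
      (!is.na(m$q_2) & m$q_2 < q_threshold)
  } else {
    !is.na(m$q_1) & m$q_1 < q_threshold &
      !is.na(m$q_2) & m$q_2 < q_threshold
  }
  m$pass <- !is.na(m$rho_1) & !is.na(m$rho_2) &
    m$rho_1 < 0 & m$rho_2 < 0 &
    m$p_1 < p_threshold & m$p_2 < p_threshold & ok_q
  list(pairs = m,
       potential_targets = sort(unique(m$gene[m$pass])),
       unpaired = unpaired)
}

#' Build the miRNA-target regulatory network
#'
#' Bipartite graph with the miRNAs and their potential target genes as
#' nodes. An edge is included for every pair that passed
#' [filter_targets()] and has q below the threshold in at least one cohort
#' (the same rule as the filter, so by default every passing pair is an
#' edge).
#'
#' @param filtered result of [filter_targets()].
#' @param q_threshold FDR threshold for edge inclusion (default 0.1).
#' @return List with `edges` (data frame: mirna, gene, rho/q per cohort)
#'   and `graph` (a bipartite [igraph::graph] with vertex attribute
#'   `type`, TRUE for genes).
#' @export
build_network <- function(filtered, q_threshold = 0.1) {
  m <- filtered$pairs
  keep <- m$pass &
    ((!is.na(m$q_1) & m$q_1 < q_threshold) |
       (!is.na(m$q_2) & m$q_2 < q_threshold))
  edges <- m[keep, c("mirna", "gene", "rho_1", "q_1", "rho_2", "q_2")]
  rownames(edges) <- NULL
  g <- if (nrow(edges)) {
    gr <- igraph::graph_from_data_frame(
      edges[, c("mirna", "gene")], directed = FALSE)
    igraph::V(gr)$type <- igraph::V(gr)$name %in% edges$gene
    gr
  } else {
    igraph::make_empty_graph(directed = FALSE)
  }
  list(edges = edges, graph = g)
}

#' Degree statistics of the target network
#'
#' Per-miRNA potential-target counts and the number and fraction of genes
#' interacting with more than one miRNA.
#'
#' @param net result of [build_network()].
#' @return List with `per_mirna` (named target counts), `n_genes`,
#'   `n_multi`, `multi_fraction`.
#' @export
network_stats <- function(net) {
  e <- net$edges
  if (!nrow(e)) {
    return(list(per_mirna = integer(), n_genes = 0L, n_multi = 0L,
                multi_fraction = NA_real_))
  }
  per_mirna <- vapply(split(e$gene, e$mirna), function(g) {
    length(unique(g))
  }, integer(1L))
  gene_deg <- vapply(split(e$mirna, e$gene), function(m) {
    length(unique(m))
  }, integer(1L))
  list(per_mirna = per_mirna,
       n_genes = length(gene_deg),
       n_multi = sum(gene_deg > 1L),
       multi_fraction = mean(gene_deg > 1L))
}

#' Export a network as a SIF file
#'
#' Simple-interaction-format export (miRNA \\t represses \\t gene) for use
#' in Cytoscape-style viewers.
#'
#' @param net result of [build_network()].
#' @param path output file path.
#' @export
write_sif <- function(net, path) {
  e <- net$edges
  writeLines(if (nrow(e)) {
    paste(e$mirna, "represses", e$gene, sep = "\t")
  } else character(), path)
  invisible(path)
}
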