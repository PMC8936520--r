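mk_expr <- function(mat, ids, samples) {
  matrix(mat, nrow = length(ids), dimnames = list(ids, samples))
}

test_that("Spearman correlation hits the monotone extremes and flags constants", {
  samples <- paste0("s", 1:12)
  mir <- mk_expr(1:12, "miR-a", samples)
  genes <- rbind(g_dec = 12:1, g_inc = (1:12)^2, g_const = rep(5, 12))
  colnames(genes) <- samples
  cand <- list("miR-a" = rownames(genes))
  ct <- correlate_targets(mir, genes, cand, "c1")
  expect_equal(ct$rho[ct$gene == "g_dec"], -1)
  expect_equal(ct$rho[ct$gene == "g_inc"], 1)
  expect_true(is.na(ct$rho[ct$gene == "g_const"]))
  expect_true(is.na(ct$q[ct$gene == "g_const"]))  # outside the FDR family
  expect_error(correlate_targets(mir[, 1:5, drop = FALSE],
                                 genes[, 1:6], cand, "c1"),
               "identical")
})

test_that("null correlations have calibrated p-values", {
  set.seed(17)
  n <- 90
  samples <- paste0("s", 1:n)
  mir <- mk_expr(rnorm(n), "miR-a", samples)
  genes <- matrix(rnorm(2000 * n), 2000, n,
                  dimnames = list(sprintf("g%04d", 1:2000), samples))
  ct <- correlate_targets(mir, genes, list("miR-a" = rownames(genes)),
                          "c1")
  expect_gt(mean(ct$p < 0.05), 0.03)
  expect_lt(mean(ct$p < 0.05), 0.07)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("dual-cohort filter applies the inclusion rule literally", {
  row <- function(mirna, gene, cohort, rho, p, q) {
    data.frame(mirna = mirna, gene = gene, cohort = cohort,
               rho = rho, p = p, q = q, stringsAsFactors = FALSE)
  }
  c1 <- rbind(row("m", "keep", "a", -0.3, 0.01, 0.05),
              row("m", "one_cohort_p", "a", -0.3, 0.01, 0.2),
              row("m", "positive", "a", 0.4, 0.001, 0.01),
              row("m", "no_q", "a", -0.3, 0.04, 0.2),
              row("m", "only_in_1", "a", -0.5, 0.001, 0.01))
  c2 <- rbind(row("m", "keep", "b", -0.2, 0.02, 0.3),
              row("m", "one_cohort_p", "b", -0.1, 0.2, 0.6),
              row("m", "positive", "b", 0.5, 0.001, 0.01),
              row("m", "no_q", "b", -0.3, 0.04, 0.3))
  f <- filter_targets(c1, c2)
  expect_equal(f$potential_targets, "keep")
  expect_false(f$pairs$pass[f$pairs$gene == "one_cohort_p"])
  expect_false(f$pairs$pass[f$pairs$gene == "positive"])
  expect_false(f$pairs$pass[f$pairs$gene == "no_q"])  # q >= 0.1 everywhere
  expect_equal(f$unpaired$gene, "only_in_1")
  # monotone in thresholds: loosening never removes a pair
  f_loose <- filter_targets(c1, c2, p_threshold = 0.10, q_threshold = 0.5)
  expect_true(all(f$pairs$gene[f$pairs$pass] %in%
                    f_loose$pairs$gene[f_loose$pairs$pass]))
})

test_that("network construction and degree statistics count correctly", {
  empty <- build_network(list(pairs = data.frame(
    mirna = character(), gene = character(), rho_1 = numeric(),
    p_1 = numeric(), q_1 = numeric(), rho_2 = numeric(),
    p_2 = numeric(), q_2 = numeric(), pass = logical())))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(network_stats(empty)$n_genes, 0)
  # 2 miRNAs sharing one gene plus one unique gene each
  pairs <- data.frame(
    mirna = c("m1", "m2", "m1", "m2"),
    gene = c("shared", "shared", "u1", "u2"),
    rho_1 = -0.5, p_1 = 0.001, q_1 = 0.01,
    rho_2 = -0.5, p_2 = 0.001, q_2 = 0.01, pass = TRUE)
  net <- build_network(list(pairs = pairs))
  st <- network_stats(net)
  expect_equal(nrow(net$edges), 4)
  expect_equal(st$n_genes, 3)
  expect_equal(st$n_multi, 1)
  expect_equal(st$multi_fraction, 1 / 3)
  expect_equal(unname(st$per_mirna[c("m1", "m2")]), c(2L, 2L))
  # star: one miRNA, five genes -> no multi-miRNA genes
  star <- pairs[rep(1, 5), ]
  star$gene <- paste0("g", 1:5)
  expect_equal(network_stats(build_network(list(pairs = star)))$multi_fraction, 0)
  # complete bipartite 2 x 3 -> every gene is multi
  cb <- expand.grid(mirna = c("m1", "m2"), gene = c("g1", "g2", "g3"),
                    stringsAsFactors = FALSE)
  cb <- cbind(cb, rho_1 = -0.4, p_1 = 0.01, q_1 = 0.01,
              rho_2 = -0.4, p_2 = 0.01, q_2 = 0.01, pass = TRUE)
  expect_equal(network_stats(build_network(list(pairs = cb)))$multi_fraction, 1)
})

test_that("degree statistics match exhaustive enumeration on random graphs", {
  set.seed(21)
  for (i in 1:5) {
    pairs <- unique(data.frame(
      mirna = sample(paste0("m", 1:4), 30, replace = TRUE),
      gene = sample(paste0("g", 1:12), 30, replace = TRUE),
      stringsAsFactors = FALSE))
    pairs <- cbind(pairs, rho_1 = -0.4, p_1 = 0.01, q_1 = 0.01,
                   rho_2 = -0.4, p_2 = 0.01, q_2 = 0.01, pass = TRUE)
    st <- network_stats(build_network(list(pairs = pairs)))
    deg <- table(pairs$gene)
    expect_equal(st$n_genes, length(deg))
    expect_equal(st$n_multi, sum(deg > 1))
    expect_equal(unname(st$per_mirna[sort(unique(pairs$mirna))]),
                 unname(as.integer(table(pairs$mirna))))
  }
})

test_that("planted targets are recovered with high recall and controlled FDR", {
  cfg <- sim_config(seed = 77)
  c1 <- gen_cohort(cfg, "explorative")
  c2 <- gen_cohort(cfg, "validation")
  g1 <- gen_gene_expression(cfg, c1$mirna, "explorative")
  g2 <- gen_gene_expression(cfg, c2$mirna, "validation")
  t1 <- correlate_targets(c1$mirna, g1$genes, g1$candidate_map, "e")
  t2 <- correlate_targets(c2$mirna, g2$genes, g2$candidate_map, "v")
  f <- filter_targets(t1, t2)
  truth <- g1$truth$gene
  recall <- mean(truth %in% f$potential_targets)
  false_frac <- mean(!(f$potential_targets %in% truth))
  expect_gte(recall, 0.9)
  expect_lte(false_frac, 0.1)
})

test_that("SIF export writes one interaction per edge", {
  pairs <- data.frame(mirna = c("m1", "m2"), gene = c("g1", "g2"),
                      rho_1 = -0.4, p_1 = 0.01, q_1 = 0.01,
                      rho_2 = -0.4, p_2 = 0.01, q_2 = 0.01, pass = TRUE)
  net <- build_network(list(pairs = pairs))
  path <- tempfile(fileext = ".sif")
  write_sif(net, path)
  expect_equal(readLines(path),
               c("m1\trepresses\tg1", "m2\trepresses\tg2"))
})
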