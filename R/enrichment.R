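#' One-sided hypergeometric over-representation test
#'
#' Tests whether a gene list overlaps a gene set more than expected by
#' chance within a finite background (gene universe). The p-value is the
#' upper hypergeometric tail P(overlap >= observed). With `ease = TRUE`
#' the observed overlap is reduced by one before testing (the conservative
#' EASE variant used by the DAVID tool).
#'
#' @param gene_list character vector, the query list (must lie within the
#'   background).
#' @param gene_set character vector, the annotation set.
#' @param background character vector, the gene universe.
#' @param ease logical; use the overlap-minus-one variant.
#' @return One-row data frame: `overlap`, `set_size`, `list_size`,
#'   `background_size`, `fold_enrichment`, `p`.
#' @export
ora_test <- function(gene_list, gene_set, background, ease = FALSE) {
  background <- unique(background)
  gene_list <- unique(gene_list)
  if (!length(gene_list)) stop("empty gene list")
  if (!length(background)) stop("empty background")
  if (!all(gene_list %in% background)) {
    stop("gene list must be a subset of the background")
  }
  set_in_bg <- unique(intersect(gene_set, background))
  if (!length(set_in_bg)) stop("gene set does not intersect the background")
  k <- length(intersect(gene_list, set_in_bg))
  K <- length(set_in_bg)
  n <- length(gene_list)
  N <- length(background)
  k_test <- if (ease) max(k - 1L, 0L) else k
  p <- if (k_test == 0L) 1 else {
    stats::phyper(k_test - 1L, K, N - K, n, lower.tail = FALSE)
  }
  data.frame(overlap = k, set_size = K, list_size = n,
             background_size = N,
             fold_enrichment = (k / n) / (K / N),
             p = p)
}

#' Over-representation analysis against a gene-set collection
#'
#' Runs [ora_test()] for every set in the collection and adjusts p-values
#' by Benjamini-Hochberg within each category (process, component,
#' function, pathway, ...), mirroring per-category annotation-tool output.
#' Two background modes reproduce the study design: the global gene
#' universe, or the full candidate-target list from which the query was
#' filtered.
#'
#' @param gene_list character vector of query genes.
#' @param collection named list of character vectors (gene sets); an
#'   optional `category` attribute (named character vector, set ->
#'   category) defines the BH families, otherwise all sets form one
#'   family.
#' @param background character vector; the gene universe for
#'   `background_mode = "global_universe"`.
#' @param background_mode "global_universe" or "candidate_list".
#' @param candidate_list character vector used as background when
#'   `background_mode = "candidate_list"`.
#' @param q_sig significance threshold on q (default 0.01).
#' @param ease passed to [ora_test()].
#' @return data frame with one row per set: `set`, `category`, the
#'   [ora_test()] columns, `q`, `significant`. Genes of the query absent
#'   from the chosen background are dropped; their ids are in the
#'   `dropped` attribute.
#' @export
enrich_all <- function(gene_list, collection, background,
                       background_mode = c("global_universe",
                                           "candidate_list"),
                       candidate_list = NULL, q_sig = 0.01, ease = FALSE) {
  background_mode <- match.arg(background_mode)
  bg <- switch(background_mode,
               global_universe = background,
               candidate_list = {
                 if (is.null(candidate_list)) {
                   stop("candidate_list background requested but not given")
                 }
                 candidate_list
               })
  bg <- unique(bg)
  dropped <- setdiff(gene_list, bg)
  gene_list <- intersect(gene_list, bg)
  if (!length(gene_list)) stop("gene list disjoint from the background")
  cats <- attr(collection, "category")
  if (is.null(cats)) {
    cats <- stats::setNames(rep("set", length(collection)),
                            names(collection))
  }
  rows <- lapply(names(collection), function(nm) {
    set_in_bg <- intersect(collection[[nm]], bg)
    if (!length(set_in_bg)) return(NULL)
    cbind(data.frame(set = nm, category = unname(cats[nm]),
                     stringsAsFactors = FALSE),
          ora_test(gene_list, set_in_bg, bg, ease = ease))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), category = character(),
                      overlap = integer(), set_size = integer(),
                      list_size = integer(), background_size = integer(),
                      fold_enrichment = numeric(), p = numeric(),
                      q = numeric(), significant = logical())
    attr(out, "note") <- "gene list disjoint from all sets"
    return(out)
  }
  out$q <- NA_real_
  for (cat in unique(out$category)) {
    idx <- out$category == cat
    out$q[idx] <- bh_adjust(out$p[idx])
  }
  out$significant <- out$q < q_sig
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Read and write GMT gene-set files
#'
#' GMT is the tab-separated gene-set format: one set per line, with the
#' set name, a description, then the member gene ids.
#'
#' @param path file path.
#' @return `read_gmt`: named list of character vectors with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) x[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1L), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1L), 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param description optional per-set description strings.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) {
    description <- attr(sets, "description")
  }
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
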