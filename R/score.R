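#' miR-200a/b/-429 score members
#'
#' The five mature members of the chromosome-1 miR-200 cluster used in the
#' sequencing-based score, and the three-member subset used for RT-qPCR
#' cohorts where only the dominant strands were profiled.
#'
#' @format Character vectors of mature miRNA names.
#' @export
MIR200_MEMBERS <- c("hsa-miR-200a-5p", "hsa-miR-200a-3p",
                    "hsa-miR-200b-5p", "hsa-miR-200b-3p", "hsa-miR-429")

#' @rdname MIR200_MEMBERS
#' @export
MIR200_MEMBERS_QPCR <- c("hsa-miR-200a-3p", "hsa-miR-200b-3p", "hsa-miR-429")

#' Normalize miRNA read counts to log2 reads-per-million
#'
#' Counts are scaled per sample to reads per million annotated mature
#' miRNAs and log2-transformed. A pseudocount is added inside the log so
#' zero counts map to 0 on the log2 scale.
#'
#' @param counts numeric matrix of non-negative counts, features x samples,
#'   with row and column names.
#' @param pseudocount value added to the RPM before log2; default 1.
#' @return An expression matrix (same dimnames) with attribute
#'   `scale = "log2_rpm"`.
#' @examples
#' m <- matrix(c(100, 999900), 2, 1,
#'             dimnames = list(c("a", "b"), "s1"))
#' normalize_rpm(m)["a", ]  # log2(101)
#' @export
normalize_rpm <- function(counts, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    bad <- colnames(counts)[totals <= 0]
    stop("zero-total sample(s): ", paste(bad, collapse = ", "))
  }
  rpm <- sweep(counts, 2, totals, "/") * 1e6
  out <- log2(rpm + pseudocount)
  attr(out, "scale") <- "log2_rpm"
  out
}

#' Median-center expression rows
#'
#' Subtracts the per-feature median across samples, so each feature row has
#' median zero within the cohort. Centering is always per cohort: centered
#' values are not comparable across cohorts, and pooled analyses must
#' re-center within each cohort before merging.
#'
#' @param m numeric expression matrix, features x samples.
#' @return Matrix of the same shape with row medians zero.
#' @export
median_center <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 1L) stop("need at least one sample")
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  if (any(is.na(med))) stop("feature(s) with no non-missing values")
  sweep(m, 1L, med, "-")
}

#' Compute the miR-200a/b/-429 score
#'
#' Per-sample arithmetic mean of the median-centered, log2-scale expression
#' of the member miRNAs. A low score means low expression of the cluster.
#'
#' @param m expression matrix on a log2-like scale, features x samples.
#' @param members feature names to average; default the five-member set.
#' @param center if TRUE (default) rows are median-centered first; set FALSE
#'   when `m` is already centered.
#' @param allow_subset if TRUE, members missing from the matrix are dropped
#'   (at least one must remain); otherwise missing members are an error.
#' @return Named numeric vector of scores (one per sample) with attribute
#'   `members` recording the rows actually used.
#' @export
compute_score <- function(m, members = MIR200_MEMBERS, center = TRUE,
                          allow_subset = FALSE) {
  m <- as.matrix(m)
  if (length(members) == 0L) stop("member list is empty")
  present <- members %in% rownames(m)
  if (!all(present)) {
    if (!allow_subset) {
      stop("member(s) not in matrix: ",
           paste(members[!present], collapse = ", "))
    }
    members <- members[present]
    if (length(members) == 0L) stop("no score members present in matrix")
  }
  sub <- m[members, , drop = FALSE]
  if (center) sub <- median_center(sub)
  score <- colMeans(sub)
  attr(score, "members") <- members
  score
}

#' Convert a Ct table to a log2-like expression matrix
#'
#' RT-qPCR threshold cycles are normalized to the mean Ct of the reference
#' miRNAs in the same sample and negated, so higher values mean higher
#' abundance (one Ct is one cycle, i.e. one log2 unit). The result carries
#' the scale tag `neg_delta_ct` and can be fed to [compute_score()].
#'
#' @param ct numeric matrix of Ct values (cycles), features x samples.
#' @param references names of the reference (normalizer) miRNA rows.
#' @return Expression matrix of -(Ct - mean reference Ct), reference rows
#'   removed, attribute `scale = "neg_delta_ct"`.
#' @export
expression_from_ct <- function(ct, references) {
  ct <- as.matrix(ct)
  if (length(references) < 1L) stop("need at least one reference feature")
  if (!all(references %in% rownames(ct))) {
    stop("reference(s) not in table: ",
         paste(setdiff(references, rownames(ct)), collapse = ", "))
  }
  refs <- ct[references, , drop = FALSE]
  if (anyNA(refs)) {
    bad <- colnames(ct)[apply(refs, 2L, anyNA)]
    stop("missing reference Ct in sample(s): ", paste(bad, collapse = ", "))
  }
  ref_mean <- colMeans(refs)
  keep <- setdiff(rownames(ct), references)
  out <- -sweep(ct[keep, , drop = FALSE], 2L, ref_mean, "-")
  attr(out, "scale") <- "neg_delta_ct"
  out
}

#' White test for heteroscedasticity
#'
#' Regresses squared residuals on the fitted values and their squares; the
#' Lagrange-multiplier statistic n R-squared is referred to a chi-square
#' distribution with 2 degrees of freedom. Used to check that miRNA
#' expression variability is constant over the measured range.
#'
#' @param fitted fitted (predicted) values of the primary regression.
#' @param residuals residuals of the primary regression.
#' @return List with `statistic`, `p.value`, `df`, and `points` (a
#'   data frame of fitted vs residual for the diagnostic plot).
#' @export
white_heteroscedasticity_test <- function(fitted, residuals) {
  if (length(fitted) != length(residuals)) stop("length mismatch")
  n <- length(fitted)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::var(fitted) == 0) stop("fitted values have zero variance")
  r2sq <- residuals^2
  if (stats::var(r2sq) < .Machine$double.eps * max(1, mean(r2sq))^2) {
    # squared residuals carry no variation: no auxiliary signal
    return(list(statistic = 0, p.value = 1, df = 2L,
                points = data.frame(fitted = fitted,
                                    residual = residuals)))
  }
  aux <- stats::lm(r2sq ~ fitted + I(fitted^2))
  r2 <- summary(aux)$r.squared
  stat <- n * r2
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
       df = 2L,
       points = data.frame(fitted = fitted, residual = residuals))
}
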