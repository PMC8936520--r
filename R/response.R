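#' Clonogenic assay metrics
#'
#' Plating efficiency is the colony-forming fraction of unirradiated
#' cells; the survival fraction at a dose is the colony yield corrected by
#' the plating efficiency, so SF at 0 Gy is 1 by construction.
#'
#' @param colonies colonies counted (the > 50-cell rule is applied
#'   upstream, at counting).
#' @param seeded cells seeded.
#' @return `plating_efficiency`: PE in \[0, 1\].
#' @export
plating_efficiency <- function(colonies, seeded) {
  if (any(seeded <= 0)) stop("seeded must be positive")
  if (any(colonies < 0) || any(colonies > seeded)) {
    stop("colonies must be in [0, seeded]")
  }
  colonies / seeded
}

#' @rdname plating_efficiency
#' @param pe plating efficiency from the matched unirradiated condition.
#' @return `survival_fraction`: SF = (colonies/seeded)/PE.
#' @export
survival_fraction <- function(colonies, seeded, pe) {
  if (any(pe <= 0)) stop("plating efficiency must be positive")
  plating_efficiency(colonies, seeded) / pe
}

#' Relative gamma-H2Ax intensity
#'
#' Flow-cytometry median gamma-H2Ax intensity normalized to the spiked-in
#' REH reference population of the same sample (removing inter-sample
#' staining variation), then expressed relative to the unirradiated
#' condition's normalized value.
#'
#' @param sample_median median intensity of the sample population.
#' @param reh_median median intensity of the REH reference population in
#'   the same tube.
#' @param baseline_ratio sample/REH ratio of the matched unirradiated
#'   condition.
#' @return Fold induction relative to unirradiated.
#' @export
relative_gamma_h2ax <- function(sample_median, reh_median,
                                baseline_ratio) {
  if (any(reh_median <= 0)) stop("REH median must be positive")
  if (any(baseline_ratio <= 0)) stop("baseline ratio must be positive")
  (sample_median / reh_median) / baseline_ratio
}

#' Tumor volume doubling time
#'
#' Fits an exponential growth model by least squares of log volume on
#' time within the (manually chosen) exponential-phase window;
#' Td = ln 2 / slope. A non-positive slope flags the tumor as non-growing
#' (infinite Td).
#'
#' @param days measurement days.
#' @param volumes volumes (any unit; Td is unit-invariant).
#' @param window optional c(first, last) day range to restrict the fit.
#' @return List with `td_days`, `slope`, `growing` (FALSE when the slope
#'   is not positive).
#' @export
doubling_time <- function(days, volumes, window = NULL) {
  if (!is.null(window)) {
    keep <- days >= window[1L] & days <= window[2L]
    days <- days[keep]; volumes <- volumes[keep]
  }
  if (length(days) < 3L) stop("need at least 3 points in the window")
  if (any(volumes <= 0)) stop("volumes must be positive")
  fit <- stats::lm(log(volumes) ~ days)
  slope <- unname(stats::coef(fit)[2L])
  growing <- slope > 0
  list(td_days = if (growing) log(2) / slope else Inf,
       slope = slope, growing = growing)
}

#' Time to reach a volume factor (T 1.5x endpoint)
#'
#' Time at which a tumor first reaches `factor` times its day-0 volume,
#' linearly interpolated between the bracketing measurements; tumors that
#' never reach it are censored at the last observation.
#'
#' @param days measurement days (day 0 required).
#' @param volumes volumes.
#' @param factor target multiple of baseline (default 1.5).
#' @return List with `t_days` and `censored`.
#' @export
time_to_factor <- function(days, volumes, factor = 1.5) {
  ord <- order(days)
  days <- days[ord]; volumes <- volumes[ord]
  if (days[1L] != 0) stop("day-0 baseline measurement required")
  target <- factor * volumes[1L]
  at <- which(volumes >= target)
  if (!length(at)) {
    return(list(t_days = days[length(days)], censored = TRUE))
  }
  i <- at[1L]
  if (i == 1L || volumes[i] == target) {
    return(list(t_days = days[i], censored = FALSE))
  }
  t <- days[i - 1L] + (days[i] - days[i - 1L]) *
    (target - volumes[i - 1L]) / (volumes[i] - volumes[i - 1L])
  list(t_days = t, censored = FALSE)
}

#' Tumor growth delay and radiation-response enhancement factor
#'
#' For each cell line, tumor growth delay (TGD) is the mean T1.5x of
#' irradiated tumors minus the mean T1.5x of unirradiated tumors; the
#' enhancement factor (EF) is the TGD of the miRNA-overexpressing line
#' divided by the TGD of the control line. Censored T1.5x values enter
#' the Kaplan-Meier comparison but are excluded from the means (a flag is
#' raised when more than 20% are censored). Irradiated groups are also
#' compared by two-sample t-test, and all pairwise group KM comparisons
#' by log-rank with Holm-Sidak adjustment.
#'
#' @param t15 data frame with columns `tumor`, `line` (e.g. "mir",
#'   "control"), `irradiated` (logical or 0/1), `t_days`, `censored`.
#' @param mir_line,control_line values of `line` identifying the
#'   overexpressing and control lines.
#' @return List with `tgd` (per line), `ef`, `t_test_p` (irradiated miR vs
#'   control), `pairwise` (log-rank with raw and Holm-Sidak p),
#'   `censoring_flag`.
#' @export
growth_delay <- function(t15, mir_line = "mir", control_line = "control") {
  t15$irradiated <- as.logical(t15$irradiated)
  t15$censored <- as.logical(t15$censored)
  mean_t <- function(line, irr) {
    v <- t15$t_days[t15$line == line & t15$irradiated == irr &
                      !t15$censored]
    if (!length(v)) return(NA_real_)
    mean(v)
  }
  tgd <- c(mean_t(mir_line, TRUE) - mean_t(mir_line, FALSE),
           mean_t(control_line, TRUE) - mean_t(control_line, FALSE))
  names(tgd) <- c(mir_line, control_line)
  ef <- if (is.na(tgd[control_line]) || tgd[control_line] <= 0) {
    NA_real_
  } else unname(tgd[mir_line] / tgd[control_line])
  a <- t15$t_days[t15$line == mir_line & t15$irradiated & !t15$censored]
  b <- t15$t_days[t15$line == control_line & t15$irradiated &
                    !t15$censored]
  t_p <- if (length(a) >= 2L && length(b) >= 2L) {
    # degenerate (constant) groups yield no test, not an error
    tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
  } else NA_real_
  grp <- interaction(t15$line, ifelse(t15$irradiated, "irr", "unirr"),
                     drop = TRUE)
  e <- data.frame(time = t15$t_days, event = 1L - as.integer(t15$censored))
  combos <- utils::combn(levels(grp), 2L)
  pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(i) {
    sel <- grp %in% combos[, i]
    p <- tryCatch(
      logrank_test(e[sel, , drop = FALSE], droplevels(grp[sel]))$p.value,
      error = function(err) NA_real_)
    data.frame(group1 = combos[1L, i], group2 = combos[2L, i], p_raw = p)
  }))
  pairwise$p_holm_sidak <- NA_real_
  ok <- !is.na(pairwise$p_raw)
  pairwise$p_holm_sidak[ok] <- holm_sidak_adjust(pairwise$p_raw[ok])
  list(tgd = tgd, ef = ef, t_test_p = t_p, pairwise = pairwise,
       censoring_flag = mean(t15$censored) > 0.20)
}
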