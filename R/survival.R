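#' Site-specific recurrence endpoints
#'
#' Builds a time/event table for one of the four study endpoints from a
#' clinical table. For a site endpoint (central, lateral, distal control)
#' the event is the first recurrence at that site; a recurrence at another
#' site only censors the endpoint at the recurrence time. Progression-free
#' survival (pfs) counts the first recurrence at any site as the event.
#' Patients without recurrence are censored at the end of follow-up, and
#' all times are administratively truncated at the horizon.
#'
#' @param clinical data frame with columns `patient_id`, `followup_months`,
#'   `recurrence_site` (one of "central", "lateral", "distant", or NA), and
#'   `recurrence_months` (NA when no recurrence).
#' @param endpoint one of "central_control", "lateral_control",
#'   "distal_control", "pfs".
#' @param horizon administrative follow-up horizon in months (default 60).
#' @return data frame with `patient_id`, `time` (months), `event` (0/1),
#'   and `endpoint`.
#' @export
build_endpoint <- function(clinical,
                           endpoint = c("pfs", "central_control",
                                        "lateral_control", "distal_control"),
                           horizon = 60) {
  endpoint <- match.arg(endpoint)
  site_of <- c(central_control = "central", lateral_control = "lateral",
               distal_control = "distant")
  rec_site <- clinical$recurrence_site
  rec_time <- clinical$recurrence_months
  known <- c("central", "lateral", "distant")
  if (any(!is.na(rec_site) & !(rec_site %in% known))) {
    stop("unknown recurrence site label: ",
         paste(unique(setdiff(rec_site, c(known, NA))), collapse = ", "))
  }
  has_rec <- !is.na(rec_site) & !is.na(rec_time)
  if (endpoint == "pfs") {
    time <- ifelse(has_rec, rec_time, clinical$followup_months)
    event <- as.integer(has_rec)
  } else {
    target <- site_of[[endpoint]]
    at_site <- has_rec & rec_site == target
    # other-site recurrence censors at its time; no recurrence censors at
    # last follow-up
    time <- ifelse(has_rec, rec_time, clinical$followup_months)
    event <- as.integer(at_site)
  }
  over <- time > horizon
  event[over] <- 0L
  time[over] <- horizon
  data.frame(patient_id = clinical$patient_id, time = time, event = event,
             endpoint = endpoint, stringsAsFactors = FALSE)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator via [survival::survfit()], returned as one tidy
#' data frame per group with at-risk counts and censor marks.
#'
#' @param e endpoint table from [build_endpoint()] (columns `time`, `event`).
#' @param groups optional factor/vector of group labels per patient; a
#'   single pooled curve when omitted.
#' @return Named list of data frames (`time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`).
#' @export
km_estimate <- function(e, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(e))
  groups <- as.factor(groups)
  if (any(table(groups) == 0L)) stop("empty group")
  fit <- survival::survfit(
    survival::Surv(e$time, e$event) ~ g,
    data = data.frame(g = groups))
  smry <- summary(fit, censored = TRUE)
  strata <- if (is.null(smry$strata)) {
    rep(levels(groups)[1L], length(smry$time))
  } else sub("^g=", "", as.character(smry$strata))
  out <- split(data.frame(time = smry$time, n_risk = smry$n.risk,
                          n_event = smry$n.event, n_censor = smry$n.censor,
                          surv = smry$surv),
               factor(strata, levels = unique(strata)))
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

# O-E and variance machinery of the k-group log-rank test, shared by
# logrank_test() and the cutoff scan (where it is called thousands of
# times, so it avoids survdiff's formula interface).
logrank_chisq <- function(time, event, group) {
  group <- as.integer(factor(group))
  k <- max(group)
  if (k < 2L) stop("need at least 2 groups")
  if (sum(event) < 1L) stop("no events")
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; group <- group[ord]
  dt <- unique(time[event == 1L])
  obs <- expd <- numeric(k)
  vv <- matrix(0, k, k)
  for (t in dt) {
    at_risk <- time >= t
    nj <- tabulate(group[at_risk], nbins = k)
    N <- sum(nj)
    dj <- tabulate(group[at_risk & time == t & event == 1L], nbins = k)
    d <- sum(dj)
    obs <- obs + dj
    expd <- expd + d * nj / N
    if (N > 1L) {
      # multivariate hypergeometric covariance of the event counts
      f <- d * (N - d) / ((N - 1) * N^2)
      vv <- vv + f * (diag(nj * N, nrow = k) - outer(nj, nj))
    }
  }
  om <- (obs - expd)[-k]
  vm <- vv[-k, -k, drop = FALSE]
  chi2 <- tryCatch(drop(t(om) %*% solve(vm, om)), error = function(e) NA_real_)
  list(chi2 = chi2, df = k - 1L, observed = obs, expected = expd)
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank comparison of survival between groups,
#' with chi-square statistic on k-1 degrees of freedom.
#'
#' @inheritParams km_estimate
#' @param groups group labels per patient (at least two groups).
#' @return List with `chi2`, `df`, `p.value`, `observed`, `expected`.
#' @export
logrank_test <- function(e, groups) {
  r <- logrank_chisq(e$time, e$event, groups)
  r$p.value <- stats::pchisq(r$chi2, r$df, lower.tail = FALSE)
  r
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit via [survival::coxph()] with Efron handling of
#' ties, returning the hazard ratio, Wald 95% CI and p per covariate.
#' Covariates may be continuous (e.g. the miR-200a/b/-429 score used as a
#' continuous variable) or dichotomized.
#'
#' @param e endpoint table (columns `time`, `event`).
#' @param covariates data frame of covariates (one column each), or a
#'   single vector.
#' @return data frame with one row per model term: `covariate`, `coef`,
#'   `se`, `HR`, `ci_low`, `ci_high`, `p`, plus attribute `fit` (the coxph
#'   object) and `converged`.
#' @export
cox_fit <- function(e, covariates) {
  if (is.null(dim(covariates))) covariates <- data.frame(x = covariates)
  covariates <- as.data.frame(covariates)
  const <- vapply(covariates, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) < 2L
  }, logical(1L))
  if (any(const)) {
    stop("constant covariate(s): ",
         paste(names(covariates)[const], collapse = ", "))
  }
  if (sum(e$event) < 1L) stop("no events")
  dat <- cbind(data.frame(.time = e$time, .event = e$event), covariates)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- survival::coxph(form, data = dat, ties = "efron")
  s <- summary(fit)
  out <- data.frame(
    covariate = names(covariates),
    coef = unname(s$coefficients[, "coef"]),
    se = unname(s$coefficients[, "se(coef)"]),
    HR = unname(s$coefficients[, "exp(coef)"]),
    ci_low = unname(s$conf.int[, "lower .95"]),
    ci_high = unname(s$conf.int[, "upper .95"]),
    p = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  attr(out, "converged") <- all(is.finite(s$coefficients[, "coef"])) &&
    all(is.finite(s$coefficients[, "se(coef)"]))
  out
}

# Likelihood-ratio p-value for adding/removing terms between two coxph fits
lrt_p <- function(fit_big, fit_small, df) {
  # the null model's loglik has length 1
  lr <- 2 * (utils::tail(fit_big$loglik, 1L) -
               utils::tail(fit_small$loglik, 1L))
  stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
}

coxph_on <- function(e, covariates, terms) {
  dat <- cbind(data.frame(.time = e$time, .event = e$event), covariates)
  rhs <- if (length(terms)) {
    paste(sprintf("`%s`", terms), collapse = " + ")
  } else "1"
  survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs)),
    data = dat, ties = "efron")
}

#' Stepwise Cox model selection
#'
#' Multivariate model building as in the clinical analysis: candidates are
#' first screened by univariate Cox p-value (kept when p <= 0.1), then a
#' forward and/or backward stepwise search over the screened set uses
#' likelihood-ratio tests with entry at p <= 0.05 and removal at p >= 0.10.
#' When both directions are run, the result records whether they agree.
#'
#' @param e endpoint table.
#' @param covariates data frame of candidate covariates.
#' @param direction "forward", "backward", or "both" (default).
#' @param screen_p univariate screening threshold (default 0.1).
#' @param enter_p,remove_p stepwise entry/removal thresholds.
#' @return List with `screened` (names passing the univariate screen),
#'   `selected` (final model terms), `univariate` (per-candidate cox_fit
#'   rows), `model` (cox_fit table of the final model, NULL when empty),
#'   `directions_agree` (logical, when direction = "both"), `note`.
#' @export
stepwise_cox <- function(e, covariates, direction = c("both", "forward",
                                                      "backward"),
                         screen_p = 0.1, enter_p = 0.05, remove_p = 0.10) {
  direction <- match.arg(direction)
  covariates <- as.data.frame(covariates)
  uni <- do.call(rbind, lapply(names(covariates), function(nm) {
    cox_fit(e, stats::setNames(covariates[nm], nm))
  }))
  screened <- uni$covariate[uni$p <= screen_p]
  if (length(screened) == 0L) {
    return(list(screened = character(), selected = character(),
                univariate = uni, model = NULL, directions_agree = NA,
                note = "no candidate passed the univariate screen"))
  }
  forward_sel <- function() {
    sel <- character()
    repeat {
      rest <- setdiff(screened, sel)
      if (!length(rest)) break
      base_fit <- coxph_on(e, covariates, sel)
      ps <- vapply(rest, function(nm) {
        lrt_p(coxph_on(e, covariates, c(sel, nm)), base_fit, 1L)
      }, numeric(1L))
      if (min(ps) > enter_p) break
      sel <- c(sel, rest[which.min(ps)])
    }
    sel
  }
  backward_sel <- function() {
    sel <- screened
    repeat {
      if (!length(sel)) break
      full_fit <- coxph_on(e, covariates, sel)
      ps <- vapply(sel, function(nm) {
        lrt_p(full_fit, coxph_on(e, covariates, setdiff(sel, nm)), 1L)
      }, numeric(1L))
      if (max(ps) < remove_p) break
      sel <- setdiff(sel, sel[which.max(ps)])
    }
    sel
  }
  fsel <- if (direction %in% c("forward", "both")) forward_sel() else NULL
  bsel <- if (direction %in% c("backward", "both")) backward_sel() else NULL
  agree <- if (direction == "both") setequal(fsel, bsel) else NA
  selected <- switch(direction, forward = fsel, backward = bsel,
                     both = fsel)
  model <- if (length(selected)) {
    cox_fit(e, covariates[selected])
  } else NULL
  list(screened = screened, selected = selected, univariate = uni,
       model = model, forward = fsel, backward = bsel,
       directions_agree = agree, note = NULL)
}

#' Optimal-cutoff scan for biomarker stratification
#'
#' Exhaustive scan over distinct score values: every cutoff whose low/high
#' split leaves at least `min_group_fraction` of patients in each group is
#' scored by the two-group log-rank chi-square, and the maximizing cutoff
#' is returned. Because the maximum over a scan inflates the nominal
#' log-rank p, a corrected p is computed either by permuting scores against
#' outcomes and re-running the full scan (default), or by a Bonferroni
#' bound over the number of candidate cutoffs ("min_p"); both corrected
#' forms are never smaller than the uncorrected p.
#'
#' @param score numeric biomarker per patient.
#' @param e endpoint table aligned with `score`.
#' @param min_group_fraction minimum fraction of patients per group.
#' @param correction "permutation", "min_p", or "none".
#' @param n_perm permutations for the permutation correction.
#' @param seed optional seed for the permutation draw.
#' @return List with `cutoff`, `n_low`, `n_high`, `fraction_low`, `chi2`,
#'   `p_uncorrected`, `p_corrected`, `n_candidates`, and the full `scan`
#'   table.
#' @export
optimal_cutoff_scan <- function(score, e, min_group_fraction = 0.10,
                                correction = c("permutation", "min_p",
                                               "none"),
                                n_perm = 1000, seed = NULL) {
  correction <- match.arg(correction)
  n <- length(score)
  if (n < 20L) stop("need at least 20 patients")
  if (sum(e$event) < 1L) stop("no events")
  if (n != nrow(e)) stop("score and endpoint table differ in length")
  min_n <- ceiling(min_group_fraction * n)
  cand <- sort(unique(score))
  # cutoff c assigns low = score <= c; both groups must respect the floor
  n_low <- vapply(cand, function(c) sum(score <= c), integer(1L))
  ok <- n_low >= min_n & (n - n_low) >= min_n
  cand <- cand[ok]
  if (!length(cand)) stop("no admissible cutoff under min_group_fraction")
  # Vectorized two-group log-rank over all cutoffs at once: at each event
  # time the low-group at-risk and event counts for every cutoff come from
  # two matrix products, so the permutation correction can re-run the full
  # scan cheaply.
  dt <- sort(unique(e$time[e$event == 1L]))
  at_risk <- outer(e$time, dt, ">=")                    # n x T
  at_event <- outer(e$time, dt, "==") & (e$event == 1L) # n x T
  Nt <- colSums(at_risk)
  Dt <- colSums(at_event)
  scan_chi2 <- function(sc) {
    low <- outer(sc, cand, "<=") * 1  # n x C
    n1 <- crossprod(at_risk, low)     # T x C
    d1 <- crossprod(at_event, low)
    oe <- colSums(d1 - Dt * n1 / Nt)
    vt <- Dt * (Nt - Dt) / pmax(Nt - 1, 1) / Nt^2
    v <- colSums(vt * n1 * (Nt - n1))
    ifelse(v > 0, oe^2 / v, NA_real_)
  }
  chi <- scan_chi2(score)
  best <- which.max(chi)
  p_unc <- stats::pchisq(chi[best], 1L, lower.tail = FALSE)
  p_cor <- switch(correction,
    none = p_unc,
    min_p = min(1, p_unc * length(cand)),
    permutation = {
      if (!is.null(seed)) set.seed(seed)
      exceed <- 0L
      for (i in seq_len(n_perm)) {
        perm <- sample(score)
        if (max(scan_chi2(perm), na.rm = TRUE) >= chi[best]) {
          exceed <- exceed + 1L
        }
      }
      (1 + exceed) / (n_perm + 1)
    })
  p_cor <- max(p_cor, p_unc)
  list(cutoff = cand[best],
       n_low = sum(score <= cand[best]),
       n_high = sum(score > cand[best]),
       fraction_low = mean(score <= cand[best]),
       chi2 = chi[best],
       p_uncorrected = p_unc,
       p_corrected = p_cor,
       n_candidates = length(cand),
       scan = data.frame(cutoff = cand, chi2 = chi))
}

#' Log-minus-log transform of survival curves
#'
#' Transforms Kaplan-Meier curves to (log t, log(-log S(t))) points for the
#' graphical proportional-hazards check: under proportional hazards, group
#' curves are vertically parallel. Points with S = 0 or S = 1 are outside
#' the domain of the transform and are skipped with a note.
#'
#' @param km result of [km_estimate()] (named list of per-group curves).
#' @return List of data frames (`log_time`, `cloglog`) per group, with
#'   attribute `note` when points were skipped.
#' @export
log_minus_log <- function(km) {
  skipped <- 0L
  out <- lapply(km, function(d) {
    keep <- d$surv > 0 & d$surv < 1 & d$time > 0
    skipped <<- skipped + sum(!keep)
    data.frame(log_time = log(d$time[keep]),
               cloglog = log(-log(d$surv[keep])))
  })
  if (skipped > 0L) {
    attr(out, "note") <- sprintf(
      "%d point(s) with S(t) in {0,1} skipped", skipped)
  }
  out
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak multiple-comparison adjustment: the i-th smallest p is
#' adjusted to 1 - (1 - p)^(m - i + 1), with monotonicity enforced by a
#' running maximum.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak_adjust <- function(p) {
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  m <- length(p)
  ord <- order(p)
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

#' Dichotomize a hypoxia score at the predefined zero cutoff
#'
#' The six-gene hypoxia signature comes with a predefined cutoff of zero:
#' scores above zero are called "more" hypoxic, scores at or below zero
#' "less" hypoxic (the boundary is assigned to "less").
#'
#' @param score numeric hypoxia scores.
#' @param cutoff cutoff value, default 0.
#' @return Factor with levels "less" and "more".
#' @export
dichotomize_hypoxia <- function(score, cutoff = 0) {
  if (any(!is.finite(score))) stop("scores must be finite")
  factor(ifelse(score > cutoff, "more", "less"), levels = c("less", "more"))
}
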