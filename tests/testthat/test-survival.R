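make_clinical <- function(followup, site, rec_time) {
  data.frame(patient_id = paste0("p", seq_along(followup)),
             followup_months = followup,
             recurrence_site = site,
             recurrence_months = rec_time,
             stringsAsFactors = FALSE)
}

test_that("endpoint construction applies site-specific censoring and the horizon", {
  cl <- make_clinical(
    followup = c(70, 50, 48, 30),
    site = c(NA, "central", "distant", "lateral"),
    rec_time = c(NA, 12, 12, 65))
  ep <- build_endpoint(cl, "central_control", horizon = 60)
  expect_equal(ep$time, c(60, 12, 12, 60))
  expect_equal(ep$event, c(0L, 1L, 0L, 0L))  # other-site recurrence censors
  pfs <- build_endpoint(cl, "pfs", horizon = 60)
  expect_equal(pfs$time, c(60, 12, 12, 60))
  expect_equal(pfs$event, c(0L, 1L, 1L, 0L))  # any site is a pfs event
  cl$recurrence_site[2] <- "brainstem"
  expect_error(build_endpoint(cl, "pfs"), "brainstem")
})

test_that("KM estimator matches hand product-limit computation", {
  e <- data.frame(time = c(1, 2), event = c(1L, 1L))
  km <- km_estimate(e)[[1]]
  expect_equal(km$surv, c(0.5, 0))
  # all censored: flat at 1
  e2 <- data.frame(time = 1:4, event = rep(0L, 4))
  expect_true(all(km_estimate(e2)[[1]]$surv == 1))
  # 10-subject mixed case against the longhand oracle
  set.seed(5)
  t10 <- sample(1:20, 10); ev10 <- rbinom(10, 1, 0.7)
  km10 <- km_estimate(data.frame(time = t10, event = ev10))[[1]]
  oracle <- km_bruteforce(t10, ev10)
  got <- km10$surv[km10$n_event > 0]
  expect_equal(got, oracle$surv, tolerance = 1e-12)
})

test_that("log-rank matches the hypergeometric-sum oracle and survdiff", {
  set.seed(9)
  e <- data.frame(time = c(2, 4, 5, 7, 8, 11, 12, 15),
                  event = c(1L, 1L, 0L, 1L, 1L, 1L, 0L, 1L))
  g <- rep(c("a", "b"), 4)
  r <- logrank_test(e, g)
  expect_equal(r$chi2, logrank_bruteforce(e$time, e$event, g),
               tolerance = 1e-12)
  sd <- survival::survdiff(survival::Surv(e$time, e$event) ~ g)
  expect_equal(r$chi2, sd$chisq, tolerance = 1e-10)
  # identical groups: observed = expected
  e2 <- rbind(e, e)
  g2 <- rep(c("x", "y"), each = 8)
  expect_equal(logrank_test(e2, g2)$chi2, 0, tolerance = 1e-12)
  expect_error(logrank_test(data.frame(time = 1:4, event = rep(0L, 4)),
                            rep(1:2, 2)), "no events")
})

test_that("three-group log-rank agrees with survdiff", {
  set.seed(31)
  n <- 60
  e <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8))
  g <- sample(letters[1:3], n, replace = TRUE)
  r <- logrank_test(e, g)
  sd <- survival::survdiff(survival::Surv(e$time, e$event) ~ g)
  expect_equal(r$df, 2L)
  expect_equal(r$chi2, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank has nominal type-I error under label permutation", {
  set.seed(77)
  n <- 100
  time <- rexp(n, 0.05); event <- as.integer(time <= 40)
  time <- pmin(time, 40)
  e <- data.frame(time = time, event = event)
  rej <- vapply(1:500, function(i) {
    logrank_test(e, sample(rep(0:1, each = 50)))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("Cox fit matches the grid-search partial-likelihood maximizer", {
  # small untied data, exhaustive grid on the written partial likelihood
  set.seed(13)
  time <- c(1.1, 2.3, 3.7, 4.2, 5.9, 6.4, 8.8, 9.5)
  event <- c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L)
  x <- c(0.5, -1.2, 0.3, 1.8, -0.7, 0.9, -1.5, 0.2)
  fit <- cox_fit(data.frame(time = time, event = event), x)
  expect_lt(abs(fit$coef - cox_grid_mle(time, event, x)), 1e-6)
  expect_true(fit$ci_low <= fit$HR && fit$HR <= fit$ci_high)
  expect_error(cox_fit(data.frame(time = time, event = event),
                       rep(1, 8)), "constant")
})

test_that("Cox recovers a true hazard ratio of 2 and its score test equals log-rank", {
  set.seed(23)
  hrs <- vapply(1:10, function(i) {
    n <- 2000
    x <- rep(0:1, each = n / 2)
    time <- rexp(n, 0.05 * 2^x)
    cox_fit(data.frame(time = time, event = rep(1L, n)), x)$HR
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 2), 0.15)
  # score test at beta = 0 for a binary covariate is the log-rank chi2
  small <- data.frame(time = c(2, 4, 5, 7, 9, 12), event = rep(1L, 6))
  xs <- c(0, 1, 0, 1, 1, 0)
  cph <- survival::coxph(survival::Surv(small$time, small$event) ~ xs)
  expect_equal(unname(cph$score), logrank_test(small, xs)$chi2,
               tolerance = 1e-8)
})

test_that("stepwise selection screens at 0.1 and finds the planted covariate", {
  set.seed(55)
  picks <- agree <- logical(60)
  for (i in 1:60) {
    n <- 200
    covs <- data.frame(strong = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                       n3 = rnorm(n), n4 = rnorm(n), n5 = rnorm(n))
    time <- rexp(n, 0.05 * exp(-0.9 * covs$strong))
    e <- data.frame(time = pmin(time, 60),
                    event = as.integer(time <= 60))
    sw <- stepwise_cox(e, covs)
    picks[i] <- "strong" %in% sw$selected
    agree[i] <- isTRUE(sw$directions_agree)
  }
  expect_gte(mean(picks), 0.90)
  expect_gte(mean(agree), 0.80)
  # nothing passes the screen -> empty model with note
  set.seed(2)
  n <- 80
  e <- data.frame(time = rexp(n, 0.05), event = rep(1L, n))
  # covariates independent of outcome, forced over the screen threshold
  sw2 <- stepwise_cox(e, data.frame(a = rnorm(n)), screen_p = 1e-10)
  expect_length(sw2$selected, 0)
  expect_match(sw2$note, "screen")
})

test_that("cutoff scan respects group floors and correction ordering", {
  set.seed(99)
  n <- 100
  sc <- rnorm(n)
  time <- rexp(n, 0.03); e <- data.frame(time = pmin(time, 60),
                                         event = as.integer(time <= 60))
  r <- optimal_cutoff_scan(sc, e, min_group_fraction = 0.10,
                           correction = "permutation", n_perm = 200,
                           seed = 1)
  expect_gte(r$n_low, 10)
  expect_gte(r$n_high, 10)
  expect_gte(r$p_corrected, r$p_uncorrected)
  expect_equal(r$n_low + r$n_high, n)
  # scan chi2 at the chosen cutoff agrees with the standalone log-rank
  direct <- logrank_test(e, sc <= r$cutoff)
  expect_equal(r$chi2, direct$chi2, tolerance = 1e-10)
  rp <- optimal_cutoff_scan(sc, e, correction = "min_p")
  expect_gte(rp$p_corrected, rp$p_uncorrected)
})

test_that("cutoff scan recovers a planted step hazard at the 30th percentile", {
  set.seed(11)
  hits <- vapply(1:60, function(i) {
    n <- 200
    sc <- rnorm(n)
    q30 <- quantile(sc, 0.3)
    lam <- ifelse(sc <= q30, 0.025, 0.004)
    t <- rexp(n, lam)
    e <- data.frame(time = pmin(t, 60), event = as.integer(t <= 60))
    r <- optimal_cutoff_scan(sc, e, correction = "none")
    abs(mean(sc <= r$cutoff) - 0.3) <= 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.80)
})

test_that("log-minus-log is linear for exponential survival and offset under PH", {
  t <- seq(1, 50, by = 1)
  km <- list(g1 = data.frame(time = t, surv = exp(-0.05 * t)),
             g2 = data.frame(time = t, surv = exp(-0.10 * t)))
  lml <- log_minus_log(km)
  # slope 1 in log t, intercept log(lambda)
  f1 <- lm(cloglog ~ log_time, data = lml$g1)
  expect_equal(unname(coef(f1)[2]), 1, tolerance = 1e-8)
  offset <- lml$g2$cloglog - lml$g1$cloglog
  expect_equal(offset, rep(log(2), length(t)), tolerance = 1e-8)
  flat <- list(g = data.frame(time = t, surv = rep(1, length(t))))
  out <- log_minus_log(flat)
  expect_equal(nrow(out$g), 0)
  expect_match(attr(out, "note"), "skipped")
})

test_that("Holm-Sidak adjustment matches hand values and is monotone", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.04)),
               c(1 - (1 - 0.01)^2, 0.04))
  expect_equal(holm_sidak_adjust(0.3), 0.3)
  set.seed(3)
  p <- runif(20)
  adj <- holm_sidak_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("hypoxia dichotomization puts the zero boundary in the less-hypoxic class", {
  out <- dichotomize_hypoxia(c(0.2, -0.2, 0))
  expect_equal(as.character(out), c("more", "less", "less"))
  expect_error(dichotomize_hypoxia(c(1, NA)), "finite")
})
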