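test_that("noiseless mono-exponential decay is inverted to machine precision", {
  b <- c(200, 400, 700, 1000)
  adc_true <- 0.001
  sig <- array(0, c(4, 4, 4))
  for (i in 1:4) sig[, , i] <- 1000 * exp(-b[i] * adc_true)
  map <- fit_adc(dwi_series(sig, b))
  expect_lt(max(abs(map$adc - adc_true) / adc_true), 1e-10)
  expect_equal(map$intercept[1, 1], log(1000), tolerance = 1e-10)
  # exactness holds for any >= 2 distinct b-values
  map2 <- fit_adc(dwi_series(sig[, , c(1, 3)], b[c(1, 3)]))
  expect_lt(max(abs(map2$adc - adc_true) / adc_true), 1e-10)
})

test_that("ADC is invariant to global signal scaling; scale enters the intercept", {
  cfg <- sim_config(seed = 2)
  phantom <- gen_dwi(cfg, noise_sd = 0)
  m1 <- fit_adc(phantom$series)
  scaled <- phantom$series
  scaled$signals <- scaled$signals * 7.5
  m2 <- fit_adc(scaled)
  expect_equal(m1$adc, m2$adc, tolerance = 1e-12)
  d <- m2$intercept - m1$intercept
  expect_equal(range(d[m1$valid]), rep(log(7.5), 2), tolerance = 1e-10)
})

test_that("non-positive signals invalidate a voxel and all-invalid errors", {
  b <- c(200, 800)
  sig <- array(1000, c(2, 2, 2))
  sig[1, 1, 2] <- 0
  map <- fit_adc(dwi_series(sig, b))
  expect_false(map$valid[1, 1])
  expect_true(is.na(map$adc[1, 1]))
  expect_true(all(map$valid[-1]))
  sig_bad <- array(-1, c(2, 2, 2))
  expect_error(fit_adc(dwi_series(sig_bad, b)), "invalid")
})

test_that("noisy recovery at SNR 20 keeps the tumor median ADC within 2%", {
  set.seed(8)
  b <- c(200, 400, 700, 1000)
  adc_true <- 0.001
  n <- 100  # 10^4 voxels
  sig <- array(0, c(n, n, 4))
  for (i in 1:4) {
    sig[, , i] <- 1000 * exp(-b[i] * adc_true) + rnorm(n * n, sd = 50)
  }
  map <- fit_adc(dwi_series(sig, b))
  # per-voxel errors at this SNR are on the 10% scale (error propagation
  # through the 4-point log-linear fit); the analysis uses the per-tumor
  # median, which is far tighter
  expect_lt(abs(median_adc(map) - adc_true) / adc_true, 0.02)
  expect_lt(median(abs(map$adc[map$valid] - adc_true) / adc_true), 0.20)
})

test_that("necrosis rule is a strict threshold and fractions are exact", {
  map <- structure(list(
    adc = matrix(c(0.0012, 0.0010, 0.0011, 0.0009), 2, 2),
    intercept = matrix(0, 2, 2),
    valid = matrix(TRUE, 2, 2)), class = "adc_map")
  cls <- classify_necrosis(map)
  expect_equal(cls$necrosis, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(cls$necrotic_fraction, 0.25)
  # exactly at 0.0011 is viable
  expect_false(cls$necrosis[1, 2])
  # phantom necrotic fraction equals generator truth exactly (noiseless)
  phantom <- gen_dwi(sim_config(seed = 3), noise_sd = 0)
  m <- fit_adc(phantom$series)
  cls2 <- classify_necrosis(m)
  expect_equal(cls2$necrotic_fraction, phantom$truth$necrotic_fraction,
               tolerance = 1 / sum(m$valid))
  expect_equal(cls2$necrosis[phantom$series$roi],
               phantom$truth$necrosis[phantom$series$roi])
})

test_that("median ADC is order-invariant and respects validity", {
  vals <- c(1, 2, 3) * 1e-3
  map <- structure(list(adc = matrix(c(vals, NA), 2, 2),
                        intercept = matrix(0, 2, 2),
                        valid = matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)),
                   class = "adc_map")
  expect_equal(median_adc(map), 2e-3)
  map$valid[] <- FALSE
  expect_error(median_adc(map), "valid")
})

test_that("relative ADC ratios and tests behave on constructed series", {
  adc <- expand.grid(tumor = paste0("t", 1:5), day = c(0, 3, 7))
  adc$group <- "mir"
  adc$median_adc <- 1e-3
  r <- relative_adc(adc)
  expect_true(all(r$ratios$ratio == 1))
  expect_true(all(is.na(r$per_day$p_vs_baseline) |
                    r$per_day$p_vs_baseline > 0.99))
  # known increase: closed-form one-sample t on {1.2, 1.3, 1.25, 1.15, 1.3}
  x <- c(1.2, 1.3, 1.25, 1.15, 1.3)
  adc2 <- data.frame(tumor = rep(paste0("t", 1:5), 2),
                     group = "mir", day = rep(c(0, 3), each = 5),
                     median_adc = c(rep(1, 5), x))
  r2 <- relative_adc(adc2)
  tstat <- (mean(x) - 1) / (sd(x) / sqrt(5))
  p_hand <- 2 * pt(-abs(tstat), df = 4)
  expect_equal(r2$per_day$p_vs_baseline[r2$per_day$day == 3], p_hand,
               tolerance = 1e-12)
  expect_lt(p_hand, 0.05)
  # single tumor per group refuses the between-group test
  adc3 <- data.frame(tumor = c("a", "b", "a", "b"),
                     group = c("g1", "g2", "g1", "g2"),
                     day = c(0, 0, 3, 3), median_adc = 1)
  expect_error(relative_adc(adc3), ">= 2 tumors")
})

test_that("DWI TIFF + YAML round-trip preserves signals and metadata", {
  cfg <- sim_config(seed = 4, dwi_shape = c(16L, 16L))
  phantom <- gen_dwi(cfg, noise_sd = 0)
  tp <- tempfile(fileext = ".tiff")
  write_dwi(phantom$series, tp)
  back <- read_dwi(tp, roi = phantom$series$roi)
  expect_equal(back$b_values, phantom$series$b_values)
  expect_equal(back$signals, phantom$series$signals, tolerance = 1e-6)
  m <- fit_adc(back)
  expect_equal(m$adc[m$valid],
               phantom$truth$adc_true[phantom$series$roi],
               tolerance = 1e-4)
})
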