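test_that("deconvolution inverts the forward stain model", {
  # pure white pixel: zero OD everywhere
  white <- array(255, c(1, 1, 3))
  d <- color_deconvolve(white, eps = 0)
  expect_lt(abs(d$hematoxylin[1, 1]), 1e-8)
  expect_lt(abs(d$dab[1, 1]), 1e-8)
  # pure DAB rendered forward: only the DAB channel lights up
  img <- render_stains(matrix(0, 2, 2), matrix(0.8, 2, 2))
  d2 <- color_deconvolve(img, eps = 0)
  expect_equal(d2$dab, matrix(0.8, 2, 2), tolerance = 1e-6)
  expect_lt(max(d2$hematoxylin), 1e-6)
  # random two-stain mixtures round-trip within 1e-6
  set.seed(12)
  ch <- matrix(runif(64, 0, 1), 8, 8)
  cd <- matrix(runif(64, 0, 1), 8, 8)
  d3 <- color_deconvolve(render_stains(ch, cd), eps = 0)
  expect_lt(max(abs(d3$hematoxylin - ch)), 1e-6)
  expect_lt(max(abs(d3$dab - cd)), 1e-6)
  expect_error(color_deconvolve(img, stains = matrix(1, 3, 3)),
               "singular")
})

test_that("threshold segmentation and area fractions follow their definitions", {
  roi <- matrix(TRUE, 10, 10)
  ch <- matrix(0, 10, 10)
  expect_equal(sum(segment_by_threshold(ch, 0.5, roi)), 0)
  ch[] <- 1
  expect_equal(segment_by_threshold(ch, 0.5, roi), roi)
  necro <- matrix(FALSE, 10, 10); necro[1:5, 1:10] <- TRUE  # 50 px
  hyp <- matrix(FALSE, 10, 10); hyp[6, 1:10] <- TRUE        # 10 px viable
  expect_equal(necrotic_fraction_mask(necro, roi), 0.5)
  expect_equal(hypoxic_fraction_mask(hyp, roi, necro), 10 / 50)
  # hypoxia entirely inside necrosis counts zero
  hyp_in <- matrix(FALSE, 10, 10); hyp_in[1, 1:10] <- TRUE
  expect_equal(hypoxic_fraction_mask(hyp_in, roi, necro), 0)
  # gfp = viable region -> 1; empty -> 0
  viable <- roi & !necro
  expect_equal(gfp_area_fraction(viable, roi, necro), 1)
  expect_equal(gfp_area_fraction(matrix(FALSE, 10, 10), roi, necro), 0)
  expect_error(necrotic_fraction_mask(necro, matrix(FALSE, 10, 10)),
               "empty")
  expect_error(hypoxic_fraction_mask(hyp, necro, necro), "zero")
})

disc_image <- function(shape, centers, r) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, 1]; cy <- centers[i, 2]
    for (x in max(1, cx - r):min(shape[1], cx + r)) {
      for (y in max(1, cy - r):min(shape[2], cy + r)) {
        if ((x - cx)^2 + (y - cy)^2 <= r^2) m[x, y] <- TRUE
      }
    }
  }
  m
}

test_that("disjoint discs are counted exactly and clusters are split", {
  centers <- cbind(c(10, 30, 50, 70, 90), rep(20, 5))
  m <- disc_image(c(100, 40), centers, 5)  # 5 discs of ~81 px
  seg <- segment_nuclei(m * 1, threshold = 0.5, cluster_area_px = 200)
  expect_equal(seg$count, 5)
  # two touching discs form one component above the cluster rule and are
  # split into two by the distance-transform watershed
  pair <- disc_image(c(60, 60), cbind(c(25, 36), c(30, 30)), 8)
  expect_gt(sum(pair), 200)
  seg2 <- segment_nuclei(pair * 1, threshold = 0.5,
                         cluster_area_px = 200)
  expect_equal(seg2$count, 2)
  # same pair below the cluster rule stays a single object
  seg3 <- segment_nuclei(pair * 1, threshold = 0.5,
                         cluster_area_px = 1e6)
  expect_equal(seg3$count, 1)
})

test_that("labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one object
  seg <- segment_nuclei(m * 1, threshold = 0.5)
  expect_equal(seg$count, 1)
})

test_that("nuclei in necrosis are removed and parenchyma membership is enforced", {
  centers <- cbind(c(10, 30, 50), rep(15, 3))
  m <- disc_image(c(60, 30), centers, 5)
  necro <- matrix(FALSE, 60, 30); necro[1:18, ] <- TRUE  # first disc
  par <- matrix(TRUE, 60, 30); par[40:60, ] <- FALSE     # excludes third
  seg <- segment_nuclei(m * 1, threshold = 0.5, necrosis = necro,
                        parenchyma = par)
  expect_equal(seg$count, 1)
  expect_equal(round(seg$centroids$x), 30)
})

test_that("cell density scales with pixel size as area", {
  gfp <- matrix(TRUE, 100, 100)
  # 100 nuclei over 0.1 mm^2 -> 1000 per mm^2
  d <- cell_density(100, matrix(TRUE, 1000, 100), pixel_size_um = 1)
  expect_equal(d, 100 / (1e5 * 1e-6))
  d1 <- cell_density(50, gfp, pixel_size_um = 0.46)
  d2 <- cell_density(50, gfp, pixel_size_um = 0.92)
  expect_equal(d1 / d2, 4)
  expect_equal(cell_density(0, gfp), 0)
  expect_error(cell_density(10, matrix(FALSE, 5, 5)), "zero")
})

test_that("synthetic scene metrics equal generator truth", {
  cfg <- sim_config(seed = 6)
  hs <- gen_histology(cfg)
  dec <- color_deconvolve(hs$images$ki67)
  met <- histo_metrics(hs$masks$roi, hs$masks$necrosis, hs$masks$hypoxia,
                       hs$masks$gfp, dec$dab, dab_threshold = 0.5)
  expect_equal(met$nucleus_count, hs$truth$n_nuclei_parenchyma)
  expect_equal(met$necrotic_fraction, hs$truth$necrotic_fraction,
               tolerance = 1e-12)
  expect_equal(met$hypoxic_fraction, hs$truth$hypoxic_fraction,
               tolerance = 1e-12)
  expect_equal(met$gfp_fraction, hs$truth$gfp_fraction, tolerance = 1e-12)
  # mask recovery from the rendered GFP / pimonidazole sections
  gfp_mask <- segment_by_threshold(color_deconvolve(hs$images$gfp)$dab,
                                   0.5, hs$masks$roi)
  expect_equal(gfp_mask, hs$masks$gfp)
  hyp_mask <- segment_by_threshold(
    color_deconvolve(hs$images$pimonidazole)$dab, 0.5, hs$masks$roi)
  expect_equal(hyp_mask, hs$masks$hypoxia)
})

test_that("metrics are invariant to joint translation of images and masks", {
  sh <- c(80L, 80L)
  nuc <- disc_image(sh, cbind(c(30, 50), c(30, 50)), 5)
  roi <- matrix(TRUE, sh[1], sh[2])
  necro <- matrix(FALSE, sh[1], sh[2]); necro[60:70, 60:70] <- TRUE
  hyp <- matrix(FALSE, sh[1], sh[2]); hyp[10:15, 10:15] <- TRUE
  gfp <- !necro
  met <- histo_metrics(roi, necro, hyp, gfp, nuc * 1,
                       dab_threshold = 0.5)
  shift <- function(m, k) rbind(matrix(m[1, 1] & FALSE, k, ncol(m)),
                                m[1:(nrow(m) - k), ])
  # shift everything down 5 rows (content stays clear of the border)
  k <- 5L
  met_s <- histo_metrics(
    rbind(matrix(TRUE, k, sh[2]), roi[1:(sh[1] - k), ]),
    shift(necro, k), shift(hyp, k),
    rbind(matrix(TRUE, k, sh[2]), gfp[1:(sh[1] - k), ]),
    shift(nuc * 1, k), dab_threshold = 0.5)
  expect_equal(met_s$nucleus_count, met$nucleus_count)
  expect_equal(met_s$hypoxic_fraction, met$hypoxic_fraction,
               tolerance = 1e-12)
  expect_equal(met_s$necrotic_fraction, met$necrotic_fraction,
               tolerance = 1e-12)
})
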