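#' Construct a diffusion-weighted series
#'
#' Bundles per-b-value signal images with their diffusion weightings and a
#' region-of-interest mask.
#'
#' @param signals numeric array (nx x ny x n_b), one slice per b-value.
#' @param b_values numeric vector of diffusion weightings (s/mm^2), one
#'   per slice, at least two distinct.
#' @param roi logical matrix (nx x ny); default all TRUE.
#' @param voxel_size_mm physical voxel size, stored as metadata.
#' @return A `dwi_series` list.
#' @export
dwi_series <- function(signals, b_values, roi = NULL, voxel_size_mm = NA) {
  signals <- if (length(dim(signals)) == 2L) {
    array(signals, dim = c(dim(signals), 1L))
  } else signals
  if (dim(signals)[3L] != length(b_values)) {
    stop("one signal slice per b-value required")
  }
  if (length(unique(b_values)) < 2L) {
    stop("need at least 2 distinct b-values")
  }
  if (is.null(roi)) roi <- matrix(TRUE, dim(signals)[1L], dim(signals)[2L])
  if (!identical(dim(roi), dim(signals)[1:2])) {
    stop("ROI shape must match the signal slices")
  }
  structure(list(signals = signals, b_values = as.numeric(b_values),
                 roi = roi, voxel_size_mm = voxel_size_mm),
            class = "dwi_series")
}

#' Voxel-wise ADC fitting
#'
#' Fits the mono-exponential diffusion model per voxel by ordinary least
#' squares of log signal against b-value, ln S(b) = c - b * ADC. Because
#' normalizing by S0 only shifts the intercept, the regression is run on
#' ln S directly — algebraically identical to fitting ln(S(b)/S0). Voxels
#' with any non-positive signal are outside the domain of the log and are
#' flagged invalid.
#'
#' @param series a [dwi_series()].
#' @return List of class `adc_map` with matrices `adc` (mm^2/s),
#'   `intercept`, and logical `valid`; voxels outside the ROI are NA and
#'   invalid.
#' @export
fit_adc <- function(series) {
  stopifnot(inherits(series, "dwi_series"))
  b <- series$b_values
  dims <- dim(series$signals)[1:2]
  nvox <- prod(dims)
  sig <- matrix(series$signals, nrow = nvox)  # voxels x b
  roi <- as.vector(series$roi)
  valid <- roi & apply(sig > 0, 1L, all)
  if (!any(valid)) stop("all ROI voxels invalid (non-positive signals)")
  bc <- b - mean(b)
  denom <- sum(bc^2)
  adc <- intercept <- rep(NA_real_, nvox)
  lnS <- log(sig[valid, , drop = FALSE])
  slope <- drop(lnS %*% bc) / denom
  adc[valid] <- -slope
  intercept[valid] <- rowMeans(lnS) - slope * mean(b)
  structure(list(adc = matrix(adc, dims[1L], dims[2L]),
                 intercept = matrix(intercept, dims[1L], dims[2L]),
                 valid = matrix(valid, dims[1L], dims[2L]),
                 roi = series$roi),
            class = "adc_map")
}

#' Necrosis classification from an ADC map
#'
#' A voxel is classified necrotic when its apparent diffusion coefficient
#' strictly exceeds the threshold (default 0.0011 mm^2/s); high ADC
#' reflects low cellularity. The necrotic fraction is taken over valid ROI
#' voxels.
#'
#' @param map an `adc_map` from [fit_adc()].
#' @param threshold ADC threshold in mm^2/s; strict inequality.
#' @return List with logical matrix `necrosis` and scalar
#'   `necrotic_fraction`.
#' @export
classify_necrosis <- function(map, threshold = 0.0011) {
  stopifnot(inherits(map, "adc_map"))
  if (!any(map$valid)) stop("no valid voxels")
  necro <- !is.na(map$adc) & map$adc > threshold & map$valid
  list(necrosis = necro,
       necrotic_fraction = sum(necro) / sum(map$valid))
}

#' Median tumor ADC
#'
#' Median over all valid ROI voxels; necrotic voxels are included, so the
#' summary reflects the whole tumor.
#'
#' @param map an `adc_map`.
#' @return Scalar median ADC (mm^2/s).
#' @export
median_adc <- function(map) {
  stopifnot(inherits(map, "adc_map"))
  v <- map$adc[map$valid]
  if (!length(v)) stop("no valid voxels")
  stats::median(v)
}

#' ADC change relative to baseline
#'
#' Expresses per-tumor median ADC time courses relative to day 0 and tests
#' the ratios: a one-sample t-test against 1 per day and group, and a
#' two-sample t-test between groups per day.
#'
#' @param adc data frame with columns `tumor`, `group`, `day`,
#'   `median_adc`; day 0 must be present for every tumor.
#' @return List with `ratios` (per tumor/day), `per_day` (group mean, sem,
#'   one-sample p per day and group), and `between_groups` (two-sample p
#'   per post-baseline day; NA with a note when a group has fewer than two
#'   tumors).
#' @export
relative_adc <- function(adc) {
  need <- c("tumor", "group", "day", "median_adc")
  if (!all(need %in% names(adc))) {
    stop("columns required: ", paste(need, collapse = ", "))
  }
  base <- adc[adc$day == 0, ]
  if (!all(unique(adc$tumor) %in% base$tumor)) stop("missing day-0 baseline")
  if (any(base$median_adc <= 0)) stop("non-positive baseline ADC")
  b <- stats::setNames(base$median_adc, base$tumor)
  ratios <- adc
  ratios$ratio <- adc$median_adc / b[as.character(adc$tumor)]
  per_day <- do.call(rbind, lapply(
    split(ratios, list(ratios$group, ratios$day), drop = TRUE),
    function(d) {
      p <- if (nrow(d) >= 2L && stats::sd(d$ratio) > 0) {
        stats::t.test(d$ratio, mu = 1)$p.value
      } else NA_real_
      data.frame(group = d$group[1L], day = d$day[1L], n = nrow(d),
                 mean_ratio = mean(d$ratio),
                 sem = stats::sd(d$ratio) / sqrt(nrow(d)),
                 p_vs_baseline = p)
    }))
  rownames(per_day) <- NULL
  groups <- unique(ratios$group)
  between <- NULL
  if (length(groups) == 2L) {
    days <- setdiff(sort(unique(ratios$day)), 0)
    between <- do.call(rbind, lapply(days, function(dd) {
      a <- ratios$ratio[ratios$day == dd & ratios$group == groups[1L]]
      c2 <- ratios$ratio[ratios$day == dd & ratios$group == groups[2L]]
      if (length(a) < 2L || length(c2) < 2L) {
        stop("two-sample comparison needs >= 2 tumors per group (day ",
             dd, ")")
      }
      data.frame(day = dd, p = stats::t.test(a, c2)$p.value)
    }))
  }
  list(ratios = ratios, per_day = per_day, between_groups = between)
}

#' Read and write DWI series as multi-page TIFF with a YAML sidecar
#'
#' The signal stack is stored as one 32-bit float page per b-value; the
#' sidecar records the b-values and voxel size. Signals are scaled to
#' \[0, 1\] on write and rescaled on read using the `scale` recorded in
#' the sidecar.
#'
#' @param series a [dwi_series()].
#' @param tiff_path path of the multi-page TIFF.
#' @param yaml_path sidecar path; default replaces the extension with
#'   `.yaml`.
#' @return `read_dwi` returns a [dwi_series()].
#' @export
write_dwi <- function(series, tiff_path, yaml_path = NULL) {
  if (is.null(yaml_path)) yaml_path <- sub("\\.tiff?$", ".yaml", tiff_path)
  scale <- max(series$signals)
  pages <- lapply(seq_along(series$b_values), function(i) {
    series$signals[, , i] / scale
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L)
  yaml::write_yaml(list(b_values = series$b_values,
                        voxel_size_mm = series$voxel_size_mm,
                        scale = scale), yaml_path)
  invisible(tiff_path)
}

#' @rdname write_dwi
#' @param roi optional ROI mask to attach on read.
#' @export
read_dwi <- function(tiff_path, yaml_path = NULL, roi = NULL) {
  if (is.null(yaml_path)) yaml_path <- sub("\\.tiff?$", ".yaml", tiff_path)
  meta <- yaml::read_yaml(yaml_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  sig <- array(unlist(pages), dim = c(dim(pages[[1L]]), length(pages)))
  dwi_series(sig * meta$scale, meta$b_values, roi = roi,
             voxel_size_mm = meta$voxel_size_mm)
}
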