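#' Standard H-DAB stain vectors
#'
#' Ruifrok-Johnston optical-density vectors for hematoxylin and DAB, with
#' the residual channel completed as the normalized cross product, as a
#' 3 x 3 matrix whose columns are unit stain vectors in RGB OD space.
#'
#' @return 3 x 3 numeric matrix, columns `hematoxylin`, `dab`, `residual`.
#' @export
hdab_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.777)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  m <- cbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  rownames(m) <- c("r", "g", "b")
  m
}

#' Render stain concentrations to an RGB image (forward model)
#'
#' Beer-Lambert forward model: per-channel intensity is
#' 255 * 10^(-OD) with OD the stain matrix applied to the concentration
#' maps. Used by the synthetic-histology generator so that color
#' deconvolution is its exact inverse in the noiseless case.
#'
#' @param conc_h,conc_d matrices of hematoxylin and DAB concentrations
#'   (optical-density units).
#' @param stains stain matrix, default [hdab_stain_matrix()].
#' @param quantize round to 8-bit integers (default FALSE keeps exact
#'   float values).
#' @return Array (nx x ny x 3) of RGB values in \[0, 255\].
#' @export
render_stains <- function(conc_h, conc_d, stains = hdab_stain_matrix(),
                          quantize = FALSE) {
  stopifnot(identical(dim(conc_h), dim(conc_d)))
  conc <- rbind(as.vector(conc_h), as.vector(conc_d),
                rep(0, length(conc_h)))
  od <- stains %*% conc  # 3 x npix
  img <- 255 * 10^(-od)
  if (quantize) img <- round(img)
  array(t(img), dim = c(dim(conc_h), 3L))
}

#' Color deconvolution of an H-DAB image
#'
#' Ruifrok-Johnston unmixing: per-pixel optical density
#' OD = -log10((I + eps)/255) is solved against the stain matrix to
#' recover per-stain concentrations; negative unmixed values are clipped
#' to zero.
#'
#' @param img RGB array (nx x ny x 3), values in \[0, 255\].
#' @param stains stain matrix (columns = stain OD vectors); must be
#'   invertible.
#' @param eps offset guarding log of zero (default 1e-6 on the 0-255
#'   scale).
#' @return List of concentration matrices `hematoxylin`, `dab`,
#'   `residual`.
#' @export
color_deconvolve <- function(img, stains = hdab_stain_matrix(),
                             eps = 1e-6) {
  if (length(dim(img)) != 3L || dim(img)[3L] != 3L) {
    stop("img must be an nx x ny x 3 RGB array")
  }
  if (abs(det(stains)) < 1e-12) stop("singular stain matrix")
  dims <- dim(img)[1:2]
  od <- -log10((pmax(matrix(img, ncol = 3L), 0) + eps) / 255)
  conc <- t(solve(stains, t(od)))  # npix x 3
  conc[conc < 0] <- 0
  list(hematoxylin = matrix(conc[, 1L], dims[1L], dims[2L]),
       dab = matrix(conc[, 2L], dims[1L], dims[2L]),
       residual = matrix(conc[, 3L], dims[1L], dims[2L]))
}

#' Threshold segmentation of a stain channel
#'
#' Binary mask of pixels with channel intensity strictly above a manually
#' chosen threshold, restricted to the ROI.
#'
#' @param channel numeric matrix (e.g. the DAB concentration).
#' @param threshold scalar threshold.
#' @param roi optional logical ROI matrix.
#' @return Logical matrix.
#' @export
segment_by_threshold <- function(channel, threshold, roi = NULL) {
  mask <- channel > threshold
  if (!is.null(roi)) mask <- mask & roi
  mask
}

#' Area-fraction metrics on mask sets
#'
#' `necrotic_fraction_mask`: necrotic area relative to the ROI.
#' `hypoxic_fraction_mask` and `gfp_area_fraction`: stained area relative
#' to the viable ROI (ROI after exclusion of necrosis).
#'
#' @param mask logical matrix of the stain-positive region.
#' @param roi logical ROI matrix.
#' @param necrosis logical necrosis matrix.
#' @return Scalar fraction in \[0, 1\].
#' @export
necrotic_fraction_mask <- function(mask, roi) {
  if (!any(roi)) stop("empty ROI")
  sum(mask & roi) / sum(roi)
}

#' @rdname necrotic_fraction_mask
#' @export
hypoxic_fraction_mask <- function(mask, roi, necrosis) {
  viable <- roi & !necrosis
  if (!any(viable)) stop("viable ROI area is zero")
  sum(mask & viable) / sum(viable)
}

#' @rdname necrotic_fraction_mask
#' @export
gfp_area_fraction <- function(mask, roi, necrosis) {
  hypoxic_fraction_mask(mask, roi, necrosis)
}

# 8-connected component labelling (EBImage's bwlabel is 4-connected).
# Builds the pixel adjacency graph over foreground pixels and labels its
# connected components.
label_components8 <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask)
  if (!length(idx)) return(matrix(0L, dims[1L], dims[2L]))
  pos <- matrix(0L, dims[1L], dims[2L])
  pos[idx] <- seq_along(idx)
  row <- (idx - 1L) %% dims[1L] + 1L
  col <- (idx - 1L) %/% dims[1L] + 1L
  edges <- list()
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (off in offsets) {
    r2 <- row + off[1L]; c2 <- col + off[2L]
    ok <- r2 >= 1L & r2 <= dims[1L] & c2 >= 1L & c2 <= dims[2L]
    nb <- pos[cbind(r2[ok], c2[ok])]
    here <- pos[idx][ok]
    keep <- nb > 0L
    edges[[length(edges) + 1L]] <- cbind(here[keep], nb[keep])
  }
  ed <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(rbind(ed, cbind(seq_along(idx),
                                                   seq_along(idx))),
                                   directed = FALSE)
  comp <- igraph::components(g)$membership
  out <- matrix(0L, dims[1L], dims[2L])
  out[idx] <- as.integer(comp)
  out
}

#' Nucleus segmentation with watershed splitting of clusters
#'
#' Thresholds the DAB channel, labels 8-connected components, and splits
#' components larger than `cluster_area_px` (assumed to be touching-cell
#' clusters) by watershed on the Euclidean distance transform (with 1-px
#' h-maxima suppression to avoid oversegmentation). Nuclei whose centroid
#' falls in the necrosis mask are removed, and only nuclei with centroid
#' inside the parenchyma mask are retained.
#'
#' @param dab numeric DAB-concentration matrix (or a logical mask, used
#'   as-is when `threshold` is NULL).
#' @param threshold intensity threshold for nucleus-positive pixels.
#' @param cluster_area_px components above this area are watershed-split
#'   (default 200).
#' @param necrosis optional logical mask of necrotic areas.
#' @param parenchyma optional logical mask of tumor parenchyma
#'   (GFP-positive region from the adjacent section).
#' @return List with integer `labels` matrix, `count`, and `centroids`
#'   (data frame label/x/y).
#' @export
segment_nuclei <- function(dab, threshold = NULL, cluster_area_px = 200,
                           necrosis = NULL, parenchyma = NULL) {
  mask <- if (is.null(threshold)) dab > 0 else dab > threshold
  lab <- label_components8(mask)
  nlab <- max(lab)
  out <- matrix(0L, nrow(mask), ncol(mask))
  next_id <- 0L
  for (i in seq_len(nlab)) {
    comp <- lab == i
    area <- sum(comp)
    if (area > cluster_area_px) {
      dm <- EBImage::distmap(EBImage::Image(comp * 1))
      ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
      wsm <- EBImage::imageData(ws)
      for (j in seq_len(max(wsm))) {
        next_id <- next_id + 1L
        out[wsm == j] <- next_id
      }
    } else {
      next_id <- next_id + 1L
      out[comp] <- next_id
    }
  }
  if (next_id == 0L) {
    return(list(labels = out, count = 0L,
                centroids = data.frame(label = integer(), x = numeric(),
                                       y = numeric())))
  }
  cent <- do.call(rbind, lapply(seq_len(next_id), function(j) {
    w <- which(out == j, arr.ind = TRUE)
    data.frame(label = j, x = mean(w[, 1L]), y = mean(w[, 2L]))
  }))
  in_mask <- function(mask, cent) {
    mask[cbind(pmin(pmax(round(cent$x), 1L), nrow(mask)),
               pmin(pmax(round(cent$y), 1L), ncol(mask)))]
  }
  keep <- rep(TRUE, nrow(cent))
  if (!is.null(necrosis)) keep <- keep & !in_mask(necrosis, cent)
  if (!is.null(parenchyma)) keep <- keep & in_mask(parenchyma, cent)
  drop_ids <- cent$label[!keep]
  out[out %in% drop_ids] <- 0L
  cent <- cent[keep, , drop = FALSE]
  rownames(cent) <- NULL
  list(labels = out, count = nrow(cent), centroids = cent)
}

#' Cell density per GFP-positive area
#'
#' Number of segmented Ki-67-positive nuclei per mm^2 of GFP-positive
#' (parenchymal) area.
#'
#' @param count nucleus count.
#' @param gfp_mask logical GFP-positive mask.
#' @param pixel_size_um pixel edge length in micrometers (default 0.46).
#' @return Density in nuclei per mm^2.
#' @export
cell_density <- function(count, gfp_mask, pixel_size_um = 0.46) {
  area_mm2 <- sum(gfp_mask) * (pixel_size_um / 1000)^2
  if (area_mm2 <= 0) stop("zero GFP-positive area")
  count / area_mm2
}

#' Full histology metrics for one tumor section set
#'
#' Convenience wrapper producing the per-section metric set: necrotic
#' fraction, hypoxic fraction, GFP area fraction, nucleus count and cell
#' density, from deconvolved masks of adjacent sections sharing one ROI.
#'
#' @param roi,necrosis,hypoxia,gfp logical masks.
#' @param ki67_dab DAB channel (or mask) of the Ki-67 section.
#' @param dab_threshold threshold for nucleus segmentation.
#' @param cluster_area_px watershed-splitting area rule.
#' @param pixel_size_um pixel size in micrometers.
#' @return One-row data frame of the five metrics.
#' @export
histo_metrics <- function(roi, necrosis, hypoxia, gfp, ki67_dab,
                          dab_threshold = NULL, cluster_area_px = 200,
                          pixel_size_um = 0.46) {
  seg <- segment_nuclei(ki67_dab, dab_threshold, cluster_area_px,
                        necrosis = necrosis, parenchyma = gfp)
  data.frame(
    necrotic_fraction = necrotic_fraction_mask(necrosis, roi),
    hypoxic_fraction = hypoxic_fraction_mask(hypoxia, roi, necrosis),
    gfp_fraction = gfp_area_fraction(gfp, roi, necrosis),
    nucleus_count = seg$count,
    cell_density = cell_density(seg$count, gfp, pixel_size_um))
}
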