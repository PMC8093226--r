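# Resolution normalization and lumen segmentation. The classical baseline
# (stain deconvolution + Otsu on luminance + morphology) stands behind a
# pluggable interface: any function mapping (image, region, cfg) to a label
# mask can be swapped in, and ground-truth masks can bypass segmentation
# entirely.

#' Rescale a region image to the 1 um/px analysis resolution
#'
#' Bilinear interpolation; output `microns_per_pixel` is exactly the target.
#' An image already at the target resolution is returned unchanged.
#'
#' @param img a [region_image()].
#' @param target_mpp target resolution (default 1.0 um/px).
#' @return A [region_image()] at `target_mpp`.
#' @export
rescale_to_analysis_resolution <- function(img, target_mpp = 1.0) {
  stopifnot(inherits(img, "region_image"))
  mpp <- img$microns_per_pixel
  if (mpp <= 0) stop("microns_per_pixel must be positive")
  if (mpp == target_mpp) return(img)
  d <- dim(img$pixels)
  new_h <- max(round(d[1] * mpp / target_mpp), 1)
  new_w <- max(round(d[2] * mpp / target_mpp), 1)
  out <- array(0, c(new_h, new_w, 3))
  for (ch in 1:3) {
    out[, , ch] <- as.matrix(EBImage::resize(
      EBImage::Image(img$pixels[, , ch]), w = new_h, h = new_w))
  }
  out <- pmin(pmax(out, 0), 1)
  region_image(out, target_mpp, img$region_id, img$site)
}

#' Ruifrok-Johnston H&E stain deconvolution
#'
#' Projects optical densities onto the standard hematoxylin / eosin /
#' residual stain vectors.
#'
#' @param img h x w x 3 RGB array in \[0, 1\].
#' @return List of three matrices: `hematoxylin`, `eosin`, `residual`
#'   (optical-density units).
#' @export
stain_deconvolve <- function(img) {
  M <- rbind(c(0.650, 0.704, 0.286),   # hematoxylin
             c(0.072, 0.990, 0.105),   # eosin
             c(0.268, 0.570, 0.776))   # residual
  M <- M / sqrt(rowSums(M^2))
  Minv <- solve(t(M))
  od <- -log10(pmax(img, 1 / 255))
  d <- dim(img)
  odm <- matrix(od, ncol = 3)
  stains <- odm %*% Minv
  list(hematoxylin = matrix(stains[, 1], d[1], d[2]),
       eosin = matrix(stains[, 2], d[1], d[2]),
       residual = matrix(stains[, 3], d[1], d[2]))
}

# Otsu threshold on a numeric vector in [0, 1].
otsu_threshold <- function(v, n_bins = 256L) {
  h <- tabulate(pmin(floor(v * n_bins) + 1L, n_bins), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  (which.max(sb2) - 0.5) / n_bins
}

#' Segment gland lumens in a region image (classical baseline)
#'
#' Lumens appear near-white (low stain density, high luminance). The
#' baseline thresholds luminance inside the annotation by Otsu's method,
#' applies a morphological opening and hole filling, labels connected
#' components, and removes components below the minimum area or with
#' centroids outside the region.
#'
#' @param img a [region_image()] at 1 um/px.
#' @param region annotation polygon (microns).
#' @param cfg `segmentation` section of [default_config()].
#' @return Integer label mask (components labeled 1..K).
#' @export
segment_lumens <- function(img, region, cfg = default_config()$segmentation) {
  stopifnot(inherits(img, "region_image"))
  if (abs(img$microns_per_pixel - cfg$analysis_mpp) > 1e-9)
    stop("image must be at the analysis resolution; call ",
         "rescale_to_analysis_resolution() first")
  lum <- rgb_luminance(img$pixels)
  inr <- rasterize_polygon(region, nrow(lum), ncol(lum), img$microns_per_pixel)
  if (mean(inr) < cfg$min_region_fraction) {
    warning("annotation covers < ", 100 * cfg$min_region_fraction,
            "% of the image; returning empty mask")
    return(matrix(0L, nrow(lum), ncol(lum)))
  }
  thr <- otsu_threshold(lum[inr])
  # guard for regions with no true bimodality (e.g. no lumens at all):
  # require candidate pixels to be bright in absolute terms as well
  cand <- inr & (lum > thr) & (lum > 0.75)
  if (!any(cand)) return(matrix(0L, nrow(lum), ncol(lum)))
  bin <- EBImage::Image(cand * 1)
  # opening by reconstruction: erosion flags speckle smaller than the brush,
  # but components that survive are restored pixel-exactly (a plain opening
  # would round every boundary and bias the high-order shape harmonics)
  brush <- EBImage::makeBrush(2 * cfg$opening_radius_px + 1, shape = "disc")
  core <- EBImage::erode(bin, brush)
  lab0 <- EBImage::bwlabel(bin)
  survivors <- setdiff(unique(as.integer(lab0)[as.integer(core) > 0]), 0L)
  bin <- EBImage::Image((matrix(as.integer(lab0), nrow(lum)) %in% survivors) * 1,
                        dim = dim(lab0))
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  lab <- matrix(as.integer(lab), nrow(lum), ncol(lum))
  filter_label_mask(lab, region, img$microns_per_pixel, cfg$min_area_um2)
}

# Drop small components and components with centroids outside the region;
# relabel compactly as 1..K.
filter_label_mask <- function(lab, region, mpp, min_area_um2) {
  if (max(lab) == 0L) return(lab)
  keep <- integer(0)
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) * mpp^2 < min_area_um2) next
    ctr_um <- c((mean(idx[, 2]) - 0.5) * mpp, (mean(idx[, 1]) - 0.5) * mpp)
    if (!points_in_polygon(matrix(ctr_um, ncol = 2), region)) next
    keep <- c(keep, k)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Vectorize a label mask into a lumen set
#'
#' Traces the 0.5-level contour of each label (linear interpolation on the
#' padded binary image), giving polygons whose area tracks the pixel count
#' to within ~2% for components of >= 100 px. Labels with fewer than 4
#' boundary pixels are dropped with a message; membership of border-touching
#' components is decided by the centroid-in-region rule.
#'
#' @param mask integer label matrix at `mpp` um/px.
#' @param region annotation polygon (microns).
#' @param mpp microns per pixel.
#' @param source provenance tag for the resulting [lumen_set()].
#' @param region_id identifier.
#' @return A [lumen_set()].
#' @export
mask_to_lumens <- function(mask, region, mpp = 1, source = "mask",
                           region_id = NULL) {
  lum <- list()
  ks <- setdiff(sort(unique(as.integer(mask))), 0L)
  for (k in ks) {
    cc <- label_contour(mask, k, mpp)
    if (is.null(cc)) {
      message("label ", k, " has too few boundary pixels; dropped")
      next
    }
    ctr <- polygon_centroid(cc)
    if (!points_in_polygon(matrix(ctr, ncol = 2), region)) next
    lum[[length(lum) + 1L]] <- cc
  }
  lumen_set(region, lum, source = source, region_id = region_id,
            validate = FALSE)
}

# 0.5-level contour of one label as a micron-coordinate polygon.
label_contour <- function(mask, k, mpp) {
  bin <- (mask == k) * 1
  if (sum(bin) < 4) return(NULL)
  idx <- which(bin == 1, arr.ind = TRUE)
  r0 <- max(min(idx[, 1]) - 2L, 0L); r1 <- min(max(idx[, 1]) + 2L, nrow(bin))
  c0 <- max(min(idx[, 2]) - 2L, 0L); c1 <- min(max(idx[, 2]) + 2L, ncol(bin))
  sub <- bin[(r0 + 1L):r1, (c0 + 1L):c1, drop = FALSE]
  padded <- matrix(0, nrow(sub) + 2L, ncol(sub) + 2L)
  padded[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  # grid coordinates of pixel centers in microns:
  # padded row i corresponds to original row (r0 + i - 1), center (r - 0.5) mpp
  ys <- (r0 + seq_len(nrow(padded)) - 1.5) * mpp
  xs <- (c0 + seq_len(ncol(padded)) - 1.5) * mpp
  cl <- grDevices::contourLines(ys, xs, padded, levels = 0.5)
  if (length(cl) == 0) return(NULL)
  lens <- vapply(cl, function(ci) length(ci$x), numeric(1))
  ring <- cl[[which.max(lens)]]
  poly <- cbind(x = ring$y, y = ring$x)
  if (nrow(poly) > 1 && all(poly[1, ] == poly[nrow(poly), ]))
    poly <- poly[-nrow(poly), , drop = FALSE]
  if (nrow(poly) < 4) return(NULL)
  polygon_ccw(poly)
}

#' Per-lumen intersection-over-union between two label masks
#'
#' Matches each reference label to the test label with maximal overlap.
#' @param truth,test integer label masks of equal size.
#' @return Numeric vector of IoU values, one per reference label.
#' @export
mask_iou <- function(truth, test) {
  ks <- setdiff(sort(unique(as.integer(truth))), 0L)
  vapply(ks, function(k) {
    tk <- truth == k
    cand <- test[tk]
    cand <- cand[cand != 0L]
    if (length(cand) == 0) return(0)
    m <- as.integer(names(which.max(table(cand))))
    sm <- test == m
    sum(tk & sm) / sum(tk | sm)
  }, numeric(1))
}
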