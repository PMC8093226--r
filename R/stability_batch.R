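# Cross-site feature stability filtering (on non-cancerous regions),
# slide-level image-quality metrics, and the batch-effect embedding audit.

#' Cross-site feature stability filter
#'
#' For each feature, computes the two-sample Kolmogorov-Smirnov statistic
#' for every pair of sites (rank-based, so invariant to monotone rescaling
#' applied identically to all sites) and drops the feature when the maximum
#' pairwise statistic exceeds `tau`. Intended to run on features extracted
#' from non-cancerous regions, so distributional differences reflect
#' pre-analytic site effects rather than biology.
#'
#' @param features matrix (regions x features).
#' @param site_labels site label per region.
#' @param tau KS statistic threshold (default 0.4).
#' @param min_per_site sites with fewer usable regions are excluded with a
#'   warning (default 10).
#' @return List of class `stability_report`: `decisions` data.frame
#'   (feature, max_ks, keep), `keep` (character vector), `sites_used`,
#'   `tau`.
#' @export
stability_filter <- function(features, site_labels, tau = 0.4,
                             min_per_site = 10L) {
  site_labels <- as.character(site_labels)
  stopifnot(nrow(features) == length(site_labels))
  tab <- table(site_labels)
  usable <- names(tab)[tab >= min_per_site]
  dropped_sites <- setdiff(names(tab), usable)
  if (length(dropped_sites) > 0)
    warning("site(s) with < ", min_per_site, " regions excluded: ",
            paste(dropped_sites, collapse = ", "))
  if (length(usable) < 2)
    stop("need at least 2 sites with >= ", min_per_site, " regions")
  pairs <- utils::combn(usable, 2)
  max_ks <- vapply(seq_len(ncol(features)), function(j) {
    v <- features[, j]
    ks <- apply(pairs, 2, function(pr) {
      a <- v[site_labels == pr[1]]; a <- a[is.finite(a)]
      b <- v[site_labels == pr[2]]; b <- b[is.finite(b)]
      if (length(a) == 0 || length(b) == 0) return(NA_real_)
      ks_statistic(a, b)
    })
    if (all(is.na(ks))) NA_real_ else max(ks, na.rm = TRUE)
  }, numeric(1))
  nms <- colnames(features) %||% sprintf("f%03d", seq_len(ncol(features)))
  keep <- is.na(max_ks) | max_ks <= tau
  if (!any(keep)) stop("stability filter dropped every feature")
  structure(list(
    decisions = data.frame(feature = nms, max_ks = max_ks, keep = keep,
                           stringsAsFactors = FALSE),
    keep = nms[keep], sites_used = usable, tau = tau),
    class = "stability_report")
}

# Two-sample KS statistic: sup |ECDF_a - ECDF_b|.
ks_statistic <- function(a, b) {
  g <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(g)
  fb <- stats::ecdf(b)(g)
  max(abs(fa - fb))
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d/%d features kept (tau = %.2f, sites: %s)\n",
              length(x$keep), nrow(x$decisions), x$tau,
              paste(x$sites_used, collapse = ", ")))
  invisible(x)
}

IMAGE_METRIC_NAMES <- c(
  "gray_mean", "gray_sd", "rms_contrast", "michelson_contrast", "gray_entropy",
  "red_mean", "red_sd", "green_mean", "green_sd", "blue_mean", "blue_sd",
  "hue_circ_mean", "hue_circ_sd", "sat_mean", "sat_sd", "val_mean", "val_sd",
  "hema_mean", "hema_sd", "hema_pos_frac",
  "eosin_mean", "eosin_sd", "eosin_pos_frac", "residual_mean",
  "edge_density", "laplacian_var", "tissue_fraction", "background_fraction",
  "saturated_white_fraction"
)

#' Slide-level image-quality metrics (29 metrics)
#'
#' Brightness/contrast, per-channel color, HSV, stain-deconvolution
#' intensities, and sharpness/background metrics. The list is fixed: always
#' 29 finite values for a valid RGB input.
#'
#' @param img a [region_image()] or h x w x 3 array in \[0, 1\].
#' @return Named numeric vector of length 29.
#' @export
image_metrics <- function(img) {
  px <- if (inherits(img, "region_image")) img$pixels else img
  if (length(dim(px)) != 3 || dim(px)[3] != 3)
    stop("image_metrics requires an RGB image")
  g <- rgb_luminance(px)
  n <- length(g)
  h <- tabulate(pmin(floor(g * 256) + 1L, 256L), nbins = 256L) / n
  ent <- -sum(ifelse(h > 0, h * log2(h), 0))
  mx <- max(g); mn <- min(g)
  mich <- if (mx + mn > 0) (mx - mn) / (mx + mn) else 0
  hsv <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                  as.vector(px[, , 3])), maxColorValue = 1)
  ang <- hsv[1, ] * 2 * pi
  cbar <- mean(cos(ang)); sbar <- mean(sin(ang))
  hue_mean <- (atan2(sbar, cbar) / (2 * pi)) %% 1
  R <- sqrt(cbar^2 + sbar^2)
  hue_sd <- sqrt(pmax(-2 * log(max(R, 1e-12)), 0))
  st <- stain_deconvolve(px)
  sobel_x <- rbind(c(-1, 0, 1), c(-2, 0, 2), c(-1, 0, 1))
  gx <- conv2_same(g, sobel_x)
  gy <- conv2_same(g, t(sobel_x))
  grad <- sqrt(gx^2 + gy^2)
  lap <- conv2_same(g, rbind(c(0, 1, 0), c(1, -4, 1), c(0, 1, 0)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  out <- c(
    gray_mean = mean(g), gray_sd = stats::sd(as.vector(g)),
    rms_contrast = pop_sd(as.vector(g)), michelson_contrast = mich,
    gray_entropy = ent,
    red_mean = mean(px[, , 1]), red_sd = stats::sd(as.vector(px[, , 1])),
    green_mean = mean(px[, , 2]), green_sd = stats::sd(as.vector(px[, , 2])),
    blue_mean = mean(px[, , 3]), blue_sd = stats::sd(as.vector(px[, , 3])),
    hue_circ_mean = hue_mean, hue_circ_sd = hue_sd,
    sat_mean = mean(hsv[2, ]), sat_sd = stats::sd(hsv[2, ]),
    val_mean = mean(hsv[3, ]), val_sd = stats::sd(hsv[3, ]),
    hema_mean = mean(st$hematoxylin), hema_sd = stats::sd(as.vector(st$hematoxylin)),
    hema_pos_frac = mean(st$hematoxylin > 0.15),
    eosin_mean = mean(st$eosin), eosin_sd = stats::sd(as.vector(st$eosin)),
    eosin_pos_frac = mean(st$eosin > 0.15),
    residual_mean = mean(st$residual),
    edge_density = mean(grad > 0.25),
    laplacian_var = stats::var(as.vector(lap)),
    tissue_fraction = mean(g < 0.8),
    background_fraction = mean(g >= 0.9),
    saturated_white_fraction = mean(px[, , 1] > 0.98 & px[, , 2] > 0.98 &
                                      px[, , 3] > 0.98)
  )
  stats::setNames(out, IMAGE_METRIC_NAMES)
}

# Same-size 2-D convolution with zero padding (small kernels).
conv2_same <- function(m, k) {
  kr <- nrow(k); kc <- ncol(k)
  pr <- (kr - 1) %/% 2; pc <- (kc - 1) %/% 2
  mp <- matrix(0, nrow(m) + 2 * pr, ncol(m) + 2 * pc)
  mp[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))] <- m
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(kr)) for (j in seq_len(kc)) {
    out <- out + k[i, j] *
      mp[(i - 1) + seq_len(nrow(m)), (j - 1) + seq_len(ncol(m))]
  }
  out
}

#' Batch-effect embedding audit
#'
#' Standardizes the feature matrix, embeds it in two dimensions with a
#' deterministic principal-component projection, and scores site clustering
#' by the mean silhouette width of the site labels in the embedding. A high
#' mixing score means site clustering (batch effect); a value near zero or
#' negative means the sites mix well.
#'
#' @param x matrix (patients x features), n >= 20.
#' @param site_labels site label per row.
#' @param seed accepted for interface stability; the embedding is
#'   deterministic.
#' @return List: `embedding` (n x 2), `mixing_score` (mean silhouette).
#' @export
audit_embedding <- function(x, site_labels, seed = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 20) stop("need at least 20 rows for the audit")
  ok <- apply(x, 2, function(v) all(is.finite(v)) && stats::sd(v) > 0)
  if (!any(ok)) stop("constant (or non-finite) feature matrix")
  xs <- scale(x[, ok, drop = FALSE])
  pc <- stats::prcomp(xs, rank. = 2, center = FALSE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  # deterministic sign convention
  for (j in 1:2) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) emb[, j] <- -emb[, j]
  }
  colnames(emb) <- c("dim1", "dim2")
  list(embedding = emb,
       mixing_score = silhouette_score(emb, site_labels))
}

# Mean silhouette width of labels in embedding space.
silhouette_score <- function(emb, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(f), stats::dist(emb))
  mean(sil[, "sil_width"])
}
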