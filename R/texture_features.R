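# Haralick texture on the annotated tumor region, disregarding the lumen
# segmentation: luminance quantized to 32 gray levels within the region,
# symmetric normalized GLCMs at distance 1 for angles {0, 45, 90, 135}
# degrees, the 13 classical second-order statistics, summarized as the
# per-statistic mean and range across angles (26 features).

HARALICK_STAT_NAMES <- c(
  "asm", "contrast", "correlation", "variance", "idm",
  "sum_average", "sum_variance", "sum_entropy", "entropy",
  "diff_variance", "diff_entropy", "imc1", "imc2"
)

#' Rec. 601 luminance of an RGB array
#' @param img h x w x 3 array in \[0, 1\].
#' @return Matrix in \[0, 1\].
#' @export
rgb_luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Gray-level co-occurrence matrix for one offset
#'
#' Counts pairs (q\[i, j\], q\[i + dr, j + dc\]) where both pixels carry a
#' level (NA marks pixels outside the region); symmetrized and normalized to
#' sum 1.
#'
#' @param q integer matrix of gray levels 1..n_levels, NA outside the region.
#' @param dr,dc row/column offset.
#' @param n_levels number of gray levels.
#' @return n_levels x n_levels matrix summing to 1 (or all zero if no pairs).
#' @export
glcm <- function(q, dr, dc, n_levels = 32L) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  counts <- matrix(tabulate((a[ok] - 1L) * n_levels + b[ok],
                            nbins = n_levels * n_levels),
                   n_levels, n_levels, byrow = TRUE)
  m <- counts + t(counts)
  m / sum(m)
}

#' The 13 classical Haralick statistics of a normalized GLCM
#'
#' Entropies use the natural logarithm with the 0 log 0 = 0 convention;
#' correlation is 0 by convention when a marginal variance vanishes.
#'
#' @param p normalized symmetric GLCM.
#' @return Named numeric vector of 13 statistics.
#' @export
haralick_stats <- function(p) {
  L <- nrow(p)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  px <- rowSums(p); py <- colSums(p)
  mx <- sum(seq_len(L) * px); my <- sum(seq_len(L) * py)
  sx <- sqrt(sum((seq_len(L) - mx)^2 * px))
  sy <- sqrt(sum((seq_len(L) - my)^2 * py))
  xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
  # p_{x+y}(k), k = 2..2L ; p_{x-y}(k), k = 0..L-1
  sidx <- as.vector(i + j)
  pxy_sum <- vapply(2:(2 * L), function(k) sum(p[sidx == k]), numeric(1))
  didx <- as.vector(abs(i - j))
  pxy_diff <- vapply(0:(L - 1), function(k) sum(p[didx == k]), numeric(1))
  asm <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (sx * sy > 0) (sum(i * j * p) - mx * my) / (sx * sy) else 0
  variance <- sum((i - mx)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))
  ks <- 2:(2 * L)
  sum_average <- sum(ks * pxy_sum)
  sum_variance <- sum((ks - sum_average)^2 * pxy_sum)
  sum_entropy <- -sum(xlogx(pxy_sum))
  entropy <- -sum(xlogx(p))
  kd <- 0:(L - 1)
  diff_mean <- sum(kd * pxy_diff)
  diff_variance <- sum((kd - diff_mean)^2 * pxy_diff)
  diff_entropy <- -sum(xlogx(pxy_diff))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pij_marg <- outer(px, py)
  hxy1 <- -sum(ifelse(pij_marg > 0, p * log(pij_marg), 0))
  hxy2 <- -sum(xlogx(pij_marg))
  imc1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  stats::setNames(c(asm, contrast, correlation, variance, idm, sum_average,
                    sum_variance, sum_entropy, entropy, diff_variance,
                    diff_entropy, imc1, imc2), HARALICK_STAT_NAMES)
}

#' Haralick texture feature block (26 features)
#'
#' Luminance within the annotation polygon is quantized to `n_levels` gray
#' levels; GLCMs are computed at distance 1 for the four standard angles;
#' each of the 13 statistics is summarized by its mean and range across
#' angles. Names follow `haralick:<mean|range>:<stat>`.
#'
#' @param img h x w x 3 RGB array in \[0, 1\] at 1 um/px (or a matrix already
#'   in luminance).
#' @param region annotation polygon in microns.
#' @param mpp microns per pixel of `img`.
#' @param cfg `texture` section of [default_config()].
#' @return Named numeric vector of length 26 (sentinels when the region is
#'   smaller than the configured minimum).
#' @export
haralick_block <- function(img, region, mpp = 1,
                           cfg = default_config()$texture) {
  nms <- as.vector(vapply(HARALICK_STAT_NAMES, function(s)
    paste("haralick", c("mean", "range"), s, sep = ":"), character(2)))
  out <- stats::setNames(rep(NA_real_, 26), nms)
  if (is.null(img)) return(out)
  if (polygon_area(region) < cfg$min_region_um2) return(out)
  g <- if (length(dim(img)) == 3) rgb_luminance(img) else img
  inr <- rasterize_polygon(region, nrow(g), ncol(g), mpp)
  vals <- g[inr]
  if (length(vals) < 4) return(out)
  rng <- range(vals)
  L <- cfg$n_levels
  if (diff(rng) < .Machine$double.eps) {
    q0 <- matrix(NA_integer_, nrow(g), ncol(g))
    q0[inr] <- 1L
  } else {
    lev <- pmin(floor((g - rng[1]) / diff(rng) * L) + 1L, L)
    q0 <- matrix(NA_integer_, nrow(g), ncol(g))
    q0[inr] <- lev[inr]
  }
  d <- cfg$distance_px
  # angles in image coordinates: 0 deg = along a row, 90 deg = up a column
  offsets <- list(c(0, d), c(-d, d), c(-d, 0), c(-d, -d))
  stats4 <- vapply(offsets, function(o)
    haralick_stats(glcm(q0, o[1], o[2], L)), numeric(13))
  for (s in HARALICK_STAT_NAMES) {
    v <- stats4[s, ]
    out[paste0("haralick:mean:", s)] <- mean(v)
    out[paste0("haralick:range:", s)] <- max(v) - min(v)
  }
  out
}
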