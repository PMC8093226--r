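# Per-lumen shape descriptors and their cohort aggregation. Each lumen
# contributes 24 dimensionless descriptors; the region-level block aggregates
# each with {mean, sd, median, p5/p95 ratio} giving 96 features.

SHAPE_DESCRIPTOR_NAMES <- c(
  paste0("fd", 1:10),
  paste0("hu", 1:7),
  "distance_ratio", "radius_sd_ratio", "area_ratio", "perimeter_ratio",
  "smoothness", "fractal_dim", "circularity"
)

AGG_STAT_NAMES <- c("mean", "sd", "median", "p5_p95_ratio")

#' Resample a polygon boundary at equal arclength
#'
#' Produces the centroid-distance signal on which the Fourier descriptors are
#' computed. Orientation is normalized counterclockwise (positive shoelace
#' area) and the centroid is the polygon area centroid.
#'
#' @param poly two-column vertex matrix (microns, open ring).
#' @param n number of samples (default 128).
#' @return List of class `boundary_signal`: `points` (n x 2), `centroid`,
#'   `radii` (length n).
#' @export
resample_boundary <- function(poly, n = 128L, check = TRUE) {
  if (!is.matrix(poly) || nrow(poly) < 3)
    stop("polygon must have at least 3 vertices")
  if (check && !polygon_is_simple(poly))
    stop("polygon is self-intersecting")
  poly <- polygon_ccw(poly)
  per <- polygon_perimeter(poly)
  if (per <= 0) stop("polygon perimeter must be positive")
  m <- nrow(poly)
  seg <- poly[c(2:m, 1), , drop = FALSE] - poly
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  s <- (seq_len(n) - 1) * per / n
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx > m] <- m
  t <- (s - cum[idx]) / seglen[idx]
  t[!is.finite(t)] <- 0
  pts <- poly[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
  ctr <- polygon_centroid(poly)
  radii <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  if (any(radii <= 0)) stop("degenerate boundary: zero radius")
  structure(list(points = pts, centroid = ctr, radii = radii),
            class = "boundary_signal")
}

#' Fourier descriptors of the centroid-distance signal
#'
#' FD_k = |F_k| / |F_0| for harmonics k = 1..n_fd of the DFT of the radius
#' signal r(t). Normalization by the DC component gives scale invariance;
#' taking magnitudes gives rotation and starting-point invariance.
#'
#' @param b a `boundary_signal` from [resample_boundary()].
#' @param n_fd number of descriptors (default 10).
#' @return Named numeric vector fd1..fd_n.
#' @export
fourier_descriptors <- function(b, n_fd = 10L) {
  r <- b$radii
  f <- stats::fft(r)
  dc <- Mod(f[1])
  if (dc <= .Machine$double.eps) stop("zero mean radius")
  fd <- Mod(f[1 + seq_len(n_fd)]) / dc
  stats::setNames(fd, paste0("fd", seq_len(n_fd)))
}

#' Central moments of a filled polygon up to order 3 (exact)
#'
#' Green's-theorem closed forms on the vertex list; exact for the polygon,
#' so the derived Hu moments are rotation invariant to machine precision.
#' @keywords internal
polygon_central_moments <- function(poly) {
  poly <- polygon_ccw(poly)
  ctr <- polygon_centroid(poly)
  x <- poly[, 1] - ctr[1]; y <- poly[, 2] - ctr[2]
  n <- nrow(poly)
  x1 <- c(x[-1], x[1]); y1 <- c(y[-1], y[1])
  a <- x * y1 - x1 * y
  list(
    m00 = sum(a) / 2,
    m20 = sum(a * (x^2 + x * x1 + x1^2)) / 12,
    m02 = sum(a * (y^2 + y * y1 + y1^2)) / 12,
    m11 = sum(a * (2 * x * y + x * y1 + x1 * y + 2 * x1 * y1)) / 24,
    m30 = sum(a * (x^3 + x^2 * x1 + x * x1^2 + x1^3)) / 20,
    m03 = sum(a * (y^3 + y^2 * y1 + y * y1^2 + y1^3)) / 20,
    m21 = sum(a * (3 * x^2 * y + 2 * x * x1 * y + x1^2 * y +
                   x^2 * y1 + 2 * x * x1 * y1 + 3 * x1^2 * y1)) / 60,
    m12 = sum(a * (3 * y^2 * x + 2 * y * y1 * x + y1^2 * x +
                   y^2 * x1 + 2 * y * y1 * x1 + 3 * y1^2 * x1)) / 60
  )
}

#' Hu invariant moments of a filled polygon
#'
#' Seven Hu moments from normalized central moments of the filled shape,
#' computed exactly from the vertex list via Green's theorem. By default
#' values are signed-log compressed,
#' m -> sign(m) log10(1 + |m| 1e6) / 6, for numeric stability.
#'
#' @param poly polygon in microns.
#' @param log_compress if FALSE, raw Hu values are returned.
#' @return Named numeric vector hu1..hu7.
#' @export
invariant_moments <- function(poly, log_compress = TRUE) {
  if (polygon_area(poly) <= 0) stop("polygon area must be positive")
  mm <- polygon_central_moments(poly)
  m00 <- mm$m00
  eta <- function(m, p, q) m / m00^(1 + (p + q) / 2)
  n20 <- eta(mm$m20, 2, 0); n02 <- eta(mm$m02, 0, 2); n11 <- eta(mm$m11, 1, 1)
  n30 <- eta(mm$m30, 3, 0); n03 <- eta(mm$m03, 0, 3)
  n21 <- eta(mm$m21, 2, 1); n12 <- eta(mm$m12, 1, 2)
  h1 <- n20 + n02
  h2 <- (n20 - n02)^2 + 4 * n11^2
  h3 <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h4 <- (n30 + n12)^2 + (n21 + n03)^2
  h5 <- (n30 - 3 * n12) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
        (3 * n21 - n03) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h6 <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
        4 * n11 * (n30 + n12) * (n21 + n03)
  h7 <- (3 * n21 - n03) * (n30 + n12) *
          ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
        (n30 - 3 * n12) * (n21 + n03) *
          (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h <- c(h1, h2, h3, h4, h5, h6, h7)
  if (log_compress) h <- sign(h) * log10(1 + abs(h) * 1e6) / 6
  stats::setNames(h, paste0("hu", 1:7))
}

#' Mean-to-maximum radius ratio of a boundary signal
#' @param b a `boundary_signal`.
#' @return Value in (0, 1].
#' @export
distance_ratio <- function(b) mean(b$radii) / max(b$radii)

#' Divider (compass) dimension of a polygon boundary
#'
#' Walks the densely resampled boundary with rulers at a geometric ladder of
#' lengths; the dimension is the slope of log N(s) against log(1/s), clamped
#' to [1, 2]. Uses inter-point distances only, so it is exactly invariant to
#' rigid motion and to uniform scaling (rulers scale with the perimeter).
#' @keywords internal
boundary_fractal_dim <- function(poly, n_dense = 1024L, n_scales = 5L) {
  b <- resample_boundary(poly, n_dense, check = FALSE)
  pts <- b$points
  per <- polygon_perimeter(poly)
  scales <- per / (2^(seq_len(n_scales) + 2))  # per/8 .. per/128
  counts <- vapply(scales, function(s) {
    cur <- pts[1, ]
    count <- 0L
    for (j in 2:(n_dense + 1L)) {
      pj <- pts[if (j > n_dense) 1L else j, ]
      if (sqrt(sum((pj - cur)^2)) >= s * (1 - 1e-9)) {
        cur <- pj
        count <- count + 1L
      }
    }
    max(count, 1L)
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / scales))
  min(max(unname(stats::coef(fit)[2]), 1), 2)
}

#' All 24 shape descriptors for one lumen polygon
#'
#' Fourier descriptors 1-10, Hu moments 1-7, and seven boundary/convexity
#' ratios. All are invariant to translation and rotation; all but none depend
#' on absolute scale (ratios and normalized descriptors).
#'
#' @param poly lumen polygon in microns.
#' @param cfg `shape` section of [default_config()].
#' @return Named numeric vector of length 24.
#' @export
lumen_shape_descriptors <- function(poly, cfg = default_config()$shape) {
  b <- resample_boundary(poly, cfg$n_boundary)
  fd <- fourier_descriptors(b, cfg$n_fd)
  hu <- invariant_moments(poly, cfg$hu_log_compress)
  r <- b$radii
  hull <- convex_hull_polygon(poly)
  area <- polygon_area(poly)
  per <- polygon_perimeter(poly)
  sm_pred <- (c(r[length(r)], r[-length(r)]) + c(r[-1], r[1])) / 2
  out <- c(
    fd, hu,
    distance_ratio = distance_ratio(b),
    radius_sd_ratio = stats::sd(r) / mean(r),
    area_ratio = area / polygon_area(hull),
    perimeter_ratio = polygon_perimeter(hull) / per,
    smoothness = mean(abs(r - sm_pred)) / mean(r),
    fractal_dim = boundary_fractal_dim(poly),
    circularity = 4 * pi * area / per^2
  )
  stats::setNames(out, SHAPE_DESCRIPTOR_NAMES)
}

#' Aggregate per-lumen values into the four catalog statistics
#'
#' Sample mean, sample SD (denominator n-1, zero for a single value), median,
#' and the ratio of the 5th to the 95th percentile (linear-interpolation
#' percentiles, quantile type 7). Non-finite inputs are dropped; an empty
#' input yields the missing sentinel for all four.
#'
#' @param values numeric vector of per-lumen descriptor values.
#' @return Named numeric vector `mean`, `sd`, `median`, `p5_p95_ratio`.
#' @export
aggregate_stats <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) {
    return(stats::setNames(rep(NA_real_, 4), AGG_STAT_NAMES))
  }
  q <- stats::quantile(v, c(0.05, 0.95), type = 7, names = FALSE)
  ratio <- if (q[2] == 0) NA_real_ else q[1] / q[2]
  s <- if (length(v) == 1) 0 else stats::sd(v)
  stats::setNames(c(mean(v), s, stats::median(v), ratio), AGG_STAT_NAMES)
}

#' Region-level shape feature block (96 features)
#'
#' 24 per-lumen descriptors x 4 aggregation statistics, named
#' `shape:<stat>:<descriptor>`.
#'
#' @param ls a [lumen_set()].
#' @param cfg `shape` section of [default_config()].
#' @return Named numeric vector of length 96.
#' @export
shape_block <- function(ls, cfg = default_config()$shape) {
  nms <- as.vector(t(outer(AGG_STAT_NAMES, SHAPE_DESCRIPTOR_NAMES,
                           function(s, d) paste("shape", s, d, sep = ":"))))
  nms <- sort_block_names(nms)
  out <- stats::setNames(rep(NA_real_, 96), nms)
  if (length(ls$lumens) < 1) return(out)
  desc <- vapply(ls$lumens, function(p) {
    tryCatch(lumen_shape_descriptors(p, cfg),
             error = function(e) stats::setNames(rep(NA_real_, 24),
                                                 SHAPE_DESCRIPTOR_NAMES))
  }, numeric(24))
  for (d in SHAPE_DESCRIPTOR_NAMES) {
    st <- aggregate_stats(desc[d, ])
    out[paste("shape", AGG_STAT_NAMES, d, sep = ":")] <- st
  }
  out
}

# Stable catalog ordering: descriptor-major, statistic-minor.
sort_block_names <- function(nms) {
  parts <- strsplit(nms, ":", fixed = TRUE)
  d <- vapply(parts, `[`, "", 3)
  s <- vapply(parts, `[`, "", 2)
  nms[order(match(d, SHAPE_DESCRIPTOR_NAMES), match(s, AGG_STAT_NAMES))]
}
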