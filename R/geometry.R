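# Planar polygon utilities shared by the segmentation, feature and
# synthetic-data modules. Polygons are two-column matrices (x, y) in microns,
# open form (last vertex != first); image origin is the top-left corner,
# x rightward, y downward. "Counterclockwise" means positive shoelace area in
# these coordinates.

#' Signed polygon area (shoelace)
#'
#' @param p two-column matrix of vertices (open ring).
#' @return Signed area; positive for counterclockwise orientation.
#' @keywords internal
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon area (absolute)
#' @inheritParams polygon_signed_area
#' @return Nonnegative area in squared input units.
#' @export
polygon_area <- function(p) abs(polygon_signed_area(p))

#' Polygon perimeter
#' @inheritParams polygon_signed_area
#' @export
polygon_perimeter <- function(p) {
  d <- p[c(seq_len(nrow(p))[-1], 1), , drop = FALSE] - p
  sum(sqrt(rowSums(d^2)))
}

#' Polygon area centroid
#' @inheritParams polygon_signed_area
#' @return Length-2 numeric (x, y).
#' @export
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(p))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Ensure counterclockwise orientation (positive signed area)
#' @inheritParams polygon_signed_area
#' @keywords internal
polygon_ccw <- function(p) {
  if (polygon_signed_area(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Convex hull of a point set as a polygon
#' @param pts two-column matrix.
#' @return Vertex matrix in counterclockwise order.
#' @keywords internal
convex_hull_polygon <- function(pts) {
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  polygon_ccw(pts[idx, , drop = FALSE])
}

#' Test points for membership in a polygon
#'
#' Thin wrapper over [mgcv::in.out()]; boundary behavior follows that routine.
#'
#' @param pts two-column matrix of query points.
#' @param poly two-column polygon vertex matrix (open ring).
#' @return Logical vector.
#' @export
points_in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, matrix(as.numeric(pts), ncol = 2))
}

#' Check that a polygon ring is simple (non-self-intersecting)
#'
#' O(n^2) segment-pair test; adequate for the <= few-hundred-vertex rings
#' this package produces.
#' @inheritParams polygon_signed_area
#' @return TRUE/FALSE.
#' @keywords internal
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  ax <- a[, 1]; ay <- a[, 2]; bx <- b[, 1]; by <- b[, 2]
  ex <- bx - ax; ey <- by - ay
  # d3[i, j] = cross(e_i, a_j - a_i); d4[i, j] = cross(e_i, b_j - a_i)
  off <- ey * ax - ex * ay
  d3 <- outer(ex, ay) - outer(ey, ax) + off
  d4 <- outer(ex, by) - outer(ey, bx) + off
  crossing <- (t(d3) * t(d4) < 0) & (d3 * d4 < 0)
  ij <- abs(outer(seq_len(n), seq_len(n), "-"))
  adjacent <- ij <= 1 | ij == n - 1
  !any(crossing & !adjacent)
}

#' Clip a polygon by a half-plane (Sutherland–Hodgman step)
#'
#' Keeps the side where `(x - m) . d <= 0`.
#' @param p subject polygon (open ring).
#' @param m point on the dividing line.
#' @param d normal direction (points away from the kept side).
#' @keywords internal
clip_halfplane <- function(p, m, d) {
  n <- nrow(p)
  if (n == 0) return(p)
  s <- (p[, 1] - m[1]) * d[1] + (p[, 2] - m[2]) * d[2]
  keep <- s <= 0
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) out <- rbind(out, p[i, ])
    if (xor(keep[i], keep[j])) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  out
}

#' Clip a polygon to a convex polygon
#' @param p subject polygon.
#' @param clip convex clip polygon (any orientation).
#' @keywords internal
clip_to_convex <- function(p, clip) {
  clip <- polygon_ccw(clip)
  n <- nrow(clip)
  out <- p
  for (i in seq_len(n)) {
    a <- clip[i, ]
    b <- clip[if (i == n) 1L else i + 1L, ]
    e <- b - a
    # interior of a CCW convex polygon lies left of each edge: cross >= 0
    d <- c(e[2], -e[1])  # outward normal for cross(e, x-a) >= 0 convention
    out <- clip_halfplane(out, a, d)
    if (nrow(out) == 0) break
  }
  out
}

#' Points of a set lying on its convex hull boundary
#'
#' Returns indices of points on the hull boundary (vertices and points
#' interior to hull edges). These are exactly the points whose unclipped
#' Voronoi cells are unbounded.
#'
#' @param pts two-column matrix.
#' @param tol absolute distance tolerance in input units.
#' @return Integer index vector.
#' @export
hull_boundary_points <- function(pts, tol = 1e-9) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  hull <- convex_hull_polygon(pts)
  m <- nrow(hull)
  on_bnd <- rep(FALSE, n)
  for (i in seq_len(m)) {
    a <- hull[i, ]
    b <- hull[if (i == m) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    on_bnd <- on_bnd | (dx * dx + dy * dy) <= tol^2
  }
  which(on_bnd)
}

#' Dilate a convex polygon by a disk (Minkowski sum, sampled)
#' @param p convex polygon.
#' @param r disk radius.
#' @param k circle samples per vertex.
#' @keywords internal
dilate_convex <- function(p, r, k = 24L) {
  th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)]
  circ <- cbind(r * cos(th), r * sin(th))
  pts <- do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
    cbind(p[i, 1] + circ[, 1], p[i, 2] + circ[, 2])
  }))
  convex_hull_polygon(pts)
}

#' Rasterize a polygon onto a pixel grid
#'
#' Pixel (row i, col j), 1-based, has center ((j - 0.5) mpp, (i - 0.5) mpp)
#' relative to `origin`.
#'
#' @param poly polygon in microns.
#' @param nrow,ncol raster dimensions.
#' @param mpp microns per pixel.
#' @param origin xy offset of the raster's top-left corner in microns.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(poly, nrow, ncol, mpp = 1, origin = c(0, 0)) {
  xs <- origin[1] + (seq_len(ncol) - 0.5) * mpp
  ys <- origin[2] + (seq_len(nrow) - 0.5) * mpp
  g <- cbind(rep(xs, each = nrow), rep(ys, times = ncol))
  inside <- points_in_polygon(g, poly)
  matrix(inside, nrow = nrow, ncol = ncol)
}

#' Pairwise Euclidean distances between rows
#' @keywords internal
pdist2 <- function(a, b) {
  self <- missing(b)
  if (self) b <- a
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d <- sqrt(pmax(d2, 0))
  if (self) diag(d) <- 0  # clear floating-point noise on the diagonal
  d
}
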