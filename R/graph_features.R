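# Gland-architecture graphs: Delaunay triangulation (Bowyer-Watson), Voronoi
# cells (half-plane intersection, clipped to the annotation), Euclidean MST,
# nearest-neighbor distances, and the 52-feature global architecture block.

#' Delaunay triangulation of a planar point set (Bowyer-Watson)
#'
#' @param pts K x 2 matrix, K >= 3, points distinct and not all collinear.
#' @return Integer matrix of triangles (rows of vertex indices).
#' @export
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  if (anyDuplicated(round(pts, 9))) stop("duplicate points")
  ctr <- colMeans(pts)
  sc <- max(max(apply(pts, 2, function(v) diff(range(v)))), 1e-9)
  p <- sweep(pts, 2, ctr) / sc
  M <- 16
  verts <- rbind(c(0, 3 * M), c(-3 * M, -2 * M), c(3 * M, -2 * M), p)
  circum <- function(t) {
    a <- verts[t[1], ]; b <- verts[t[2], ]; cc <- verts[t[3], ]
    d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) +
              cc[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(c(0, 0, Inf))
    a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(cc^2)
    ux <- (a2 * (b[2] - cc[2]) + b2 * (cc[2] - a[2]) + c2 * (a[2] - b[2])) / d
    uy <- (a2 * (cc[1] - b[1]) + b2 * (a[1] - cc[1]) + c2 * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  tris <- matrix(c(1L, 2L, 3L), ncol = 3)
  cc <- matrix(circum(c(1L, 2L, 3L)), ncol = 3)
  for (ip in 4:(n + 3)) {
    px <- verts[ip, ]
    d2 <- (px[1] - cc[, 1])^2 + (px[2] - cc[, 2])^2
    bad <- which(d2 < cc[, 3] * (1 + 1e-12))
    if (length(bad) == 0) next  # numerically degenerate; skip point
    ed <- rbind(tris[bad, c(1, 2), drop = FALSE],
                tris[bad, c(2, 3), drop = FALSE],
                tris[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    keep_edge <- key %in% names(which(table(key) == 1))
    bnd <- ed[keep_edge, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    newt <- cbind(bnd, ip)
    tris <- rbind(tris, newt)
    cc <- rbind(cc, t(apply(newt, 1, circum)))
  }
  keep <- rowSums(tris <= 3L) == 0
  tris <- tris[keep, , drop = FALSE] - 3L
  # drop degenerate slivers that cocircular ties can leave behind
  areas <- apply(tris, 1, function(t) polygon_area(pts[t, , drop = FALSE]))
  tris[areas > 1e-12 * sc^2, , drop = FALSE]
}

#' Unique undirected edges of a triangle list
#' @keywords internal
triangles_to_edges <- function(tris) {
  ed <- rbind(tris[, c(1, 2), drop = FALSE],
              tris[, c(2, 3), drop = FALSE],
              tris[, c(3, 1), drop = FALSE])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  unique(ed)
}

#' Voronoi cell of one point, clipped to a convex polygon
#'
#' The cell is the intersection of the clip polygon with the half-planes
#' closer to `pts[i, ]` than to every other point.
#' @param pts point set.
#' @param i index of the focal point.
#' @param clip convex polygon.
#' @return Cell polygon (possibly empty matrix).
#' @export
voronoi_cell <- function(pts, i, clip) {
  cell <- polygon_ccw(clip)
  pi_ <- pts[i, ]
  for (j in seq_len(nrow(pts))) {
    if (j == i) next
    pj <- pts[j, ]
    m <- (pi_ + pj) / 2
    d <- pj - pi_           # keep (x - m) . d <= 0, the side nearer p_i
    cell <- clip_halfplane(cell, m, d)
    if (nrow(cell) == 0) break
  }
  cell
}

#' Build the gland-architecture graphs for a lumen set
#'
#' Voronoi cells clipped to the annotation polygon, Delaunay triangulation,
#' Euclidean minimum spanning tree, and 1st/3rd/5th nearest-neighbor
#' distances, all on lumen centroids in microns.
#'
#' @param ls a [lumen_set()].
#' @return List of class `gland_graphs`; `present = FALSE` when fewer than 3
#'   non-collinear centroids exist (dependent features become sentinels).
#' @export
build_graphs <- function(ls) {
  ctr <- lumen_centroids(ls)
  k <- nrow(ctr)
  collinear <- FALSE
  if (k >= 3) {
    cm <- sweep(ctr, 2, colMeans(ctr))
    collinear <- min(svd(cm)$d) < 1e-9 * max(svd(cm)$d, 1)
  }
  if (k < 3 || collinear) {
    return(structure(list(present = FALSE, centroids = ctr),
                     class = "gland_graphs"))
  }
  tris <- delaunay_triangulate(ctr)
  edges <- triangles_to_edges(tris)
  elen <- sqrt(rowSums((ctr[edges[, 1], , drop = FALSE] -
                        ctr[edges[, 2], , drop = FALSE])^2))
  tarea <- apply(tris, 1, function(t) polygon_area(ctr[t, , drop = FALSE]))
  cells <- lapply(seq_len(k), function(i) voronoi_cell(ctr, i, ls$region))
  dm <- pdist2(ctr)
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  mst_edges <- igraph::as_edgelist(mst, names = FALSE)
  mst_len <- igraph::E(mst)$weight
  nn <- t(apply(dm, 1, function(r) {
    s <- sort(r[r > 0])
    vapply(c(1, 3, 5), function(kk) if (length(s) >= kk) s[kk] else NA_real_,
           numeric(1))
  }))
  colnames(nn) <- c("k1", "k3", "k5")
  structure(list(present = TRUE, centroids = ctr,
                 delaunay = list(triangles = tris, edges = edges,
                                 edge_lengths = elen,
                                 triangle_areas = tarea),
                 voronoi = cells,
                 mst = list(edges = mst_edges, lengths = mst_len),
                 nn = nn),
            class = "gland_graphs")
}

graph_agg <- function(values) {
  st <- aggregate_stats(values)
  st
}

#' Global architecture feature block (52 features)
#'
#' Voronoi cell geometry, Delaunay edge/triangle statistics, MST edge
#' lengths, nearest-neighbor distances, and local gland density, each
#' summarized with the four catalog statistics, plus four region-level
#' scalars. Names follow `graph:<family>:<stat>:<metric>`.
#'
#' @param ls a [lumen_set()].
#' @param g optional precomputed [build_graphs()] result.
#' @param cfg `graphs` section of [default_config()].
#' @return Named numeric vector of length 52.
#' @export
global_graph_block <- function(ls, g = NULL, cfg = default_config()$graphs) {
  metrics <- list(
    voronoi = c("cell_area", "cell_perimeter", "cell_chord"),
    delaunay = c("edge_length", "triangle_area"),
    mst = c("edge_length"),
    nn = c("dist_k1", "dist_k3", "dist_k5"),
    density = c("count_r50", "count_r100", "area_frac_r50")
  )
  nms <- unlist(lapply(names(metrics), function(fam) {
    as.vector(vapply(metrics[[fam]], function(m)
      paste("graph", fam, AGG_STAT_NAMES, m, sep = ":"), character(4)))
  }), use.names = FALSE)
  scalars <- paste("graph:density:value",
                   c("gland_count", "glands_per_mm2", "lumen_area_fraction",
                     "median_lumen_area"), sep = ":")
  out <- stats::setNames(rep(NA_real_, 52), c(nms, scalars))
  ctr <- lumen_centroids(ls)
  k <- nrow(ctr)
  region_area <- polygon_area(ls$region)
  areas <- lumen_areas(ls)
  out["graph:density:value:gland_count"] <- k
  if (k > 0) {
    out["graph:density:value:glands_per_mm2"] <- k / (region_area / 1e6)
    out["graph:density:value:lumen_area_fraction"] <- sum(areas) / region_area
    out["graph:density:value:median_lumen_area"] <- stats::median(areas)
  }
  if (k >= 1) {
    dm <- if (k > 1) pdist2(ctr) else matrix(0, 1, 1)
    for (ri in seq_along(cfg$density_radii_um)) {
      r <- cfg$density_radii_um[ri]
      counts <- vapply(seq_len(k), function(i) sum(dm[i, -i] <= r), numeric(1))
      out[paste0("graph:density:", AGG_STAT_NAMES, ":count_r", r)] <-
        aggregate_stats(counts)
    }
    r1 <- cfg$density_radii_um[1]
    afrac <- vapply(seq_len(k), function(i) {
      sum(areas[dm[i, ] <= r1]) / (pi * r1^2)
    }, numeric(1))
    out[paste0("graph:density:", AGG_STAT_NAMES, ":area_frac_r", r1)] <-
      aggregate_stats(afrac)
  }
  if (is.null(g)) g <- build_graphs(ls)
  if (!isTRUE(g$present)) return(out)
  cell_area <- vapply(g$voronoi, function(cp)
    if (nrow(cp) >= 3) polygon_area(cp) else NA_real_, numeric(1))
  cell_per <- vapply(g$voronoi, function(cp)
    if (nrow(cp) >= 3) polygon_perimeter(cp) else NA_real_, numeric(1))
  cell_chord <- vapply(g$voronoi, function(cp) {
    if (nrow(cp) < 2) return(NA_real_)
    max(pdist2(cp))
  }, numeric(1))
  fill <- function(fam, metric, values) {
    out[paste("graph", fam, AGG_STAT_NAMES, metric, sep = ":")] <<-
      aggregate_stats(values)
  }
  fill("voronoi", "cell_area", cell_area)
  fill("voronoi", "cell_perimeter", cell_per)
  fill("voronoi", "cell_chord", cell_chord)
  fill("delaunay", "edge_length", g$delaunay$edge_lengths)
  fill("delaunay", "triangle_area", g$delaunay$triangle_areas)
  fill("mst", "edge_length", g$mst$lengths)
  fill("nn", "dist_k1", g$nn[, "k1"])
  fill("nn", "dist_k3", g$nn[, "k3"])
  fill("nn", "dist_k5", g$nn[, "k5"])
  out
}
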