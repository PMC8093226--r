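# Proximity sub-graph features: connected components of the
# epsilon-neighborhood graph on gland centroids, 17 metrics aggregated by
# {mean, SD, skewness (g1), excess kurtosis (g2)} = 68 features.

SUBGRAPH_METRIC_NAMES <- c(
  "edge_length",                       # pooled over all edges
  "degree",                            # pooled over all nodes
  "node_count", "edge_count", "graph_density", "mean_degree", "max_degree",
  "transitivity", "diameter", "radius", "mean_path_length",
  "eccentricity_mean", "betweenness_mean", "hull_area",
  "mean_edge_length", "max_edge_length", "min_edge_length"
)

SUBGRAPH_STAT_NAMES <- c("mean", "sd", "skewness", "kurtosis")

# Moment-estimator summary: g1 skewness, g2 (Fisher excess) kurtosis; both 0
# by convention for zero-variance or short input.
moment_stats <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0)
    return(stats::setNames(rep(NA_real_, 4), SUBGRAPH_STAT_NAMES))
  m <- mean(v)
  s <- if (n == 1) 0 else stats::sd(v)
  # numerically-degenerate spread counts as zero variance for the
  # higher-moment conventions
  if (s <= 1e-10 * max(1, abs(m)) || n < 3) {
    sk <- 0; ku <- 0
  } else {
    sk <- e1071::skewness(v, type = 1)
    ku <- e1071::kurtosis(v, type = 1)
    if (!is.finite(sk)) sk <- 0
    if (!is.finite(ku)) ku <- 0
  }
  stats::setNames(c(m, s, sk, ku), SUBGRAPH_STAT_NAMES)
}

#' Epsilon-neighborhood graph on lumen centroids
#'
#' Edge between two glands iff centroid distance <= eps, with
#' eps = `eps_factor` x median 1-nearest-neighbor distance (data-adaptive, so
#' the construction is scale-free across gland densities).
#'
#' @param ls a [lumen_set()].
#' @param eps_factor multiplier on the median 1-NN distance.
#' @return List: `graph` (igraph, edges weighted by length), `eps`,
#'   `centroids`.
#' @export
epsilon_graph <- function(ls, eps_factor = 2.0) {
  ctr <- lumen_centroids(ls)
  k <- nrow(ctr)
  if (k == 0) stop("empty lumen set")
  if (k == 1) {
    return(list(graph = igraph::make_empty_graph(1, directed = FALSE),
                eps = 0, centroids = ctr))
  }
  dm <- pdist2(ctr)
  nn1 <- apply(dm + diag(Inf, k), 1, min)
  eps <- eps_factor * stats::median(nn1)
  adj <- (dm <= eps) & (dm > 0)
  w <- dm * adj
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  list(graph = g, eps = eps, centroids = ctr)
}

#' Proximity sub-graph feature block (68 features)
#'
#' 17 metrics over the epsilon-neighborhood graph — pooled edge lengths,
#' pooled node degrees, and 15 per-component topology/geometry metrics —
#' each aggregated by mean, SD, skewness and Fisher excess kurtosis.
#' `subgraph:kurtosis:edge_length` is the excess kurtosis of all edge
#' lengths pooled across components (0 when the variance is 0). Names
#' follow `subgraph:<stat>:<metric>`.
#'
#' @param ls a [lumen_set()].
#' @param cfg `graphs` section of [default_config()].
#' @return Named numeric vector of length 68.
#' @export
subgraph_block <- function(ls, cfg = default_config()$graphs) {
  nms <- as.vector(vapply(SUBGRAPH_METRIC_NAMES, function(m)
    paste("subgraph", SUBGRAPH_STAT_NAMES, m, sep = ":"), character(4)))
  out <- stats::setNames(rep(NA_real_, 68), nms)
  if (length(ls$lumens) < 1) return(out)
  eg <- epsilon_graph(ls, cfg$subgraph_eps_factor)
  g <- eg$graph
  ctr <- eg$centroids
  elen <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else numeric(0)
  out[paste0("subgraph:", SUBGRAPH_STAT_NAMES, ":edge_length")] <-
    moment_stats(elen)
  out[paste0("subgraph:", SUBGRAPH_STAT_NAMES, ":degree")] <-
    moment_stats(igraph::degree(g))
  comp <- igraph::components(g)
  percomp <- lapply(seq_len(comp$no), function(ci) {
    vs <- which(comp$membership == ci)
    sg <- igraph::induced_subgraph(g, vs)
    nv <- igraph::vcount(sg); ne <- igraph::ecount(sg)
    el <- if (ne > 0) igraph::E(sg)$weight else numeric(0)
    dens <- if (nv > 1) ne / (nv * (nv - 1) / 2) else NA_real_
    if (nv > 1) {
      dd <- igraph::distances(sg, weights = igraph::E(sg)$weight)
      finite_off <- dd[upper.tri(dd)][is.finite(dd[upper.tri(dd)])]
      ecc <- apply(dd, 1, function(r) max(r[is.finite(r)]))
      diam <- max(finite_off)
      rad <- min(ecc)
      mpl <- mean(finite_off)
      bet <- mean(igraph::betweenness(sg, weights = igraph::E(sg)$weight))
    } else {
      ecc <- 0; diam <- NA_real_; rad <- NA_real_; mpl <- NA_real_
      bet <- NA_real_
    }
    trans <- igraph::transitivity(sg, type = "global")
    if (!is.finite(trans)) trans <- 0
    hull <- if (nv >= 3) {
      polygon_area(convex_hull_polygon(ctr[vs, , drop = FALSE]))
    } else 0
    c(node_count = nv, edge_count = ne, graph_density = dens,
      mean_degree = mean(igraph::degree(sg)),
      max_degree = max(igraph::degree(sg)),
      transitivity = trans, diameter = diam, radius = rad,
      mean_path_length = mpl, eccentricity_mean = mean(ecc),
      betweenness_mean = bet, hull_area = hull,
      mean_edge_length = if (ne > 0) mean(el) else NA_real_,
      max_edge_length = if (ne > 0) max(el) else NA_real_,
      min_edge_length = if (ne > 0) min(el) else NA_real_)
  })
  cm <- do.call(rbind, percomp)
  for (m in colnames(cm)) {
    out[paste0("subgraph:", SUBGRAPH_STAT_NAMES, ":", m)] <-
      moment_stats(cm[, m])
  }
  out
}
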