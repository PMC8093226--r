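# The full 242-feature morphometric catalog: 96 shape + 52 global
# architecture + 68 proximity sub-graph (216 morphology/architecture
# features from the lumen segmentation) + 26 Haralick texture features from
# the region pixels.

#' The full per-region feature vector (242 features)
#'
#' Concatenates the shape (96), global graph (52), sub-graph (68) and
#' Haralick texture (26) blocks in fixed catalog order. Degenerate inputs
#' (too few glands, missing image) propagate the missing sentinel instead of
#' failing.
#'
#' @param ls a [lumen_set()].
#' @param img optional RGB array at `mpp` um/px for the texture block;
#'   `NULL` leaves texture features at the sentinel.
#' @param mpp microns per pixel of `img`.
#' @param cfg full configuration from [default_config()].
#' @return Named numeric vector of length 242.
#' @export
full_feature_vector <- function(ls, img = NULL, mpp = 1,
                                cfg = default_config()) {
  g <- if (length(ls$lumens) >= 3) build_graphs(ls) else NULL
  c(shape_block(ls, cfg$shape),
    global_graph_block(ls, g, cfg$graphs),
    subgraph_block(ls, cfg$graphs),
    haralick_block(img, ls$region, mpp, cfg$texture))
}

#' The feature catalog
#'
#' @return data.frame with columns `name`, `family`, `statistic`, `metric`
#'   describing all 242 features in catalog order.
#' @export
feature_catalog <- function() {
  empty <- lumen_set(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
                     list(), source = "synthetic", validate = FALSE)
  nms <- names(full_feature_vector(empty))
  parts <- strsplit(nms, ":", fixed = TRUE)
  data.frame(
    name = nms,
    family = vapply(parts, function(p)
      if (p[1] %in% c("shape", "subgraph", "haralick")) p[1]
      else paste(p[1], p[2], sep = ":"), character(1)),
    statistic = vapply(parts, function(p)
      if (p[1] %in% c("shape", "subgraph", "haralick")) p[2] else p[3],
      character(1)),
    metric = vapply(parts, function(p)
      if (p[1] %in% c("shape", "subgraph", "haralick")) p[3] else p[4],
      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Extract features for a whole cohort of lumen sets
#'
#' @param lumen_sets list of [lumen_set()] objects.
#' @param renders optional list of renders (each with `$image`, `$mpp`) for
#'   the texture block.
#' @param cfg configuration list.
#' @return Matrix (regions x 242) with lumen-set region ids as row names.
#' @export
cohort_features <- function(lumen_sets, renders = NULL,
                            cfg = default_config()) {
  rows <- lapply(seq_along(lumen_sets), function(i) {
    img <- if (!is.null(renders)) renders[[i]]$image else NULL
    mpp <- if (!is.null(renders)) renders[[i]]$mpp else 1
    full_feature_vector(lumen_sets[[i]], img, mpp, cfg)
  })
  m <- do.call(rbind, rows)
  ids <- vapply(seq_along(lumen_sets), function(i) {
    id <- lumen_sets[[i]]$region_id
    if (is.null(id)) sprintf("region%03d", i) else id
  }, character(1))
  rownames(m) <- ids
  m
}
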