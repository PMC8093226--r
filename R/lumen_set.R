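# LumenSet: the central container tying a tumor-region annotation to the
# per-lumen boundary polygons, everything in micron coordinates.

#' Construct a lumen set
#'
#' @param region annotation polygon (two-column matrix, microns).
#' @param lumens list of simple lumen polygons (microns).
#' @param source provenance: `"mask"`, `"segmenter"`, or `"synthetic"`.
#' @param region_id optional identifier.
#' @param validate check the container invariants (centroids inside the
#'   region, simple polygons). Disable for hot loops on trusted input.
#' @return Object of class `lumen_set`.
#' @export
lumen_set <- function(region, lumens, source = "mask", region_id = NULL,
                      validate = TRUE) {
  stopifnot(is.matrix(region), ncol(region) == 2)
  lumens <- lapply(lumens, function(p) {
    p <- as.matrix(p)
    colnames(p) <- c("x", "y")
    p
  })
  if (validate && length(lumens) > 0) {
    ctr <- t(vapply(lumens, polygon_centroid, numeric(2)))
    inside <- points_in_polygon(ctr, region)
    if (!all(inside)) {
      stop("lumen centroid(s) outside region polygon: ",
           paste(which(!inside), collapse = ", "))
    }
    simple <- vapply(lumens, polygon_is_simple, logical(1))
    if (!all(simple)) {
      stop("non-simple lumen polygon(s): ",
           paste(which(!simple), collapse = ", "))
    }
  }
  structure(list(region = region, lumens = lumens, source = source,
                 region_id = region_id),
            class = "lumen_set")
}

#' @export
print.lumen_set <- function(x, ...) {
  cat(sprintf("<lumen_set> %s: %d lumens, region area %.0f um^2 (source: %s)\n",
              if (is.null(x$region_id)) "region" else x$region_id,
              length(x$lumens), polygon_area(x$region), x$source))
  invisible(x)
}

#' Lumen centroids of a lumen set
#' @param ls a `lumen_set`.
#' @return K x 2 matrix (x, y) in microns.
#' @export
lumen_centroids <- function(ls) {
  if (length(ls$lumens) == 0) return(matrix(numeric(0), ncol = 2))
  t(vapply(ls$lumens, polygon_centroid, numeric(2)))
}

#' Lumen areas of a lumen set
#' @param ls a `lumen_set`.
#' @return Numeric vector of areas in um^2.
#' @export
lumen_areas <- function(ls) {
  vapply(ls$lumens, polygon_area, numeric(1))
}
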