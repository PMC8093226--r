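# Readers and writers: PNG/TIFF region images, GeoJSON annotations and lumen
# polygon sets, 16-bit label-mask TIFFs, and CSV feature/clinical tables.
# All round-trips are lossless at the documented tolerances.

#' Construct a region image
#'
#' @param pixels h x w x 3 array in \[0, 1\] (8-bit provenance).
#' @param microns_per_pixel positive scalar (um/px).
#' @param region_id identifier.
#' @param site site label.
#' @return Object of class `region_image`.
#' @export
region_image <- function(pixels, microns_per_pixel, region_id = "region",
                         site = "site1") {
  d <- dim(pixels)
  if (length(d) == 2) pixels <- array(rep(pixels, 3), c(d, 3))
  d <- dim(pixels)
  if (d[1] < 32 || d[2] < 32) stop("image must be at least 32 x 32 px")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("microns_per_pixel must be positive")
  structure(list(pixels = pixels, microns_per_pixel = microns_per_pixel,
                 region_id = region_id, site = site),
            class = "region_image")
}

#' @export
print.region_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<region_image> %s: %d x %d px @ %.3g um/px (site %s)\n",
              x$region_id, d[1], d[2], x$microns_per_pixel, x$site))
  invisible(x)
}

#' Read a region image and its annotation polygon
#'
#' The annotation GeoJSON holds micron coordinates; every vertex must fall
#' inside the image bounds after micron-to-pixel conversion.
#'
#' @param image_path PNG or TIFF file.
#' @param annotation_path GeoJSON polygon file.
#' @param microns_per_pixel image resolution (um/px).
#' @param region_id,site metadata carried on the image.
#' @return List: `image` ([region_image()]), `annotation` (vertex matrix,
#'   microns).
#' @export
read_region <- function(image_path, annotation_path, microns_per_pixel,
                        region_id = "region", site = "site1") {
  if (!file.exists(image_path)) stop("unreadable image file: ", image_path)
  px <- if (grepl("\\.png$", image_path, ignore.case = TRUE)) {
    png::readPNG(image_path)
  } else {
    tiff::readTIFF(image_path)
  }
  img <- region_image(px, microns_per_pixel, region_id, site)
  ann <- read_annotation(annotation_path)
  d <- dim(img$pixels)
  w_um <- d[2] * microns_per_pixel
  h_um <- d[1] * microns_per_pixel
  bad <- which(ann[, 1] < 0 | ann[, 1] > w_um | ann[, 2] < 0 | ann[, 2] > h_um)
  if (length(bad) > 0)
    stop("annotation vertex outside image bounds at index ", bad[1])
  list(image = img, annotation = ann)
}

geojson_polygon_feature <- function(poly, props = list()) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  list(type = "Feature", properties = props,
       geometry = list(type = "Polygon",
                       coordinates = list(lapply(seq_len(nrow(ring)),
                                                 function(i) ring[i, ]))))
}

parse_geojson_polygon <- function(geom) {
  ring <- geom$coordinates[[1]]
  m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' Write a single annotation polygon to GeoJSON
#' @param poly vertex matrix in microns.
#' @param path output file.
#' @param region_id identifier stored in the feature properties.
#' @export
write_annotation <- function(poly, path, region_id = "region") {
  fc <- list(type = "FeatureCollection",
             features = list(geojson_polygon_feature(
               poly, list(region_id = region_id))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation polygon from GeoJSON
#' @param path GeoJSON file with at least one Polygon feature.
#' @return Vertex matrix (microns), validated simple with positive area.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("unreadable annotation file: ", path)
  gj <- jsonlite::read_json(path)
  feat <- if (identical(gj$type, "FeatureCollection")) gj$features[[1]] else gj
  poly <- parse_geojson_polygon(feat$geometry)
  if (!polygon_is_simple(poly)) stop("annotation polygon is self-intersecting")
  if (polygon_area(poly) <= 0) stop("annotation polygon has zero area")
  poly
}

#' Write a lumen set (annotation + lumen polygons) to GeoJSON
#' @param ls a [lumen_set()].
#' @param path output file.
#' @export
write_lumen_set <- function(ls, path) {
  feats <- c(
    list(geojson_polygon_feature(ls$region,
                                 list(role = "region",
                                      region_id = ls$region_id,
                                      source = ls$source))),
    lapply(seq_along(ls$lumens), function(i)
      geojson_polygon_feature(ls$lumens[[i]],
                              list(role = "lumen", lumen_id = i)))
  )
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lumen set written by [write_lumen_set()]
#' @param path GeoJSON file.
#' @return A [lumen_set()].
#' @export
read_lumen_set <- function(path) {
  gj <- jsonlite::read_json(path)
  roles <- vapply(gj$features, function(f)
    as.character(f$properties$role %||% "lumen"), character(1))
  region_feat <- gj$features[[which(roles == "region")[1]]]
  region <- parse_geojson_polygon(region_feat$geometry)
  lum <- lapply(gj$features[roles == "lumen"], function(f)
    parse_geojson_polygon(f$geometry))
  src <- region_feat$properties$source %||% "mask"
  rid <- region_feat$properties$region_id
  lumen_set(region, lum, source = src,
            region_id = if (is.null(rid)) NULL else as.character(rid),
            validate = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label mask as 16-bit single-channel TIFF
#' @param mask integer matrix (0 = background, k = lumen k; max 65535).
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535) stop("label overflow for 16-bit mask")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Read a label mask written by [write_mask()]
#' @param path TIFF file.
#' @return Integer label matrix.
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a region image to PNG (8-bit)
#' @param img a [region_image()] or h x w x 3 array in \[0, 1\].
#' @param path output file.
#' @export
write_image <- function(img, path) {
  px <- if (inherits(img, "region_image")) img$pixels else img
  png::writePNG(px, path)
  invisible(path)
}

#' Write a cohort feature table to CSV
#'
#' One header row of feature names, one row per region. All vectors must
#' share one catalog ordering; mixed catalogs are an error.
#'
#' @param features matrix (regions x features, rownames = region ids) or a
#'   named list of equally-named vectors.
#' @param path output CSV.
#' @export
write_feature_table <- function(features, path) {
  if (is.list(features) && !is.data.frame(features)) {
    nms <- lapply(features, names)
    if (length(features) > 1 &&
        !all(vapply(nms[-1], identical, logical(1), nms[[1]])))
      stop("mixed feature catalogs: vectors do not share one ordering")
    features <- do.call(rbind, features)
  }
  df <- data.frame(region_id = rownames(features) %||%
                     sprintf("region%03d", seq_len(nrow(features))),
                   features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV file.
#' @return Matrix with region ids as row names.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a clinical/survival table to CSV
#' @param clinical data.frame of survival records.
#' @param path output CSV.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table from CSV
#' @param path CSV file.
#' @return Validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_clinical(df)
  df
}

validate_clinical <- function(df) {
  req <- c("patient_id", "time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("clinical table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient identifiers")
  if (any(df$time < 0, na.rm = TRUE))
    stop("negative follow-up times")
  if (!all(df$event %in% c(0, 1)))
    stop("event flag must be 0/1")
  invisible(df)
}
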