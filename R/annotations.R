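# Annotation polygons: even-odd point-in-polygon tests, rasterization to
# binary masks, and GeoJSON / scanner-style XML I/O.
#
# Polygons are n x 2 matrices of (x, y) vertices in the image pixel frame
# (0-based pixel centers, x rightward, y downward), implicitly closed.

#' Even-odd point-in-polygon test
#'
#' Crossing-number (even-odd) rule; points exactly on a horizontal edge
#' follow the half-open convention so shared edges are never counted twice.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly n x 2 vertex matrix (x, y), n >= 3.
#' @return logical vector, TRUE where the point is inside.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Construct an annotation set
#'
#' @param polygons list of entries, each `list(label =, vertices =)` where
#'   `vertices` is an n x 2 (x, y) matrix with n >= 3.
#' @param scale_to_map factor applied to vertex coordinates to bring slide
#'   coordinates onto the map grid (1 = already in map coordinates).
#' @return an `annotation_set` object.
#' @export
annotation_set <- function(polygons = list(), scale_to_map = 1) {
  stopifnot(is.list(polygons), scale_to_map > 0)
  for (p in polygons) {
    if (is.null(p$label) || is.null(p$vertices)) {
      stop("each polygon needs a 'label' and a 'vertices' matrix")
    }
    if (nrow(as.matrix(p$vertices)) < 3L) {
      stop("degenerate polygon (label '", p$label, "'): fewer than 3 vertices")
    }
  }
  structure(list(polygons = polygons, scale_to_map = scale_to_map),
            class = "annotation_set")
}

#' Rasterize annotation polygons of one label to a binary mask
#'
#' A pixel is set iff its center (0-based integer coordinates) lies inside
#' any polygon carrying `label`, under the even-odd rule. Vertices are
#' multiplied by the set's `scale_to_map` first.
#'
#' @param ann an [annotation_set()].
#' @param label label to rasterize (e.g. "cortex", "tumor").
#' @param shape integer (h, w) of the target mask.
#' @return logical h x w matrix.
#' @export
polygon_to_mask <- function(ann, label, shape) {
  stopifnot(inherits(ann, "annotation_set"), length(shape) == 2)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  mask <- matrix(FALSE, h, w)
  polys <- Filter(function(p) p$label == label, ann$polygons)
  if (length(polys) == 0L) return(mask)
  xs <- as.vector(col(mask)) - 1
  ys <- as.vector(row(mask)) - 1
  for (p in polys) {
    v <- as.matrix(p$vertices) * ann$scale_to_map
    mask <- mask | matrix(point_in_polygon(xs, ys, v), h, w)
  }
  mask
}

#' Write annotation polygons as GeoJSON
#'
#' One Feature per polygon with the label under `properties$label`.
#'
#' @param ann an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_geojson <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  feats <- lapply(ann$polygons, function(p) {
    v <- as.matrix(p$vertices)
    ring <- rbind(v, v[1, , drop = FALSE])  # closed ring per GeoJSON
    list(
      type = "Feature",
      properties = list(label = p$label),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
      )
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read annotation polygons from GeoJSON
#'
#' Accepts FeatureCollections of Polygon features; only the outer ring is
#' used and the label is taken from `properties$label`.
#'
#' @param path GeoJSON file path.
#' @param scale_to_map factor stored on the returned set.
#' @return an [annotation_set()].
#' @export
read_annotation_geojson <- function(path, scale_to_map = 1) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  polys <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    v <- do.call(rbind, lapply(ring, function(q) c(q[[1]], q[[2]])))
    # drop the closing vertex if present
    if (nrow(v) > 1 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
    list(label = f$properties$label %||% "unlabeled", vertices = v)
  })
  annotation_set(polys, scale_to_map)
}

#' Read scanner-style annotation XML
#'
#' Minimal reader for the renamed scanner annotation dialect: it extracts
#' `<ndpviewstate>` titles and their `<pointlist>` of `<point><x><y>`
#' entries, nothing else.
#'
#' @param path XML file path.
#' @param scale_to_map factor stored on the returned set.
#' @return an [annotation_set()].
#' @export
read_annotation_xml <- function(path, scale_to_map = 1) {
  doc <- xml2::read_xml(path)
  states <- xml2::xml_find_all(doc, ".//ndpviewstate")
  polys <- lapply(states, function(s) {
    title <- xml2::xml_text(xml2::xml_find_first(s, "./title"))
    pts <- xml2::xml_find_all(s, ".//pointlist/point")
    v <- cbind(
      as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "./x"))),
      as.numeric(xml2::xml_text(xml2::xml_find_all(pts, "./y")))
    )
    list(label = if (is.na(title) || !nzchar(title)) "unlabeled" else title,
         vertices = v)
  })
  annotation_set(polys, scale_to_map)
}

# area of a simple polygon (shoelace), in squared vertex units
polygon_area <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  i <- seq_len(n); j <- c(2:n, 1)
  abs(sum(poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2])) / 2
}
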