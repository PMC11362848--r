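# Centroid count maps, disk-kernel density heatmaps (objects per mm^2),
# and multi-resolution block-mean downsampling.

#' Pipeline scale parameters
#'
#' Records the resolution chain of a run: the full-resolution pixel size,
#' the primary downsampling applied before segmentation, the map-level
#' downsampling applied to heatmaps and masks, and the density kernel
#' radius. Derived quantities (map pixel size/area, kernel area) are
#' computed from these and validated for mutual consistency when given
#' explicitly.
#'
#' @param um_per_px full-resolution pixel size (micrometres).
#' @param primary_downsample factor in (0, 1] applied before segmentation
#'   (0.5 in the reference setup).
#' @param map_downsample factor in (0, 1] from the segmentation level to
#'   the map level (0.0125 in the reference setup).
#' @param kernel_radius_px disk kernel radius in segmentation-level pixels
#'   (200 in the reference setup).
#' @param map_pixel_um optional explicit map pixel side (micrometres);
#'   when given it overrides the derived value (scanner exports quote it
#'   directly) and `map_pixel_area_um2` is its square.
#' @return a `pipeline_scales` object with fields `seg_um_per_px`,
#'   `map_pixel_um`, `map_pixel_area_um2`, `kernel_radius_px`,
#'   `kernel_area_mm2` (disk pixel count x pixel area).
#' @export
pipeline_scales <- function(um_per_px = 0.92,
                            primary_downsample = 0.5,
                            map_downsample = 0.0125,
                            kernel_radius_px = 200L,
                            map_pixel_um = NULL) {
  stopifnot(um_per_px > 0,
            primary_downsample > 0, primary_downsample <= 1,
            map_downsample > 0, map_downsample <= 1,
            kernel_radius_px >= 1)
  seg_um <- um_per_px / primary_downsample
  derived_map_um <- seg_um / map_downsample
  map_um <- map_pixel_um %||% derived_map_um
  k <- disk_kernel(kernel_radius_px)
  kernel_area_mm2 <- attr(k, "pixel_count") * (seg_um / 1000)^2
  structure(list(
    um_per_px = um_per_px,
    primary_downsample = primary_downsample,
    map_downsample = map_downsample,
    seg_um_per_px = seg_um,
    map_pixel_um = map_um,
    map_pixel_area_um2 = map_um^2,
    kernel_radius_px = as.integer(kernel_radius_px),
    kernel_pixel_count = attr(k, "pixel_count"),
    kernel_area_mm2 = kernel_area_mm2
  ), class = "pipeline_scales")
}

#' Rasterize centroids into a per-pixel count map
#'
#' @param centroids data.frame / matrix with x, y columns (0-based pixel
#'   coordinates); each centroid is binned to its nearest pixel center.
#' @param shape integer (h, w).
#' @return integer h x w matrix whose sum equals the number of centroids.
#' @export
centroid_count_map <- function(centroids, shape) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  cm <- matrix(0L, h, w)
  if (is.data.frame(centroids)) {
    xs <- centroids$x; ys <- centroids$y
  } else if (length(centroids) == 0L || nrow(as.matrix(centroids)) == 0L) {
    return(cm)
  } else {
    centroids <- as.matrix(centroids)
    xs <- centroids[, 1]; ys <- centroids[, 2]
  }
  if (length(xs) == 0L) return(cm)
  ci <- round(xs) + 1L
  ri <- round(ys) + 1L
  bad <- ci < 1L | ci > w | ri < 1L | ri > h
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("centroid out of range: (%g, %g) for %d x %d map",
                 xs[i], ys[i], h, w))
  }
  idx <- (ci - 1L) * h + ri
  tab <- tabulate(idx, h * w)
  matrix(as.integer(tab), h, w)
}

#' Disk-kernel density map from a centroid count map
#'
#' Convolves the count map with a binary disk kernel and divides by the
#' kernel's physical area (disk pixel count x pixel area), giving objects
#' per mm^2: a single isolated object reads as 1 object per kernel area
#' across its plateau. Zero padding at the frame edge; with
#' `edge = "renormalize"` each centroid's kernel mass is renormalized by
#' the in-frame pixel count at its location, so the total mass (density
#' integrated over the frame) equals the centroid count exactly and rim
#' objects are not under-counted.
#'
#' @param count_map integer matrix from [centroid_count_map()].
#' @param kernel_radius_px disk radius in pixels at this level.
#' @param um_per_px pixel size at this level (micrometres).
#' @param edge "renormalize" (default) or "none".
#' @param marker marker name stored on the map ("nuclei", "NeuN", "Abeta",
#'   "pTau", "Iba1", ...).
#' @return a `density_map`: list with `values` (h x w, per mm^2),
#'   `um_per_px`, `kernel_radius_px`, `kernel_pixel_count`, `marker`.
#' @export
density_from_centroids <- function(count_map, kernel_radius_px, um_per_px,
                                   edge = c("renormalize", "none"),
                                   marker = "nuclei") {
  edge <- match.arg(edge)
  stopifnot(is.matrix(count_map), kernel_radius_px >= 1, um_per_px > 0)
  k <- disk_kernel(kernel_radius_px)
  if (nrow(k) > nrow(count_map) || ncol(k) > ncol(count_map)) {
    stop("kernel larger than image")
  }
  kcount <- attr(k, "pixel_count")
  px_area_mm2 <- (um_per_px / 1000)^2
  cm <- matrix(as.numeric(count_map), nrow(count_map), ncol(count_map))
  if (edge == "renormalize" && sum(cm) > 0) {
    infr <- EBImage::filter2(matrix(1, nrow(cm), ncol(cm)), k, boundary = 0)
    infr <- pmax(round(infr), 1)          # in-frame kernel px per location
    src <- cm * (kcount / infr)           # per-source mass renormalization
  } else {
    src <- cm
  }
  conv <- EBImage::filter2(src, k, boundary = 0)
  vals <- pmax(conv, 0) / (kcount * px_area_mm2)   # clamp FFT round-off
  structure(list(
    values = vals,
    um_per_px = um_per_px,
    kernel_radius_px = as.integer(kernel_radius_px),
    kernel_pixel_count = kcount,
    marker = marker
  ), class = "density_map")
}

#' Downsample a density map (or matrix) by block averaging
#'
#' Aggregates blocks of side `round(1/factor)` by their mean, so a
#' constant map stays constant and the map-wide mean density is preserved
#' up to partial edge blocks. `um_per_px` is rescaled by 1/factor.
#'
#' @param map a `density_map` or plain numeric matrix.
#' @param factor downsampling factor in (0, 1).
#' @return object of the same type at the coarser resolution.
#' @export
downsample_map <- function(map, factor) {
  stopifnot(factor > 0, factor < 1)
  block <- as.integer(round(1 / factor))
  v <- if (inherits(map, "density_map")) map$values else map
  stopifnot(is.matrix(v))
  if (round(nrow(v) * factor) < 1 || round(ncol(v) * factor) < 1) {
    stop("downsampled map smaller than 1 x 1")
  }
  if (inherits(map, "density_map")) {
    out <- map
    out$values <- block_mean(v, block)
    out$um_per_px <- map$um_per_px * block
    return(out)
  }
  block_mean(v, block)
}

#' Downsample a binary mask by block majority
#'
#' Masks are aggregated with the same block grid as [downsample_map()] but
#' thresholded at 50% coverage so they stay binary.
#'
#' @param mask logical matrix.
#' @param factor downsampling factor in (0, 1).
#' @return logical matrix.
#' @export
downsample_mask <- function(mask, factor) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  m <- downsample_map(matrix(as.numeric(mask), nrow(mask), ncol(mask)), factor)
  m >= 0.5
}

#' Write a density map as 32-bit float TIFF
#' @param map a `density_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_density_tiff <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  v <- map$values
  tiff::writeTIFF(v / max(max(v), 1e-12), path, bits.per.sample = 32L)
  invisible(path)
}
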