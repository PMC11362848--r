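# Per-slide stain color model: reference vector estimation from marked
# pixels, blue-channel tissue masking, angle-based pixel classification,
# and projection-threshold segmentation of nuclei and immunostained
# particles.

PIXEL_LABELS <- c(background = 0L, unstained = 1L, hematoxylin = 2L,
                  immunostain = 3L)

#' Classifier parameter set
#'
#' Houses the tunable thresholds of the pixel classifier and segmenter.
#' The two angle thresholds are empirical choices of this package (the
#' method's defining thresholds are the 30% / 40% projection cut-offs);
#' all are exposed for tuning per staining batch.
#'
#' @param angle_threshold_hema_deg,angle_threshold_immuno_deg maximum
#'   color-vector angle (degrees) for a tissue pixel to count as
#'   hematoxylin- / immunostained.
#' @param hema_projection_threshold fraction of the min-max normalized
#'   hematoxylin projection above which pixels enter nucleus segmentation
#'   (default 0.30).
#' @param immuno_projection_threshold as above for the immunostain
#'   (default 0.40).
#' @param erosion_radius_px disk radius of the pre-labeling erosion
#'   (default 1).
#' @param tissue_morph_radius_px disk radius of the erosion + dilation
#'   applied to the raw tissue mask (default 3).
#' @return a `classifier_params` object.
#' @export
classifier_params <- function(angle_threshold_hema_deg = 15,
                              angle_threshold_immuno_deg = 15,
                              hema_projection_threshold = 0.30,
                              immuno_projection_threshold = 0.40,
                              erosion_radius_px = 1L,
                              tissue_morph_radius_px = 3L) {
  stopifnot(hema_projection_threshold > 0, hema_projection_threshold < 1,
            immuno_projection_threshold > 0, immuno_projection_threshold < 1,
            erosion_radius_px >= 0, tissue_morph_radius_px >= 0,
            angle_threshold_hema_deg > 0, angle_threshold_immuno_deg > 0)
  structure(list(
    angle_threshold_hema_deg = angle_threshold_hema_deg,
    angle_threshold_immuno_deg = angle_threshold_immuno_deg,
    hema_projection_threshold = hema_projection_threshold,
    immuno_projection_threshold = immuno_projection_threshold,
    erosion_radius_px = as.integer(erosion_radius_px),
    tissue_morph_radius_px = as.integer(tissue_morph_radius_px)
  ), class = "classifier_params")
}

image_channels <- function(image) {
  stopifnot(is.array(image), length(dim(image)) == 3, dim(image)[3] == 3)
  list(r = image[, , 1], g = image[, , 2], b = image[, , 3])
}

#' Estimate per-slide stain reference vectors
#'
#' Averages the RGB values over operator-marked pixels of each stain
#' (conventionally 10 per class) — the per-slide color reference used by
#' the classifier.
#'
#' @param image h x w x 3 RGB array.
#' @param immuno_px,hema_px n x 2 matrices / data frames of 0-based (x, y)
#'   pixel coordinates, n >= 1 each.
#' @return a `stain_reference`: `immunostain_rgb`, `hematoxylin_rgb`,
#'   `source_pixel_count`.
#' @export
estimate_stain_vectors <- function(image, immuno_px, hema_px) {
  ch <- image_channels(image)
  h <- nrow(ch$r); w <- ncol(ch$r)
  pick <- function(px, what) {
    px <- as.matrix(px)
    if (nrow(px) < 1L) stop("no ", what, " reference pixels given")
    bad <- px[, 1] < 0 | px[, 1] > (w - 1) | px[, 2] < 0 | px[, 2] > (h - 1)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("%s reference pixel out of bounds: (%g, %g)",
                   what, px[i, 1], px[i, 2]))
    }
    idx <- cbind(px[, 2] + 1L, px[, 1] + 1L)
    c(mean(ch$r[idx]), mean(ch$g[idx]), mean(ch$b[idx]))
  }
  structure(list(
    immunostain_rgb = pick(immuno_px, "immunostain"),
    hematoxylin_rgb = pick(hema_px, "hematoxylin"),
    source_pixel_count = c(n_immuno = nrow(as.matrix(immuno_px)),
                           n_hema = nrow(as.matrix(hema_px)))
  ), class = "stain_reference")
}

disk_brush <- function(r) {
  k <- disk_kernel(r)
  attr(k, "pixel_count") <- NULL
  k
}

erode_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  matrix(as.logical(EBImage::erode(m, disk_brush(r))), nrow(mask), ncol(mask))
}

dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  matrix(as.logical(EBImage::dilate(m, disk_brush(r))), nrow(mask), ncol(mask))
}

#' Tissue-on-background mask from the blue channel
#'
#' A pixel is tissue iff its blue value lies below the image-wide blue
#' mean (tissue absorbs light; the bare glass background is bright),
#' followed by one erosion and one dilation with a disk of
#' `tissue_morph_radius_px` to remove speckle.
#'
#' @param image h x w x 3 RGB array.
#' @param params a [classifier_params()].
#' @return logical h x w matrix.
#' @export
tissue_mask <- function(image, params = classifier_params()) {
  b <- image_channels(image)$b
  if (diff(range(b)) == 0) {
    stop("degenerate threshold: blue channel is constant")
  }
  mask <- b < mean(b)
  r <- params$tissue_morph_radius_px
  dilate_mask(erode_mask(mask, r), r)
}

#' Classify tissue pixels by stain color angle
#'
#' For every tissue pixel the angles between its RGB vector and the two
#' stain reference vectors are computed from the normalized dot product
#' (arccos); a pixel is labeled with a stain when that angle is below the
#' stain's threshold and smaller than the competing angle (exact ties go
#' to hematoxylin), otherwise it is unstained. Non-tissue pixels are
#' background. Angles depend only on color direction, so the labeling is
#' invariant to uniform intensity scaling.
#'
#' @param image h x w x 3 RGB array.
#' @param ref a [estimate_stain_vectors()] reference.
#' @param params a [classifier_params()].
#' @param tissue optional precomputed tissue mask; computed via
#'   [tissue_mask()] when NULL.
#' @return integer label matrix (0 background, 1 unstained, 2 hematoxylin,
#'   3 immunostain) of class `pixel_label_map`, with attributes `labels`
#'   and `n_zero_norm` (count of pure-black pixels forced to unstained).
#' @export
classify_pixels <- function(image, ref, params = classifier_params(),
                            tissue = NULL) {
  stopifnot(inherits(ref, "stain_reference"))
  ch <- image_channels(image)
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  stopifnot(all(dim(tissue) == dim(ch$r)))
  norm_px <- sqrt(ch$r^2 + ch$g^2 + ch$b^2)
  angle_to <- function(v) {
    nv <- v / sqrt(sum(v^2))
    dp <- (ch$r * nv[1] + ch$g * nv[2] + ch$b * nv[3]) / pmax(norm_px, .Machine$double.eps)
    acos(clamp(dp, -1, 1)) * 180 / pi
  }
  ah <- angle_to(ref$hematoxylin_rgb)
  ai <- angle_to(ref$immunostain_rgb)
  zero <- norm_px == 0
  lab <- matrix(PIXEL_LABELS[["unstained"]], nrow(tissue), ncol(tissue))
  is_h <- ah <= params$angle_threshold_hema_deg & ah <= ai
  is_i <- ai <= params$angle_threshold_immuno_deg & ai < ah
  lab[is_h] <- PIXEL_LABELS[["hematoxylin"]]
  lab[is_i] <- PIXEL_LABELS[["immunostain"]]
  lab[zero] <- PIXEL_LABELS[["unstained"]]
  lab[!tissue] <- PIXEL_LABELS[["background"]]
  structure(lab, class = c("pixel_label_map", class(lab)),
            labels = PIXEL_LABELS,
            n_zero_norm = sum(zero & tissue))
}

# Absorbance-space projection onto a stain direction: stained pixels load
# positively, the bright background near zero. white = illumination level.
stain_projection <- function(image, stain_rgb, white = 255) {
  ch <- image_channels(image)
  a <- white - stain_rgb
  a <- a / sqrt(sum(a^2))
  (white - ch$r) * a[1] + (white - ch$g) * a[2] + (white - ch$b) * a[3]
}

segment_stain <- function(image, ref, params, stain, tissue, labels) {
  if (is.null(tissue)) tissue <- tissue_mask(image, params)
  if (is.null(labels)) labels <- classify_pixels(image, ref, params, tissue)
  if (stain == "hematoxylin") {
    proj <- stain_projection(image, ref$hematoxylin_rgb)
    want <- labels == PIXEL_LABELS[["hematoxylin"]]
    thr <- params$hema_projection_threshold
  } else {
    proj <- stain_projection(image, ref$immunostain_rgb)
    want <- labels == PIXEL_LABELS[["immunostain"]]
    thr <- params$immuno_projection_threshold
  }
  score <- proj
  score[!want] <- 0
  tv <- score[tissue]
  if (length(tv) == 0L || max(tv) <= min(tv)) {
    return(data.frame(x = numeric(0), y = numeric(0), size = integer(0)))
  }
  norm <- (score - min(tv)) / (max(tv) - min(tv))   # min-max over tissue px
  binary <- norm > thr & tissue & want
  binary <- erode_mask(binary, params$erosion_radius_px)
  if (!any(binary)) {
    return(data.frame(x = numeric(0), y = numeric(0), size = integer(0)))
  }
  component_centroids(label_components(binary))
}

#' Segment hematoxylin-stained nuclei
#'
#' Projects each pixel's absorbance onto the hematoxylin direction,
#' restricted to pixels the angle classifier labeled hematoxylin,
#' min-max-normalizes the score over tissue pixels, thresholds at
#' `hema_projection_threshold` (30%), erodes with a disk of
#' `erosion_radius_px`, and returns one centroid per 8-connected
#' component. Touching nuclei merged into one component yield one
#' centroid — no splitting is attempted.
#'
#' @inheritParams classify_pixels
#' @param labels optional precomputed [classify_pixels()] result.
#' @return data.frame of centroids (0-based `x`, `y`) with component
#'   pixel `size`.
#' @export
segment_nuclei <- function(image, ref, params = classifier_params(),
                           tissue = NULL, labels = NULL) {
  segment_stain(image, ref, params, "hematoxylin", tissue, labels)
}

#' Segment immunostained particles
#'
#' As [segment_nuclei()] but for the immunostain direction at
#' `immuno_projection_threshold` (40%); one component corresponds to one
#' plaque/vessel, one tangle, or one microglial cell depending on the
#' marker.
#'
#' @inheritParams segment_nuclei
#' @return data.frame of centroids (0-based `x`, `y`, `size`).
#' @export
segment_particles <- function(image, ref, params = classifier_params(),
                              tissue = NULL, labels = NULL) {
  segment_stain(image, ref, params, "immunostain", tissue, labels)
}

#' Pick stain-reference pixels from ground truth
#'
#' Emulates the operator marking stained pixels: samples `n` blob-core
#' pixels per class from a synthetic slide's ground-truth centroid lists.
#'
#' @param slide output of [generate_slide()].
#' @param n pixels per class (default 10, the conventional count).
#' @param seed RNG seed.
#' @return list of `immuno_px` and `hema_px` 0-based (x, y) matrices.
#' @export
pick_reference_pixels <- function(slide, n = 10, seed = 1L) {
  core <- function(blobs, k) {
    if (nrow(blobs) == 0L) return(matrix(numeric(0), 0, 2))
    i <- sample(nrow(blobs), k, replace = TRUE)
    cbind(round(blobs$x[i]), round(blobs$y[i]))   # centers = core pixels
  }
  with_local_seed(seed, list(
    immuno_px = core(slide$truth$particle_centroids, n),
    hema_px = core(slide$truth$nucleus_centroids, n)
  ))
}
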