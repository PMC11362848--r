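# Synthetic brightfield IHC slides with exported ground truth.
#
# A slide is rendered as an h x w x 3 array of RGB values in [0, 255]:
# a bright glass background, a faintly absorbing tissue region bounded by
# a polygon, hematoxylin-colored nuclei and DAB-colored immunostained
# particles drawn as anti-aliased disks with per-blob color jitter.

#' Specify a synthetic slide
#'
#' Defaults emulate a typical hematoxylin + DAB brightfield scan: dark
#' blue-purple nuclei and brown immunostained particles on a pale
#' background, with mild per-blob color jitter standing in for staining
#' variability.
#'
#' @param width_px,height_px image size in pixels.
#' @param um_per_px physical pixel size in micrometres.
#' @param nucleus_count,particle_count number of blobs per class.
#' @param nucleus_radius_px,particle_radius_px length-2 radius ranges (px).
#' @param background_rgb,tissue_rgb,hematoxylin_rgb,immunostain_rgb RGB
#'   3-vectors in \[0, 255\]; `tissue_rgb` is the faint tint of unstained
#'   tissue (slightly absorbing, so the blue channel separates tissue from
#'   glass).
#' @param color_jitter_sd per-blob RGB jitter standard deviation.
#' @param tissue_polygon n x 2 (x, y) vertex matrix bounding the tissue;
#'   default is an irregular octagon inset ~6% from the frame.
#' @param nucleus_gradient,particle_gradient linear placement gradients in
#'   \[-1, 1\] along x: 0 = uniform, +1 concentrates blobs to the right,
#'   -1 to the left. Used to construct spatial couplings with known sign.
#' @param seed integer RNG seed; all randomness in [generate_slide()] is
#'   drawn from one stream seeded with it.
#' @return a `slide_spec` object.
#' @export
slide_spec <- function(width_px, height_px,
                       um_per_px = 0.92,
                       nucleus_count = 0L, particle_count = 0L,
                       nucleus_radius_px = c(4, 7),
                       particle_radius_px = c(5, 10),
                       background_rgb = c(245, 243, 240),
                       tissue_rgb = c(228, 216, 206),
                       hematoxylin_rgb = c(70, 60, 130),
                       immunostain_rgb = c(130, 80, 40),
                       color_jitter_sd = 6,
                       tissue_polygon = NULL,
                       nucleus_gradient = 0,
                       particle_gradient = 0,
                       seed = 1L) {
  stopifnot(width_px > 0, height_px > 0, um_per_px > 0,
            nucleus_count >= 0, particle_count >= 0,
            all(nucleus_radius_px >= 1), all(particle_radius_px >= 1),
            color_jitter_sd >= 0,
            abs(nucleus_gradient) <= 1, abs(particle_gradient) <= 1)
  for (v in list(background_rgb, tissue_rgb, hematoxylin_rgb, immunostain_rgb)) {
    stopifnot(length(v) == 3, all(v >= 0), all(v <= 255))
  }
  if (is.null(tissue_polygon)) {
    w <- width_px; h <- height_px
    mx <- 0.06 * w; my <- 0.06 * h
    tissue_polygon <- cbind(
      x = c(mx, 0.45 * w, w - mx, w - mx, 0.80 * w, 0.30 * w, mx),
      y = c(0.25 * h, my, 0.15 * h, 0.78 * h, h - my, h - my, 0.70 * h)
    )
  }
  tissue_polygon <- as.matrix(tissue_polygon)
  stopifnot(nrow(tissue_polygon) >= 3)
  structure(list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    um_per_px = um_per_px,
    nucleus_count = as.integer(nucleus_count),
    particle_count = as.integer(particle_count),
    nucleus_radius_px = sort(as.numeric(nucleus_radius_px)),
    particle_radius_px = sort(as.numeric(particle_radius_px)),
    background_rgb = as.numeric(background_rgb),
    tissue_rgb = as.numeric(tissue_rgb),
    hematoxylin_rgb = as.numeric(hematoxylin_rgb),
    immunostain_rgb = as.numeric(immunostain_rgb),
    color_jitter_sd = color_jitter_sd,
    tissue_polygon = tissue_polygon,
    nucleus_gradient = nucleus_gradient,
    particle_gradient = particle_gradient,
    seed = as.integer(seed)
  ), class = "slide_spec")
}

# circle-circle intersection area
lens_area <- function(d, r1, r2) {
  r1 <- rep_len(r1, length(d)); r2 <- rep_len(r2, length(d))
  rs <- pmin(r1, r2); rl <- pmax(r1, r2)
  out <- numeric(length(d))
  full <- d <= (rl - rs)
  out[full] <- pi * rs[full]^2
  part <- !full & d < (r1 + r2)
  if (any(part)) {
    dd <- d[part]; a <- r1[part]; b <- r2[part]
    out[part] <- a^2 * acos(clamp((dd^2 + a^2 - b^2) / (2 * dd * a), -1, 1)) +
      b^2 * acos(clamp((dd^2 + b^2 - a^2) / (2 * dd * b), -1, 1)) -
      0.5 * sqrt(pmax(0, (-dd + a + b) * (dd + a - b) * (dd - a + b) * (dd + a + b)))
  }
  out
}

# Rejection-sample blob centers inside a polygon with a pairwise overlap cap.
# placed: existing x/y/r matrix the new blobs must also respect.
place_blobs <- function(n, radius_range, poly, w, h, gradient = 0,
                        placed = NULL, max_overlap = 0.3, max_attempts = 1e4) {
  if (n == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), r = numeric(0)))
  }
  bb <- apply(poly, 2, range)
  xs <- ys <- rs <- numeric(0)
  if (!is.null(placed) && nrow(placed) > 0) {
    xs <- placed$x; ys <- placed$y; rs <- placed$r
  }
  n_prior <- length(xs)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      r <- stats::runif(1, radius_range[1], radius_range[2])
      x <- stats::runif(1, bb[1, 1], bb[2, 1])
      y <- stats::runif(1, bb[1, 2], bb[2, 2])
      if (gradient != 0) {
        wgt <- 1 + gradient * (2 * x / (w - 1) - 1)   # in [1-|g|, 1+|g|]
        if (stats::runif(1) > wgt / (1 + abs(gradient))) next
      }
      if (x < r || y < r || x > (w - 1 - r) || y > (h - 1 - r)) next
      if (!point_in_polygon(x, y, poly)) next
      if (length(xs) > 0) {
        d <- sqrt((xs - x)^2 + (ys - y)^2)
        near <- d < (rs + r)
        if (any(near)) {
          ov <- lens_area(d[near], rs[near], r) / (pi * pmin(rs[near], r)^2)
          if (any(ov > max_overlap)) next
        }
      }
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
      ok <- TRUE
      break
    }
    if (!ok) {
      stop(sprintf(
        "overlap saturation: placed %d of %d blobs within %d attempts each",
        i - 1L, n, as.integer(max_attempts)
      ))
    }
  }
  keep <- seq.int(n_prior + 1L, length.out = n)
  data.frame(x = xs[keep], y = ys[keep], r = rs[keep])
}

# window + soft-edge alpha of one disk (anti-aliasing via a Gaussian edge)
disk_window <- function(cx, cy, r, h, w, edge_sd = 0.6) {
  r0 <- max(1L, floor(cy - r - 3) + 1L); r1 <- min(h, ceiling(cy + r + 3) + 1L)
  c0 <- max(1L, floor(cx - r - 3) + 1L); c1 <- min(w, ceiling(cx + r + 3) + 1L)
  rows <- r0:r1; cols <- c0:c1
  d <- sqrt(outer(((rows - 1) - cy)^2, ((cols - 1) - cx)^2, `+`))
  list(rows = rows, cols = cols, alpha = stats::pnorm((r - d) / edge_sd))
}

render_scene <- function(spec, nuclei, particles) {
  h <- spec$height_px; w <- spec$width_px
  tissue <- matrix(
    point_in_polygon(as.vector(col(matrix(0, h, w))) - 1,
                     as.vector(row(matrix(0, h, w))) - 1,
                     spec$tissue_polygon), h, w)
  noise <- matrix(stats::rnorm(h * w, 0, 1.5), h, w)
  # channel planes as plain matrices so disk subassignments stay in place
  Rm <- matrix(spec$background_rgb[1], h, w)
  Gm <- matrix(spec$background_rgb[2], h, w)
  Bm <- matrix(spec$background_rgb[3], h, w)
  Rm[tissue] <- spec$tissue_rgb[1] + noise[tissue]
  Gm[tissue] <- spec$tissue_rgb[2] + noise[tissue]
  Bm[tissue] <- spec$tissue_rgb[3] + noise[tissue]
  blobs <- rbind(
    if (nrow(nuclei) > 0) cbind(nuclei, class = "nucleus"),
    if (nrow(particles) > 0) cbind(particles, class = "particle")
  )
  if (!is.null(blobs) && nrow(blobs) > 0) {
    for (i in seq_len(nrow(blobs))) {
      base <- if (blobs$class[i] == "nucleus") spec$hematoxylin_rgb else spec$immunostain_rgb
      rgb <- clamp(base + stats::rnorm(3, 0, spec$color_jitter_sd), 0, 255)
      win <- disk_window(blobs$x[i], blobs$y[i], blobs$r[i], h, w)
      a <- win$alpha
      Rm[win$rows, win$cols] <- a * rgb[1] + (1 - a) * Rm[win$rows, win$cols]
      Gm[win$rows, win$cols] <- a * rgb[2] + (1 - a) * Gm[win$rows, win$cols]
      Bm[win$rows, win$cols] <- a * rgb[3] + (1 - a) * Bm[win$rows, win$cols]
    }
  }
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- clamp(Rm, 0, 255)
  img[, , 2] <- clamp(Gm, 0, 255)
  img[, , 3] <- clamp(Bm, 0, 255)
  list(image = img, tissue_mask = tissue)
}

#' Generate a synthetic slide with ground truth
#'
#' Renders the scene described by a [slide_spec()] and returns both the
#' image and the exact ground truth (centroids, tissue polygon and mask).
#' Deterministic: the same spec (including its seed) yields a bit-identical
#' image.
#'
#' @param spec a [slide_spec()].
#' @return list with elements `image` (h x w x 3 array in \[0,255\]),
#'   `um_per_px`, and `truth`: a list of `nucleus_centroids` /
#'   `particle_centroids` data frames (columns x, y, r; 0-based pixel
#'   coordinates), `tissue_polygon`, `tissue_mask`, and
#'   `rigid_transform_to_reference` (rotation deg, tx, ty; identity here).
#' @export
generate_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  with_local_seed(spec$seed, {
    nuclei <- place_blobs(spec$nucleus_count, spec$nucleus_radius_px,
                          spec$tissue_polygon, spec$width_px, spec$height_px,
                          gradient = spec$nucleus_gradient)
    particles <- place_blobs(spec$particle_count, spec$particle_radius_px,
                             spec$tissue_polygon, spec$width_px, spec$height_px,
                             gradient = spec$particle_gradient, placed = nuclei)
    scene <- render_scene(spec, nuclei, particles)
    list(
      image = scene$image,
      um_per_px = spec$um_per_px,
      spec = spec,
      truth = list(
        nucleus_centroids = nuclei,
        particle_centroids = particles,
        tissue_polygon = spec$tissue_polygon,
        tissue_mask = scene$tissue_mask,
        rigid_transform_to_reference = c(rotation_deg = 0, tx = 0, ty = 0)
      )
    )
  })
}

#' Generate a serial section of a reference slide
#'
#' Re-renders the reference scene under a small rigid transform (rotation
#' about the image center, then translation), optionally with different
#' stain colors and a fresh, independently placed particle set — emulating
#' a neighbouring section stained for a different marker. Nuclei keep the
#' reference layout (transformed), as adjacent 2 um sections share cells.
#'
#' @param reference output of [generate_slide()].
#' @param transform numeric (rotation_deg, tx_px, ty_px); |rotation| <= 20
#'   and |t| <= 10% of the image size.
#' @param seed RNG seed for jitter (and particle placement if re-placed).
#' @param immunostain_rgb optional replacement immunostain color.
#' @param particles NULL to transform the reference particle layout, or a
#'   list with `count`, `radius_px`, `gradient` to place a fresh set for
#'   the new marker.
#' @return same structure as [generate_slide()];
#'   `truth$rigid_transform_to_reference` records `transform`.
#' @export
generate_serial_section <- function(reference, transform = c(0, 0, 0),
                                    seed = 1L, immunostain_rgb = NULL,
                                    particles = NULL) {
  spec <- reference$spec
  stopifnot(inherits(spec, "slide_spec"), length(transform) == 3)
  rot <- transform[1]; tx <- transform[2]; ty <- transform[3]
  if (abs(rot) > 20) stop("serial-section rotation must be within 20 degrees")
  if (abs(tx) > 0.1 * spec$width_px || abs(ty) > 0.1 * spec$height_px) {
    stop("serial-section translation must be within 10% of the image size")
  }
  tr <- rigid_transform(rot, tx, ty,
                        center = c((spec$width_px - 1) / 2,
                                   (spec$height_px - 1) / 2))
  poly_t <- transform_points(tr, spec$tissue_polygon)
  # refuse transforms that push a substantial part of the tissue off-frame
  spec2 <- spec
  spec2$tissue_polygon <- poly_t
  if (!is.null(immunostain_rgb)) spec2$immunostain_rgb <- as.numeric(immunostain_rgb)
  area_px <- polygon_area(poly_t)
  h <- spec$height_px; w <- spec$width_px
  in_frame <- sum(point_in_polygon(as.vector(col(matrix(0, h, w))) - 1,
                                   as.vector(row(matrix(0, h, w))) - 1, poly_t))
  if (in_frame < 0.9 * area_px) {
    stop(sprintf("transform moves %.1f%% of tissue out of frame (limit 10%%)",
                 100 * (1 - in_frame / area_px)))
  }
  nuclei <- reference$truth$nucleus_centroids
  if (nrow(nuclei) > 0) {
    xy <- transform_points(tr, cbind(nuclei$x, nuclei$y))
    nuclei <- data.frame(x = xy[, 1], y = xy[, 2], r = nuclei$r)
    keep <- nuclei$x >= 0 & nuclei$x <= (w - 1) & nuclei$y >= 0 & nuclei$y <= (h - 1)
    nuclei <- nuclei[keep, , drop = FALSE]
  }
  with_local_seed(seed, {
    if (is.null(particles)) {
      part <- reference$truth$particle_centroids
      if (nrow(part) > 0) {
        xy <- transform_points(tr, cbind(part$x, part$y))
        part <- data.frame(x = xy[, 1], y = xy[, 2], r = part$r)
        keep <- part$x >= 0 & part$x <= (w - 1) & part$y >= 0 & part$y <= (h - 1)
        part <- part[keep, , drop = FALSE]
      }
    } else {
      part <- place_blobs(particles$count %||% 0L,
                          particles$radius_px %||% spec$particle_radius_px,
                          poly_t, w, h,
                          gradient = particles$gradient %||% 0,
                          placed = nuclei)
    }
    scene <- render_scene(spec2, nuclei, part)
    list(
      image = scene$image,
      um_per_px = spec$um_per_px,
      spec = spec2,
      truth = list(
        nucleus_centroids = nuclei,
        particle_centroids = part,
        tissue_polygon = poly_t,
        tissue_mask = scene$tissue_mask,
        rigid_transform_to_reference = c(rotation_deg = rot, tx = tx, ty = ty)
      )
    )
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws i.i.d. semiquantitative patient records whose category
#' distribution follows `prevalence`; the remaining probability mass is
#' assigned to "none". Downstream scores (CERAD, Braak group, CAA,
#' infiltration, APP, axonal-injury) are drawn from plausible conditional
#' distributions consistent with the record's ADNC category.
#'
#' @param n_patients number of records.
#' @param prevalence named probabilities for categories among
#'   `AT`, `T`, `A`, `vascular_only`; must be >= 0 and sum to <= 1.
#' @param age_model numeric (mean, sd) of the age distribution in years
#'   (clamped to 27-92).
#' @param seed RNG seed.
#' @return data.frame of patient records.
#' @export
generate_cohort <- function(n_patients,
                            prevalence = c(AT = 41, T = 37, A = 22,
                                           vascular_only = 7) / 205,
                            age_model = c(mean = 66, sd = 12),
                            seed = 1L) {
  stopifnot(n_patients >= 1)
  allowed <- c("AT", "T", "A", "vascular_only")
  if (is.null(names(prevalence)) || !all(names(prevalence) %in% allowed)) {
    stop("prevalence must be named with categories among: ",
         paste(allowed, collapse = ", "))
  }
  if (any(prevalence < 0) || sum(prevalence) > 1 + 1e-12) {
    stop("invalid probability vector: entries must be >= 0 and sum to <= 1")
  }
  p <- setNames(numeric(4), allowed)
  p[names(prevalence)] <- prevalence
  with_local_seed(seed, {
    cat <- sample(c(allowed, "none"), n_patients, replace = TRUE,
                  prob = c(p, 1 - sum(p)))
    age <- clamp(round(stats::rnorm(n_patients, age_model[1], age_model[2])), 27, 92)
    sex <- sample(c("F", "M"), n_patients, replace = TRUE, prob = c(0.367, 0.633))
    lobe <- sample(c("temporal", "frontal", "parietal", "occipital", NA),
                   n_patients, replace = TRUE,
                   prob = c(0.385, 0.244, 0.127, 0.117, 0.127))
    hemi <- sample(c("R", "L", NA), n_patients, replace = TRUE,
                   prob = c(0.45, 0.35, 0.20))
    has_abeta <- cat %in% c("AT", "A")
    has_ptau <- cat %in% c("AT", "T")
    cerad <- ifelse(has_abeta,
                    sample(c("0", "A", "B", "C"), n_patients, replace = TRUE,
                           prob = c(0.35, 0.2, 0.2, 0.25)),
                    "0")
    braak <- ifelse(has_ptau,
                    sample(c("I-II", "III-IV", "V-VI"), n_patients,
                           replace = TRUE, prob = c(0.2, 0.55, 0.25)),
                    "0")
    amyloid_any <- has_abeta | cat == "vascular_only"
    caa_vessel <- cat == "vascular_only" |
      (amyloid_any & stats::runif(n_patients) < 0.15)
    caa_capillary <- amyloid_any & stats::runif(n_patients) < 0.25
    infiltration <- sample(c("low", "medium", "high"), n_patients, replace = TRUE)
    app_tumor <- sample(c("absent", "sparse", "moderate", "abundant"),
                        n_patients, replace = TRUE,
                        prob = c(0.5, 0.15, 0.18, 0.17))
    app_neuron <- sample(c("sparse", "moderate", "abundant"),
                         n_patients, replace = TRUE, prob = c(0.03, 0.08, 0.89))
    dai <- sample(c("absent", "sparse", "moderate", "frequent"),
                  n_patients, replace = TRUE, prob = c(0.05, 0.35, 0.33, 0.27))
    survival_days <- round(stats::rlnorm(n_patients, log(400), 0.6))
    mgmt <- stats::runif(n_patients) < 0.45
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      age = age, sex = sex, lobe = lobe, hemisphere = hemi,
      adnc_category = cat, cerad = cerad, braak_group = braak,
      caa_vessel = caa_vessel, caa_capillary = caa_capillary,
      infiltration = infiltration, app_tumor = app_tumor,
      app_neuron = app_neuron, dai = dai,
      survival_days = survival_days, mgmt_methylated = mgmt,
      stringsAsFactors = FALSE
    )
  })
}

#' Write a slide image as PNG
#' @param image h x w x 3 array in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Write a slide image as TIFF
#' @inheritParams write_slide_png
#' @export
write_slide_tiff <- function(image, path) {
  tiff::writeTIFF(image / 255, path)
  invisible(path)
}

#' Write ground-truth centroids as CSV (class, x, y)
#' @param truth `truth` element of [generate_slide()] output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centroids_csv <- function(truth, path) {
  df <- rbind(
    if (nrow(truth$nucleus_centroids) > 0)
      data.frame(class = "nucleus", truth$nucleus_centroids[, c("x", "y")]),
    if (nrow(truth$particle_centroids) > 0)
      data.frame(class = "particle", truth$particle_centroids[, c("x", "y")])
  )
  if (is.null(df)) df <- data.frame(class = character(0), x = numeric(0), y = numeric(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
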