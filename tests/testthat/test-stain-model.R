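test_that("stain vectors are arithmetic means of the marked pixels", {
  img <- array(0, dim = c(4, 4, 3))
  img[1, 1, ] <- c(130, 80, 40)
  img[2, 2, ] <- c(130, 80, 40)
  img[3, 3, ] <- c(100, 100, 100)
  img[4, 4, ] <- c(120, 80, 60)
  ref <- estimate_stain_vectors(img,
                                immuno_px = rbind(c(0, 0), c(1, 1)),
                                hema_px = rbind(c(2, 2), c(3, 3)))
  expect_equal(ref$immunostain_rgb, c(130, 80, 40))
  expect_equal(ref$hematoxylin_rgb, c(110, 90, 80))
  expect_equal(unname(ref$source_pixel_count), c(2, 2))

  expect_error(estimate_stain_vectors(img, rbind(c(9, 0)), rbind(c(0, 0))),
               "out of bounds.*\\(9, 0\\)")
  expect_error(estimate_stain_vectors(img, matrix(numeric(0), 0, 2),
                                      rbind(c(0, 0))),
               "no immunostain reference pixels")
})

test_that("estimated vectors on a synthetic slide sit within the jitter", {
  s <- small_slide()
  refs <- pick_reference_pixels(s, n = 10, seed = 4)
  ref <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
  jit <- s$spec$color_jitter_sd
  expect_lt(max(abs(ref$hematoxylin_rgb - s$spec$hematoxylin_rgb)), 2 * jit)
  expect_lt(max(abs(ref$immunostain_rgb - s$spec$immunostain_rgb)), 2 * jit)
})

test_that("tissue mask matches the generating polygon and rejects flat images", {
  s <- small_slide()
  m <- tissue_mask(s$image)
  gt <- s$truth$tissue_mask
  expect_gte(sum(m & gt) / sum(m | gt), 0.95)

  flat <- array(200, dim = c(8, 8, 3))
  expect_error(tissue_mask(flat), "degenerate threshold")
})

test_that("erosion then dilation only nibbles a thin boundary band of a disk", {
  # convex set: opening with a small disk is near-identity
  m <- matrix(FALSE, 64, 64)
  d2 <- (row(m) - 32)^2 + (col(m) - 32)^2
  m[d2 <= 20^2] <- TRUE
  opened <- ihcquant:::dilate_mask(ihcquant:::erode_mask(m, 3), 3)
  changed <- which(xor(opened, m))
  if (length(changed) > 0) {
    ys <- (changed - 1) %% 64 + 1; xs <- (changed - 1) %/% 64 + 1
    rad <- sqrt((ys - 32)^2 + (xs - 32)^2)
    expect_true(all(abs(rad - 20) <= 1.5))
  }
  expect_gt(sum(opened & m) / sum(m), 0.97)
})

test_that("angle classification is exact on reference colors and scale-invariant", {
  ref <- structure(list(immunostain_rgb = c(130, 80, 40),
                        hematoxylin_rgb = c(70, 60, 130),
                        source_pixel_count = c(10, 10)),
                   class = "stain_reference")
  img <- array(0, dim = c(2, 2, 3))
  img[1, 1, ] <- c(70, 60, 130)        # hematoxylin direction
  img[1, 2, ] <- c(65, 40, 20)         # immunostain direction x 0.5
  img[2, 1, ] <- c(200, 200, 200)      # gray: unstained
  img[2, 2, ] <- c(0, 0, 0)            # zero-norm
  tis <- matrix(TRUE, 2, 2)
  lab <- classify_pixels(img, ref, tissue = tis)
  expect_equal(lab[1, 1], 2L)  # hematoxylin
  expect_equal(lab[1, 2], 3L)  # immunostain (angle is scale-invariant)
  expect_equal(lab[2, 1], 1L)  # unstained
  expect_equal(lab[2, 2], 1L)  # zero-norm counted as unstained
  expect_equal(attr(lab, "n_zero_norm"), 1L)

  s <- small_slide()
  tis2 <- tissue_mask(s$image)
  l1 <- classify_pixels(s$image, ref, tissue = tis2)
  l2 <- classify_pixels(s$image * 0.4, ref, tissue = tis2)
  expect_equal(unclass(l1), unclass(l2), ignore_attr = TRUE)
})

test_that("pixel labels partition the image", {
  s <- small_slide()
  refs <- pick_reference_pixels(s, seed = 4)
  ref <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
  tis <- tissue_mask(s$image)
  lab <- classify_pixels(s$image, ref, tissue = tis)
  counts <- table(factor(lab, levels = 0:3))
  expect_equal(sum(counts), length(lab))
  expect_equal(unname(counts[["0"]]), sum(!tis))
})

test_that("core pixels of rendered blobs classify to their stain", {
  s <- small_slide()
  refs <- pick_reference_pixels(s, seed = 4)
  ref <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
  tis <- tissue_mask(s$image)
  lab <- classify_pixels(s$image, ref, tissue = tis)
  core_labels <- function(blobs) {
    unlist(lapply(seq_len(nrow(blobs)), function(i) {
      lab[round(blobs$y[i]) + 1, round(blobs$x[i]) + 1]
    }))
  }
  nuc <- core_labels(s$truth$nucleus_centroids)
  par <- core_labels(s$truth$particle_centroids)
  expect_gte(mean(nuc == 2L), 0.95)
  expect_gte(mean(par == 3L), 0.95)
})

test_that("segmentation recovers counts and centroids on a synthetic slide", {
  s <- small_slide()
  refs <- pick_reference_pixels(s, seed = 4)
  ref <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
  tis <- tissue_mask(s$image)
  lab <- classify_pixels(s$image, ref, tissue = tis)
  nuc <- segment_nuclei(s$image, ref, tissue = tis, labels = lab)
  part <- segment_particles(s$image, ref, tissue = tis, labels = lab)
  expect_lte(abs(nrow(nuc) - 40) / 40, 0.1)
  expect_lte(abs(nrow(part) - 15) / 15, 0.1)
  expect_lt(mean(centroid_errors(nuc, s$truth$nucleus_centroids)), 2)
  expect_lt(mean(centroid_errors(part, s$truth$particle_centroids)), 2)
})

test_that("an empty slide yields empty centroid lists", {
  spec <- slide_spec(100, 100, nucleus_count = 0, particle_count = 0, seed = 2)
  s <- generate_slide(spec)
  ref <- structure(list(immunostain_rgb = c(130, 80, 40),
                        hematoxylin_rgb = c(70, 60, 130),
                        source_pixel_count = c(10, 10)),
                   class = "stain_reference")
  tis <- s$truth$tissue_mask   # blue threshold is valid here; use truth mask
  nuc <- segment_nuclei(s$image, ref, tissue = tis)
  expect_equal(nrow(nuc), 0)
})

test_that("touching nuclei merge into a single centroid", {
  # two blobs fused into one 8-connected component -> one centroid
  spec <- slide_spec(40, 40, seed = 1, color_jitter_sd = 0)
  img <- array(0, dim = c(40, 40, 3))
  for (ch in 1:3) img[, , ch] <- spec$background_rgb[ch]
  for (b in list(c(15, 20), c(21, 20))) {   # centers 6 px apart, radius 5
    win <- ihcquant:::disk_window(b[1], b[2], 5, 40, 40)
    a <- win$alpha
    for (ch in 1:3) {
      img[win$rows, win$cols, ch] <- a * spec$hematoxylin_rgb[ch] +
        (1 - a) * img[win$rows, win$cols, ch]
    }
  }
  ref <- structure(list(immunostain_rgb = c(130, 80, 40),
                        hematoxylin_rgb = c(70, 60, 130),
                        source_pixel_count = c(1, 1)),
                   class = "stain_reference")
  nuc <- segment_nuclei(img, ref)
  expect_equal(nrow(nuc), 1)
  expect_equal(nuc$x, 18, tolerance = 1)
  expect_equal(nuc$y, 20, tolerance = 0.5)
})

test_that("raising a projection threshold never increases component count", {
  s <- small_slide()
  refs <- pick_reference_pixels(s, seed = 4)
  ref <- estimate_stain_vectors(s$image, refs$immuno_px, refs$hema_px)
  tis <- tissue_mask(s$image)
  lab <- classify_pixels(s$image, ref, tissue = tis)
  counts <- vapply(c(0.3, 0.4, 0.5, 0.7), function(th) {
    p <- classifier_params(immuno_projection_threshold = th)
    nrow(segment_particles(s$image, ref, p, tis, lab))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("component labeling matches a flood-fill oracle on small rasters", {
  set.seed(42)
  for (k in 1:10) {
    m <- matrix(runif(32 * 32) < 0.35, 32, 32)
    lab <- label_components(m)
    oracle <- flood_label_oracle(m)
    expect_equal(max(lab), max(oracle))
    # same partition: label pairs must be in bijection
    key <- paste(lab[m], oracle[m])
    expect_equal(length(unique(key)), max(oracle))
    cent <- component_centroids(lab)
    cent_o <- component_centroids(oracle)
    expect_equal(cent[order(cent$x, cent$y), c("x", "y", "size")],
                 cent_o[order(cent_o$x, cent_o$y), c("x", "y", "size")],
                 ignore_attr = TRUE)
  }
})
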