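test_that("empty spec renders pure background with empty ground truth", {
  spec <- slide_spec(64, 64, nucleus_count = 0, particle_count = 0, seed = 1)
  s <- generate_slide(spec)
  expect_equal(nrow(s$truth$nucleus_centroids), 0)
  expect_equal(nrow(s$truth$particle_centroids), 0)
  # outside the tissue polygon the image is exactly the background color
  out <- !s$truth$tissue_mask
  expect_true(all(s$image[, , 1][out] == spec$background_rgb[1]))
  expect_true(all(s$image[, , 3][out] == spec$background_rgb[3]))
})

test_that("generation is deterministic for a fixed seed", {
  spec <- slide_spec(200, 200, nucleus_count = 200, particle_count = 30, seed = 1)
  a <- generate_slide(spec)
  b <- generate_slide(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$nucleus_centroids, b$truth$nucleus_centroids)
  spec2 <- spec; spec2$seed <- 2L
  expect_false(identical(generate_slide(spec2)$image, a$image))
})

test_that("ground truth lists exactly the requested blobs, placed uniformly", {
  spec <- slide_spec(512, 512, nucleus_count = 150, seed = 11)
  s <- generate_slide(spec)
  expect_equal(nrow(s$truth$nucleus_centroids), 150)
  cc <- s$truth$nucleus_centroids
  expect_true(all(point_in_polygon(cc$x, cc$y, spec$tissue_polygon)))
  # mean nearest-neighbour spacing vs direct resampling of the placement
  nn_mean <- function(df) {
    d <- as.matrix(dist(df[, c("x", "y")]))
    diag(d) <- Inf
    mean(apply(d, 1, min))
  }
  obs <- nn_mean(cc)
  ref <- vapply(1:20, function(k) {
    sp <- spec; sp$seed <- 1000L + k
    nn_mean(generate_slide(sp)$truth$nucleus_centroids)
  }, numeric(1))
  # observed spacing within the resampled spread (generous band)
  expect_gt(obs, min(ref) - 3 * sd(ref))
  expect_lt(obs, max(ref) + 3 * sd(ref))
})

test_that("blob colors honour the color contract", {
  s <- small_slide()
  spec <- s$spec
  img <- s$image
  mean_rgb_at <- function(b) {
    # average over the blob core (half radius)
    rows <- round(b$y) + 1 + seq(-1, 1)
    cols <- round(b$x) + 1 + seq(-1, 1)
    c(mean(img[rows, cols, 1]), mean(img[rows, cols, 2]), mean(img[rows, cols, 3]))
  }
  for (i in seq_len(min(10, nrow(s$truth$nucleus_centroids)))) {
    v <- mean_rgb_at(s$truth$nucleus_centroids[i, ])
    expect_lt(sum((v - spec$hematoxylin_rgb)^2), sum((v - spec$immunostain_rgb)^2))
  }
  for (i in seq_len(min(10, nrow(s$truth$particle_centroids)))) {
    v <- mean_rgb_at(s$truth$particle_centroids[i, ])
    expect_lt(sum((v - spec$immunostain_rgb)^2), sum((v - spec$hematoxylin_rgb)^2))
  }
})

test_that("impossible packing fails naming the achieved count", {
  spec <- slide_spec(60, 60, nucleus_count = 500, nucleus_radius_px = c(6, 8),
                     seed = 1)
  expect_error(generate_slide(spec), "overlap saturation: placed \\d+ of 500")
})

test_that("serial sections record and apply the rigid transform", {
  spec <- slide_spec(256, 256, nucleus_count = 120, particle_count = 20, seed = 5)
  ref <- generate_slide(spec)
  ser <- generate_serial_section(ref, transform = c(5, 10, -7), seed = 2)
  expect_equal(unname(ser$truth$rigid_transform_to_reference),
               c(5, 10, -7))
  # centroids match the closed-form rigid map of the reference centroids
  tr <- rigid_transform(3, 0, 0, c((256 - 1) / 2, (256 - 1) / 2))
  ser3 <- generate_serial_section(ref, transform = c(3, 0, 0), seed = 2)
  mapped <- transform_points(tr, as.matrix(ref$truth$nucleus_centroids[, c("x", "y")]))
  keep <- mapped[, 1] >= 0 & mapped[, 1] <= 255 & mapped[, 2] >= 0 & mapped[, 2] <= 255
  expect_equal(nrow(ser3$truth$nucleus_centroids), sum(keep))
  err <- sqrt(rowSums((as.matrix(ser3$truth$nucleus_centroids[, c("x", "y")]) -
                         mapped[keep, , drop = FALSE])^2))
  expect_lt(max(err), 0.5)
})

test_that("identity serial section reproduces the reference layout", {
  spec <- slide_spec(128, 128, nucleus_count = 30, seed = 8)
  ref <- generate_slide(spec)
  ser <- generate_serial_section(ref, transform = c(0, 0, 0), seed = 99)
  expect_equal(ser$truth$nucleus_centroids$x, ref$truth$nucleus_centroids$x,
               tolerance = 1e-12)
  # same layout, different jitter seed: images close but not identical
  expect_false(identical(ser$image, ref$image))
})

test_that("transforms pushing tissue off-frame are rejected", {
  # tissue filling the frame: a 10% shift moves ~19% of it off-frame
  full <- rbind(c(0, 0), c(199, 0), c(199, 199), c(0, 199))
  spec <- slide_spec(200, 200, tissue_polygon = full, seed = 1)
  ref <- generate_slide(spec)
  expect_error(generate_serial_section(ref, transform = c(0, 20, 20)),
               "out of frame")
  expect_error(generate_serial_section(ref, transform = c(45, 0, 0)),
               "rotation")
  expect_error(generate_serial_section(ref, transform = c(0, 30, 0)),
               "10%")
})

test_that("cohort categories follow the requested prevalences", {
  co <- generate_cohort(10, prevalence = c(AT = 0, T = 0, A = 0,
                                           vascular_only = 0), seed = 1)
  expect_true(all(co$adnc_category == "none"))

  # the observed study-scale fractions: sampled shares within 95% binomial CI
  prev <- c(AT = 0.20, T = 0.18, A = 0.11, vascular_only = 0.03)
  co <- generate_cohort(205, prevalence = prev, seed = 7)
  for (cat in names(prev)) {
    k <- sum(co$adnc_category == cat)
    ci <- qbinom(c(0.025, 0.975), 205, prev[[cat]])
    expect_gte(k, ci[1])
    expect_lte(k, ci[2])
  }

  # law of large numbers at n = 1e5
  co <- generate_cohort(1e5, prevalence = c(AT = 0.2), seed = 3)
  expect_lt(abs(mean(co$adnc_category == "AT") - 0.2), 0.01)

  expect_error(generate_cohort(10, prevalence = c(AT = 0.9, T = 0.3)),
               "invalid probability")
  expect_error(generate_cohort(10, prevalence = c(bogus = 0.1)), "named")
})

test_that("slide and ground-truth writers round-trip", {
  s <- generate_slide(slide_spec(48, 48, nucleus_count = 5, particle_count = 3,
                                 seed = 2))
  png_path <- withr::local_tempfile(fileext = ".png")
  write_slide_png(s$image, png_path)
  back <- png::readPNG(png_path) * 255
  expect_equal(dim(back), dim(s$image))
  expect_lt(max(abs(back - s$image)), 0.51)  # 8-bit quantization only

  csv_path <- withr::local_tempfile(fileext = ".csv")
  write_centroids_csv(s$truth, csv_path)
  df <- read.csv(csv_path)
  expect_equal(nrow(df), 8)
  expect_equal(sum(df$class == "nucleus"), 5)

  gj <- withr::local_tempfile(fileext = ".geojson")
  ann <- annotation_set(list(list(label = "cortex",
                                  vertices = s$truth$tissue_polygon)))
  write_annotation_geojson(ann, gj)
  ann2 <- read_annotation_geojson(gj)
  expect_equal(ann2$polygons[[1]]$label, "cortex")
  expect_equal(ann2$polygons[[1]]$vertices, unname(s$truth$tissue_polygon),
               tolerance = 1e-9)
})
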